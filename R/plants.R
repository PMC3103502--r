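#' Musculoskeletal model (MSM) parameters
#'
#' Parameter vector of the third-order linearized musculoskeletal plant: a
#' one-degree-of-freedom segment driven by a Hill-type muscle consisting of a
#' visco-elastic contractile element (CE stiffness `k_ce` in parallel with CE
#' damping `b_ce`) in series with an elastic tendon (SE stiffness `k_se`).
#'
#' `k_ce` may be negative (muscles above optimum length operate on the
#' descending limb of the force-length curve), but `k_ce + k_se` must not
#' vanish when `b_ce = 0`, otherwise the plant is degenerate.
#'
#' @param k_ce CE stiffness, Nm/rad.
#' @param b_ce CE damping, Nms/rad (non-negative).
#' @param k_se SE (tendon) stiffness, Nm/rad (positive).
#' @param inertia segment inertia, kg m^2 (positive).
#' @return An object of class `msm_params`.
#' @examples
#' p <- msm_params(32, 3.2, 100, 0.1)
#' msm_impedance(p)
#' @export
msm_params <- function(k_ce, b_ce, k_se, inertia) {
  stopifnot(is.numeric(k_ce), length(k_ce) == 1L, is.finite(k_ce),
            is.numeric(b_ce), length(b_ce) == 1L, is.finite(b_ce),
            is.numeric(k_se), length(k_se) == 1L, is.finite(k_se),
            is.numeric(inertia), length(inertia) == 1L, is.finite(inertia))
  if (b_ce < 0) stop("b_ce must be non-negative")
  if (k_se <= 0) stop("k_se must be positive")
  if (inertia <= 0) stop("inertia must be positive")
  if (b_ce == 0 && k_ce + k_se == 0)
    stop("degenerate plant: b_ce = 0 and k_ce + k_se = 0")
  structure(list(k_ce = k_ce, b_ce = b_ce, k_se = k_se, inertia = inertia),
            class = "msm_params")
}

#' Stiffness-damping-inertia (KBI) model parameters
#'
#' Parameter vector of the second-order model conventionally fitted to joint
#' perturbation responses: a spring `k` and damper `b` in parallel, acting on
#' a segment of inertia `inertia`. Impedance `Z(s) = I s^2 + B s + K`.
#'
#' `k` and `b` are unconstrained in sign: fits are free to return negative
#' values and the sign is part of the result.
#'
#' @param k stiffness, Nm/rad.
#' @param b damping, Nms/rad.
#' @param inertia inertia, kg m^2 (positive).
#' @return An object of class `kbi_params`.
#' @export
kbi_params <- function(k, b, inertia) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k),
            is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(inertia), length(inertia) == 1L, is.finite(inertia))
  if (inertia <= 0) stop("inertia must be positive")
  structure(list(k = k, b = b, inertia = inertia), class = "kbi_params")
}

#' @export
print.msm_params <- function(x, ...) {
  cat(sprintf(
    "MSM plant: K_CE = %g Nm/rad, B_CE = %g Nms/rad, K_SE = %g Nm/rad, I = %g kg m^2\n",
    x$k_ce, x$b_ce, x$k_se, x$inertia))
  invisible(x)
}

#' @export
print.kbi_params <- function(x, ...) {
  cat(sprintf("KBI model: K = %g Nm/rad, B = %g Nms/rad, I = %g kg m^2\n",
              x$k, x$b, x$inertia))
  invisible(x)
}

# rational function of the Laplace variable, coefficient vectors in
# descending powers of s, with leading zeros stripped
new_impedance <- function(num, den, label) {
  num <- strip_leading_zeros(num)
  den <- strip_leading_zeros(den)
  if (length(den) == 0L || all(den == 0))
    stop("invalid plant: impedance denominator is identically zero")
  structure(list(num = num, den = den, label = label), class = "impedance")
}

strip_leading_zeros <- function(x, tol = 0) {
  i <- 1L
  while (i < length(x) && abs(x[i]) <= tol) i <- i + 1L
  x[i:length(x)]
}

#' @export
print.impedance <- function(x, ...) {
  fmt <- function(co) paste(signif(co, 6), collapse = " ")
  cat(sprintf("Impedance %s(s): num [%s] / den [%s]  (descending powers of s)\n",
              x$label, fmt(x$num), fmt(x$den)))
  invisible(x)
}

#' MSM impedance
#'
#' Torque-per-angle transfer function of the musculoskeletal plant in the
#' Laplace domain,
#' \deqn{Z(s) = I s^2 + \frac{K_{SE}(K_{CE} + B_{CE} s)}{K_{CE} + K_{SE} + B_{CE} s},}
#' i.e. segment inertia in parallel (at the joint) with the series connection
#' of the tendon spring and the visco-elastic CE. The joint angle response to
#' a torque input is governed by the admittance `1/Z(s)`, which is third
#' order (second order when `b_ce = 0`, in which case the common factor is
#' cancelled exactly).
#'
#' @param p an [msm_params()] object.
#' @return An `impedance` object: numerator and denominator coefficient
#'   vectors in descending powers of `s`.
#' @export
msm_impedance <- function(p) {
  stopifnot(inherits(p, "msm_params"))
  I <- p$inertia; kce <- p$k_ce; bce <- p$b_ce; kse <- p$k_se
  if (bce == 0) {
    # two springs in series: exactly second order, the (k_ce + k_se) factor
    # is cancelled symbolically rather than left as a pole-zero pair
    new_impedance(c(I, 0, kse * kce / (kce + kse)), 1, "Z_MSM")
  } else {
    new_impedance(c(I * bce, I * (kce + kse), kse * bce, kse * kce),
                  c(bce, kce + kse), "Z_MSM")
  }
}

#' KBI impedance
#'
#' `Z(s) = I s^2 + B s + K`, the impedance of the second-order
#' stiffness-damping-inertia model.
#'
#' @param p a [kbi_params()] object.
#' @return An `impedance` object.
#' @export
kbi_impedance <- function(p) {
  stopifnot(inherits(p, "kbi_params"))
  new_impedance(c(p$inertia, p$b, p$k), 1, "Z_KBI")
}

#' Evaluate an impedance at given Laplace-variable values
#'
#' @param z an `impedance` object.
#' @param s numeric or complex vector of Laplace-variable values.
#' @return Complex (or numeric) vector `Z(s)`.
#' @export
eval_impedance <- function(z, s) {
  stopifnot(inherits(z, "impedance"))
  polyval_asc(rev(z$num), s) / polyval_asc(rev(z$den), s)
}

# ascending-coefficient Horner evaluation, works for complex s
polyval_asc <- function(coef_asc, s) {
  out <- rep(coef_asc[length(coef_asc)], length(s))
  if (length(coef_asc) > 1L)
    for (i in (length(coef_asc) - 1L):1L) out <- out * s + coef_asc[i]
  out
}

# admittance 1/Z as a strictly proper rational function; the plants used
# here always have deg(den of Z) < deg(num of Z)
admittance <- function(z) {
  stopifnot(inherits(z, "impedance"))
  num <- z$den
  den <- z$num
  if (length(num) >= length(den))
    stop("improper admittance: joint response would not be strictly proper")
  list(num = num, den = den)
}
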