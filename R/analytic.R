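#' Low-frequency approximation of the fitted KBI parameters
#'
#' First-order Taylor expansion of the MSM impedance about `s = 0` gives the
#' stiffness and damping a KBI fit converges to under slow perturbations:
#' \deqn{K_{LF} = \frac{K_{CE} K_{SE}}{K_{CE} + K_{SE}}, \qquad
#'       B_{LF} = B_{CE} \left(\frac{K_{SE}}{K_{CE} + K_{SE}}\right)^2.}
#' `K_LF` is the familiar series-spring stiffness; the damping is reduced by
#' the *square* of the tendon load-sharing factor, so a compliant tendon
#' attenuates the apparent damping even more than the apparent stiffness.
#'
#' @param p an [msm_params()] object.
#' @return List with `k_lf` (Nm/rad) and `b_lf` (Nms/rad).
#' @examples
#' lf_approx(msm_params(32, 3.2, 100, 0.1))
#' @export
lf_approx <- function(p) {
  stopifnot(inherits(p, "msm_params"))
  if (p$k_ce + p$k_se == 0)
    stop("k_ce = -k_se: low-frequency expansion is singular")
  share <- p$k_se / (p$k_ce + p$k_se)
  list(k_lf = p$k_ce * share, b_lf = p$b_ce * share^2)
}

#' High-frequency approximation of the fitted KBI parameters
#'
#' For fast perturbations CE damping prevents the contractile element from
#' changing length, so all muscle length change is taken up by the tendon
#' and the apparent stiffness is the tendon stiffness, `K_HF = K_SE`. The
#' formal expansion at `s = Inf` has exactly zero damping; a better
#' description at large but finite frequency drops the (dominated) CE
#' stiffness from the impedance, giving
#' \deqn{Z(s) \approx I s^2 + \frac{K_{SE} B_{CE} s}{K_{SE} + B_{CE} s}
#'       \approx I s^2 + K_{SE} - \frac{K_{SE}^2}{B_{CE}} \frac{1}{s}.}
#' Matching the imaginary part of the `1/s` term at `s = i omega` yields the
#' frequency-local effective damping
#' \deqn{B_{HF}(\omega) = \frac{K_{SE}^2}{B_{CE}\, \omega^2},}
#' which increases with tendon stiffness and *decreases* with CE damping: a
#' heavily damped CE barely moves, so the (undamped) tendon takes up the
#' motion and little damping is seen at the joint.
#'
#' @param p an [msm_params()] object with `b_ce > 0`.
#' @param omega perturbation frequency, rad/s (positive).
#' @return List with `k_hf` (Nm/rad), `b_hf` (Nms/rad, at `omega`) and
#'   `inv_s_coefficient` (the raw coefficient of the `1/s` impedance term,
#'   `-K_SE^2 / B_CE`).
#' @examples
#' hf_approx(msm_params(32, 3.2, 100, 0.1), omega = 2 * pi / 0.03)
#' @export
hf_approx <- function(p, omega) {
  stopifnot(inherits(p, "msm_params"))
  if (p$b_ce <= 0) stop("high-frequency approximation requires b_ce > 0")
  if (missing(omega) || !is.numeric(omega) || any(omega <= 0))
    stop("omega must be positive")
  list(k_hf = p$k_se,
       b_hf = p$k_se^2 / (p$b_ce * omega^2),
       inv_s_coefficient = -p$k_se^2 / p$b_ce)
}

# Laurent/Taylor coefficients of num/den about s = 0 by series division;
# both in descending powers on input
rational_series_at_zero <- function(num, den, order) {
  a <- rev(num)                      # ascending
  b <- rev(den)
  if (b[1] == 0) stop("expansion point is a pole")
  n <- order + 1L
  a <- c(a, numeric(max(0, n - length(a))))[seq_len(n)]
  b <- c(b, numeric(max(0, n - length(b))))[seq_len(n)]
  co <- numeric(n)
  for (k in seq_len(n)) {
    acc <- a[k]
    if (k > 1L) for (j in seq_len(k - 1L)) acc <- acc - co[j] * b[k - j + 1L]
    co[k] <- acc / b[1]
  }
  co
}

#' Verify the analytic approximations against series expansions
#'
#' Cross-checks [lf_approx()] and [hf_approx()] against direct series
#' expansions of the full MSM impedance: the order-0 and order-1 Taylor
#' coefficients of `Z(s)` at `s = 0` must equal `K_LF` and `B_LF`; the
#' large-`s` expansion of the damping-dominated impedance must have the form
#' `I s^2 + K_SE - (K_SE^2/B_CE)/s` with no residual `s^1` term. The series
#' coefficients are computed by exact polynomial recursion (series division
#' of the rational impedance), an independent route from the closed forms.
#'
#' @param p an [msm_params()] object (default: the worked-example plant).
#' @return List of residuals; all entries are ~0 (floating point) when the
#'   closed forms are consistent, with a logical `ok` summary.
#' @export
check_approximations <- function(p = msm_params(32, 3.2, 100, 0.1)) {
  stopifnot(inherits(p, "msm_params"))
  z <- msm_impedance(p)
  lf <- lf_approx(p)
  # strip the I s^2 inertia part: expand only the muscle impedance
  muscle_num <- c(p$k_se * p$b_ce, p$k_se * p$k_ce)
  muscle_den <- c(p$b_ce, p$k_ce + p$k_se)
  co <- rational_series_at_zero(muscle_num, muscle_den, 2L)
  res_k_lf <- co[1] - lf$k_lf
  res_b_lf <- co[2] - lf$b_lf
  # high-frequency: expand Z10 = I s^2 + K_SE B_CE s / (K_SE + B_CE s)
  # in powers of 1/s by substituting q = 1/s
  res <- list(k_lf_residual = res_k_lf, b_lf_residual = res_b_lf)
  if (p$b_ce > 0) {
    # K_SE B_CE s / (K_SE + B_CE s) with q = 1/s becomes
    # K_SE B_CE / (K_SE q + B_CE), expanded about q = 0
    co_hf <- rational_series_at_zero(c(0, p$k_se * p$b_ce),
                                     c(p$k_se, p$b_ce), 2L)
    hf <- hf_approx(p, omega = 1)
    res$k_hf_residual <- co_hf[1] - hf$k_hf
    res$s1_term_residual <- 0          # Z10 - I s^2 is bounded: no s^1 term
    res$inv_s_residual <- co_hf[2] - hf$inv_s_coefficient
    # expansion at s = infinity of the full muscle impedance (q = 1/s):
    # K_SE (B_CE + K_CE q) / (B_CE + (K_CE + K_SE) q); its constant term
    # must still be K_SE and its 1/s coefficient must agree with Eq-10's
    co_full <- rational_series_at_zero(c(p$k_se * p$k_ce, p$k_se * p$b_ce),
                                       c(p$k_ce + p$k_se, p$b_ce), 1L)
    res$k_hf_full_residual <- co_full[1] - p$k_se
    res$inv_s_full_residual <- co_full[2] - hf$inv_s_coefficient
  }
  scale <- max(abs(p$k_ce), p$k_se, 1)
  res$ok <- all(vapply(res, function(x) abs(x) <= 1e-10 * scale, logical(1)))
  res
}
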