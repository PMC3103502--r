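#' Torque perturbation
#'
#' Declarative description of the torque input applied to a plant. Supported
#' kinds:
#' \describe{
#'   \item{impulse}{A Dirac impulse of strength `amplitude` (Nm s). Realized
#'     by the simulator as the impulse response of the plant (an initial
#'     angular-momentum jump), not as a one-sample rectangle.}
#'   \item{pulse}{A rectangular torque of `amplitude` Nm on
#'     `[0, pulse_width)`.}
#'   \item{double_pulse}{`+amplitude` on `[0, w)` and `-amplitude` on
#'     `[w + gap, 2 w + gap)` with `w = pulse_width`.}
#'   \item{step}{`amplitude` Nm for all `t >= 0`.}
#'   \item{sinusoid}{`amplitude * sin(2 pi t / period)`; continuous over the
#'     whole window by default, or a finite burst of `cycles` periods.}
#' }
#'
#' @param kind one of `"impulse"`, `"pulse"`, `"double_pulse"`, `"step"`,
#'   `"sinusoid"`.
#' @param amplitude torque amplitude in Nm (impulse: strength in Nm s).
#'   Must be non-zero. Defaults: 20 Nm for the finite-torque kinds, 0.1 Nm s
#'   for the impulse.
#' @param period sinusoid period in s (default 0.03).
#' @param pulse_width pulse duration in s (default 0.01).
#' @param gap double-pulse inter-pulse gap in s (default 0.005).
#' @param cycles number of sinusoid periods, `Inf` for a continuous wave.
#' @return An object of class `torque_perturbation`.
#' @examples
#' u <- torque_perturbation("sinusoid", amplitude = 20, period = 0.03)
#' sample_torque(u, seq(0, 0.05, by = 1e-3))
#' @export
torque_perturbation <- function(kind = c("impulse", "pulse", "double_pulse",
                                         "step", "sinusoid"),
                                amplitude = NULL, period = 0.03,
                                pulse_width = 0.01, gap = 0.005,
                                cycles = Inf) {
  kind <- match.arg(kind)
  if (is.null(amplitude)) amplitude <- if (kind == "impulse") 0.1 else 20
  stopifnot(is.numeric(amplitude), length(amplitude) == 1L,
            is.finite(amplitude))
  if (amplitude == 0) stop("amplitude must be non-zero")
  if (kind == "sinusoid" && period <= 0) stop("period must be positive")
  if (kind %in% c("pulse", "double_pulse") && pulse_width <= 0)
    stop("pulse_width must be positive")
  if (kind == "double_pulse" && gap < 0) stop("gap must be non-negative")
  structure(list(kind = kind, amplitude = amplitude, period = period,
                 pulse_width = pulse_width, gap = gap, cycles = cycles),
            class = "torque_perturbation")
}

#' @export
print.torque_perturbation <- function(x, ...) {
  extra <- switch(x$kind,
    sinusoid = sprintf(", period %g s", x$period),
    pulse = sprintf(", width %g s", x$pulse_width),
    double_pulse = sprintf(", width %g s, gap %g s", x$pulse_width, x$gap),
    "")
  unit <- if (x$kind == "impulse") "Nm s" else "Nm"
  cat(sprintf("Torque perturbation: %s, amplitude %g %s%s\n",
              x$kind, x$amplitude, unit, extra))
  invisible(x)
}

#' Sample a torque perturbation on a time grid
#'
#' Evaluates the torque signal at the given times. An impulse has no
#' finite-torque representation on a grid; for it this function returns
#' zeros (the simulator realizes the impulse as an initial-state
#' excitation) with attribute `impulse = TRUE`.
#'
#' @param u a [torque_perturbation()] object.
#' @param t numeric vector of times, s (uniform grid).
#' @return Numeric vector of torques, Nm; attribute `impulse` flags the
#'   Dirac case.
#' @export
sample_torque <- function(u, t) {
  stopifnot(inherits(u, "torque_perturbation"), is.numeric(t))
  A <- u$amplitude
  tau <- switch(u$kind,
    impulse = rep(0, length(t)),
    step = ifelse(t >= 0, A, 0),
    pulse = ifelse(t >= 0 & t < u$pulse_width, A, 0),
    double_pulse = {
      w <- u$pulse_width; g <- u$gap
      ifelse(t >= 0 & t < w, A,
             ifelse(t >= w + g & t < 2 * w + g, -A, 0))
    },
    sinusoid = {
      y <- A * sin(2 * pi * t / u$period)
      if (is.finite(u$cycles)) y[t >= u$cycles * u$period | t < 0] <- 0
      y
    })
  attr(tau, "impulse") <- u$kind == "impulse"
  tau
}
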