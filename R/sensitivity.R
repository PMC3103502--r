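#' Finite-difference Hessian of the error criterion at a fit optimum
#'
#' Central-difference approximation of the 3x3 second-derivative matrix of
#' the shape-error criterion `E` with respect to the KBI parameters
#' `(K, B, I)`, evaluated at the fitted optimum, where the gradient vanishes
#' by definition. Steps are relative to each parameter (`rel_step`, with an
#' absolute floor of 1e-6) and the result is symmetrized as
#' `(H + t(H)) / 2`.
#'
#' The Hessian can be taken of the criterion itself (`on = "identity"`) or
#' of its square (`on = "squared"`, the default). The two differ only by
#' the exact factor `2 E*` at the optimum (same eigenvectors), but the
#' choice sets the scale on which an error increase `delta_E` is measured:
#' the squared criterion is the sum-of-squares objective the simplex search
#' effectively explores, and is the scale on which the study's headline
#' sensitivities are defined (see the methods vignette).
#'
#' @param fit a `fit_result` from [fit_kbi()].
#' @param rel_step relative finite-difference step per parameter.
#' @param check_steps if `TRUE`, recompute with the step halved and error
#'   unless the smallest eigenvalue agrees within 5 percent.
#' @param on differentiate the criterion (`"identity"`) or its square
#'   (`"squared"`).
#' @return The symmetric 3x3 Hessian (rows/cols ordered `K, B, I`).
#' @export
hessian_of_error <- function(fit, rel_step = 1e-3, check_steps = FALSE,
                             on = c("squared", "identity")) {
  stopifnot(inherits(fit, "fit_result"))
  on <- match.arg(on)
  if (!fit$converged)
    warning("fit did not converge; Hessian may not be at a minimum")
  E <- fit_objective(fit)
  if (on == "squared") {
    E_raw <- E
    E <- function(p) E_raw(p)^2
  }
  p <- c(fit$p_star$k, fit$p_star$b, fit$p_star$inertia)
  H <- fd_hessian(E, p, rel_step)
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-4 * max(abs(ev)))
    stop("negative curvature at the fitted optimum: not a local minimum ",
         "(smallest eigenvalue ", signif(min(ev), 4), ")")
  if (check_steps) {
    H2 <- fd_hessian(E, p, rel_step / 2)
    l1 <- min(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
    l2 <- min(eigen(H2, symmetric = TRUE, only.values = TRUE)$values)
    if (abs(l1 - l2) > 0.05 * max(abs(l1), abs(l2)))
      stop("smallest Hessian eigenvalue not converged under step halving (",
           signif(l1, 4), " vs ", signif(l2, 4), ")")
  }
  dimnames(H) <- list(c("K", "B", "I"), c("K", "B", "I"))
  H
}

fd_hessian <- function(f, p, rel_step) {
  n <- length(p)
  h <- pmax(abs(p) * rel_step, 1e-6)
  H <- matrix(0, n, n)
  f0 <- f(p)
  for (i in seq_len(n)) {
    ei <- numeric(n); ei[i] <- h[i]
    H[i, i] <- (f(p + ei) - 2 * f0 + f(p - ei)) / h[i]^2
    if (i < n) for (j in (i + 1L):n) {
      ej <- numeric(n); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(p + ei + ej) - f(p + ei - ej) - f(p - ei + ej) + f(p - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

#' Largest parameter change for a given error increase
#'
#' Near the optimum the error increase is the quadratic form
#' \eqn{\Delta E = \frac{1}{2} \Delta p^T H \Delta p}. The direction in
#' which the parameters can move farthest before `E` rises by `delta_E` is
#' the eigenvector of the smallest eigenvalue \eqn{\lambda_{min}} of `H`,
#' with norm \eqn{\|\Delta p\| = \sqrt{2 \Delta E / \lambda_{min}}}. The
#' sign of the (otherwise equivalent) eigenvector is normalized so that the
#' stiffness component is non-negative.
#'
#' @param H symmetric Hessian from [hessian_of_error()].
#' @param delta_E requested error increase (same units as the criterion the
#'   Hessian was computed from). Default 0.001.
#' @return List with `delta_p` (named `K, B, I`), `lambda_min` and `v_min`.
#' @export
max_param_change <- function(H, delta_E = 0.001) {
  stopifnot(is.matrix(H), nrow(H) == ncol(H), delta_E > 0)
  e <- eigen(H, symmetric = TRUE)
  lambda_min <- e$values[length(e$values)]
  if (lambda_min <= 0)
    stop("smallest Hessian eigenvalue is not positive (", lambda_min,
         "); the quadratic sensitivity model does not apply")
  v <- e$vectors[, length(e$values)]
  if (v[1] < 0) v <- -v
  dp <- sqrt(2 * delta_E / lambda_min) * v
  names(dp) <- rownames(H)
  list(delta_p = dp, lambda_min = lambda_min, v_min = v)
}

#' Sensitivity of fitted KBI parameters to measurement error
#'
#' Full sensitivity analysis at a fit optimum: Hessian of the criterion,
#' its smallest eigenvalue/eigenvector, the maximal parameter change
#' `delta_p` for the requested `delta_E`, the re-simulated (realized) error
#' increase `E(p* + delta_p) - E*` as a check on the quadratic
#' approximation, and the relative changes `100 |dK| / |K*|` and
#' `100 |dB| / |B*|` in percent.
#'
#' @inheritParams hessian_of_error
#' @param delta_E requested error increase, measured on the scale set by
#'   `on` (the study default is 0.001 on the squared-criterion scale).
#' @return An object of class `sensitivity_result`.
#' @examples
#' fit <- fit_kbi(msm_params(32, 3.2, 100, 0.1),
#'                torque_perturbation("impulse"), window = 0.05)
#' sensitivity_analysis(fit)
#' @export
sensitivity_analysis <- function(fit, delta_E = 0.001, rel_step = 1e-3,
                                 check_steps = FALSE,
                                 on = c("squared", "identity")) {
  on <- match.arg(on)
  H <- hessian_of_error(fit, rel_step = rel_step, check_steps = check_steps,
                        on = on)
  mp <- max_param_change(H, delta_E)
  E_raw <- fit_objective(fit)
  E <- if (on == "squared") function(p) E_raw(p)^2 else E_raw
  E0 <- if (on == "squared") fit$E_star^2 else fit$E_star
  p <- c(fit$p_star$k, fit$p_star$b, fit$p_star$inertia)
  realized <- E(p + mp$delta_p) - E0
  structure(list(
    H = H,
    lambda_min = mp$lambda_min,
    v_min = mp$v_min,
    delta_p = mp$delta_p,
    delta_E_requested = delta_E,
    delta_E_realized = realized,
    on = on,
    rel_dk = 100 * abs(mp$delta_p[["K"]]) / abs(fit$p_star$k),
    rel_db = 100 * abs(mp$delta_p[["B"]]) / abs(fit$p_star$b),
    fit = fit),
    class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    paste0("Sensitivity at Delta E = %g:\n",
           "  lambda_min = %.4g, delta_p = [%.4g, %.4g, %.4g] (K, B, I)\n",
           "  dK/K = %.1f%%, dB/B = %.1f%%, realized Delta E = %.4g\n"),
    x$delta_E_requested, x$lambda_min,
    x$delta_p[["K"]], x$delta_p[["B"]], x$delta_p[["I"]],
    x$rel_dk, x$rel_db, x$delta_E_realized))
  invisible(x)
}

#' Relative parameter sensitivities in percent
#'
#' @param fit a `fit_result`.
#' @param sens the matching `sensitivity_result`.
#' @return Named vector `c(dK_over_K, dB_over_B)` in percent; `NA` where the
#'   fitted parameter is zero.
#' @export
relative_sensitivity <- function(fit, sens) {
  stopifnot(inherits(fit, "fit_result"), inherits(sens, "sensitivity_result"))
  dk <- if (fit$p_star$k == 0) NA_real_ else
    100 * abs(sens$delta_p[["K"]]) / abs(fit$p_star$k)
  db <- if (fit$p_star$b == 0) NA_real_ else
    100 * abs(sens$delta_p[["B"]]) / abs(fit$p_star$b)
  c(dK_over_K = dk, dB_over_B = db)
}
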