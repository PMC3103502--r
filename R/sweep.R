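#' Sweep configuration
#'
#' Full-factorial study design over the MSM parameter grid. The default
#' grid is the study's standard design: CE stiffness from 10
#' to 200 Nm/rad in 20 evenly spaced values, CE damping from 2 to 30
#' Nms/rad in 15 values (300 cells), tendon stiffness tied to CE stiffness
#' through a ratio, inertia 0.10 kg m^2, and fitting windows of 50, 100 and
#' 200 ms. The CE-damping range 2-32 Nms/rad is available by passing
#' `b_ce = seq(2, 32, length.out = 15)`.
#'
#' @param k_ce CE stiffness grid, Nm/rad.
#' @param b_ce CE damping grid, Nms/rad.
#' @param ratios `K_SE / K_CE` ratios (tendon tracks CE stiffness because
#'   the tendon is loaded by the CE force).
#' @param inertia segment inertia, kg m^2.
#' @param windows fitting windows, s.
#' @param perturbations list of [torque_perturbation()] objects.
#' @param delta_E error increase for the sensitivity analysis.
#' @param dt simulation grid spacing, s.
#' @param mode criterion form, see [error_criterion()].
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(k_ce = seq(10, 200, length.out = 20),
                         b_ce = seq(2, 30, length.out = 15),
                         ratios = c(2, 5, 10),
                         inertia = 0.1,
                         windows = c(0.05, 0.1, 0.2),
                         perturbations = list(torque_perturbation("impulse")),
                         delta_E = 0.001,
                         dt = 1e-4,
                         mode = "relative") {
  stopifnot(is.numeric(k_ce), is.numeric(b_ce), is.numeric(ratios),
            all(ratios > 0), inertia > 0, all(windows > 0), dt > 0,
            delta_E > 0)
  if (!all(vapply(perturbations, inherits, logical(1), "torque_perturbation")))
    stop("perturbations must be a list of torque_perturbation objects")
  structure(list(k_ce = k_ce, b_ce = b_ce, ratios = ratios,
                 inertia = inertia, windows = windows,
                 perturbations = perturbations, delta_E = delta_E,
                 dt = dt, mode = mode),
            class = "sweep_config")
}

#' @export
print.sweep_config <- function(x, ...) {
  cat(sprintf(
    "Sweep: %d x %d (K_CE x B_CE) cells, ratios {%s}, windows {%s} ms, %d perturbation(s), Delta E = %g\n",
    length(x$k_ce), length(x$b_ce), paste(x$ratios, collapse = ", "),
    paste(1000 * x$windows, collapse = ", "),
    length(x$perturbations), x$delta_E))
  invisible(x)
}

#' Run the full-factorial identification study
#'
#' For every cell of the grid (CE stiffness x CE damping x tendon ratio x
#' window x perturbation): simulate the MSM response, fit the KBI model,
#' and run the sensitivity analysis at the configured `delta_E`. The
#' computation is fully deterministic. Failed cells are recorded with
#' `ok = FALSE` and a note rather than dropped.
#'
#' @param cfg a [sweep_config()].
#' @param cache_dir optional directory for per-cell result caching; reruns
#'   with the same configuration reuse cached cells, so an interrupted
#'   sweep is resumable.
#' @param progress print one line per grid cell.
#' @param sensitivity_on objective for the sensitivity Hessian, see
#'   [hessian_of_error()].
#' @return A data frame of class `sweep_result`, one row per cell, with
#'   the MSM parameters, fitted `K, B, I`, `E_star`, `lambda_min`, the
#'   maximal changes `dK, dB, dI`, relative sensitivities `rel_dk, rel_db`
#'   (percent), the realized error increase, and bookkeeping flags.
#' @export
run_sweep <- function(cfg, cache_dir = NULL, progress = FALSE,
                      sensitivity_on = c("squared", "identity")) {
  sensitivity_on <- match.arg(sensitivity_on)
  stopifnot(inherits(cfg, "sweep_config"))
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  grid <- expand.grid(k_ce = cfg$k_ce, b_ce = cfg$b_ce, ratio = cfg$ratios,
                      window = cfg$windows,
                      pert = seq_along(cfg$perturbations),
                      KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    u <- cfg$perturbations[[g$pert]]
    key <- sprintf("cell_%s.rds",
                   paste(c(signif(c(g$k_ce, g$b_ce, g$ratio, cfg$inertia,
                                    g$window, cfg$delta_E, cfg$dt), 12),
                           u$kind, cfg$mode, sensitivity_on),
                         collapse = "_"))
    cache_file <- if (is.null(cache_dir)) NULL else file.path(cache_dir, key)
    if (!is.null(cache_file) && file.exists(cache_file)) {
      rows[[i]] <- readRDS(cache_file)
      next
    }
    row <- sweep_cell(g$k_ce, g$b_ce, g$ratio * g$k_ce, cfg$inertia, u,
                      g$window, cfg$dt, cfg$mode, cfg$delta_E,
                      sensitivity_on)
    row$ratio <- g$ratio
    if (!is.null(cache_file)) saveRDS(row, cache_file)
    if (progress)
      cat(sprintf(
        "cell %d/%d K_CE=%.1f B_CE=%.1f ratio=%g T=%g %s: E*=%.3g evals=%d\n",
        i, nrow(grid), g$k_ce, g$b_ce, g$ratio, g$window, u$kind,
        row$E_star, row$n_evals))
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_result", class(out))
  attr(out, "config") <- cfg
  out
}

sweep_cell <- function(k_ce, b_ce, k_se, inertia, u, window, dt, mode,
                       delta_E, sensitivity_on = "squared") {
  base <- data.frame(k_ce = k_ce, b_ce = b_ce, k_se = k_se,
                     inertia = inertia, window = window,
                     perturbation = u$kind, ratio = NA_real_,
                     E_star = NA_real_, K = NA_real_, B = NA_real_,
                     I = NA_real_, lambda_min = NA_real_, dK = NA_real_,
                     dB = NA_real_, dI = NA_real_, rel_dk = NA_real_,
                     rel_db = NA_real_, delta_E_realized = NA_real_,
                     n_evals = NA_integer_, converged = NA, ok = FALSE,
                     note = "", stringsAsFactors = FALSE)
  tryCatch({
    p <- msm_params(k_ce, b_ce, k_se, inertia)
    fit <- fit_kbi(p, u, window, dt, mode)
    sens <- sensitivity_analysis(fit, delta_E, on = sensitivity_on)
    base$E_star <- fit$E_star
    base$K <- fit$p_star$k
    base$B <- fit$p_star$b
    base$I <- fit$p_star$inertia
    base$lambda_min <- sens$lambda_min
    base$dK <- sens$delta_p[["K"]]
    base$dB <- sens$delta_p[["B"]]
    base$dI <- sens$delta_p[["I"]]
    base$rel_dk <- sens$rel_dk
    base$rel_db <- sens$rel_db
    base$delta_E_realized <- sens$delta_E_realized
    base$n_evals <- fit$n_evals
    base$converged <- fit$converged
    base$ok <- TRUE
    base
  }, error = function(e) {
    base$note <- conditionMessage(e)
    base
  })
}

#' Summarize sensitivity over a sweep
#'
#' Arithmetic mean and standard deviation of the relative maximal
#' stiffness and damping changes (percent) over the grid cells selected by
#' window, perturbation kind, and tendon ratio. All cells with a
#' successful fit are included; a variant restricted to well-fitting cells
#' (`E_star <= good_fit`) is reported alongside, since grid corners where
#' the KBI model fits poorly could arguably be excluded.
#'
#' @param sr a `sweep_result` from [run_sweep()].
#' @param window fitting window to select, s.
#' @param perturbation perturbation kind to select.
#' @param ratio tendon ratio to select (default 5, the figure setting).
#' @param good_fit `E_star` threshold for the filtered variant.
#' @return List with `n`, `n_failed`, `mean_dk`, `sd_dk`, `mean_db`,
#'   `sd_db`, `mean_E_star`, and a `filtered` sub-list.
#' @export
summarize_sweep <- function(sr, window, perturbation = "impulse", ratio = 5,
                            good_fit = 0.01) {
  stopifnot(inherits(sr, "sweep_result"))
  sel <- sr[abs(sr$window - window) < 1e-12 &
              sr$perturbation == perturbation &
              (is.na(ratio) | sr$ratio == ratio), ]
  if (nrow(sel) == 0L) stop("no sweep cells match the selection")
  ok <- sel[sel$ok, ]
  stat <- function(d) list(
    n = nrow(d),
    mean_dk = mean(d$rel_dk), sd_dk = stats::sd(d$rel_dk),
    mean_db = mean(d$rel_db), sd_db = stats::sd(d$rel_db),
    mean_E_star = mean(d$E_star))
  out <- stat(ok)
  out$n_failed <- nrow(sel) - nrow(ok)
  out$filtered <- stat(ok[ok$E_star <= good_fit, ])
  out
}

#' Write a sweep result to CSV
#'
#' One row per grid cell with the documented [run_sweep()] columns.
#'
#' @param sr a `sweep_result`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sr, path) {
  stopifnot(inherits(sr, "sweep_result"))
  utils::write.csv(as.data.frame(sr), path, row.names = FALSE)
  invisible(path)
}
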