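test_that("finite-difference Hessian recovers a known quadratic form", {
  A <- matrix(c(4, 1, 0.5, 1, 9, -2, 0.5, -2, 25), 3, 3)
  f <- function(p) 0.5 * sum(p * (A %*% p))
  H <- kbident:::fd_hessian(f, c(1, 2, 0.5), 1e-3)
  expect_equal(H, A, tolerance = 1e-6)
})

test_that("eigen-direction algebra: Delta E = half lambda norm^2, square-root law, signs", {
  H <- diag(c(2, 8, 50))
  rownames(H) <- colnames(H) <- c("K", "B", "I")
  mp <- max_param_change(H, delta_E = 0.001)
  expect_equal(sqrt(sum(mp$delta_p^2)), sqrt(2 * 0.001 / 2), tolerance = 1e-12)
  expect_equal(abs(mp$delta_p[["K"]]), sqrt(2 * 0.001 / 2), tolerance = 1e-12)
  # exact quadratic identity at machine precision
  expect_equal(0.5 * mp$lambda_min * sum(mp$delta_p^2), 0.001,
               tolerance = 1e-14)
  # quadrupling the error increase doubles the excursion
  mp4 <- max_param_change(H, delta_E = 0.004)
  expect_equal(sqrt(sum(mp4$delta_p^2)), 2 * sqrt(sum(mp$delta_p^2)),
               tolerance = 1e-12)
  # stiffness component reported non-negative
  expect_gte(mp$delta_p[["K"]], 0)
  expect_error(max_param_change(diag(c(-1, 2, 3)), 0.001), "not positive")
})

test_that("a self-fit optimum has strictly positive curvature", {
  fit <- fit_kbi(kbi_params(40, 1, 0.1), torque_perturbation("impulse"), 0.05)
  H <- hessian_of_error(fit, on = "squared")
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("identity-mode Hessian scales linearly with response amplitude in rms mode", {
  u1 <- torque_perturbation("impulse", amplitude = 0.1)
  u2 <- torque_perturbation("impulse", amplitude = 0.2)
  f1 <- fit_kbi(ref_plant(), u1, 0.05, mode = "rms")
  f2 <- fit_kbi(ref_plant(), u2, 0.05, mode = "rms")
  H1 <- hessian_of_error(f1, on = "identity")
  H2 <- hessian_of_error(f2, on = "identity")
  expect_equal(H2, 2 * H1, tolerance = 1e-4)
})

test_that("the quadratic sensitivity model predicts the realized error increase", {
  fit <- fit_kbi(ref_plant(), torque_perturbation("impulse"), 0.05)
  sens <- sensitivity_analysis(fit, delta_E = 0.001, on = "squared")
  expect_lt(abs(sens$delta_E_realized - 0.001), 0.25 * 0.001)
  # the eigen quantities are internally consistent
  expect_equal(sqrt(sum(sens$v_min^2)), 1, tolerance = 1e-12)
  expect_equal(0.5 * sens$lambda_min * sum(sens$delta_p^2),
               sens$delta_E_requested, tolerance = 1e-12)
})

test_that("smallest eigenvalue is stable under step halving for the worked example", {
  fit <- fit_kbi(ref_plant(), torque_perturbation("impulse"), 0.05)
  expect_silent(H <- hessian_of_error(fit, rel_step = 1e-3,
                                      check_steps = TRUE, on = "squared"))
  expect_true(isSymmetric(H))
})

test_that("relative sensitivities report percentages and flag zero parameters", {
  fit <- fit_kbi(ref_plant(), torque_perturbation("impulse"), 0.05)
  sens <- sensitivity_analysis(fit, 0.001)
  rs <- relative_sensitivity(fit, sens)
  expect_equal(rs[["dK_over_K"]],
               100 * abs(sens$delta_p[["K"]]) / abs(fit$p_star$k))
  fit0 <- fit
  fit0$p_star$b <- 0
  expect_true(is.na(relative_sensitivity(fit0, sens)[["dB_over_B"]]))
})
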