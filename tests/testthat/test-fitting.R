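test_that("error criterion forms behave as defined", {
  r <- simulate_response(ref_plant(), torque_perturbation("impulse"), 0.05)
  expect_equal(error_criterion(r, r), 0)
  # constant offset in plain-RMS mode
  a <- rep(0.01, 100); b <- rep(0, 100)
  expect_equal(error_criterion(a, b, mode = "rms"), 0.01)
  # relative mode is invariant to a common scale
  r2 <- r; r2$phi <- 1.3 * r$phi
  r3 <- r; r3$phi <- r$phi * 0.9
  r2s <- r2; r2s$phi <- 1.7 * r2$phi
  r3s <- r3; r3s$phi <- 1.7 * r3$phi
  expect_equal(error_criterion(r2, r3, mode = "relative"),
               error_criterion(r2s, r3s, mode = "relative"),
               tolerance = 1e-12)
  # peak mode only sees shape: scaled copies are identical
  expect_equal(error_criterion(r, r2, mode = "peak"), 0)
  # grid mismatch
  short <- simulate_response(ref_plant(), torque_perturbation("impulse"), 0.04)
  expect_error(error_criterion(r, short), "grid mismatch")
})

test_that("self-fit recovers a KBI plant essentially exactly", {
  truth <- kbi_params(40, 1, 0.1)
  fit <- fit_kbi(truth, torque_perturbation("impulse"), 0.05)
  expect_equal(fit$p_star$k, 40, tolerance = 1e-3)
  expect_equal(fit$p_star$b, 1, tolerance = 1e-3)
  expect_equal(fit$p_star$inertia, 0.1, tolerance = 1e-3)
  expect_lt(fit$E_star, 1e-8)
})

test_that("fits are deterministic and independent of the impulse magnitude", {
  p <- ref_plant()
  f1 <- fit_kbi(p, torque_perturbation("impulse", amplitude = 0.1), 0.05)
  f2 <- fit_kbi(p, torque_perturbation("impulse", amplitude = 0.1), 0.05)
  expect_identical(f1$E_star, f2$E_star)
  expect_identical(f1$p_star, f2$p_star)
  # linearity + shape criterion: any impulse strength gives the same fit
  f3 <- fit_kbi(p, torque_perturbation("impulse", amplitude = 2.5), 0.05)
  expect_equal(f3$p_star$k, f1$p_star$k, tolerance = 1e-6)
  expect_equal(f3$p_star$b, f1$p_star$b, tolerance = 1e-5)
  expect_equal(f3$E_star, f1$E_star, tolerance = 1e-8)
})

test_that("zero CE damping gives the exact series-spring stiffness and zero damping", {
  for (pars in list(c(20, 40), c(100, 500))) {
    fit <- fit_kbi(msm_params(pars[1], 0, pars[2], 0.1),
                   torque_perturbation("impulse"), 0.05)
    expect_equal(fit$p_star$k, pars[1] * pars[2] / (pars[1] + pars[2]),
                 tolerance = 1e-6)
    expect_lt(abs(fit$p_star$b), 1e-8)
  }
})

test_that("E_star is the minimum over everything the optimizer probed", {
  fit <- fit_kbi(ref_plant(), torque_perturbation("impulse"), 0.05)
  obj <- kbident:::fit_objective(fit)
  p <- fit$p_star
  expect_equal(obj(c(p$k, p$b, p$inertia)), fit$E_star, tolerance = 1e-12)
  for (start in list(fit$init_used, c(30, 2, 0.1), c(100, 0.2, 0.12)))
    expect_lte(fit$E_star, obj(start))
})

test_that("an exhausted optimizer is flagged, not an error", {
  fit <- fit_kbi(ref_plant(), torque_perturbation("impulse"), 0.05,
                 maxit = 4)
  expect_false(fit$converged)
  expect_s3_class(fit$p_star, "kbi_params")
})

test_that("the fitted stiffness lies between the LF and HF analytic bounds", {
  p <- ref_plant()
  lf <- lf_approx(p)
  # slow, long-window perturbation: near the series-spring value
  slow <- fit_kbi(p, torque_perturbation("step"), 0.5)
  expect_gt(slow$p_star$k, lf$k_lf * 0.99)
  expect_lt(slow$p_star$k, p$k_se)
  # fast perturbation over its own (short) window: near the tendon value
  fast <- fit_kbi(p, torque_perturbation("sinusoid", period = 0.005), 0.005)
  expect_gt(fast$p_star$k, lf$k_lf)
  expect_lt(fast$p_star$k, 1.1 * p$k_se)
})

test_that("window trend: grid-mean E* does not decrease with window length", {
  ks <- c(30, 120); bs <- c(4, 20)
  mean_E <- sapply(c(0.05, 0.1, 0.2), function(Tw) {
    mean(sapply(ks, function(k) sapply(bs, function(b)
      fit_kbi(msm_params(k, b, 5 * k, 0.1), torque_perturbation("impulse"),
              Tw)$E_star)))
  })
  expect_true(all(diff(mean_E) >= 0))
})
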