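test_that("pure inertia under an impulse gives a linear velocity ramp", {
  # repeated pole at the origin: exercises the ZOH fallback path
  r <- simulate_response(kbi_params(0, 0, 0.1),
                         torque_perturbation("impulse", amplitude = 0.1),
                         window = 0.05, allow_unstable = TRUE)
  expect_equal(r$phi, r$t, tolerance = 1e-12)
})

test_that("KBI impulse response matches the closed-form damped oscillator", {
  u <- torque_perturbation("impulse", amplitude = 0.1)
  for (pars in list(c(40, 0, 0.1), c(40, 1.2, 0.1), c(120, 0.3, 0.08))) {
    r <- simulate_response(kbi_params(pars[1], pars[2], pars[3]), u, 0.05,
                           dt = 5e-4)
    exact <- oscillator_impulse(pars[1], pars[2], pars[3], 0.1, r$t)
    expect_lt(max(abs(r$phi - exact)), 1e-9)
  }
})

test_that("MSM impulse response matches a high-accuracy ODE integration", {
  r <- simulate_response(ref_plant(), torque_perturbation("impulse"), 0.05)
  exact <- msm_impulse_ode_oracle(ref_plant(), 0.1, r$t)
  expect_lt(max(abs(r$phi - exact)), 1e-8)
})

test_that("ZOH filter path agrees with direct state-space stepping", {
  p <- ref_plant()
  adm <- kbident:::admittance(msm_impedance(p))
  t <- seq(0, 0.05, by = 1e-4)
  for (u in list(torque_perturbation("sinusoid"),
                 torque_perturbation("pulse"),
                 torque_perturbation("double_pulse"),
                 torque_perturbation("step"))) {
    r <- simulate_response(p, u, 0.05)
    oracle <- step_zoh_oracle(adm$num, adm$den, sample_torque(u, t), 1e-4)
    expect_lt(max(abs(r$phi - oracle)), 1e-9 * max(abs(oracle)))
  }
  # impulse: modal partial-fraction path vs stepping from the initial state
  r <- simulate_response(p, torque_perturbation("impulse"), 0.05)
  oracle <- step_zoh_oracle(adm$num, adm$den, numeric(length(t)), 1e-4,
                            impulse = 0.1)
  expect_lt(max(abs(r$phi - oracle)), 1e-9 * max(abs(oracle)))
})

test_that("simulation is linear in the input amplitude", {
  p <- ref_plant()
  for (kind in c("impulse", "sinusoid", "step")) {
    u1 <- torque_perturbation(kind, amplitude = if (kind == "impulse") 0.1 else 20)
    u3 <- torque_perturbation(kind, amplitude = 3 * u1$amplitude)
    r1 <- simulate_response(p, u1, 0.05)
    r3 <- simulate_response(p, u3, 0.05)
    expect_equal(r3$phi, 3 * r1$phi, tolerance = 1e-12)
  }
})

test_that("simulated output is realization-invariant", {
  # similarity-transformed realization stepped directly must reproduce the
  # package output
  p <- ref_plant()
  adm <- kbident:::admittance(msm_impedance(p))
  ss <- kbident:::ss_realization(adm)
  set.seed(7)
  T_mat <- matrix(rnorm(9), 3, 3)
  A2 <- solve(T_mat) %*% ss$A %*% T_mat
  B2 <- solve(T_mat) %*% ss$B
  C2 <- as.numeric(t(ss$C) %*% T_mat)
  t <- seq(0, 0.05, by = 1e-4)
  tau <- sample_torque(torque_perturbation("step"), t)
  M <- as.matrix(Matrix::expm(Matrix::Matrix(rbind(cbind(A2, B2), rep(0, 4)) * 1e-4)))
  Ad <- M[1:3, 1:3]; Bd <- M[1:3, 4]
  x <- numeric(3); y <- numeric(length(t))
  for (k in seq_along(t)) {
    y[k] <- sum(C2 * x)
    x <- Ad %*% x + Bd * tau[k]
  }
  r <- simulate_response(p, torque_perturbation("step"), 0.05)
  # slack covers the conditioning of the random similarity transform
  expect_lt(max(abs(r$phi - y)), 1e-7 * max(abs(y)))
})

test_that("step-response final value equals the DC admittance", {
  # window spans many time constants of the slowest pole (~0.12 s here)
  p <- msm_params(60, 8, 300, 0.1)
  r <- simulate_response(p, torque_perturbation("step", amplitude = 20), 2,
                         dt = 1e-3)
  expect_equal(r$phi[length(r$phi)],
               20 / Re(eval_impedance(msm_impedance(p), 0)),
               tolerance = 1e-6)
})

test_that("unstable plants error unless explicitly allowed", {
  unstable <- kbi_params(-50, 1, 0.1)
  expect_error(simulate_response(unstable, torque_perturbation("step"), 0.05),
               "unstable")
  r <- simulate_response(unstable, torque_perturbation("step"), 0.05,
                         allow_unstable = TRUE)
  expect_true(all(is.finite(r$phi)))
})

test_that("dt must divide the window", {
  expect_error(simulate_response(ref_plant(), torque_perturbation("impulse"),
                                 window = 0.0501, dt = 2e-4),
               "divide")
})

test_that("measurement noise is reproducible, correctly scaled, and optional", {
  r <- simulate_response(ref_plant(), torque_perturbation("impulse"), 0.0999,
                         dt = 1e-4)
  expect_identical(add_measurement_noise(r, 0)$phi, r$phi)
  n1 <- add_measurement_noise(r, 1e-3, seed = 42)
  n2 <- add_measurement_noise(r, 1e-3, seed = 42)
  expect_identical(n1$phi, n2$phi)
  # 1000 samples: sample SD within the chi-square band around 1e-3
  s <- sd(n1$phi - r$phi)
  expect_gt(s, 0.9e-3)
  expect_lt(s, 1.1e-3)
  # caller's RNG state untouched
  set.seed(1); before <- .Random.seed
  invisible(add_measurement_noise(r, 1e-3, seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("responses survive a CSV + JSON round trip", {
  r <- simulate_response(ref_plant(), torque_perturbation("sinusoid"), 0.05)
  path <- file.path(tempdir(), "resp.csv")
  write_response(r, path)
  r2 <- read_response(path)
  expect_equal(r2$phi, r$phi, tolerance = 1e-12)
  expect_equal(r2$t, r$t, tolerance = 1e-12)
  expect_equal(r2$window, r$window)
  expect_equal(r2$perturbation$kind, "sinusoid")
  expect_equal(r2$plant$num, r$plant$num)
})
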