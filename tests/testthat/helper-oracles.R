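# Independent simulation oracles used to validate the package's
# filter/modal simulation paths.

# direct state-space ZOH stepping (plain R loop; independent of the
# package's discrete-transfer-function route)
step_zoh_oracle <- function(num, den, tau, dt, impulse = 0) {
  den0 <- den / den[1]
  num0 <- num / den[1]
  n <- length(den0) - 1L
  A <- matrix(0, n, n)
  if (n > 1L) A[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- 1
  A[n, ] <- -rev(den0[-1])
  B <- c(rep(0, n - 1L), 1)
  C <- c(rev(num0), rep(0, n - length(num0)))
  M <- as.matrix(Matrix::expm(Matrix::Matrix(rbind(cbind(A, B), rep(0, n + 1L)) * dt)))
  Ad <- M[seq_len(n), seq_len(n), drop = FALSE]
  Bd <- M[seq_len(n), n + 1L]
  x <- B * impulse
  y <- numeric(length(tau))
  for (k in seq_along(tau)) {
    y[k] <- sum(C * x)
    x <- Ad %*% x + Bd * tau[k]
  }
  y
}

# analytic impulse response of the damped harmonic oscillator
# I phi'' + B phi' + K phi = J delta(t)
oscillator_impulse <- function(k, b, inertia, J, t) {
  disc <- as.complex(b^2 - 4 * k * inertia)
  r1 <- (-b + sqrt(disc)) / (2 * inertia)
  r2 <- (-b - sqrt(disc)) / (2 * inertia)
  Re(J / (inertia * (r1 - r2)) * (exp(r1 * t) - exp(r2 * t)))
}

# high-accuracy ODE integration of the third-order MSM state equations
msm_impulse_ode_oracle <- function(p, J, t) {
  adm <- kbident:::admittance(msm_impedance(p))
  den0 <- adm$den / adm$den[1]
  num0 <- adm$num / adm$den[1]
  n <- length(den0) - 1L
  A <- matrix(0, n, n)
  if (n > 1L) A[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- 1
  A[n, ] <- -rev(den0[-1])
  C <- c(rev(num0), rep(0, n - length(num0)))
  x0 <- c(rep(0, n - 1L), 1) * J
  sol <- deSolve::lsoda(
    y = x0, times = t,
    func = function(tt, x, parms) list(A %*% x),
    rtol = 1e-12, atol = 1e-14)
  as.numeric(sol[, -1, drop = FALSE] %*% C)
}

ref_plant <- function() msm_params(32, 3.2, 100, 0.1)
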