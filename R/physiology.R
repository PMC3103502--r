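#' Muscle-level parameters
#'
#' Properties of a (lumped) muscle-tendon actuator used to derive
#' joint-level MSM parameters: maximal isometric CE force, optimum CE
#' length, tendon slack length, moment arm, the width of the parabolic
#' force-length relationship, and the Hill force-velocity constants.
#'
#' @param f_max maximal isometric CE force, N.
#' @param l_ce_opt optimum CE length, m.
#' @param l_se_slack tendon slack length, m.
#' @param arm moment arm, m (constant).
#' @param w force-length width: active force vanishes at `l_ce_rel = 1 +- w`.
#'   Default 0.56 (sliding-filament estimate).
#' @param a,b Hill force-velocity constants; defaults 0.41 and 5.2, so the
#'   maximal (normalized) shortening velocity is `b / a ~ 12.7` optimum
#'   lengths per second.
#' @return An object of class `muscle_params`.
#' @export
muscle_params <- function(f_max, l_ce_opt, l_se_slack, arm,
                          w = 0.56, a = 0.41, b = 5.2) {
  stopifnot(f_max > 0, l_ce_opt > 0, l_se_slack > 0, arm > 0,
            w > 0, w < 1, a > 0, b > 0)
  structure(list(f_max = f_max, l_ce_opt = l_ce_opt,
                 l_se_slack = l_se_slack, arm = arm, w = w, a = a, b = b),
            class = "muscle_params")
}

#' @export
print.muscle_params <- function(x, ...) {
  cat(sprintf(
    "Muscle: F_max = %g N, l_CE_opt = %g m, l_SE_slack = %g m, arm = %g m, w = %g, Hill a = %g, b = %g\n",
    x$f_max, x$l_ce_opt, x$l_se_slack, x$arm, x$w, x$a, x$b))
  invisible(x)
}

#' Joint-level tendon stiffness from a quadratic tendon
#'
#' The tendon is a non-linear quadratic spring, `F_SE = k dl^2`, calibrated
#' so that at maximal isometric CE force it is elongated by 4 percent of its
#' slack length: `k = F_max / (0.04 l_SE_slack)^2`. The joint-level tendon
#' stiffness at elongation `dl` is the local slope times the squared moment
#' arm, `K_SE = 2 k dl arm^2`: zero at zero CE force and growing linearly
#' with elongation.
#'
#' @param m a [muscle_params()] object.
#' @param delta_l_se tendon elongation, m (non-negative, vectorized).
#' @return `K_SE` in Nm/rad.
#' @export
tendon_joint_stiffness <- function(m, delta_l_se) {
  stopifnot(inherits(m, "muscle_params"), all(delta_l_se >= 0))
  k <- m$f_max / (0.04 * m$l_se_slack)^2
  2 * k * delta_l_se * m$arm^2
}

# quadratic tendon force at elongation dl
tendon_force <- function(m, delta_l_se) {
  m$f_max / (0.04 * m$l_se_slack)^2 * delta_l_se^2
}

#' Joint-level CE stiffness from the parabolic force-length relationship
#'
#' At maximal activation the CE force-length relationship is the parabola
#' `F = F_max (1 - ((l_rel - 1)/w)^2)` with `l_rel` the CE length relative
#' to optimum. Its negative slope, mapped to the joint through the moment
#' arm, gives
#' `K_CE = 2 F_max (1 - l_rel) arm^2 / (w^2 l_CE_opt)`, scaled by the
#' activation level: zero at optimum length, maximal near active slack
#' (`l_rel = 1 - w`), and negative above optimum (descending limb).
#'
#' @param m a [muscle_params()] object.
#' @param l_ce_rel relative CE length, in `[1 - w, 1 + w]` (vectorized).
#' @param activation_scale activation scaling in `[0, 1]`.
#' @return `K_CE` in Nm/rad (sign convention: positive below optimum).
#' @export
ce_joint_stiffness <- function(m, l_ce_rel, activation_scale = 1) {
  stopifnot(inherits(m, "muscle_params"),
            activation_scale >= 0, activation_scale <= 1)
  if (any(abs(l_ce_rel - 1) > m$w))
    stop("l_ce_rel outside the active range [1 - w, 1 + w]")
  2 * m$f_max * (1 - l_ce_rel) / (m$w^2 * m$l_ce_opt) * m$arm^2 *
    activation_scale
}

# parabolic active force-length factor (0..1)
force_length_factor <- function(m, l_ce_rel) {
  pmax(0, 1 - ((l_ce_rel - 1) / m$w)^2)
}

#' Normalized Hill force-velocity relationship
#'
#' Concentric hyperbola `(F_n + a)(v_rel + b) = b (1 + a)` with shortening
#' velocity positive, so `F_n(0) = 1` and `F_n(b/a) = 0` (maximal
#' shortening velocity `b/a` optimum lengths per second).
#'
#' @param m a [muscle_params()] object.
#' @param v_rel normalized contraction velocity, optimum lengths / s.
#' @return Normalized CE force.
#' @export
hill_force_velocity <- function(m, v_rel) {
  stopifnot(inherits(m, "muscle_params"))
  m$b * (1 + m$a) / (v_rel + m$b) - m$a
}

#' Joint-level CE damping from the Hill force-velocity slope
#'
#' The slope of the normalized Hill hyperbola at zero velocity is
#' `(1 + a) / b` per normalized velocity. Scaled by the maximal CE force,
#' converted from normalized to absolute velocity through `l_CE_opt`, and
#' mapped to the joint through the moment arm:
#' `B_CE = F_max arm^2 (1 + a) / (b l_CE_opt)`. The eccentric
#' force-velocity slope at zero velocity is about twice the concentric one,
#' so `eccentric = TRUE` doubles the damping.
#'
#' @param m a [muscle_params()] object.
#' @param eccentric use the (doubled) eccentric slope.
#' @return `B_CE` in Nms/rad.
#' @export
ce_joint_damping <- function(m, eccentric = FALSE) {
  stopifnot(inherits(m, "muscle_params"))
  bce <- m$f_max * m$arm^2 * (1 + m$a) / (m$b * m$l_ce_opt)
  if (eccentric) 2 * bce else bce
}

#' Joint-level parameter table across CE lengths
#'
#' Maps muscle-level properties to the joint-level plant parameters
#' `(K_CE, K_SE, B_CE)` over a grid of relative CE lengths, with the tendon
#' elongation at each length set by force balance between the active CE
#' force (parabolic force-length, full activation) and the quadratic
#' tendon.
#'
#' @param m a [muscle_params()] object.
#' @param l_ce_rel grid of relative CE lengths.
#' @param eccentric passed to [ce_joint_damping()].
#' @return A data frame with columns `l_ce_rel`, `f_ce` (N), `delta_l_se`
#'   (m), `k_ce`, `k_se` (Nm/rad) and `b_ce` (Nms/rad).
#' @export
joint_parameter_table <- function(m, l_ce_rel = seq(0.6, 1.4, by = 0.05),
                                  eccentric = FALSE) {
  stopifnot(inherits(m, "muscle_params"))
  f <- m$f_max * force_length_factor(m, l_ce_rel)
  kq <- m$f_max / (0.04 * m$l_se_slack)^2
  dl <- sqrt(f / kq)
  data.frame(
    l_ce_rel = l_ce_rel,
    f_ce = f,
    delta_l_se = dl,
    k_ce = ce_joint_stiffness(m, l_ce_rel),
    k_se = tendon_joint_stiffness(m, dl),
    b_ce = ce_joint_damping(m, eccentric))
}
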