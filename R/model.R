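#' @name wrist-model
#' @title Simplified six-muscle wrist musculoskeletal model
#'
#' @description
#' A self-contained replacement for a generic OpenSim arm model, reduced to
#' the wrist joint: six rigid-tendon Hill-type muscle-tendon units (FCR, FCU,
#' ECRL, ECU, PT, SUP) acting through constant signed moment arms on three
#' degrees of freedom (FE = flexion/extension, RU = radial/ulnar deviation,
#' PS = pronation/supination), with per-DoF lumped inertia, passive joint
#' stiffness and damping. Passive muscle force vanishes at the rest posture,
#' so zero excitation keeps the wrist at rest (the published models instead
#' rescale maximal isometric forces to remove the rest offset).
NULL

MUSCLES <- c("FCR", "FCU", "ECRL", "ECU", "PT", "SUP")
DOFS <- c("FE", "RU", "PS")

#' Construct the wrist musculoskeletal model
#'
#' @param f_max maximal isometric forces (N), named or in muscle order
#'   FCR, FCU, ECRL, ECU, PT, SUP.
#' @param l_opt optimal fiber lengths (m).
#' @param v_max maximal shortening velocities (optimal lengths per second).
#' @param tau_act,tau_deact activation/deactivation time constants (s).
#' @param moment_arms 6 x 3 signed moment-arm matrix (m), columns FE, RU, PS.
#'   Positive FE = flexion, positive RU = radial deviation, positive
#'   PS = pronation.
#' @param inertia per-DoF lumped inertia (kg m^2).
#' @param stiffness,damping passive joint stiffness (N m/rad) and damping
#'   (N m s/rad) per DoF.
#' @param q_min,q_max joint limits (rad) per DoF.
#' @return an object of class `wrist_model`.
#' @export
wrist_model <- function(f_max = c(100, 130, 120, 90, 300, 250),
                        l_opt = rep(0.06, 6),
                        v_max = rep(10, 6),
                        tau_act = rep(0.015, 6),
                        tau_deact = rep(0.060, 6),
                        moment_arms = default_moment_arms(),
                        inertia = c(FE = 0.004, RU = 0.004, PS = 0.002),
                        stiffness = c(FE = 1.0, RU = 2.5, PS = 1.0),
                        damping = c(FE = 0.2, RU = 0.2, PS = 0.2),
                        q_min = c(FE = -1.2, RU = -0.4, PS = -1.4),
                        q_max = c(FE = 1.2, RU = 0.4, PS = 1.4)) {
  stopifnot(length(f_max) == 6, all(f_max > 0), all(l_opt > 0),
            all(tau_act > 0), all(tau_deact > 0), all(v_max > 0),
            all(inertia > 0), all(stiffness > 0), all(damping > 0),
            nrow(moment_arms) == 6, ncol(moment_arms) == 3,
            all(q_min < 0), all(q_max > 0))
  m <- list(
    muscles = MUSCLES, dofs = DOFS,
    f_max = unname(f_max), l_opt = unname(l_opt), v_max = unname(v_max),
    tau_act = unname(tau_act), tau_deact = unname(tau_deact),
    moment_arms = structure(unname(as.matrix(moment_arms)),
                            dimnames = list(MUSCLES, DOFS)),
    inertia = unname(inertia), stiffness = unname(stiffness),
    damping = unname(damping),
    q_min = unname(q_min), q_max = unname(q_max), q_rest = c(0, 0, 0),
    # force-length Gaussian width, passive exponential curve, hyperbolic
    # force-velocity (shortening curvature, eccentric plateau)
    shape = list(fl_width = 0.45, fp_k = 5, fp_c = 0.01,
                 fv_av = 0.25, fv_ecc_gain = 0.8, fv_ecc_k = 0.13)
  )
  class(m) <- "wrist_model"
  m
}

#' Default signed moment arms (m)
#'
#' FCR and FCU flex (+FE); ECRL and ECU extend; FCR/ECRL deviate radially
#' (+RU), FCU/ECU ulnarly; PT pronates (+PS), SUP supinates. PT/SUP
#' flexion/deviation cross-moments are set to zero (their contribution to
#' those DoFs is negligible at the wrist in this reduced model).
#' @export
default_moment_arms <- function() {
  matrix(c(
    #   FE      RU      PS
    0.015,  0.008,  0.000,  # FCR
    0.015, -0.010,  0.000,  # FCU
   -0.012,  0.010,  0.000,  # ECRL
   -0.012, -0.012,  0.000,  # ECU
    0.000,  0.000,  0.010,  # PT
    0.000,  0.000, -0.012   # SUP
  ), nrow = 6, byrow = TRUE, dimnames = list(MUSCLES, DOFS))
}

#' Wrist state
#'
#' @param q joint angles (rad), length 3 (FE, RU, PS).
#' @param qdot joint angular velocities (rad/s).
#' @param a muscle activations in `[0, 1]`, length 6.
#' @return an object of class `wrist_state`.
#' @export
wrist_state <- function(q = c(0, 0, 0), qdot = c(0, 0, 0), a = rep(0, 6)) {
  stopifnot(length(q) == 3, length(qdot) == 3, length(a) == 6,
            all(a >= 0 & a <= 1))
  structure(list(q = unname(q), qdot = unname(qdot), a = unname(a)),
            class = "wrist_state")
}

#' First-order activation dynamics, exact discrete update
#'
#' Integrates `da/dt = (u - a)/tau` over a step `dt` with constant
#' excitation `u`, using the closed-form exponential solution. The time
#' constant is `tau_act` when the excitation exceeds the activation and
#' `tau_deact` otherwise.
#'
#' @param a current activation(s) in `[0, 1]`.
#' @param u excitation(s) in `[0, 1]`, recycled against `a`.
#' @param dt time step (s).
#' @param tau_act,tau_deact activation/deactivation time constants (s).
#' @return updated activation(s), guaranteed in `[0, 1]`.
#' @export
activation_step <- function(a, u, dt, tau_act = 0.015, tau_deact = 0.060) {
  stopifnot(dt > 0, all(a >= 0 & a <= 1), all(u >= 0 & u <= 1))
  tau <- ifelse(u > a, tau_act, tau_deact)
  out <- u + (a - u) * exp(-dt / tau)
  pmin(pmax(out, 0), 1)
}

#' Hill-type muscle-tendon forces
#'
#' Rigid-tendon force: `F = f_max * (a * f_l * f_v + f_p)`, with Gaussian
#' active force-length, hyperbolic force-velocity normalized to 1 at zero
#' velocity, and an exponential passive curve that is zero at and below
#' optimal length. Fiber length follows the constant-moment-arm geometry
#' `l = l_opt - r . (q - q_rest)`.
#'
#' @param model a [wrist_model()].
#' @param a activations, length 6.
#' @param q,qdot joint angles (rad) and velocities (rad/s), length 3.
#' @return named vector of 6 non-negative forces (N).
#' @export
muscle_force <- function(model, a, q = model$q_rest, qdot = c(0, 0, 0)) {
  stopifnot(inherits(model, "wrist_model"), all(a >= 0 & a <= 1))
  f <- .cpp_muscle_forces(model, as.numeric(a), as.numeric(q),
                          as.numeric(qdot))
  names(f) <- model$muscles
  f
}

#' Joint torques from muscle forces
#'
#' `tau = t(R) %*% F - K (q - q_rest) - B qdot` with `R` the 6 x 3 signed
#' moment-arm matrix, passive joint stiffness `K` and damping `B`.
#'
#' @param model a [wrist_model()].
#' @param forces muscle forces (N), length 6.
#' @param q,qdot joint state.
#' @return named torque vector (N m), length 3.
#' @export
joint_torques <- function(model, forces, q = model$q_rest,
                          qdot = c(0, 0, 0)) {
  stopifnot(length(forces) == 6, all(forces >= 0))
  tau <- drop(crossprod(model$moment_arms, forces)) -
    model$stiffness * (q - model$q_rest) - model$damping * qdot
  names(tau) <- model$dofs
  tau
}

#' Open-loop forward simulation of the wrist
#'
#' Integrates activation dynamics and `I qddot = tau` with fixed-step RK4,
#' zero-order-holding the per-window excitations between control samples.
#' Joint limits are enforced by clamping with velocity zeroing. No feedback
#' correction is applied.
#'
#' @param model a [wrist_model()].
#' @param excitations an [excitation_set()] (windows x 6 matrix on a window
#'   grid), values in `[0, 1]`.
#' @param initial a [wrist_state()]; defaults to rest.
#' @param dt integration step (s), default 1e-3; must not exceed the
#'   excitation hold interval.
#' @param dof_mask optional windows x 3 0/1 matrix; a 0 entry suppresses all
#'   muscle torque on that DoF during that window (single-DoF gating).
#' @param t_end simulation end time; defaults to the grid's trial duration.
#' @return a list of class `kin_sim` with `time`, `q` (n x 3), `qdot`, `a`.
#' @export
forward_simulate <- function(model, excitations, initial = wrist_state(),
                             dt = 1e-3, dof_mask = NULL, t_end = NULL) {
  stopifnot(inherits(model, "wrist_model"),
            inherits(excitations, "excitation_set"))
  grid <- attr(excitations, "grid")
  U <- unclass(excitations)
  attr(U, "grid") <- NULL
  stopifnot(dt <= grid$step + 1e-12)
  if (is.null(t_end)) t_end <- grid$duration
  if (!is.null(dof_mask)) {
    dof_mask <- matrix(as.integer(dof_mask), nrow = nrow(U), ncol = 3)
  }
  sim <- .cpp_simulate(model, U, grid$step, t_end, dt,
                       initial$q, initial$qdot, initial$a, dof_mask)
  colnames(sim$q) <- model$dofs
  colnames(sim$qdot) <- model$dofs
  colnames(sim$a) <- model$muscles
  class(sim) <- "kin_sim"
  sim
}

#' Verify rest equilibrium of a wrist model
#'
#' With zero activations at the rest posture the net joint torque must
#' vanish; in this model that holds because passive muscle force is zero at
#' and below optimal fiber length and the rest posture is held by passive
#' joint stiffness.
#'
#' @param model a [wrist_model()].
#' @param tol residual tolerance (N m).
#' @return list with `pass` and `residual` (max absolute net torque, N m).
#' @export
verify_rest_equilibrium <- function(model, tol = 1e-9) {
  f <- muscle_force(model, a = rep(0, 6), q = model$q_rest,
                    qdot = c(0, 0, 0))
  tau <- joint_torques(model, f, q = model$q_rest, qdot = c(0, 0, 0))
  res <- max(abs(tau))
  list(pass = res < tol, residual = res)
}

#' @export
print.wrist_model <- function(x, ...) {
  cat("<wrist_model> 6 Hill-type muscle-tendon units, 3 DoF\n")
  cat("  f_max (N):", paste(x$muscles, x$f_max, collapse = ", "), "\n")
  cat("  joint limits (rad):",
      paste(sprintf("%s [%.2f, %.2f]", x$dofs, x$q_min, x$q_max),
            collapse = "  "), "\n")
  invisible(x)
}
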