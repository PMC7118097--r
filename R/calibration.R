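#' @name calibration
#' @title Computed-muscle-control style calibration
#'
#' @description
#' Closed-loop use of the wrist model to produce the supervision signal for
#' neural-mapping training: recorded kinematics are scaled to the model's
#' joint boundaries, then tracking muscle excitations are computed window by
#' window with a PD acceleration law resolved by static optimization
#' (minimum sum of squared activations), restricting antagonist muscles to
#' zero while the absolute angle of the actuated DoF increases.
NULL

#' Fit a per-DoF kinematics scaler
#'
#' Maps the observed per-direction extremes of each DoF onto the model's
#' joint limits with a zero-preserving piecewise-linear map (positive
#' angles scaled by `q_max/obs_max`, negative by `q_min/obs_min`), with the
#' exact inverse for mapping model output back to recorded units.
#'
#' @param kins a `kin_series` or list of them (e.g. all calibration trials).
#' @param model a [wrist_model()] supplying the joint limits.
#' @param min_range smallest acceptable observed range (rad) per direction.
#' @return an object of class `kin_scaler` with `gain_pos`, `gain_neg`.
#' @export
fit_scaler <- function(kins, model, min_range = 1e-6) {
  if (inherits(kins, "kin_series")) kins <- list(kins)
  Q <- do.call(rbind, lapply(kins, function(k) k$q))
  obs_max <- apply(Q, 2, max); obs_min <- apply(Q, 2, min)
  if (any(obs_max < min_range) || any(obs_min > -min_range))
    stop("degenerate input: a DoF direction has (near-)zero recorded range")
  structure(list(gain_pos = model$q_max / obs_max,
                 gain_neg = model$q_min / obs_min,
                 obs_max = obs_max, obs_min = obs_min),
            class = "kin_scaler")
}

scale_q <- function(scaler, q, inverse = FALSE) {
  gp <- scaler$gain_pos; gn <- scaler$gain_neg
  if (inverse) { gp <- 1 / gp; gn <- 1 / gn }
  pos <- q > 0
  q * ifelse(pos, rep(gp, each = nrow(q)), rep(gn, each = nrow(q)))
}

#' Apply or invert a kinematics scaler
#'
#' @param scaler a [fit_scaler()] object.
#' @param kin a `kin_series`.
#' @param inverse if `TRUE`, map model units back to recorded units.
#' @return scaled `kin_series`.
#' @export
scale_kinematics <- function(scaler, kin, inverse = FALSE) {
  stopifnot(inherits(scaler, "kin_scaler"), inherits(kin, "kin_series"))
  kin_series(kin$time, scale_q(scaler, kin$q, inverse))
}

# smoothed d|q|/dt of the actuated DoF (50-ms moving average of the slope)
abs_angle_slope <- function(kin, dof, smooth_s = 0.05) {
  t <- kin$time; x <- abs(kin$q[, dof])
  dt <- mean(diff(t))
  sl <- c(diff(x) / diff(t), 0)
  k <- max(1, round(smooth_s / dt))
  if (k > 1) {
    kern <- rep(1 / k, k)
    sl <- as.numeric(stats::filter(sl, kern, sides = 2))
    sl[is.na(sl)] <- 0
  }
  sl
}

#' Antagonist mask for single-DoF calibration trials
#'
#' While the absolute angle of the actuated DoF increases (slope of a 50-ms
#' moving average above `slope_tol`), muscles whose moment arm opposes the
#' ongoing direction are forced to zero; during pauses and the return the
#' mask is released. Muscles with no moment on the actuated DoF are never
#' masked.
#'
#' @param reference reference `kin_series` of a single-DoF trial.
#' @param model a [wrist_model()].
#' @param grid the window grid on which excitations are computed.
#' @param dof actuated DoF (`"FE"`, `"RU"`, `"PS"`); inferred as the DoF
#'   with the largest range when `NULL`.
#' @param slope_tol slope threshold (rad/s).
#' @return logical windows x 6 matrix; `TRUE` = muscle forced to zero.
#' @export
antagonist_mask <- function(reference, model, grid, dof = NULL,
                            slope_tol = 0.02) {
  stopifnot(inherits(reference, "kin_series"))
  rng <- apply(abs(reference$q), 2, max)
  if (is.null(dof)) dof <- DOFS[which.max(rng)]
  if (max(rng) > 1e-6 && sum(rng > 0.2 * max(rng)) > 1)
    stop("unsupported: antagonist mask is defined for single-DoF trials")
  d <- match(dof, DOFS)
  sl <- abs_angle_slope(reference, d)
  slope_w <- approx(reference$time, sl, xout = grid$starts, rule = 2)$y
  qd <- approx(reference$time, reference$q[, d], xout = grid$starts,
               rule = 2)$y
  mask <- matrix(FALSE, grid$n, 6, dimnames = list(NULL, model$muscles))
  up <- slope_w > slope_tol
  dir <- sign(qd)
  r <- model$moment_arms[, d]
  for (w in which(up)) {
    if (dir[w] == 0) next
    mask[w, r * dir[w] < 0] <- TRUE
  }
  mask
}

# Bounded ridge least squares: minimize ||A x - b||^2 + mu ||x||^2 subject
# to 0 <= x <= 1 and x[forced] = 0, by a small active-set iteration. The
# ridge term (mu -> 0) selects the minimum-norm solution of the redundant
# torque-sharing problem.
solve_bounded_ls <- function(A, b, forced = rep(FALSE, ncol(A)),
                             mu = NULL, max_iter = 60) {
  p <- ncol(A)
  if (is.null(mu)) mu <- 1e-8 * max(colSums(A^2), 1e-12)
  at_zero <- forced
  at_one <- rep(FALSE, p)
  for (it in seq_len(max_iter)) {
    free <- !(at_zero | at_one)
    x <- numeric(p); x[at_one] <- 1
    if (any(free)) {
      Af <- A[, free, drop = FALSE]
      rhs <- b - if (any(at_one)) rowSums(A[, at_one, drop = FALSE]) else 0
      M <- crossprod(Af) + diag(mu, sum(free))
      x[free] <- drop(solve(M, crossprod(Af, rhs)))
    }
    changed <- FALSE
    neg <- free & x < -1e-12
    big <- free & x > 1 + 1e-12
    if (any(neg)) { at_zero[which(neg)[which.min(x[neg])]] <- TRUE; changed <- TRUE }
    else if (any(big)) { at_one[which(big)[which.max(x[big])]] <- TRUE; changed <- TRUE }
    if (!changed) {
      # KKT release check for variables clamped by the iteration (not forced)
      g <- 2 * (crossprod(A, A %*% pmin(pmax(x, 0), 1) - b) + mu * x)
      rel0 <- at_zero & !forced & g < -1e-9
      rel1 <- at_one & g > 1e-9
      if (any(rel0)) { at_zero[which(rel0)[1]] <- FALSE }
      else if (any(rel1)) { at_one[which(rel1)[1]] <- FALSE }
      else return(pmin(pmax(x, 0), 1))
    }
  }
  pmin(pmax(x, 0), 1)
}

#' Static optimization of the muscle redundancy problem
#'
#' Finds activations minimizing the sum of squared activations subject to
#' the muscle torques matching a required torque (within a slack tolerance),
#' bounds `[0, 1]`, and an optional mask of muscles forced to zero. With the
#' rigid-tendon Hill force the constraint is linear in the activations, so
#' the problem reduces to bounded least squares with a vanishing ridge.
#'
#' @param model a [wrist_model()].
#' @param state a [wrist_state()] fixing fiber lengths and velocities.
#' @param tau_req required muscle torque (N m), length 3; this is the torque
#'   the muscle forces (active plus passive) must produce.
#' @param mask logical length-6; `TRUE` = activation forced to zero.
#' @param tol torque-residual tolerance (N m) above which the step is
#'   flagged saturated.
#' @return list with `a` (length 6), `residual` (achieved-torque error,
#'   length 3) and `saturated` flag.
#' @export
static_optimization_step <- function(model, state, tau_req,
                                     mask = rep(FALSE, 6), tol = 1e-3) {
  stopifnot(all(is.finite(tau_req)))
  comp <- .cpp_force_components(model, state$q, state$qdot)
  A <- t(model$moment_arms * comp$gain)            # 3 x 6
  b <- tau_req - drop(crossprod(model$moment_arms, comp$passive))
  a <- solve_bounded_ls(A, b, forced = mask)
  resid <- drop(A %*% a) - b
  list(a = a, residual = resid, saturated = max(abs(resid)) > tol)
}

#' Tracking muscle excitations for a reference trial
#'
#' The computed-muscle-control recipe: at each control interval (one window
#' step) a desired acceleration
#' `qddot_des = qddot_ref + kv (qdot_ref - qdot) + kp (q_ref - q)` evaluated
#' one lookahead ahead is converted into a required muscle torque, resolved
#' into activations by [static_optimization_step()] under the
#' [antagonist_mask()], and converted into excitations by exact inversion of
#' the first-order activation dynamics. The model state is advanced with the
#' computed excitation (closed loop), so the returned excitation profiles
#' are dynamically consistent: replaying them open loop reproduces the
#' tracked kinematics.
#'
#' @param model a [wrist_model()].
#' @param reference `kin_series` scaled to the model's boundaries.
#' @param grid window grid for the excitation samples.
#' @param kp,kv position (1/s^2) and velocity (1/s) tracking gains.
#' @param lookahead reference lookahead (s); defaults to one window step.
#' @param dof actuated DoF for the antagonist mask (inferred when `NULL`).
#' @param dt inner integration step (s).
#' @param tol torque-residual tolerance (N m).
#' @return an [excitation_set()] with attributes `saturated` (per-window
#'   flag) and `tracked` (the closed-loop kinematics on the control grid).
#' @export
tracking_excitations <- function(model, reference, grid, kp = 400, kv = 40,
                                 lookahead = NULL, dof = NULL, dt = 1e-3,
                                 tol = 1e-3) {
  stopifnot(inherits(model, "wrist_model"), inherits(reference, "kin_series"))
  if (is.null(lookahead)) lookahead <- grid$step
  rng <- apply(abs(reference$q), 2, max)
  moving <- max(rng) > 1e-9
  mask <- if (moving) antagonist_mask(reference, model, grid, dof = dof)
          else matrix(FALSE, grid$n, 6)

  # reference position/velocity/acceleration at arbitrary times
  tref <- reference$time
  qref_f <- lapply(1:3, function(d) approxfun(tref, reference$q[, d],
                                              rule = 2))
  dtr <- mean(diff(tref))
  qd_ref <- apply(reference$q, 2, function(x) c(diff(x) / dtr, 0))
  qdd_ref <- apply(qd_ref, 2, function(x) c(0, diff(x) / dtr))
  qd_f <- lapply(1:3, function(d) approxfun(tref, qd_ref[, d], rule = 2))
  qdd_f <- lapply(1:3, function(d) approxfun(tref, qdd_ref[, d], rule = 2))

  st <- wrist_state()
  n <- grid$n
  U <- matrix(0, n, 6)
  sat <- logical(n)
  Qtrk <- matrix(0, n, 3)
  bounds <- c(grid$starts, grid$duration)
  for (k in seq_len(n)) {
    Qtrk[k, ] <- st$q
    h <- bounds[k + 1] - bounds[k]
    tl <- min(bounds[k] + lookahead, grid$duration)
    qr <- vapply(qref_f, function(f) f(tl), 0)
    qdr <- vapply(qd_f, function(f) f(tl), 0)
    qddr <- vapply(qdd_f, function(f) f(tl), 0)
    qdd_des <- qddr + kv * (qdr - st$qdot) + kp * (qr - st$q)
    tau_req <- model$inertia * qdd_des +
      model$stiffness * (st$q - model$q_rest) + model$damping * st$qdot
    sol <- static_optimization_step(model, st, tau_req, mask = mask[k, ],
                                    tol = tol)
    sat[k] <- sol$saturated
    # invert exact activation update over the hold interval
    tau_a <- ifelse(sol$a > st$a, model$tau_act, model$tau_deact)
    E <- exp(-h / tau_a)
    u <- (sol$a - st$a * E) / (1 - E)
    u[mask[k, ]] <- 0
    u <- pmin(pmax(u, 0), 1)
    U[k, ] <- u
    sim <- .cpp_simulate(model, matrix(u, 1), h, h, dt, st$q, st$qdot,
                         st$a, NULL)
    m <- nrow(sim$q)
    st <- wrist_state(sim$q[m, ], sim$qdot[m, ], sim$a[m, ])
  }
  out <- excitation_set(U, grid)
  attr(out, "saturated") <- sat
  attr(out, "tracked") <- kin_series(grid$starts, Qtrk)
  attr(out, "mask") <- mask
  out
}
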