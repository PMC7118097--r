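test_that("kinematics scaler maps observed extremes onto model limits", {
  m <- wrist_model()
  t <- seq(0, 1, by = 0.01)
  q <- cbind(0.6 * sin(2 * pi * t), 0.2 * sin(2 * pi * t),
             0.7 * sin(2 * pi * t))
  kin <- kin_series(t, q)
  sc <- fit_scaler(kin, m)
  expect_equal(unname(sc$gain_pos[1]), 1.2 / 0.6) # FE peak 0.6 -> limit 1.2
  scaled <- scale_kinematics(sc, kin)
  expect_equal(max(scaled$q[, 1]), m$q_max[1], tolerance = 1e-9)
  expect_equal(min(scaled$q[, 3]), m$q_min[3], tolerance = 1e-9)
  # rest maps to rest and the round trip is the identity
  expect_equal(scaled$q[1, ], c(FE = 0, RU = 0, PS = 0))
  back <- scale_kinematics(sc, scaled, inverse = TRUE)
  expect_equal(back$q, kin$q, tolerance = 1e-12)

  flat <- kin_series(t, cbind(0.6 * sin(2 * pi * t), 0, 0))
  expect_error(fit_scaler(flat, m), "degenerate")
})

test_that("antagonist mask follows direction and releases at the pause", {
  m <- wrist_model()
  grid <- build_window_grid(2.5, 0.1, 0.05)
  kin <- generate_task_profile(task_profile("FE", "positive", 1.2))
  mask <- antagonist_mask(kin, m, grid, dof = "FE")
  up <- grid$starts > 0.15 & grid$starts < 0.85 # well inside the up-ramp
  expect_true(all(mask[up, "ECU"]))
  expect_true(all(mask[up, "ECRL"]))
  expect_true(!any(mask[, "FCR"] & up)) # agonists never masked going up
  pause <- grid$starts > 1.1 & grid$starts < 1.35
  expect_true(!any(mask[pause, ])) # |q| constant: nothing masked

  kin_ps <- generate_task_profile(task_profile("PS", "positive", 1.4))
  mps <- antagonist_mask(kin_ps, m, grid, dof = "PS")
  expect_true(all(mps[up, "SUP"]))
  expect_false(any(mps[, "PT"]))
  expect_false(any(mps[up, "FCR"])) # zero PS moment arm: not an antagonist

  multi <- kin_series(kin$time, cbind(kin$q[, 1], kin$q[, 1], 0))
  expect_error(antagonist_mask(multi, m, grid), "single-DoF")
})

test_that("static optimization returns zero at rest and honors masks", {
  m <- wrist_model()
  st <- wrist_state()
  sol <- static_optimization_step(m, st, c(0, 0, 0))
  expect_equal(sol$a, rep(0, 6))
  expect_false(sol$saturated)

  # +FE torque with extensors masked: only flexors recruited
  mask <- c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  sol2 <- static_optimization_step(m, st, c(0.5, 0, 0), mask = mask)
  expect_true(all(sol2$a[3:4] == 0))
  expect_gt(sum(sol2$a[1:2]), 0)
  expect_lt(max(abs(sol2$residual)), 1e-3)

  # infeasible demand is flagged, not an error
  sol3 <- static_optimization_step(m, st, c(50, 0, 0))
  expect_true(sol3$saturated)
  expect_true(all(sol3$a >= 0 & sol3$a <= 1))
})

test_that("static optimization matches a dense grid search on 2 muscles", {
  m <- wrist_model()
  st <- wrist_state()
  comp <- wristnms:::`.cpp_force_components`(m, st$q, st$qdot)
  A3 <- t(m$moment_arms * comp$gain)
  mu <- 1e-8 * max(colSums(A3^2))
  set.seed(31)
  for (trial in 1:20) {
    keep <- sample(1:6, 2)
    A <- A3[, keep, drop = FALSE]
    b <- drop(A %*% runif(2, 0, 0.6)) # feasible demand
    sol <- wristnms:::solve_bounded_ls(A, b, mu = mu)
    gr <- seq(0, 1, by = 0.004)
    G <- as.matrix(expand.grid(a1 = gr, a2 = gr))
    obj <- colSums((A %*% t(G) - b)^2) + mu * rowSums(G^2)
    best <- G[which.min(obj), ]
    expect_lt(max(abs(sol - unlist(best))), 0.01)
  }
})

test_that("tracking a rest reference produces (near-)zero excitations", {
  m <- wrist_model()
  grid <- build_window_grid(1, 0.1, 0.05)
  kin <- kin_series(seq(0, 1, by = 0.01), matrix(0, 101, 3))
  exc <- tracking_excitations(m, kin, grid)
  expect_lt(max(unclass(exc)), 1e-3)
})

test_that("masked antagonists have exactly zero excitation on the up-ramp", {
  m <- wrist_model()
  grid <- build_window_grid(2.5, 0.1, 0.05)
  kin <- generate_task_profile(task_profile("FE", "positive", 1.2))
  exc <- tracking_excitations(m, kin, grid, dof = "FE")
  mask <- attr(exc, "mask")
  expect_true(all(unclass(exc)[mask] == 0))
  up <- grid$starts > 0.15 & grid$starts < 0.85
  expect_true(all(unclass(exc)[up, c("ECU", "ECRL")] == 0))
  expect_true(all(unclass(exc) >= 0 & unclass(exc) <= 1))
})

test_that("tracking error decreases with stiffer position gain", {
  m <- wrist_model()
  grid <- build_window_grid(2.5, 0.1, 0.05)
  kin <- generate_task_profile(task_profile("RU", "positive", 0.4))
  err <- vapply(c(50, 400), function(kp) {
    exc <- tracking_excitations(m, kin, grid, kp = kp, kv = 2 * sqrt(kp),
                                dof = "RU")
    trk <- attr(exc, "tracked")
    ref <- approx(kin$time, kin$q[, 2], xout = trk$time, rule = 2)$y
    sqrt(mean((trk$q[, 2] - ref)^2))
  }, 0)
  expect_lt(err[2], err[1])
})

test_that("replaying tracking excitations reproduces the reference", {
  m <- wrist_model()
  grid <- build_window_grid(2.5, 0.1, 0.01)
  kin <- generate_task_profile(task_profile("FE", "positive", 1.2))
  exc <- tracking_excitations(m, kin, grid, dof = "FE")
  sim <- forward_simulate(m, exc)
  qw <- approx(sim$time, sim$q[, 1], xout = kin$time, rule = 2)$y
  expect_gt(r2(kin$q[, 1], qw), 0.95)
})
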