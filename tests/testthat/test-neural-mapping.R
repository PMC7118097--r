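test_that("IRLS recovers exact coefficients on clean linear data", {
  set.seed(41)
  x <- rpois(60, 3)
  x[1:2] <- c(0, 8) # guarantee spread
  y <- 0.1 + 0.02 * x
  fit <- fit_unit_regressor(x, y)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$slope, 0.02, tolerance = 1e-10)
})

test_that("IRLS beats OLS under gross outliers", {
  set.seed(42)
  wins <- 0
  for (s in 1:25) {
    x <- rpois(80, 4) + 1
    y <- 0.1 + 0.02 * x + rnorm(80, 0, 0.002)
    bad <- sample(80, 8)
    y[bad] <- 1.0 # gross outliers
    rob <- fit_unit_regressor(x, y)
    ols <- coef(lm(y ~ x))
    err_rob <- abs(rob$intercept - 0.1) + abs(rob$slope - 0.02)
    err_ols <- abs(ols[1] - 0.1) + abs(ols[2] - 0.02)
    wins <- wins + (err_rob < err_ols)
  }
  expect_gte(wins, 24) # robust practically always wins
})

test_that("IRLS rejects constant predictors", {
  expect_error(fit_unit_regressor(rep(3, 10), runif(10)),
               "rank deficiency")
  expect_error(fit_unit_regressor(1, 0.5)) # fewer than 2 points
})

test_that("assignment follows the coincidence threshold", {
  g <- build_window_grid(1, 0.1, 0.1)
  # FCR excitation positive in windows 1..8 (0-0.8 s), zero after
  E <- matrix(0, 10, 6)
  E[1:8, 1] <- 0.5
  exc <- excitation_set(E, g)
  # 10 discharges at window centers: 8 coincide with FCR activity
  t8 <- seq(0.05, 0.95, by = 0.1)
  sp <- spike_train_set(list(u1 = t8), 1)
  am <- assign_units(sp, exc, threshold = 0.8)
  expect_identical(am$units$u1, "FCR")

  # only 7 coincident -> not assigned
  E7 <- matrix(0, 10, 6); E7[1:7, 1] <- 0.5
  am7 <- assign_units(sp, excitation_set(E7, g), threshold = 0.8)
  expect_identical(am7$unassigned, "u1")

  # qualifying for two muscles assigns to both
  E2 <- E; E2[1:8, 2] <- 0.3
  am2 <- assign_units(sp, excitation_set(E2, g))
  expect_setequal(am2$units$u1, c("FCR", "FCU"))

  # a unit with zero spikes is unassigned (flagged)
  sp0 <- spike_train_set(list(u1 = t8, u2 = numeric(0)), 1)
  am0 <- assign_units(sp0, exc)
  expect_true("u2" %in% am0$unassigned)
})

test_that("median ensemble, clamping and fallback behave as specified", {
  g <- build_window_grid(0.3, 0.1, 0.1)
  # three units assigned to FCR with models giving 0.2 / 0.4 / 0.9 at
  # count 1; every other muscle gets unit "a" mapping to 0 so no window is
  # ever silent for them
  mk <- function(b0) structure(list(intercept = b0, slope = 0),
                               class = "linear_unit_model")
  am <- structure(list(units = list(a = MUSCLES6(), b = "FCR", c = "FCR"),
                       unassigned = character(0), threshold = 0.8),
                  class = "assignment_map")
  um <- lapply(MUSCLES6(), function(m) list(a = mk(0)))
  names(um) <- MUSCLES6()
  um$FCR <- list(a = mk(0.2), b = mk(0.4), c = mk(0.9))
  nm <- structure(list(assignment = am, unit_models = um,
                       fallback = NULL, fallback_only = character(0)),
                  class = "neural_model")
  counts <- matrix(0L, 3, 3, dimnames = list(NULL, c("a", "b", "c")))
  counts[1, ] <- 1L        # all three active -> median 0.4
  counts[2, c(1, 2)] <- 1L # two active -> midpoint 0.3
  dsc <- structure(counts, grid = g, unit_ids = c("a", "b", "c"),
                   class = "dsc_matrix")
  # window 3 is fully silent and no fallback exists: configuration error
  expect_error(predict_excitations(nm, dsc), "no fallback")

  counts[3, 1] <- 1L # every window has an active unit; no fallback needed
  dsc <- structure(counts, grid = g, unit_ids = c("a", "b", "c"),
                   class = "dsc_matrix")
  E <- unclass(predict_excitations(nm, dsc))
  expect_equal(unname(E[1, "FCR"]), 0.4)
  expect_equal(unname(E[2, "FCR"]), 0.3)
  expect_equal(unname(E[3, "FCR"]), 0.2)
  expect_true(all(E[, "FCU"] == 0))

  # negative raw estimates clamp to zero
  nm$unit_models$FCR <- list(a = mk(-0.05))
  E2 <- unclass(predict_excitations(nm, dsc))
  expect_equal(unname(E2[1, "FCR"]), 0)
})

test_that("median ensemble is insensitive to corrupting a single unit", {
  ds <- small_dataset()
  grid <- ds$grid
  tr <- ds$trials[[which(sapply(ds$trials, function(t)
    t$task$dof == "FE" && t$task$direction == "positive"))[1]]]
  exc <- tr$true_excitations
  am <- assign_units(tr$spikes, exc)
  dsc <- extract_dsc(tr$spikes, grid)
  nm <- train_neural_model(list(dsc), list(exc), NULL, am)
  nm$fallback <- zero_fallback() # silent muscles predict 0
  td <- zero_td(grid)
  base <- unclass(predict_excitations(nm, dsc, td))

  # delete 20% of spikes from one assigned FCR unit
  fcr_units <- names(nm$unit_models$FCR)
  expect_gt(length(fcr_units), 0)
  id <- fcr_units[1]
  sp2 <- tr$spikes
  tt <- sp2$trains[[id]]
  set.seed(7)
  sp2$trains[[id]] <- sort(sample(tt, round(0.8 * length(tt))))
  dsc2 <- extract_dsc(sp2, grid)
  pert <- unclass(predict_excitations(nm, dsc2, td))

  f <- nm$unit_models$FCR[[id]]
  est1 <- f$intercept + f$slope * unclass(dsc)[, id]
  est2 <- f$intercept + f$slope * unclass(dsc2)[, id]
  act <- unclass(dsc)[, id] > 0 & unclass(dsc2)[, id] > 0
  expect_lt(mean(abs(base[act, "FCR"] - pert[act, "FCR"])),
            mean(abs(est1[act] - est2[act])))
})

test_that("unit models are fitted per assigned (muscle, unit) pair", {
  ds <- small_dataset()
  grid <- ds$grid
  idx <- which(sapply(ds$trials, function(t) t$repetition_index == 1))
  exc_list <- lapply(ds$trials[idx], `[[`, "true_excitations")
  spk_list <- lapply(ds$trials[idx], `[[`, "spikes")
  dsc_list <- lapply(spk_list, extract_dsc, grid = grid)
  am <- assign_units(spk_list, exc_list)
  nm <- train_neural_model(dsc_list, exc_list, NULL, am)
  for (m in c("FCR", "FCU")) {
    ids <- names(nm$unit_models[[m]])
    # every fitted model corresponds to an assigned pair
    for (id in ids) expect_true(m %in% am$units[[id]])
    # a unit assigned to two muscles yields two independent models
  }
  multi <- names(am$units)[vapply(am$units, length, 0L) >= 2]
  if (length(multi)) {
    id <- multi[1]
    ms <- am$units[[id]][1:2]
    f1 <- nm$unit_models[[ms[1]]][[id]]
    f2 <- nm$unit_models[[ms[2]]][[id]]
    if (!is.null(f1) && !is.null(f2))
      expect_false(isTRUE(all.equal(c(f1$intercept, f1$slope),
                                    c(f2$intercept, f2$slope))))
  }
})
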