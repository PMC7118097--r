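test_that("task profiles are triangular with a plateau", {
  task <- task_profile("FE", "positive", 1.0, ramp_duration = 1,
                       pause_duration = 0.5, sample_rate = 100)
  kin <- generate_task_profile(task)
  expect_equal(max(kin$time), 2.5)
  at <- function(t) kin$q[which.min(abs(kin$time - t)), 1]
  expect_equal(unname(at(0.5)), 0.5, tolerance = 1e-9) # linear ramp midpoint
  plateau <- kin$time >= 1.0 & kin$time <= 1.5
  expect_true(all(abs(kin$q[plateau, 1] - 1.0) < 1e-9))
  expect_equal(unname(kin$q[1, 1]), 0)
  expect_equal(unname(kin$q[nrow(kin$q), 1]), 0)
  expect_true(all(kin$q[, 2] == 0) && all(kin$q[, 3] == 0))

  neg <- generate_task_profile(task_profile("RU", "negative", 0.4))
  expect_equal(unname(min(neg$q[, 2])), -0.4)
  expect_error(task_profile("FE", "positive", -1), "invalid argument")
  expect_error(task_profile("FE", "positive", 1, sample_rate = 0),
               "invalid argument")
})

test_that("spike sampling respects thresholds, rates and the seed", {
  pool <- motoneuron_pool("FCR", thresholds = 0.3, gains = 50)
  # below threshold everywhere: no spikes
  s0 <- sample_spikes(pool, function(t) 0.1, duration = 5, seed = 1)
  expect_length(s0$trains[[1]], 0)

  # constant suprathreshold excitation: empirical rate ~ r_min + g (e - th)
  s1 <- sample_spikes(pool, function(t) 0.5, duration = 30, seed = 2)
  rate <- length(s1$trains[[1]]) / 30
  expect_equal(rate, 8 + 50 * 0.2, tolerance = 1 / 18) # 18 +/- 1 pps

  # rate saturates at r_max
  s2 <- sample_spikes(pool, function(t) 1.0, duration = 30, seed = 3)
  expect_lt(length(s2$trains[[1]]) / 30, 35 * 1.1)

  # determinism
  s3 <- sample_spikes(pool, function(t) 0.5, duration = 30, seed = 2)
  expect_identical(s1$trains, s3$trains)
  # spikes only where excitation exceeds the threshold
  ef <- function(t) ifelse(t < 5, 0.6, 0)
  s4 <- sample_spikes(pool, ef, duration = 10, seed = 4)
  expect_true(all(s4$trains[[1]] < 5 + 0.3)) # small renewal overhang only
})

test_that("corruption is a pure filter with the specified modes", {
  pool <- motoneuron_pool("FCR", thresholds = c(0.1, 0.2),
                          gains = c(50, 50))
  kin <- generate_task_profile(task_profile("FE", "positive", 1.0))
  g <- build_window_grid(2.5, 0.1, 0.01)
  ramp <- function(t) approx(kin$time, abs(kin$q[, 1]), xout = t,
                             rule = 2)$y
  sp <- sample_spikes(pool, ramp, duration = 2.5, seed = 5)
  expect_gt(length(sp$trains[[1]]), 5)

  idspec <- corruption_spec(0, 0, 0, seed = 9)
  expect_identical(corrupt_spikes(sp, idspec, kin, 1.0, "FE")$trains,
                   sp$trains)

  allspec <- corruption_spec(1, 0, 0, seed = 9)
  out <- corrupt_spikes(sp, allspec, kin, 1.0, "FE")
  expect_true(all(lengths(out$trains) == 0))

  silspec <- corruption_spec(0, 0, 0.2, seed = 9)
  sil <- corrupt_spikes(sp, silspec, kin, 1.0, "FE")
  for (tt in sil$trains) if (length(tt))
    expect_true(all(ramp(tt) >= 0.2 * 1.0))

  # pure filter: surviving spikes are a subset, order preserved
  mix <- corrupt_spikes(sp, corruption_spec(0.3, 0.2, 0.1, seed = 10),
                        kin, 1.0, "FE")
  for (id in names(mix$trains)) {
    expect_true(all(mix$trains[[id]] %in% sp$trains[[id]]))
    expect_false(is.unsorted(mix$trains[[id]]))
  }
})

test_that("surrogate EMG has the contracted rate, floor and monotonicity", {
  g <- build_window_grid(1, 0.1, 0.05)
  zero <- excitation_set(matrix(0, g$n, 6), g)
  e0 <- synthesize_emg(zero, n_channels = 4, seed = 6, baseline_sd = 0.02)
  expect_equal(e0$sample_rate, 2048)
  rms0 <- apply(e0$samples, 1, function(x) sqrt(mean(x^2)))
  expect_true(all(abs(rms0 - 0.02) / 0.02 < 0.05)) # baseline only

  lvl <- function(amp, seed) {
    E <- matrix(0, g$n, 6); E[, 1] <- amp
    e <- synthesize_emg(excitation_set(E, g), n_channels = 4, seed = seed)
    apply(e$samples, 1, function(x) sqrt(mean(x^2)))
  }
  # doubling a constant excitation raises RMS on every channel (paired
  # noise realizations via the shared seed)
  wins <- mapply(function(s) all(lvl(0.8, s) > lvl(0.4, s)), 1:10)
  expect_true(all(wins))
})

test_that("datasets have the protocol structure and are reproducible", {
  ds <- small_dataset(corrupted = TRUE)
  expect_length(ds$trials, 18)
  meta <- data.frame(
    dof = sapply(ds$trials, function(t) t$task$dof),
    dir = sapply(ds$trials, function(t) t$task$direction),
    rep = sapply(ds$trials, function(t) t$repetition_index))
  counts <- table(meta$dof, meta$dir)
  expect_true(all(counts == 3)) # 3 reps x 2 directions x 3 DoFs
  for (cb in split(meta$rep, paste(meta$dof, meta$dir)))
    expect_setequal(cb, 1:3)

  # spike-train count bounded by pool size
  for (tr in ds$trials)
    expect_lte(length(tr$spikes$trains), 6 * ds$config$n_units)

  # same seed -> identical dataset (spot-check deep equality cheaply)
  ds2 <- generate_dataset(small_config(corruption = corruption_spec()),
                          seed = 101)
  expect_identical(ds$trials[[4]]$spikes, ds2$trials[[4]]$spikes)
  expect_identical(ds$trials[[9]]$emg$samples[1, 1:50],
                   ds2$trials[[9]]$emg$samples[1, 1:50])
})

test_that("ground-truth excitations are dynamically consistent", {
  ds <- small_dataset()
  tr <- ds$trials[[1]]
  sim <- forward_simulate(ds$model, tr$true_excitations)
  d <- match(tr$task$dof, c("FE", "RU", "PS"))
  qw <- approx(sim$time, sim$q[, d], xout = tr$kinematics$time, rule = 2)$y
  expect_gt(r2(tr$kinematics$q[, d], qw), 0.95)
  # rest: all-zero reference gives (near-)zero excitations
  g <- ds$grid
  rest <- kin_series(seq(0, g$duration, by = 0.01),
                     matrix(0, length(seq(0, g$duration, by = 0.01)), 3))
  e0 <- ground_truth_excitations(ds$model, rest, g)
  expect_lt(max(unclass(e0)), 1e-3)
})
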