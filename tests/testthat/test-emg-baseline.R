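test_that("band-pass design attenuates out-of-band tones", {
  fs <- 2048
  bp <- butter_design(4, c(20, 500) / (fs / 2), "band")
  t <- seq(0, 2, by = 1 / fs)
  tone <- function(f) sin(2 * pi * f * t)
  rms <- function(x) sqrt(mean(x^2))
  r_low <- rms(filtfilt(bp, tone(4)))
  r_mid <- rms(filtfilt(bp, tone(100)))
  r_hi <- rms(filtfilt(bp, tone(900)))
  expect_lt(20 * log10(r_low / r_mid), -20)  # >= 20 dB down at 4 Hz
  expect_lt(20 * log10(r_hi / r_mid), -20)
  expect_gt(r_mid / rms(tone(100)), 0.9)     # passband ~unity
})

test_that("preprocessing rectifies and filters per channel", {
  set.seed(51)
  x <- matrix(rnorm(2 * 4096), 2, 4096)
  emg <- emg_recording(x, 2048)
  out <- preprocess_emg(emg)
  expect_equal(dim(out$samples), dim(x))
  # zero in, zero out
  z <- preprocess_emg(emg_recording(matrix(0, 1, 4096), 2048))
  expect_true(all(abs(z$samples) < 1e-12))
  # conventional order produces a non-negative signal
  conv <- preprocess_emg(emg, rectify_first = FALSE)
  expect_true(all(conv$samples >= 0))
  expect_error(preprocess_emg(emg_recording(x, 800)), "invalid argument")
})

test_that("TD features match their definitions on canonical signals", {
  g <- build_window_grid(0.1, 0.1, 0.1)
  # constant signal
  emg <- emg_recording(matrix(0.5, 1, 205), 2048)
  f <- unclass(extract_td(emg, g))
  expect_equal(unname(f[1, ]), c(0.5, 0, 0, 0))
  # alternating +/-1: ZC = N-1, WL = 2(N-1), with deadband below 2
  n <- 205
  alt <- matrix(rep(c(1, -1), length.out = n), 1)
  fa <- unclass(extract_td(emg_recording(alt, 2048), g))
  expect_equal(unname(fa[1, "ch1_zc"]), n - 1)
  expect_equal(unname(fa[1, "ch1_wl"]), 2 * (n - 1))
})

test_that("TD features equal brute force on random windows", {
  set.seed(52)
  g <- build_window_grid(0.3, 0.1, 0.1)
  for (rep in 1:25) {
    x <- matrix(rnorm(1 * 615), 1, 615)
    emg <- emg_recording(x, 2048)
    f <- unclass(extract_td(emg, g))
    delta <- 0.01 * sqrt(mean(x^2))
    for (w in 1:3) {
      i0 <- floor(g$starts[w] * 2048 + 1e-9) + 1
      i1 <- ceiling((g$starts[w] + 0.1) * 2048 - 1e-9)
      expect_equal(unname(f[w, ]), brute_td(x[1, i0:i1], delta),
                   tolerance = 1e-12)
    }
  }
})

test_that("PCA keeps the smallest component count reaching the target", {
  set.seed(53)
  # exactly 2 directions of variance among 10 columns
  base <- matrix(rnorm(200 * 2), 200, 2)
  X <- base %*% matrix(rnorm(2 * 10), 2, 10)
  p <- fit_pca(X, 0.98)
  expect_lte(p$n_components, 2)
  expect_gte(p$explained, 0.98)
  # training variance reproduced by the retained scores
  S <- apply_pca(p, X)
  expect_gte(sum(apply(S, 2, var)) / sum(apply(X, 2, var)), 0.98)
  # the training mean projects to the zero score vector
  expect_equal(unname(drop(apply_pca(p, matrix(colMeans(X), 1)))),
               rep(0, p$n_components), tolerance = 1e-10)
  # loadings depend on training data only
  p2 <- fit_pca(X, 0.98)
  expect_identical(p$rotation, p2$rotation)
})

test_that("the ANN fits simple functions and selection takes the minimum", {
  set.seed(54)
  x <- matrix(runif(200, -1, 1))
  y <- 0.3 + 0.5 * x[, 1] + rnorm(200, 0, 0.005)
  m <- train_ann(x, y, restarts = 8, seed = 5)
  expect_lt(mean((ann_predict(m, x) - y)^2), 1e-3)
  # best-of-restarts: selected validation error is the minimum
  expect_equal(m$val_mse, min(m$record$val_mse))
  # determinism under the seed
  m2 <- train_ann(x, y, restarts = 8, seed = 5)
  expect_identical(m$theta, m2$theta)
  m3 <- train_ann(x, y, restarts = 8, seed = 6)
  expect_false(identical(m$theta, m3$theta))
  expect_error(train_ann(cbind(c(1, NA)), c(1, 2)), "non-finite")
})

test_that("estimate low-pass is zero-phase with unit DC gain", {
  rate <- 100
  const <- rep(0.7, 200)
  expect_equal(lowpass_estimates(const, 1.5, rate), const, tolerance = 1e-9)
  set.seed(55)
  noise <- rnorm(500)
  expect_lt(var(lowpass_estimates(noise, 1.5, rate)), var(noise) * 0.5)
  ramp <- seq(0, 1, length.out = 300)
  sm <- lowpass_estimates(ramp, 1.5, rate)
  interior <- 100:200
  expect_lt(max(abs(sm[interior] - ramp[interior])), 0.01)
  expect_error(lowpass_estimates(const, 60, rate), "invalid argument")
})

test_that("TD and DSC concatenate on a shared grid", {
  ds <- small_dataset()
  g <- ds$grid
  tr <- ds$trials[[1]]
  td <- extract_td(preprocess_emg(tr$emg), g)
  dsc <- extract_dsc(tr$spikes, g)
  both <- concat_td_dsc(td, dsc)
  expect_equal(ncol(both), ncol(td) + ncol(dsc))
  expect_equal(nrow(both), nrow(td))
  expect_identical(unname(unclass(both)[, seq_len(ncol(td))]),
                   unname(unclass(td)[, ]))
  g2 <- build_window_grid(g$duration, g$length, g$step * 2)
  dsc2 <- extract_dsc(tr$spikes, g2)
  expect_error(concat_td_dsc(td, dsc2), "grid mismatch")
})
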