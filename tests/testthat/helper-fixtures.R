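# Shared fixtures: a small synthetic world used across test files.
# Desk-scale settings (fewer units/channels than the defaults) keep the
# suite fast; tests that probe the stated default world build it explicitly.

small_config <- function(corruption = NULL, window_step = 0.01) {
  default_config(n_units = 8, n_channels = 16, window_step = window_step,
                 corruption = corruption)
}

# cache: one small pristine dataset + one corrupted, built once per run
.fixtures <- new.env()

small_dataset <- function(seed = 101, corrupted = FALSE) {
  key <- paste0("ds_", seed, "_", corrupted)
  if (is.null(.fixtures[[key]])) {
    cfg <- small_config(corruption = if (corrupted) corruption_spec()
                        else NULL)
    .fixtures[[key]] <- generate_dataset(cfg, seed = seed)
  }
  .fixtures[[key]]
}

# brute-force DSC: double loop over (window, spike)
brute_dsc <- function(spikes, grid) {
  ids <- names(spikes$trains)
  out <- matrix(0L, grid$n, length(ids), dimnames = list(NULL, ids))
  for (w in seq_len(grid$n)) {
    s <- grid$starts[w]; e <- s + grid$length
    for (j in seq_along(ids)) {
      for (t in spikes$trains[[j]]) if (t >= s && t < e)
        out[w, j] <- out[w, j] + 1L
    }
  }
  out
}

# brute-force TD features of one window by their literal definitions
brute_td <- function(x, delta) {
  n <- length(x)
  rms <- sqrt(sum(x^2) / n)
  wl <- 0; zc <- 0; ssc <- 0
  for (i in 1:(n - 1)) {
    wl <- wl + abs(x[i + 1] - x[i])
    if (x[i] * x[i + 1] < 0 && abs(x[i + 1] - x[i]) >= delta) zc <- zc + 1
  }
  if (n >= 3) for (i in 2:(n - 1)) {
    d1 <- x[i] - x[i - 1]; d2 <- x[i] - x[i + 1]
    if (d1 * d2 > 0 && (abs(d1) >= delta || abs(d2) >= delta))
      ssc <- ssc + 1
  }
  c(rms, ssc, zc, wl)
}

# torque by explicit loops
brute_torques <- function(model, forces, q, qdot) {
  tau <- numeric(3)
  for (d in 1:3) {
    for (j in 1:6) tau[d] <- tau[d] + model$moment_arms[j, d] * forces[j]
    tau[d] <- tau[d] - model$stiffness[d] * (q[d] - model$q_rest[d]) -
      model$damping[d] * qdot[d]
  }
  tau
}

# strip feature-matrix attributes for identical() comparisons with oracles
plain_counts <- function(d) {
  m <- unclass(d)
  attr(m, "grid") <- NULL
  attr(m, "unit_ids") <- NULL
  m
}

MUSCLES6 <- function() c("FCR", "FCU", "ECRL", "ECU", "PT", "SUP")

# a fallback bundle predicting 0 everywhere, plus a matching TD matrix,
# for tests that need the prediction path but no trained ANNs
zero_fallback <- function() {
  ann0 <- structure(list(theta = rep(0, 10), n_hidden = 3, n_inputs = 1,
                         x_center = 0, x_scale = 1, y_lo = 0, y_hi = 0,
                         selected = 1, val_mse = 0, record = data.frame()),
                    class = "ann_model")
  list(pca = structure(list(rotation = matrix(c(1, 0, 0, 0), 4, 1),
                            center = rep(0, 4), n_components = 1,
                            explained = 1, target = 0.98),
                       class = "pca_model"),
       anns = setNames(rep(list(ann0), 6), MUSCLES6()))
}

zero_td <- function(grid) {
  structure(matrix(0, grid$n, 4), grid = grid, class = "td_matrix")
}
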