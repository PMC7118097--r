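#' @name synthetic-data
#' @title Synthetic neuromuscular subjects
#'
#' @description
#' Generates complete synthetic "subjects" mirroring a triangular
#' single-DoF wrist protocol: for each direction of each DoF the wrist angle
#' ramps linearly from rest to the maximum range of motion in 1 s, holds for
#' a 500-ms pause, and returns in 1 s; three repetitions of each of the six
#' direction tasks are produced in randomized order (18 trials). Ground-truth
#' muscle excitations come from the tracking calibration on the noiseless
#' model (so they are dynamically consistent by construction), motoneuron
#' pools convert them to spike trains by recruitment-threshold rate coding
#' with Gaussian-renewal inter-spike intervals, decomposition-like corruption
#' deletes spikes, and a surrogate amplitude-modulated interference EMG is
#' synthesized so the time-domain baseline is runnable.
NULL

#' Task profile of a triangular single-DoF trial
#'
#' @param dof `"FE"`, `"RU"` or `"PS"`.
#' @param direction `"positive"` or `"negative"`.
#' @param range_of_motion peak angle magnitude (rad).
#' @param ramp_duration up/down ramp duration (s), default 1.
#' @param pause_duration hold at the peak (s), default 0.5.
#' @param sample_rate kinematics sampling rate (Hz), default 100.
#' @return an object of class `task_profile`.
#' @export
task_profile <- function(dof, direction = c("positive", "negative"),
                         range_of_motion, ramp_duration = 1,
                         pause_duration = 0.5, sample_rate = 100) {
  dof <- match.arg(dof, DOFS)
  direction <- match.arg(direction)
  if (ramp_duration <= 0 || range_of_motion <= 0 || sample_rate <= 0 ||
      pause_duration < 0)
    stop("invalid argument: durations, range and rate must be positive")
  structure(list(dof = dof, direction = direction,
                 range_of_motion = range_of_motion,
                 ramp_duration = ramp_duration,
                 pause_duration = pause_duration,
                 sample_rate = sample_rate),
            class = "task_profile")
}

#' Generate the 3-DoF angle time series of a task
#'
#' The actuated DoF follows 0 -> (+/-)range (over the ramp) -> hold (pause)
#' -> 0 (ramp); the other two DoFs are identically zero. Total duration is
#' `2 * ramp + pause`.
#'
#' @param task a [task_profile()].
#' @return a `kin_series`.
#' @export
generate_task_profile <- function(task) {
  stopifnot(inherits(task, "task_profile"))
  rd <- task$ramp_duration; pd <- task$pause_duration
  dur <- 2 * rd + pd
  t <- seq(0, dur, by = 1 / task$sample_rate)
  peak <- task$range_of_motion * if (task$direction == "positive") 1 else -1
  x <- ifelse(t < rd, t / rd,
              ifelse(t <= rd + pd, 1, pmax(0, (dur - t) / rd)))
  q <- matrix(0, length(t), 3)
  q[, match(task$dof, DOFS)] <- peak * x
  kin_series(t, q)
}

#' Motoneuron pool of one muscle
#'
#' Units are recruited when the excitation exceeds their threshold and then
#' fire at `min(r_max, r_min + gain * (e - threshold))` pulses per second.
#'
#' @param muscle muscle name.
#' @param thresholds recruitment thresholds in `[0, 1)`, sorted ascending.
#' @param gains rate gains (pps per unit excitation).
#' @param r_min,r_max minimal/maximal discharge rates (pps).
#' @param isi_cov coefficient of variation of the inter-spike intervals.
#' @return an object of class `motoneuron_pool`.
#' @export
motoneuron_pool <- function(muscle, thresholds, gains, r_min = 8, r_max = 35,
                            isi_cov = 0.2) {
  stopifnot(all(thresholds >= 0 & thresholds < 1), r_min > 0,
            r_max >= r_min, length(gains) == length(thresholds),
            !is.unsorted(thresholds))
  structure(list(muscle = muscle, thresholds = thresholds, gains = gains,
                 r_min = r_min, r_max = r_max, isi_cov = isi_cov),
            class = "motoneuron_pool")
}

#' Default motoneuron pools for the six muscles
#'
#' @param n_units units per muscle, default 20.
#' @param theta_max largest recruitment threshold, default 0.6.
#' @param seed RNG seed for thresholds and gains.
#' @return named list of [motoneuron_pool()]s.
#' @export
default_pools <- function(n_units = 20, theta_max = 0.6, seed = 42) {
  seeds <- child_seeds(seed, 6)
  pools <- lapply(seq_along(MUSCLES), function(j) with_seed(seeds[j], {
    motoneuron_pool(MUSCLES[j],
                    thresholds = sort(runif(n_units, 0, theta_max)),
                    gains = runif(n_units, 40, 60))
  }))
  names(pools) <- MUSCLES
  pools
}

#' Sample spike trains from a motoneuron pool
#'
#' A unit fires only while the excitation exceeds its threshold; its
#' instantaneous rate is `min(r_max, r_min + gain * (e - theta))` and
#' inter-spike intervals are drawn from a Gaussian renewal process with the
#' pool's coefficient of variation (truncated at 20% of the mean interval).
#'
#' @param pool a [motoneuron_pool()].
#' @param excitation an [excitation_set()] column or a function `e(t)`;
#'   alternatively pass the [excitation_set()] with `muscle`.
#' @param duration trial duration (s).
#' @param seed RNG seed; identical seeds give identical spike times.
#' @param muscle muscle column used when `excitation` is an excitation set.
#' @return a [spike_train_set()] with unit ids `<muscle>_<k>`.
#' @export
sample_spikes <- function(pool, excitation, duration, seed,
                          muscle = pool$muscle) {
  stopifnot(inherits(pool, "motoneuron_pool"))
  ef <- if (is.function(excitation)) {
    excitation
  } else if (inherits(excitation, "excitation_set")) {
    grid <- attr(excitation, "grid")
    vals <- unclass(excitation)[, muscle]
    function(t) vals[window_index_at(grid, t)]
  } else stop("excitation must be a function or an excitation_set")
  n <- length(pool$thresholds)
  seeds <- child_seeds(seed, n)
  scan_dt <- 0.001
  trains <- lapply(seq_len(n), function(j) with_seed(seeds[j], {
    th <- pool$thresholds[j]; g <- pool$gains[j]
    tt <- numeric(0)
    t <- 0
    while (t < duration) {
      e <- ef(t)
      if (e <= th) { t <- t + scan_dt; next }
      lam <- min(pool$r_max, pool$r_min + g * (e - th))
      mu <- 1 / lam
      isi <- max(rnorm(1, mu, pool$isi_cov * mu), 0.2 * mu)
      t <- t + isi
      if (t < duration && ef(t) > th) tt <- c(tt, t)
    }
    tt
  }))
  names(trains) <- sprintf("%s_%02d", muscle, seq_len(n))
  spike_train_set(trains, duration, dof_label = NULL)
}

#' Corruption of spike trains emulating decomposition failure modes
#'
#' @param miss_probability per-spike deletion probability.
#' @param dropout_probability per-unit, per-repetition complete deletion
#'   probability.
#' @param silence_angle_fraction all spikes are deleted while the actuated
#'   angle magnitude is below this fraction of the range of motion
#'   (decomposition finds few spikes below ~20% of the maximal angle).
#' @param seed RNG seed.
#' @return an object of class `corruption_spec`.
#' @export
corruption_spec <- function(miss_probability = 0.1,
                            dropout_probability = 0.15,
                            silence_angle_fraction = 0.2, seed = 1) {
  p <- c(miss_probability, dropout_probability, silence_angle_fraction)
  stopifnot(all(p >= 0 & p <= 1))
  structure(list(miss_probability = miss_probability,
                 dropout_probability = dropout_probability,
                 silence_angle_fraction = silence_angle_fraction,
                 seed = seed),
            class = "corruption_spec")
}

#' Apply decomposition-like corruption to spike trains
#'
#' A pure filter: spikes are deleted (independently, per unit-repetition,
#' or inside the low-angle silent band) but never created or moved.
#'
#' @param spikes a [spike_train_set()].
#' @param spec a [corruption_spec()].
#' @param kinematics the trial's `kin_series` (for the silent band).
#' @param range_of_motion the task's range of motion (rad).
#' @param dof actuated DoF name.
#' @param seed RNG seed (defaults to `spec$seed`).
#' @return corrupted [spike_train_set()].
#' @export
corrupt_spikes <- function(spikes, spec, kinematics, range_of_motion,
                           dof, seed = spec$seed) {
  stopifnot(inherits(spikes, "spike_train_set"),
            inherits(spec, "corruption_spec"))
  d <- match(dof, DOFS)
  angf <- approxfun(kinematics$time, abs(kinematics$q[, d]), rule = 2)
  lim <- spec$silence_angle_fraction * range_of_motion
  with_seed(seed, {
    trains <- lapply(spikes$trains, function(tt) {
      if (runif(1) < spec$dropout_probability) return(numeric(0))
      if (!length(tt)) return(tt)
      keep <- runif(length(tt)) >= spec$miss_probability
      tt <- tt[keep]
      if (lim > 0 && length(tt)) tt <- tt[angf(tt) >= lim]
      tt
    })
    spike_train_set(trains, spikes$trial_duration, spikes$dof_label)
  })
}

#' Surrogate multichannel interference EMG
#'
#' Channel `c` is `sum_m w_cm * e_m(t) * n_m(t)` plus per-channel baseline
#' noise, with `n_m` one band-limited interference source per muscle,
#' shared across channels as volume conduction shares real muscle activity
#' across a grid, and each channel's weights dominated by the muscle it
#' sits over. The source spectrum shifts from a low (20-150 Hz) towards a
#' high (150-500 Hz) band as the excitation grows, mimicking the spectral
#' compression/expansion of the interference EMG with recruitment, so both
#' amplitude (RMS, waveform length) and complexity (zero crossings,
#' slope-sign changes) features carry excitation information. No motor-unit
#' action-potential structure is modelled.
#'
#' @param excitations an [excitation_set()].
#' @param n_channels number of channels, default 64 (an 8 x 8 grid).
#' @param sample_rate output rate (Hz), default 2048.
#' @param seed RNG seed for the noise realization (and for the montage when
#'   `weights` is not supplied).
#' @param baseline_sd baseline noise standard deviation (signal units).
#' @param weights optional channels x 6 non-negative mixing matrix from
#'   [emg_montage()]. The montage is a property of the recording setup:
#'   when simulating several trials of one subject, draw it once and pass
#'   it to every call, varying only `seed`.
#' @return an [emg_recording()].
#' @export
synthesize_emg <- function(excitations, n_channels = 64, sample_rate = 2048,
                           seed = 1, baseline_sd = 0.02, weights = NULL) {
  stopifnot(inherits(excitations, "excitation_set"), n_channels >= 1)
  if (is.null(weights)) weights <- emg_montage(n_channels, seed = seed)
  stopifnot(nrow(weights) == n_channels, ncol(weights) == 6,
            all(weights >= 0))
  grid <- attr(excitations, "grid")
  nt <- floor(grid$duration * sample_rate)
  t <- (seq_len(nt) - 1) / sample_rate
  Ew <- excitation_at(excitations, t) # nt x 6
  bp_lo <- butter_design(4, c(20, 150) / (sample_rate / 2), "band")
  bp_hi <- butter_design(4, c(150, 500) / (sample_rate / 2), "band")
  with_seed(seed, {
    W <- weights
    src <- vapply(1:6, function(m) {
      lo <- filtfilt(bp_lo, rnorm(nt)); lo <- lo / sd(lo)
      hi <- filtfilt(bp_hi, rnorm(nt)); hi <- hi / sd(hi)
      e <- Ew[, m]
      e * ((1 - 0.7 * e) * lo + (0.3 + 0.7 * e) * hi)
    }, numeric(nt)) # nt x 6 amplitude- and spectrum-modulated sources
    X <- W %*% t(src) +
      matrix(rnorm(n_channels * nt, 0, baseline_sd), n_channels, nt)
    rc <- c(floor(sqrt(n_channels)), ceiling(n_channels /
                                             floor(sqrt(n_channels))))
    emg_recording(X, sample_rate, channel_layout = rc)
  })
}

#' Random electrode-montage mixing matrix
#'
#' Each channel sits "over" one muscle (dominant weight) with smaller
#' crosstalk weights from the remaining muscles, emulating grid electrodes
#' distributed around the forearm; rows are normalized to sum to one.
#'
#' @param n_channels number of channels.
#' @param seed RNG seed.
#' @return channels x 6 non-negative matrix.
#' @export
emg_montage <- function(n_channels, seed = 1) {
  with_seed(seed, {
    primary <- sample(rep_len(1:6, n_channels))
    W <- matrix(runif(n_channels * 6, 0, 0.10), n_channels, 6)
    W[cbind(seq_len(n_channels), primary)] <- runif(n_channels, 0.6, 0.9)
    W / rowSums(W)
  })
}

#' Default configuration of the synthetic subject generator
#'
#' Defaults encode the stated experimental world: 1-s ramps with a 0.5-s
#' pause; ranges of motion FE +/-1.2, RU +/-0.4, PS +/-1.4 rad; 20
#' units/muscle with thresholds below 0.6; corruption with 10% missed
#' spikes, 15% per-repetition dropout and a 20% low-angle silent band;
#' 100-ms windows.
#'
#' @param n_units units per muscle.
#' @param n_channels surrogate EMG channels.
#' @param window_step window-grid step (s).
#' @param corruption a [corruption_spec()] or `NULL` for pristine spikes.
#' @return configuration list.
#' @export
default_config <- function(n_units = 20, n_channels = 64,
                           window_step = 0.01,
                           corruption = corruption_spec()) {
  list(rom = c(FE = 1.2, RU = 0.4, PS = 1.4),
       ramp_duration = 1, pause_duration = 0.5, kin_rate = 100,
       window_length = 0.1, window_step = window_step,
       n_units = n_units, theta_max = 0.6,
       n_channels = n_channels, emg_rate = 2048, emg_baseline_sd = 0.02,
       corruption = corruption)
}

#' Ground-truth excitations for a reference trial
#'
#' Delegates to [tracking_excitations()] on the noiseless model so that the
#' synthetic truth is dynamically consistent by construction.
#'
#' @param model a [wrist_model()].
#' @param kinematics reference `kin_series` (already in model units).
#' @param grid window grid.
#' @param ... passed to [tracking_excitations()].
#' @return an [excitation_set()].
#' @export
ground_truth_excitations <- function(model, kinematics, grid, ...) {
  tracking_excitations(model, kinematics, grid, ...)
}

#' Generate a complete synthetic subject dataset
#'
#' 18 trials (3 repetitions x 2 directions x 3 DoFs) in seed-randomized
#' order, each carrying task, kinematics, ground-truth excitations,
#' (optionally corrupted) spike trains and surrogate EMG on a common window
#' grid.
#'
#' @param config a [default_config()] list.
#' @param seed master seed; the full dataset is reproducible from it.
#' @param model a [wrist_model()]; the default model is used when `NULL`.
#' @return an object of class `nms_dataset` with `trials`, `model`,
#'   `pools`, `config`.
#' @export
generate_dataset <- function(config = default_config(), seed = 1,
                             model = NULL) {
  if (is.null(model)) model <- wrist_model()
  dur <- 2 * config$ramp_duration + config$pause_duration
  grid <- build_window_grid(dur, config$window_length, config$window_step)
  pools <- default_pools(config$n_units, config$theta_max, seed = seed)
  montage <- emg_montage(config$n_channels, seed = seed + 1L)

  combos <- expand.grid(direction = c("positive", "negative"),
                        dof = DOFS, stringsAsFactors = FALSE)
  # one reference kinematics + truth per direction task (shared by reps)
  refs <- lapply(seq_len(nrow(combos)), function(i) {
    task <- task_profile(combos$dof[i], combos$direction[i],
                         range_of_motion = config$rom[[combos$dof[i]]],
                         ramp_duration = config$ramp_duration,
                         pause_duration = config$pause_duration,
                         sample_rate = config$kin_rate)
    kin <- generate_task_profile(task)
    truth <- ground_truth_excitations(model, kin, grid, dof = task$dof)
    list(task = task, kin = kin, truth = truth)
  })

  seeds <- child_seeds(seed, nrow(combos) * 3 * 8 + 1)
  si <- 0
  trials <- list()
  for (i in seq_len(nrow(combos))) {
    for (rep_idx in 1:3) {
      ref <- refs[[i]]
      sp <- list()
      for (m in MUSCLES) {
        si <- si + 1
        sp[[m]] <- sample_spikes(pools[[m]], ref$truth, dur,
                                 seed = seeds[si], muscle = m)
      }
      spikes <- spike_train_set(do.call(c, unname(lapply(sp, `[[`,
                                                         "trains"))),
                                dur, dof_label = ref$task$dof)
      si <- si + 1
      if (!is.null(config$corruption)) {
        spikes <- corrupt_spikes(spikes, config$corruption, ref$kin,
                                 ref$task$range_of_motion, ref$task$dof,
                                 seed = seeds[si])
      }
      si <- si + 1
      emg <- synthesize_emg(ref$truth, config$n_channels, config$emg_rate,
                            seed = seeds[si], config$emg_baseline_sd,
                            weights = montage)
      trials[[length(trials) + 1]] <-
        list(task = ref$task, kinematics = ref$kin, true_excitations =
               ref$truth, spikes = spikes, emg = emg,
             repetition_index = rep_idx)
    }
  }
  order_seed <- seeds[length(seeds)]
  trials <- with_seed(order_seed, sample(trials))
  structure(list(trials = trials, model = model, pools = pools,
                 montage = montage, config = config, grid = grid,
                 seed = seed),
            class = "nms_dataset")
}

#' @export
print.nms_dataset <- function(x, ...) {
  cat("<nms_dataset>", length(x$trials), "trials,",
      x$config$n_units, "units/muscle,",
      x$config$n_channels, "EMG channels\n")
  invisible(x)
}
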