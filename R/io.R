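#' @name io
#' @title Plain-text readers and writers
#'
#' @description
#' Spike trains round-trip as JSON (unit id -> sorted discharge times in
#' seconds) or long-format CSV; kinematics and excitations as CSV with a
#' time/window column; model parameters and dataset manifests as YAML. EMG
#' is written as plain CSV (channels in columns).
NULL

#' @rdname io
#' @param spikes a [spike_train_set()].
#' @param path output file.
#' @export
write_spikes_json <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  obj <- list(trial_duration = spikes$trial_duration,
              dof_label = spikes$dof_label, trains = spikes$trains)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname io
#' @export
read_spikes_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trains <- lapply(obj$trains, as.numeric)
  spike_train_set(trains, obj$trial_duration,
                  if (is.null(obj$dof_label)) NULL else obj$dof_label)
}

#' @rdname io
#' @export
write_spikes_csv <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train_set"))
  df <- do.call(rbind, lapply(names(spikes$trains), function(id) {
    tt <- spikes$trains[[id]]
    if (!length(tt)) return(NULL)
    data.frame(unit = id, time = tt)
  }))
  if (is.null(df)) df <- data.frame(unit = character(0), time = numeric(0))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param kin a `kin_series`.
#' @export
write_kinematics_csv <- function(kin, path) {
  stopifnot(inherits(kin, "kin_series"))
  df <- data.frame(time = kin$time, kin$q)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_kinematics_csv <- function(path) {
  df <- read.csv(path)
  kin_series(df$time, as.matrix(df[, DOFS]))
}

#' @rdname io
#' @param exc an [excitation_set()].
#' @export
write_excitations_csv <- function(exc, path) {
  stopifnot(inherits(exc, "excitation_set"))
  grid <- attr(exc, "grid")
  df <- data.frame(window_start = grid$starts, unclass(exc))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param window_length,window_step grid parameters used when reading back.
#' @export
read_excitations_csv <- function(path, window_length = 0.1,
                                 window_step = 0.01) {
  df <- read.csv(path)
  n <- nrow(df)
  dur <- df$window_start[n] + window_length
  grid <- build_window_grid(dur, window_length, window_step)
  excitation_set(as.matrix(df[, MUSCLES]), grid)
}

#' @rdname io
#' @param dsc a [extract_dsc()] matrix.
#' @export
write_dsc_csv <- function(dsc, path) {
  stopifnot(inherits(dsc, "dsc_matrix"))
  grid <- attr(dsc, "grid")
  df <- data.frame(window_start = grid$starts, unclass(dsc))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param emg an [emg_recording()].
#' @export
write_emg_csv <- function(emg, path) {
  stopifnot(inherits(emg, "emg_recording"))
  df <- as.data.frame(t(emg$samples))
  names(df) <- sprintf("ch%03d", seq_len(nrow(emg$samples)))
  write.csv(cbind(time = (seq_len(ncol(emg$samples)) - 1) /
                    emg$sample_rate, df), path, row.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @param model a [wrist_model()].
#' @export
write_model_yaml <- function(model, path) {
  stopifnot(inherits(model, "wrist_model"))
  obj <- unclass(model)
  obj$moment_arms <- lapply(seq_len(6), function(j)
    as.list(setNames(model$moment_arms[j, ], DOFS)))
  names(obj$moment_arms) <- model$muscles
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname io
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  ma <- t(vapply(MUSCLES, function(m) unlist(obj$moment_arms[[m]])[DOFS],
                 numeric(3)))
  wrist_model(f_max = obj$f_max, l_opt = obj$l_opt, v_max = obj$v_max,
              tau_act = obj$tau_act, tau_deact = obj$tau_deact,
              moment_arms = ma, inertia = obj$inertia,
              stiffness = obj$stiffness, damping = obj$damping,
              q_min = obj$q_min, q_max = obj$q_max)
}

#' Write a synthetic dataset to a directory
#'
#' One subdirectory per trial (spikes JSON, kinematics/excitations/EMG CSV)
#' plus a YAML manifest and the model parameters.
#'
#' @param dataset an [generate_dataset()] dataset.
#' @param dir output directory (created if missing).
#' @param write_emg include the (large) EMG CSV files.
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, write_emg = FALSE) {
  stopifnot(inherits(dataset, "nms_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(n_trials = length(dataset$trials),
                   seed = dataset$seed,
                   window_length = dataset$grid$length,
                   window_step = dataset$grid$step,
                   trials = list())
  write_model_yaml(dataset$model, file.path(dir, "model.yaml"))
  for (i in seq_along(dataset$trials)) {
    tr <- dataset$trials[[i]]
    td <- file.path(dir, sprintf("trial%02d", i))
    dir.create(td, showWarnings = FALSE)
    write_spikes_json(tr$spikes, file.path(td, "spikes.json"))
    write_kinematics_csv(tr$kinematics, file.path(td, "kinematics.csv"))
    write_excitations_csv(tr$true_excitations,
                          file.path(td, "true_excitations.csv"))
    if (write_emg) write_emg_csv(tr$emg, file.path(td, "emg.csv"))
    manifest$trials[[i]] <- list(
      dir = basename(td), dof = tr$task$dof,
      direction = tr$task$direction, repetition = tr$repetition_index,
      range_of_motion = tr$task$range_of_motion)
  }
  mp <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, mp)
  invisible(mp)
}
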