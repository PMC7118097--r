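#' @name spike-features
#' @title Discharge-count features on a sliding-window grid
#'
#' @description
#' All pipeline stages share one sliding-window grid. The neural feature is
#' the decomposed spike count (DSC): the number of discharges of each
#' motor-unit spike train inside each 100-ms observation window. Windows are
#' half-open `[start, start + length)` so boundary spikes are counted once.
NULL

#' Spike train set
#'
#' @param trains named list, one sorted numeric vector of discharge times
#'   (seconds) per motor unit.
#' @param trial_duration trial length (s).
#' @param dof_label optional label of the DoF(s) the units were detected in.
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(trains, trial_duration, dof_label = NULL) {
  stopifnot(is.list(trains), trial_duration > 0)
  if (is.null(names(trains)) && length(trains) > 0)
    names(trains) <- sprintf("u%02d", seq_along(trains))
  for (id in names(trains)) {
    tt <- trains[[id]]
    if (length(tt)) {
      if (is.unsorted(tt, strictly = TRUE))
        stop("spike times must be strictly increasing (unit ", id, ")")
      if (min(tt) < 0 || max(tt) > trial_duration)
        stop("spike times outside [0, trial_duration] (unit ", id, ")")
    }
  }
  structure(list(trains = trains, trial_duration = trial_duration,
                 dof_label = dof_label),
            class = "spike_train_set")
}

#' Build the sliding-window grid
#'
#' Windows of `window_length` seconds advance by `window_step` from time 0
#' while they fit inside the trial: `n = floor((duration - length)/step) + 1`.
#'
#' The default step of 0.01 s is the 10-ms window increment standard in
#' myoelectric regression; the alternative reading of a 10-ms *overlap*
#' (`window_step = 0.09`) is equally supported everywhere downstream.
#'
#' @param trial_duration trial length (s), at least one window long.
#' @param window_length window length (s), default 0.1.
#' @param window_step advance between window starts (s); must satisfy
#'   `0 < step <= length`.
#' @return an object of class `window_grid` with `starts`, `length`, `step`,
#'   `n`, `duration`.
#' @export
build_window_grid <- function(trial_duration, window_length = 0.1,
                              window_step = 0.01) {
  if (!(window_step > 0 && window_step <= window_length))
    stop("invalid argument: need 0 < window_step <= window_length")
  if (trial_duration < window_length)
    stop("invalid argument: trial_duration shorter than one window")
  n <- floor((trial_duration - window_length) / window_step + 1e-9) + 1
  structure(list(starts = (seq_len(n) - 1) * window_step,
                 length = window_length, step = window_step, n = n,
                 duration = trial_duration),
            class = "window_grid")
}

grids_equal <- function(g1, g2, tol = 1e-9) {
  g1$n == g2$n && abs(g1$length - g2$length) < tol &&
    abs(g1$step - g2$step) < tol && abs(g1$duration - g2$duration) < tol
}

# window index holding time t for per-window series (ZOH on control
# intervals [start_k, start_k + step), last window extends to duration)
window_index_at <- function(grid, t) {
  k <- floor(t / grid$step + 1e-9) + 1
  pmin(pmax(k, 1), grid$n)
}

#' Extract the decomposed spike count matrix
#'
#' `counts[w, j]` is the number of discharges of unit `j` inside the
#' half-open window `[start_w, start_w + length)`. With overlapping windows
#' one spike contributes to several windows.
#'
#' @param spikes a [spike_train_set()].
#' @param grid a [build_window_grid()] grid fitting the trial.
#' @return a `dsc_matrix`: integer matrix windows x units with the grid and
#'   unit ids attached as attributes.
#' @export
extract_dsc <- function(spikes, grid) {
  stopifnot(inherits(spikes, "spike_train_set"), inherits(grid, "window_grid"))
  if (grid$duration > spikes$trial_duration + 1e-9)
    stop("invalid argument: grid longer than trial")
  ids <- names(spikes$trains)
  counts <- matrix(0L, nrow = grid$n, ncol = length(ids),
                   dimnames = list(NULL, ids))
  ends <- grid$starts + grid$length
  for (j in seq_along(ids)) {
    tt <- spikes$trains[[j]]
    if (!length(tt)) next
    if (is.unsorted(tt, strictly = TRUE))
      stop("invalid argument: unsorted spike train")
    # windows containing each spike: start <= t < start + length
    lo <- findInterval(grid$starts, tt, left.open = TRUE)   # spikes < start
    hi <- findInterval(ends, tt, left.open = TRUE)          # spikes < end
    counts[, j] <- as.integer(hi - lo)
  }
  structure(counts, grid = grid, unit_ids = ids, class = "dsc_matrix")
}

#' Per-window activity mask
#'
#' A unit is active in a window iff its count is positive; a window is
#' active iff any unit is.
#'
#' @param dsc a [extract_dsc()] matrix.
#' @return list with `unit_active` (windows x units logical) and
#'   `window_active` (logical vector).
#' @export
activity_mask <- function(dsc) {
  stopifnot(inherits(dsc, "dsc_matrix"))
  m <- unclass(dsc) > 0
  list(unit_active = m, window_active = rowSums(m) > 0)
}

#' Per-muscle excitation trajectory on a window grid
#'
#' @param values windows x 6 matrix of excitations in `[0, 1]`, columns in
#'   muscle order FCR, FCU, ECRL, ECU, PT, SUP.
#' @param grid the shared [build_window_grid()].
#' @return an object of class `excitation_set`.
#' @export
excitation_set <- function(values, grid) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == 6, nrow(values) == grid$n,
            all(is.finite(values)), min(values) > -1e-9, max(values) < 1 + 1e-9)
  values <- pmin(pmax(values, 0), 1)
  colnames(values) <- MUSCLES
  structure(values, grid = grid, class = "excitation_set")
}

# sample a per-window excitation series at arbitrary times (ZOH)
excitation_at <- function(exc, times) {
  grid <- attr(exc, "grid")
  unclass(exc)[window_index_at(grid, times), , drop = FALSE]
}

#' Kinematics time series
#'
#' @param time sample times (s), uniform and increasing.
#' @param q n x 3 matrix of joint angles (rad), columns FE, RU, PS.
#' @return an object of class `kin_series`.
#' @export
kin_series <- function(time, q) {
  q <- as.matrix(q)
  stopifnot(length(time) == nrow(q), ncol(q) == 3, all(is.finite(q)))
  colnames(q) <- DOFS
  structure(list(time = as.numeric(time), q = q), class = "kin_series")
}

# linear interpolation of a kin_series at new times
kin_at <- function(kin, times) {
  q <- vapply(1:3, function(d)
    approx(kin$time, kin$q[, d], xout = times, rule = 2)$y,
    numeric(length(times)))
  kin_series(times, q)
}
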