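#' @name pipeline-eval
#' @title End-to-end prediction, gating and cross-validated evaluation
#'
#' @description
#' Ties the stages together: spike counts are mapped to muscle excitations,
#' single-DoF gating suppresses DoFs not actuated by a complete agonist
#' set, the wrist model integrates the gated excitations open loop, and the
#' result is rescaled to recorded units. Evaluation uses three-fold
#' cross-validation over the three repetitions (two train / one test per
#' direction per DoF), repeated with independent fold assignments, scoring
#' R-squared and RMSE (degrees) per DoF.
NULL

GATING_SETS <- list(
  flexion = c("FCR", "FCU"), extension = c("ECRL", "ECU"),
  radial = c("FCR", "ECRL"), ulnar = c("FCU", "ECU"),
  pronation = "PT", supination = "SUP")

#' Single-DoF gating of muscle excitations
#'
#' A DoF-direction counts as actuated only when every muscle of its agonist
#' set exceeds the activity threshold, with the set's strength defined as
#' the smallest agonist excitation. Gating is decided per movement segment
#' (a maximal run of windows with any muscle active): if any complete
#' agonist set occurs in the segment, the set with the largest
#' time-integrated strength claims its DoF for the whole segment and the
#' other DoFs are set to zero (a flexion claim, for example, suppresses
#' deviation and pronation/supination); if only
#' lone flexors/extensors/deviators are ever active, both wrist DoFs are
#' estimated, with pronation/supination added when its agonist is active.
#' When `spike_backed` is supplied, detection rests on neural evidence:
#' fallback-extrapolated excitations cannot raise or decide a claim, and
#' segments without any backed activity are treated as rest. Gating only
#' ever zeroes.
#'
#' @param excitations an [excitation_set()].
#' @param eps activity threshold (excitation units), default 0.01.
#' @param spike_backed optional windows x muscles logical: whether each
#'   excitation value is backed by at least one discharging assigned unit
#'   (i.e. not a fallback extrapolation). Detection decisions — claims and
#'   the lone-muscle rule — then count backed values only, while the
#'   excitations that drive the model keep their fallback estimates.
#' @return list with `excitations` (gated set), `dof_mask` (windows x 3
#'   0/1) and `actuated` (windows x 6 logical per DoF-direction).
#' @export
gate_excitations <- function(excitations, eps = 0.01, spike_backed = NULL) {
  stopifnot(inherits(excitations, "excitation_set"), eps > 0)
  E <- unclass(excitations)
  grid <- attr(excitations, "grid")
  n <- nrow(E)
  if (is.null(spike_backed)) spike_backed <- matrix(TRUE, n, 6)
  Eb <- E * spike_backed # detection evidence
  act <- Eb > eps
  # set strength: smallest (backed) agonist excitation per direction set
  strength <- vapply(GATING_SETS, function(set)
    apply(Eb[, set, drop = FALSE], 1, min), numeric(n))
  on <- strength > eps
  mask <- matrix(0L, n, 3, dimnames = list(NULL, DOFS))

  active_any <- rowSums(E > eps) > 0 # segmentation uses the full estimates
  runs <- rle(active_any)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (s in which(runs$values)) {
    idx <- starts[s]:ends[s]
    if (!any(act[idx, ])) next # no spike-backed evidence: rest
    peak <- apply(strength[idx, , drop = FALSE], 2, max)
    mass <- colSums(strength[idx, , drop = FALSE]) * (peak > eps)
    fe_best <- max(mass[c("flexion", "extension")])
    ru_best <- max(mass[c("radial", "ulnar")])
    ps_best <- max(mass[c("pronation", "supination")])
    if (max(peak[c("flexion", "extension", "radial", "ulnar")]) > eps) {
      # a complete wrist agonist set occurred: the strongest claim (which
      # may be pronation/supination) takes the segment exclusively
      winner <- which.max(c(fe_best, ru_best, ps_best))
      mask[idx, winner] <- 1L
    } else {
      # only lone wrist muscles (if any): both wrist DoFs are estimated;
      # pronation/supination is gated by its own agonist
      if (any(act[idx, c("FCR", "FCU", "ECRL", "ECU")]))
        mask[idx, c("FE", "RU")] <- 1L
      if (ps_best > 0) mask[idx, "PS"] <- 1L
    }
  }

  gated <- E
  gated[mask[, "PS"] == 0L, c("PT", "SUP")] <- 0
  both_off <- mask[, "FE"] == 0L & mask[, "RU"] == 0L
  gated[both_off, c("FCR", "FCU", "ECRL", "ECU")] <- 0
  list(excitations = excitation_set(gated, grid), dof_mask = mask,
       actuated = on)
}

#' Run the model-based prediction chain on one trial
#'
#' Extracts discharge counts, predicts muscle excitations (median ensemble
#' with ANN fallback), applies single-DoF gating, integrates the wrist
#' model open loop from rest, and maps the simulated angles back to
#' recorded units.
#'
#' @param trial a dataset trial (needs `spikes`, `emg`, `kinematics`).
#' @param neural_model a [train_neural_model()] model.
#' @param model a [wrist_model()].
#' @param scaler the calibration [fit_scaler()] object.
#' @param grid the shared window grid.
#' @param gate_eps gating activity threshold.
#' @param dt integration step (s).
#' @return list with `kin` (predicted `kin_series` at window times, recorded
#'   units), `excitations`, `gated`, `dof_mask`.
#' @export
run_dsc_nms <- function(trial, neural_model, model, scaler, grid,
                        gate_eps = 0.01, dt = 1e-3) {
  dsc <- extract_dsc(trial$spikes, grid)
  td <- if (!is.null(neural_model$fallback) && !is.null(trial$emg))
    extract_td(preprocess_emg(trial$emg), grid) else NULL
  exc <- predict_excitations(neural_model, dsc, td)
  # detection evidence: a muscle counts as neurally active in a window
  # when a meaningful share of its assigned units is discharging (a truly
  # recruited muscle fires many low-threshold units, not an isolated
  # cross-assigned one)
  nu <- attr(exc, "active_units")
  need <- pmax(1, ceiling(0.25 * attr(exc, "n_models")))
  backed <- nu >= rep(need, each = nrow(nu))
  g <- gate_excitations(exc, eps = gate_eps, spike_backed = backed)
  sim <- forward_simulate(model, g$excitations, dt = dt,
                          dof_mask = g$dof_mask)
  qw <- vapply(1:3, function(d)
    approx(sim$time, sim$q[, d], xout = grid$starts, rule = 2)$y,
    numeric(grid$n))
  qw <- qw * g$dof_mask # non-estimated DoFs are reported as zero
  pred_model <- kin_series(grid$starts, qw)
  pred <- scale_kinematics(scaler, pred_model, inverse = TRUE)
  list(kin = pred, excitations = exc, gated = g$excitations,
       dof_mask = g$dof_mask)
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SSE/SST` about the mean of `y`.
#'
#' @param y observed values (must have nonzero variance).
#' @param yhat predictions.
#' @return scalar R-squared (at most 1, unbounded below).
#' @export
r2 <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) >= 2)
  sst <- sum((y - mean(y))^2)
  if (sst < 1e-300) stop("undefined R2: zero-variance reference")
  1 - sum((y - yhat)^2) / sst
}

#' Root mean squared error
#'
#' @param y,yhat observed and predicted values (same units).
#' @return scalar RMSE.
#' @export
rmse <- function(y, yhat) {
  stopifnot(length(y) == length(yhat))
  sqrt(mean((y - yhat)^2))
}

# recorded kinematics at window times for each trial
trial_targets <- function(trials, grid) {
  lapply(trials, function(tr) kin_at(tr$kinematics, grid$starts)$q)
}

fit_baseline <- function(feat_list, kin_list, train_idx, ann_restarts,
                         ann_hidden, pca_variance, seed) {
  X <- do.call(rbind, lapply(feat_list[train_idx], unclass))
  pca <- fit_pca(X, pca_variance)
  S <- apply_pca(pca, X)
  seeds <- child_seeds(seed, 3)
  anns <- lapply(1:3, function(d) {
    y <- unlist(lapply(kin_list[train_idx], function(q) q[, d]))
    train_ann(S, y, n_hidden = ann_hidden, restarts = ann_restarts,
              seed = seeds[d])
  })
  list(pca = pca, anns = anns)
}

#' Per-DoF ANN kinematics estimates
#'
#' Applies one trained network per DoF to PCA scores and low-pass filters
#' the resulting estimate streams (zero phase).
#'
#' @param models list of 3 [train_ann()] models (FE, RU, PS).
#' @param scores PCA score matrix for one trial.
#' @param grid the window grid (sets the estimate stream rate).
#' @param lowpass_cutoff post-hoc low-pass cutoff (Hz); `NULL` disables.
#' @return `kin_series` of the estimates at window times.
#' @export
predict_ann_dof <- function(models, scores, grid, lowpass_cutoff = 1.5) {
  stopifnot(length(models) == 3)
  q <- vapply(1:3, function(d) ann_predict(models[[d]], scores),
              numeric(nrow(scores)))
  if (!is.null(lowpass_cutoff))
    q <- lowpass_estimates(q, lowpass_cutoff, rate = 1 / grid$step)
  kin_series(grid$starts, q)
}

calibrate_fold <- function(dataset, train_idx, dsc_list, td_list,
                           ann_restarts, seed, kp = 400, kv = 40) {
  model <- dataset$model
  grid <- dataset$grid
  kins <- lapply(dataset$trials[train_idx], `[[`, "kinematics")
  scaler <- fit_scaler(kins, model)
  exc_list <- lapply(train_idx, function(i) {
    tr <- dataset$trials[[i]]
    ref <- scale_kinematics(scaler, tr$kinematics)
    tracking_excitations(model, ref, grid, kp = kp, kv = kv,
                         dof = tr$task$dof)
  })
  spikes_list <- lapply(dataset$trials[train_idx], `[[`, "spikes")
  assignment <- assign_units(spikes_list, exc_list)
  nm <- train_neural_model(dsc_list[train_idx], exc_list,
                           td_list[train_idx], assignment,
                           ann_restarts = ann_restarts, seed = seed)
  list(scaler = scaler, assignment = assignment, neural_model = nm,
       excitations = exc_list)
}

#' Cross-validated evaluation of the mapping methods
#'
#' Three-fold cross-validation over the three repetitions: per repeat, each
#' direction-of-DoF task gets an independent random permutation of its
#' repetitions; fold `f` tests the `f`-th entry and trains on the other
#' two. All fitting (calibration, assignment, robust regression, PCA
#' loadings, ANN training) sees training folds only. Metrics are computed
#' per DoF on the test trajectories concatenated across test trials (or per
#' trial and averaged).
#'
#' @param dataset an [generate_dataset()] dataset.
#' @param methods subset of `"td"`, `"td_dsc"`, `"dsc_nms"`.
#' @param folds number of folds; must be 3 (one per repetition).
#' @param repeats independent fold-assignment repeats, default 10.
#' @param seed master seed.
#' @param ann_restarts ANN restarts (both baselines and fallback).
#' @param gate_eps gating threshold for the model-based method.
#' @param lowpass_cutoff post-hoc low-pass (Hz) for the ANN baselines.
#' @param per_trial if `TRUE`, metrics are averaged over test trials
#'   instead of concatenated.
#' @param subject subject label for the result table.
#' @return `data.frame` with columns method, subject, repeat, fold, dof,
#'   r2, rmse_deg, seed.
#' @export
crossvalidate <- function(dataset, methods = c("td", "td_dsc", "dsc_nms"),
                          folds = 3, repeats = 10, seed = 1,
                          ann_restarts = 50, gate_eps = 0.01,
                          lowpass_cutoff = 1.5, per_trial = FALSE,
                          subject = "S1") {
  stopifnot(inherits(dataset, "nms_dataset"), folds == 3)
  methods <- match.arg(methods, several.ok = TRUE)
  trials <- dataset$trials
  grid <- dataset$grid
  combo_of <- vapply(trials, function(tr)
    paste(tr$task$dof, tr$task$direction), "")
  rep_of <- vapply(trials, `[[`, 0, "repetition_index")
  combos <- unique(combo_of)
  for (cb in combos)
    if (!setequal(rep_of[combo_of == cb], 1:3))
      stop("invalid dataset: need repetitions 1..3 for every task")

  dsc_list <- lapply(trials, function(tr) extract_dsc(tr$spikes, grid))
  td_list <- lapply(trials, function(tr)
    extract_td(preprocess_emg(tr$emg), grid))
  tddsc_list <- if ("td_dsc" %in% methods)
    lapply(seq_along(trials), function(i)
      concat_td_dsc(td_list[[i]], dsc_list[[i]])) else NULL
  targets <- trial_targets(trials, grid)

  score <- function(pred_list, test_idx) {
    out <- data.frame()
    for (d in 1:3) {
      if (per_trial) {
        r2s <- mapply(function(p, i) r2(targets[[i]][, d], p$q[, d]),
                      pred_list, test_idx)
        rms <- mapply(function(p, i) rmse(targets[[i]][, d], p$q[, d]),
                      pred_list, test_idx)
        out <- rbind(out, data.frame(dof = DOFS[d], r2 = mean(r2s),
                                     rmse_deg = mean(rms) * 180 / pi))
      } else {
        y <- unlist(lapply(test_idx, function(i) targets[[i]][, d]))
        yh <- unlist(lapply(pred_list, function(p) p$q[, d]))
        out <- rbind(out, data.frame(dof = DOFS[d], r2 = r2(y, yh),
                                     rmse_deg = rmse(y, yh) * 180 / pi))
      }
    }
    out
  }

  rep_seeds <- child_seeds(seed, repeats)
  results <- data.frame()
  for (rp in seq_len(repeats)) {
    perms <- with_seed(rep_seeds[rp], {
      p <- lapply(combos, function(cb) sample(1:3))
      names(p) <- combos
      p
    })
    fold_seeds <- child_seeds(rep_seeds[rp] + 1L, folds * 4L)
    for (f in seq_len(folds)) {
      test_rep <- vapply(combos, function(cb) perms[[cb]][f], 0L)
      is_test <- vapply(seq_along(trials), function(i)
        rep_of[i] == test_rep[[combo_of[i]]], TRUE)
      test_idx <- which(is_test)
      train_idx <- which(!is_test)
      fs <- fold_seeds[(f - 1) * 4 + 1:4]
      for (mth in methods) {
        if (mth %in% c("td", "td_dsc")) {
          feats <- if (mth == "td") td_list else tddsc_list
          fit <- fit_baseline(feats, targets, train_idx, ann_restarts,
                              3, 0.98, fs[if (mth == "td") 1 else 2])
          preds <- lapply(test_idx, function(i)
            predict_ann_dof(fit$anns, apply_pca(fit$pca, feats[[i]]),
                            grid, lowpass_cutoff))
        } else {
          cal <- calibrate_fold(dataset, train_idx, dsc_list, td_list,
                                ann_restarts, fs[3])
          preds <- lapply(test_idx, function(i)
            run_dsc_nms(trials[[i]], cal$neural_model, dataset$model,
                        cal$scaler, grid, gate_eps = gate_eps)$kin)
        }
        sc <- score(preds, test_idx)
        results <- rbind(results,
                         data.frame(method = mth, subject = subject,
                                    rep = rp, fold = f, dof = sc$dof,
                                    r2 = sc$r2, rmse_deg = sc$rmse_deg,
                                    seed = seed))
      }
    }
  }
  rownames(results) <- NULL
  results
}

#' Summarize cross-validation results
#'
#' Grouped means and standard deviations per method and DoF (descriptive
#' aggregation only; inferential statistics are out of scope).
#'
#' @param results a [crossvalidate()] table.
#' @return `data.frame` with method, dof, mean/sd of R-squared and RMSE,
#'   and the number of aggregated rows.
#' @export
compare_methods <- function(results) {
  stopifnot(nrow(results) > 0)
  grp <- split(results, list(results$method, results$dof), drop = TRUE)
  out <- do.call(rbind, lapply(grp, function(g) data.frame(
    method = g$method[1], dof = g$dof[1],
    r2_mean = mean(g$r2), r2_sd = if (nrow(g) > 1) sd(g$r2) else 0,
    rmse_mean = mean(g$rmse_deg),
    rmse_sd = if (nrow(g) > 1) sd(g$rmse_deg) else 0,
    n = nrow(g))))
  rownames(out) <- NULL
  out[order(out$method, out$dof), ]
}
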