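#' @name neural-mapping
#' @title Robust neural regression from discharge counts to muscle excitations
#'
#' @description
#' The model-based mapping core: motor units are assigned to muscle-tendon
#' units by discharge/excitation coincidence (a unit belongs to every muscle
#' whose calibration excitation is positive at >= 80% of its discharges), a
#' robust linear model (IRLS with Tukey's bisquare) is fitted per
#' (muscle, unit) pair from the unit's spike-containing windows, and muscle
#' excitations are predicted as the median over the currently active units'
#' estimates, falling back to a per-muscle ANN on time-domain EMG features
#' when no assigned unit fires in a window.
NULL

#' Robust linear fit by IRLS with the bisquare weight
#'
#' Fits `y = b0 + b1 x` by iteratively reweighted least squares with
#' Tukey's biweight `w(r) = (1 - (r/(c s))^2)^2` for `|r| < c s` (else 0),
#' tuning constant `c = 4.685` (95% Gaussian efficiency) and MAD-based
#' scale, starting from ordinary least squares.
#'
#' @param x,y predictor (spike count) and response (excitation) restricted
#'   to the unit's spike-containing windows; needs >= 2 distinct `x`.
#' @param c_tune bisquare tuning constant.
#' @param tol coefficient-change convergence tolerance.
#' @param max_iter iteration cap.
#' @return list of class `linear_unit_model`: `intercept`, `slope`,
#'   `iterations`, `scale`.
#' @export
fit_unit_regressor <- function(x, y, c_tune = 4.685, tol = 1e-8,
                               max_iter = 50) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2)
    stop("rank deficiency: constant spike counts, no slope identifiable")
  X <- cbind(1, x)
  beta <- drop(solve(crossprod(X), crossprod(X, y)))
  s <- 0
  for (it in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    s <- mad(r, center = 0)
    if (s < 1e-12) break # (near-)perfect fit; weights undefined, keep OLS
    u <- r / (c_tune * s)
    w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
    if (sum(w > 0) < 2) break
    XtW <- t(X * w)
    beta_new <- tryCatch(drop(solve(XtW %*% X, XtW %*% y)),
                         error = function(e) beta)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) break
  }
  structure(list(intercept = unname(beta[1]), slope = unname(beta[2]),
                 iterations = it, scale = s),
            class = "linear_unit_model")
}

#' Assign motor units to muscle-tendon units
#'
#' A unit is assigned to every muscle whose calibration excitation exceeds
#' `tol` at the times of at least `threshold` of its discharges (pooled
#' across all calibration trials); excitations are looked up on the window
#' grid (zero-order hold). Units meeting no criterion (or with no spikes)
#' are left unassigned.
#'
#' @param spikes a [spike_train_set()] or list of them (one per trial).
#' @param excitations matching [excitation_set()] or list of them.
#' @param threshold coincidence fraction, default 0.8.
#' @param tol positivity tolerance absorbing optimizer noise. The default
#'   matches the calibration's torque-residual scale: tracking excitations
#'   carry numerical dust of order 1e-4 in windows where a muscle is
#'   mechanically idle, and a tolerance below that floor cross-assigns
#'   units to muscles that merely twitched numerically.
#' @return an `assignment_map`: list with `units` (unit id -> character
#'   vector of muscles), `unassigned`, `coincidence` (units x muscles
#'   fraction matrix), `threshold`.
#' @export
assign_units <- function(spikes, excitations, threshold = 0.8, tol = 1e-3) {
  if (inherits(spikes, "spike_train_set")) spikes <- list(spikes)
  if (inherits(excitations, "excitation_set")) excitations <- list(excitations)
  stopifnot(length(spikes) == length(excitations))
  ids <- unique(unlist(lapply(spikes, function(s) names(s$trains))))
  hits <- matrix(0, length(ids), 6, dimnames = list(ids, MUSCLES))
  nsp <- setNames(numeric(length(ids)), ids)
  for (i in seq_along(spikes)) {
    exc <- excitations[[i]]
    for (id in names(spikes[[i]]$trains)) {
      tt <- spikes[[i]]$trains[[id]]
      if (!length(tt)) next
      e <- excitation_at(exc, tt)
      hits[id, ] <- hits[id, ] + colSums(e > tol)
      nsp[id] <- nsp[id] + length(tt)
    }
  }
  frac <- hits / pmax(nsp, 1)
  units <- lapply(ids, function(id) {
    if (nsp[id] == 0) return(character(0))
    MUSCLES[frac[id, ] >= threshold]
  })
  names(units) <- ids
  unassigned <- ids[vapply(units, length, 0L) == 0]
  structure(list(units = units, unassigned = unassigned, coincidence = frac,
                 n_spikes = nsp, threshold = threshold),
            class = "assignment_map")
}

#' Train the complete neural mapping model
#'
#' Fits one robust linear model per assigned (muscle, unit) pair across all
#' calibration trials (windows where the unit has at least one spike), and
#' one fallback ANN per muscle from PCA-reduced time-domain EMG features to
#' the calibration excitation (same architecture and training as the
#' baseline regressor).
#'
#' @param dsc_list list of [extract_dsc()] matrices, one per calibration
#'   trial.
#' @param exc_list matching list of calibration [excitation_set()]s.
#' @param td_list matching list of [extract_td()] matrices (fallback
#'   inputs); may be `NULL` to skip fallback training.
#' @param assignment an [assign_units()] map.
#' @param ann_restarts,ann_hidden fallback ANN training parameters.
#' @param pca_variance retained-variance target for the fallback PCA.
#' @param seed RNG seed for the fallback ANNs.
#' @return an object of class `neural_model`.
#' @export
train_neural_model <- function(dsc_list, exc_list, td_list, assignment,
                               ann_restarts = 50, ann_hidden = 3,
                               pca_variance = 0.98, seed = 1) {
  stopifnot(length(dsc_list) == length(exc_list))
  unit_models <- list()
  fallback_only <- character(0)
  for (m in MUSCLES) {
    m_units <- names(assignment$units)[vapply(assignment$units,
                                              function(s) m %in% s, TRUE)]
    fitted <- list()
    for (id in m_units) {
      xs <- numeric(0); ys <- numeric(0)
      for (i in seq_along(dsc_list)) {
        D <- dsc_list[[i]]
        if (!(id %in% colnames(D))) next
        cnt <- unclass(D)[, id]
        act <- cnt > 0
        if (!any(act)) next
        xs <- c(xs, cnt[act])
        ys <- c(ys, unclass(exc_list[[i]])[act, m])
      }
      if (length(xs) >= 2 && length(unique(xs)) >= 2)
        fitted[[id]] <- fit_unit_regressor(xs, ys)
    }
    if (!length(fitted)) fallback_only <- c(fallback_only, m)
    unit_models[[m]] <- fitted
  }
  fallback <- NULL
  if (!is.null(td_list)) {
    TD <- do.call(rbind, lapply(td_list, unclass))
    pca <- fit_pca(TD, pca_variance)
    S <- apply_pca(pca, TD)
    seeds <- child_seeds(seed, 6)
    anns <- lapply(seq_along(MUSCLES), function(j) {
      y <- unlist(lapply(exc_list, function(e) unclass(e)[, j]))
      train_ann(S, y, n_hidden = ann_hidden, restarts = ann_restarts,
                seed = seeds[j])
    })
    names(anns) <- MUSCLES
    fallback <- list(pca = pca, anns = anns)
  }
  structure(list(assignment = assignment, unit_models = unit_models,
                 fallback = fallback, fallback_only = fallback_only),
            class = "neural_model")
}

#' Predict muscle excitations from spike counts (with ANN fallback)
#'
#' For each window and muscle, every assigned unit with at least one spike
#' in the window contributes `b0 + b1 * count`; the muscle excitation is the
#' median of those contributions (midpoint of the central pair for even
#' counts), clamped to `[0, 1]`. Windows in which no assigned unit fires use
#' the muscle's fallback ANN on the time-domain features.
#'
#' @param model a [train_neural_model()] model.
#' @param dsc an [extract_dsc()] matrix for the trial.
#' @param td matching [extract_td()] matrix (may be `NULL` if the model has
#'   no fallback and no silent windows occur).
#' @return an [excitation_set()] on the trial grid, with attribute
#'   `fallback_used` (windows x muscles logical).
#' @export
predict_excitations <- function(model, dsc, td = NULL) {
  stopifnot(inherits(model, "neural_model"), inherits(dsc, "dsc_matrix"))
  grid <- attr(dsc, "grid")
  n <- grid$n
  counts <- unclass(dsc)
  E <- matrix(0, n, 6, dimnames = list(NULL, MUSCLES))
  used_fb <- matrix(FALSE, n, 6, dimnames = list(NULL, MUSCLES))
  n_active <- matrix(0L, n, 6, dimnames = list(NULL, MUSCLES))
  fb_scores <- NULL
  for (j in seq_along(MUSCLES)) {
    m <- MUSCLES[j]
    fits <- model$unit_models[[m]]
    est <- matrix(NA_real_, n, length(fits))
    for (u in seq_along(fits)) {
      id <- names(fits)[u]
      if (!(id %in% colnames(counts))) next
      cnt <- counts[, id]
      act <- cnt > 0
      n_active[act, j] <- n_active[act, j] + 1L
      est[act, u] <- fits[[id]]$intercept + fits[[id]]$slope * cnt[act]
    }
    med <- if (length(fits) == 0) rep(NA_real_, n)
           else apply(est, 1, function(r) if (all(is.na(r))) NA_real_
                      else median(r, na.rm = TRUE))
    silent <- is.na(med)
    if (any(silent)) {
      if (is.null(model$fallback))
        stop("configuration error: silent windows but no fallback ANN")
      if (is.null(td))
        stop("configuration error: fallback needed but no TD features given")
      if (is.null(fb_scores)) fb_scores <- apply_pca(model$fallback$pca, td)
      med[silent] <- ann_predict(model$fallback$anns[[m]],
                                 fb_scores[silent, , drop = FALSE])
      used_fb[silent, j] <- TRUE
    }
    E[, j] <- pmin(pmax(med, 0), 1)
  }
  out <- excitation_set(E, grid)
  attr(out, "fallback_used") <- used_fb
  attr(out, "active_units") <- n_active
  attr(out, "n_models") <- vapply(model$unit_models, length, 0L)
  out
}
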