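#' @name td-features
#' @title Time-domain EMG features and PCA reduction
#'
#' @description
#' Classical per-channel, per-window time-domain (TD) features of the
#' interference EMG: root mean square (RMS), slope-sign changes (SSC), zero
#' crossings (ZC) and waveform length (WL). ZC/SSC use an amplitude deadband
#' of 1% of the channel RMS. Feature matrices are reduced by PCA fitted on
#' training data only, keeping the smallest number of components that
#' retains 98% of the variance.
NULL

td_window_features <- function(x, delta) {
  n <- length(x)
  rms <- sqrt(mean(x^2))
  d <- diff(x)
  wl <- sum(abs(d))
  zc <- sum(x[-n] * x[-1] < 0 & abs(d) >= delta)
  if (n >= 3) {
    d1 <- d[-(n - 1)]; d2 <- d[-1]
    ssc <- sum(d1 * -d2 > 0 & (abs(d1) >= delta | abs(d2) >= delta))
  } else ssc <- 0
  c(rms, ssc, zc, wl)
}

#' Extract TD features on the window grid
#'
#' @param emg a (preprocessed) [emg_recording()].
#' @param grid the shared [build_window_grid()].
#' @param deadband_frac ZC/SSC amplitude deadband as a fraction of each
#'   channel's whole-trial RMS.
#' @return a `td_matrix`: windows x (channels * 4) matrix, per-channel
#'   column blocks ordered RMS, SSC, ZC, WL; grid attached as attribute.
#' @export
extract_td <- function(emg, grid, deadband_frac = 0.01) {
  stopifnot(inherits(emg, "emg_recording"), inherits(grid, "window_grid"))
  fs <- emg$sample_rate
  X <- emg$samples
  nch <- nrow(X)
  # half-open windows: sample k (time (k-1)/fs) belongs iff
  # start <= (k-1)/fs < start + length
  i0 <- floor(grid$starts * fs + 1e-9) + 1
  i1 <- ceiling((grid$starts + grid$length) * fs - 1e-9)
  i1 <- pmin(i1, ncol(X))
  if (any(i1 < i0)) stop("invalid argument: window outside signal span")
  out <- matrix(0, nrow = grid$n, ncol = nch * 4)
  for (c in seq_len(nch)) {
    delta <- deadband_frac * sqrt(mean(X[c, ]^2))
    for (w in seq_len(grid$n)) {
      out[w, (c - 1) * 4 + 1:4] <-
        td_window_features(X[c, i0[w]:i1[w]], delta)
    }
  }
  colnames(out) <- as.vector(t(outer(seq_len(nch), c("rms", "ssc", "zc", "wl"),
                                     function(i, f) paste0("ch", i, "_", f))))
  structure(out, grid = grid, class = "td_matrix")
}

#' Fit PCA retaining a target fraction of variance
#'
#' Loadings and centering are computed from the training matrix only; the
#' number of components is the smallest that reaches the retained-variance
#' target (rank-limited for degenerate inputs).
#'
#' @param x training feature matrix (windows x features).
#' @param target_variance retained-variance target, default 0.98.
#' @return an object of class `pca_model`.
#' @export
fit_pca <- function(x, target_variance = 0.98) {
  x <- unclass(x)
  stopifnot(nrow(x) >= 2)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  v <- pc$sdev^2
  cum <- cumsum(v) / sum(v)
  k <- which(cum >= target_variance - 1e-12)[1]
  if (is.na(k)) k <- length(v)
  structure(list(rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 center = pc$center, n_components = k,
                 explained = cum[k], target = target_variance),
            class = "pca_model")
}

#' Project features with stored PCA loadings
#'
#' @param model a [fit_pca()] model.
#' @param x feature matrix with the same columns as the training matrix.
#' @return scores matrix (windows x n_components).
#' @export
apply_pca <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  x <- unclass(x)
  attr(x, "grid") <- NULL
  sweep(as.matrix(x), 2, model$center) %*% model$rotation
}

#' Concatenate TD and DSC feature blocks
#'
#' Column-wise concatenation (TD block first) of feature matrices sharing
#' one window grid; the combined matrix then follows the same PCA path as
#' TD alone.
#'
#' @param td a [extract_td()] matrix.
#' @param dsc a [extract_dsc()] matrix.
#' @return combined feature matrix with the grid attached.
#' @export
concat_td_dsc <- function(td, dsc) {
  gt <- attr(td, "grid"); gd <- attr(dsc, "grid")
  if (!grids_equal(gt, gd)) stop("invalid argument: window grid mismatch")
  out <- cbind(unclass(td), unclass(dsc))
  structure(out, grid = gt, class = "td_matrix")
}
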