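#' @name filters
#' @title Butterworth filtering utilities
#'
#' @description
#' Minimal Butterworth IIR design (low-pass and band-pass) via the bilinear
#' transform with frequency pre-warping, and zero-phase forward-backward
#' filtering with reflective edge padding. Implemented in-package because no
#' signal-processing package is available in the target environment; the
#' recursion itself runs in compiled code.
NULL

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (rt in r) p <- c(p, 0) - c(0, p * rt)
  p
}

#' Design a digital Butterworth filter
#'
#' @param n filter order of the analog prototype (a band-pass doubles the
#'   number of poles, matching common practice of quoting prototype order).
#' @param w cutoff(s) normalized to the Nyquist frequency: scalar in (0,1)
#'   for `"low"`, length-2 for `"band"`.
#' @param type `"low"` or `"band"`.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_design <- function(n, w, type = c("low", "band")) {
  type <- match.arg(type)
  if (any(w <= 0 | w >= 1)) stop("invalid argument: cutoffs must be in (0,1)")
  # analog prototype poles on the unit left half circle
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  warp <- function(f) 2 * tan(pi * f / 2)
  if (type == "low") {
    wc <- warp(w[1])
    pa <- p * wc
    za <- complex(0)
    ref <- 0 # match gain at DC
  } else {
    stopifnot(length(w) == 2, w[1] < w[2])
    w1 <- warp(w[1]); w2 <- warp(w[2])
    w0 <- sqrt(w1 * w2); bw <- w2 - w1
    # s -> (s^2 + w0^2) / (bw s): each prototype pole yields two
    pb <- p * bw / 2
    disc <- sqrt(pb^2 - w0^2)
    pa <- c(pb + disc, pb - disc)
    za <- rep(0 + 0i, n)
    ref <- 2 * atan(w0 / 2) / pi # digital center frequency (of Nyquist)
  }
  # bilinear transform, T = 1 with the warp above
  zp <- (2 + pa) / (2 - pa)
  zz <- c((2 + za) / (2 - za), rep(-1 + 0i, length(pa) - length(za)))
  b <- Re(poly_from_roots(zz))
  a <- Re(poly_from_roots(zp))
  # normalize gain at the reference frequency
  zr <- exp(1i * pi * ref)
  h <- sum(b * zr^(-(seq_along(b) - 1))) / sum(a * zr^(-(seq_along(a) - 1)))
  list(b = b / abs(h), a = a)
}

# steady-state filter state for a unit step input (direct form II
# transposed); scaled by the first sample it removes start-up transients
filter_zi <- function(b, a) {
  nf <- max(length(a), length(b))
  bb <- c(b, rep(0, nf - length(b))) / a[1]
  aa <- c(a, rep(0, nf - length(a))) / a[1]
  if (nf < 2) return(numeric(0))
  comp_t <- cbind(-aa[-1], rbind(diag(1, nf - 2), 0))
  B <- bb[-1] - bb[1] * aa[-1]
  drop(solve(diag(1, nf - 1) - comp_t, B))
}

#' Zero-phase filtering (forward-backward)
#'
#' Applies the filter forwards and backwards with odd-reflection padding
#' and steady-state initial conditions, so the result has zero phase
#' distortion, squared magnitude response, and no start-up transient.
#'
#' @param filt a list with `b`, `a` as from [butter_design()].
#' @param x numeric vector (or matrix, filtered column-wise).
#' @return filtered signal, same shape as `x`.
#' @export
filtfilt <- function(filt, x) {
  if (is.matrix(x)) return(apply(x, 2, function(col) filtfilt(filt, col)))
  n <- length(x)
  np <- min(3 * (max(length(filt$a), length(filt$b)) - 1), n - 1)
  ext <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  zi <- filter_zi(filt$b, filt$a)
  y <- .cpp_iir(filt$b, filt$a, ext, zi * ext[1])
  y <- rev(.cpp_iir(filt$b, filt$a, rev(y), zi * y[length(y)]))
  y[(np + 1):(np + n)]
}

#' Multichannel surface EMG recording
#'
#' @param samples channels x time numeric matrix (arbitrary units).
#' @param sample_rate sampling rate (Hz), default 2048.
#' @param channel_layout optional `c(rows, cols)` electrode grid shape.
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(samples, sample_rate = 2048, channel_layout = NULL) {
  samples <- as.matrix(samples)
  stopifnot(all(is.finite(samples)), sample_rate > 0)
  structure(list(samples = samples, sample_rate = sample_rate,
                 channel_layout = channel_layout),
            class = "emg_recording")
}

#' Preprocess interference EMG
#'
#' Full-wave rectification followed by a zero-phase 4th-order Butterworth
#' band-pass (20-500 Hz), per channel, exactly in that (unconventional)
#' order; set `rectify_first = FALSE` for the conventional
#' band-pass-then-rectify variant.
#'
#' @param emg an [emg_recording()]; sample rate must exceed 1 kHz so the
#'   500 Hz edge is below Nyquist.
#' @param low,high band edges (Hz).
#' @param order Butterworth prototype order.
#' @param rectify_first logical.
#' @return filtered [emg_recording()].
#' @export
preprocess_emg <- function(emg, low = 20, high = 500, order = 4,
                           rectify_first = TRUE) {
  stopifnot(inherits(emg, "emg_recording"))
  fs <- emg$sample_rate
  if (fs <= 1000) stop("invalid argument: sample rate must exceed 1 kHz")
  if (high >= fs / 2) stop("invalid argument: cutoff at or above Nyquist")
  bp <- butter_design(order, c(low, high) / (fs / 2), "band")
  x <- emg$samples
  if (rectify_first) x <- abs(x)
  y <- t(apply(x, 1, function(ch) filtfilt(bp, ch)))
  if (!rectify_first) y <- abs(y)
  emg_recording(y, fs, emg$channel_layout)
}

#' Low-pass filter estimate streams
#'
#' Zero-phase 2nd-order Butterworth low-pass applied to per-window estimate
#' series (the post-hoc smoothing used for the time-domain ANN baselines,
#' not for the model-based path).
#'
#' @param x numeric vector or matrix (series in columns).
#' @param cutoff cutoff frequency (Hz), default 1.5.
#' @param rate series sampling rate (Hz), e.g. `1/window_step`.
#' @return filtered series.
#' @export
lowpass_estimates <- function(x, cutoff = 1.5, rate) {
  if (cutoff >= rate / 2) stop("invalid argument: cutoff at or above Nyquist")
  lp <- butter_design(2, cutoff / (rate / 2), "low")
  filtfilt(lp, x)
}
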