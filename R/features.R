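#' Canonical feature names
#'
#' The fixed 18-feature order is part of the dataset file contract:
#' magnitude mean, variance, min, max, range, skewness, excess kurtosis (7);
#' per-axis |mean|, variance, range for x, y, z (9); PSD peak count and
#' dominant-peak frequency in Hz (2).
#'
#' @export
HAR_FEATURE_NAMES <- c(
  "mag_mean", "mag_var", "mag_min", "mag_max", "mag_range", "mag_skew", "mag_kurt",
  "x_absmean", "x_var", "x_range",
  "y_absmean", "y_var", "y_range",
  "z_absmean", "z_var", "z_range",
  "psd_peaks", "psd_domfreq")

#' Segment an accelerometer stream into 1-s windows
#'
#' Sliding windows of `fs * window_s` samples (30 at the nominal 30 Hz) with
#' 50% overlap (hop of half a window). A trailing partial window is
#' discarded. Gaps in the stream — sample spacing larger than twice the
#' nominal period — break the tiling: no window straddles a gap.
#'
#' @param accel data.frame with columns `t`, `x`, `y`, `z`.
#' @param fs nominal sampling rate in Hz.
#' @param window_s window length in seconds.
#' @param overlap fractional overlap between consecutive windows.
#' @return integer matrix with one row per window and columns `first`,
#'   `last` (sample indices); `start`/`end` times are
#'   `accel$t[first]` and `accel$t[first] + window_s`.
#' @export
segment_windows <- function(accel, fs = 30, window_s = 1, overlap = 0.5) {
  nwin <- round(fs * window_s)
  hop <- max(1L, round(nwin * (1 - overlap)))
  n <- nrow(accel)
  if (n < nwin) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("first", "last"))))
  gap_after <- which(diff(accel$t) > 2 / fs)       # index i: gap between i and i+1
  run_start <- c(1L, gap_after + 1L)
  run_end <- c(gap_after, n)
  idx <- list()
  for (r in seq_along(run_start)) {
    len <- run_end[r] - run_start[r] + 1L
    if (len < nwin) next
    firsts <- run_start[r] + seq(0L, len - nwin, by = hop)
    idx[[length(idx) + 1]] <- cbind(first = firsts, last = firsts + nwin - 1L)
  }
  if (!length(idx)) return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("first", "last"))))
  do.call(rbind, idx)
}

#' 3D magnitude of a window
#'
#' @param window data.frame or matrix with columns `x`, `y`, `z`.
#' @return numeric vector `sqrt(x^2 + y^2 + z^2)` per sample.
#' @export
magnitude <- function(window) {
  w <- as.matrix(as.data.frame(window)[c("x", "y", "z")])
  sqrt(rowSums(w^2))
}

#' PSD peak features of a magnitude series
#'
#' Power spectral density from the N-point discrete Fourier transform of the
#' mean-removed series (rectangular window, one-sided, DC excluded). With
#' N = 30 samples at 30 Hz the bins are exactly 1 Hz, covering 1--15 Hz — the
#' band that carries essentially all locomotion information. A peak is a bin
#' strictly greater than its neighbors (single-neighbor comparison at the
#' band edges) with power at least 10% of the maximum bin. The dominant
#' frequency is the argmax bin in Hz; exact ties go to the lower frequency.
#' Flat spectra return `c(0, 0)`.
#'
#' @param mag numeric magnitude series (one window).
#' @param fs sampling rate in Hz.
#' @param peak_floor minimum power relative to the maximum bin for a bin to
#'   count as a peak.
#' @return named numeric `c(psd_peaks, psd_domfreq)`.
#' @export
psd_features <- function(mag, fs = 30, peak_floor = 0.1) {
  n <- length(mag)
  x <- mag - mean(mag)
  nb <- floor(n / 2)
  power <- Mod(stats::fft(x))[2:(nb + 1)]^2
  freq_hz <- seq_len(nb) * fs / n
  if (max(power) < 1e-12) return(c(psd_peaks = 0, psd_domfreq = 0))
  left <- c(-Inf, power[-nb])
  right <- c(power[-1], -Inf)
  is_peak <- power > left & power > right & power >= peak_floor * max(power)
  # ties (within FP noise) resolve toward the lower frequency
  dom <- which(power >= max(power) * (1 - 1e-9))[1]
  c(psd_peaks = sum(is_peak), psd_domfreq = freq_hz[dom])
}

#' Extract the 18-feature vector of one window
#'
#' Statistical moments use the population convention; kurtosis is excess
#' kurtosis; zero-variance windows return skewness and kurtosis 0. Per-axis
#' features are the absolute mean (sign-invariant), population variance and
#' range. See [HAR_FEATURE_NAMES] for the order.
#'
#' @param window data.frame or matrix with columns `x`, `y`, `z` (one
#'   window, nominally 30 samples).
#' @param fs sampling rate in Hz.
#' @return named numeric vector of length 18.
#' @export
extract_features <- function(window, fs = 30) {
  w <- as.matrix(as.data.frame(window)[c("x", "y", "z")])
  assert_no_nan(w, "window samples")
  m <- sqrt(rowSums(w^2))
  mm <- mean(m)
  d <- m - mm
  v <- mean(d^2)
  sk <- if (v > 1e-24) mean(d^3) / v^1.5 else 0
  ku <- if (v > 1e-24) mean(d^4) / v^2 - 3 else 0
  per_axis <- function(a) {
    c(abs(mean(a)), mean((a - mean(a))^2), max(a) - min(a))
  }
  out <- c(mm, v, min(m), max(m), max(m) - min(m), sk, ku,
           per_axis(w[, "x"]), per_axis(w[, "y"]), per_axis(w[, "z"]),
           psd_features(m, fs = fs))
  stats::setNames(out, HAR_FEATURE_NAMES)
}

#' Extract features for every window of a stream
#'
#' Vectorized over windows (column-wise matrix operations and a single
#' multivariate FFT), so multi-hour streams extract in seconds.
#'
#' @param accel data.frame with columns `t`, `x`, `y`, `z`.
#' @param fs,window_s,overlap see [segment_windows()].
#' @return data.frame with columns `start`, `end`, `f1` .. `f18` (in
#'   [HAR_FEATURE_NAMES] order).
#' @export
extract_features_stream <- function(accel, fs = 30, window_s = 1, overlap = 0.5) {
  idx <- segment_windows(accel, fs = fs, window_s = window_s, overlap = overlap)
  nwin <- round(fs * window_s)
  empty <- stats::setNames(
    data.frame(matrix(numeric(0), ncol = 20)),
    c("start", "end", paste0("f", 1:18)))
  if (!nrow(idx)) return(empty)
  assert_no_nan(as.matrix(accel[c("x", "y", "z")]), "accelerometer samples")
  take <- function(col) {
    matrix(accel[[col]][outer(0:(nwin - 1L), idx[, "first"], `+`)], nrow = nwin)
  }
  X <- take("x"); Y <- take("y"); Z <- take("z")
  M <- sqrt(X^2 + Y^2 + Z^2)
  mm <- colMeans(M)
  D <- sweep(M, 2, mm)
  v <- colMeans(D^2)
  mn <- apply(M, 2, min); mx <- apply(M, 2, max)
  ok <- v > 1e-24
  sk <- ifelse(ok, colMeans(D^3) / pmax(v, 1e-300)^1.5, 0)
  ku <- ifelse(ok, colMeans(D^4) / pmax(v, 1e-300)^2 - 3, 0)
  axis_feats <- function(A) {
    am <- colMeans(A)
    list(absmean = abs(am),
         var = colMeans(sweep(A, 2, am)^2),
         range = apply(A, 2, max) - apply(A, 2, min))
  }
  ax <- axis_feats(X); ay <- axis_feats(Y); az <- axis_feats(Z)
  # one-sided PSD for all windows at once
  nb <- floor(nwin / 2)
  P <- Mod(stats::mvfft(D))[2:(nb + 1), , drop = FALSE]^2
  pmaxv <- apply(P, 2, max)
  flat <- pmaxv < 1e-12
  up <- rbind(-Inf, P[-nb, , drop = FALSE])
  down <- rbind(P[-1, , drop = FALSE], -Inf)
  peaks <- colSums(P > up & P > down & sweep(P, 2, peak_floor_power(pmaxv), `>=`))
  near_max <- sweep(P, 2, pmaxv * (1 - 1e-9), `>=`)  # FP-tolerant tie handling
  dom <- max.col(t(near_max), ties.method = "first") * fs / nwin
  peaks[flat] <- 0; dom[flat] <- 0
  out <- data.frame(
    start = accel$t[idx[, "first"]],
    end = accel$t[idx[, "first"]] + window_s,
    mm, v, mn, mx, mx - mn, sk, ku,
    ax$absmean, ax$var, ax$range,
    ay$absmean, ay$var, ay$range,
    az$absmean, az$var, az$range,
    peaks, dom)
  names(out) <- c("start", "end", paste0("f", 1:18))
  rownames(out) <- NULL
  out
}

peak_floor_power <- function(pmaxv, peak_floor = 0.1) peak_floor * pmaxv
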