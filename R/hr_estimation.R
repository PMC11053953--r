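# Clip-level heart-rate estimation from the green-channel skin video:
# 10 x 10 averaging downsample, 6th-order Butterworth band-pass of every
# per-pixel time series, per-pixel FFT dominant frequency, 3 x 3 spatial
# median filter, and the median of the non-zero map values.

#' Band-pass filter specification
#'
#' @param order total filter order of the Butterworth band-pass (must be
#'   even; the default 6 gives three pole pairs per band edge).
#' @param low_hz,high_hz pass-band edges in Hz.  The default 0.75--3.5 Hz
#'   corresponds to 45--210 beats per minute.
#' @return An object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(order = 6L, low_hz = 0.75, high_hz = 3.5) {
  order <- as.integer(order)
  if (order < 2L || order %% 2L != 0L) stop("`order` must be a positive even integer")
  if (!(0 < low_hz && low_hz < high_hz)) stop("need 0 < low_hz < high_hz")
  structure(list(order = order, low_hz = low_hz, high_hz = high_hz),
            class = "bandpass_spec")
}

butter_coefs <- function(spec, fs) {
  if (spec$high_hz >= fs / 2) {
    stop("high_hz = ", spec$high_hz, " must be below the Nyquist frequency ",
         fs / 2)
  }
  bf <- signal::butter(spec$order %/% 2L,
                       c(spec$low_hz, spec$high_hz) / (fs / 2), type = "pass")
  list(b = bf$b, a = bf$a)
}

# Direct-form-II-transposed IIR filter applied down the columns of X.
iir_filter_cols <- function(b, a, X) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  T <- nrow(X); m <- ncol(X)
  Y <- matrix(0, T, m)
  z <- matrix(0, n - 1L, m)
  for (t in seq_len(T)) {
    x <- X[t, ]
    y <- b[1] * x + z[1, ]
    for (k in seq_len(n - 2L)) {
      z[k, ] <- b[k + 1L] * x + z[k + 1L, ] - a[k + 1L] * y
    }
    z[n - 1L, ] <- b[n] * x - a[n] * y
    Y[t, ] <- y
  }
  Y
}

# Zero-phase forward-backward filtering with odd-reflection edge padding,
# applied down the columns of X.
filtfilt_cols <- function(b, a, X) {
  T <- nrow(X)
  pad <- min(3L * (max(length(a), length(b)) - 1L), T - 1L)
  top <- 2 * X[rep(1L, pad), , drop = FALSE] - X[pad + 1L - seq_len(pad) + 1L, , drop = FALSE]
  bot <- 2 * X[rep(T, pad), , drop = FALSE] - X[T - seq_len(pad), , drop = FALSE]
  Xp <- rbind(top, X, bot)
  Y <- iir_filter_cols(b, a, Xp)
  Y <- iir_filter_cols(b, a, Y[rev(seq_len(nrow(Y))), , drop = FALSE])
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  Y[pad + seq_len(T), , drop = FALSE]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Removes the mean, then applies the band-pass forward and backward
#' (zero phase, so extrema timing is preserved for the downstream peak
#' detection) with odd-reflection edge padding.
#'
#' @param x numeric vector (one time series) or `T x m` matrix (one series
#'   per column).
#' @param fs sampling rate in Hz.
#' @param spec a [bandpass_spec()].
#' @return Filtered series of the same shape.
#' @export
bandpass_filter <- function(x, fs, spec = bandpass_spec()) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, ncol = 1L) else x
  if (nrow(X) < 3L * spec$order) {
    stop_pulsemap(sprintf("series of length %d is too short for an order-%d band-pass (need >= %d samples)",
                          nrow(X), spec$order, 3L * spec$order),
                  "pulsemap_short_series")
  }
  co <- butter_coefs(spec, fs)
  X <- sweep(X, 2L, colMeans(X))
  Y <- filtfilt_cols(co$b, co$a, X)
  if (vec) as.numeric(Y) else Y
}

#' Per-pixel dominant-frequency map
#'
#' Band-pass filters the time series of every skin pixel, takes its FFT,
#' and records the frequency of the maximum-magnitude bin restricted to
#' the pass band.  Ties break toward the lowest frequency.  Non-skin
#' pixels are 0.
#'
#' @param skin_clip_green `T x h x w` green-channel array (already
#'   downsampled and masked).
#' @param fs frame rate in Hz.
#' @param spec a [bandpass_spec()].
#' @param skin_mask_lowres binary `h x w` matrix of valid pixels.
#' @return An object of class `frequency_map` with `freq_hz` (`h x w`,
#'   Hz) and `valid`.
#' @export
dominant_frequency_map <- function(skin_clip_green, fs,
                                   spec = bandpass_spec(),
                                   skin_mask_lowres) {
  d <- dim(skin_clip_green)
  sel <- which(skin_mask_lowres != 0)
  if (length(sel) == 0L) stop("`skin_mask_lowres` is empty")
  X <- skin_clip_green
  dim(X) <- c(d[1], d[2] * d[3])
  X <- X[, sel, drop = FALSE]
  Xf <- bandpass_filter(X, fs, spec)
  mag <- Mod(stats::mvfft(Xf))
  freqs <- (seq_len(d[1]) - 1) * fs / d[1]
  band <- which(freqs >= spec$low_hz & freqs <= spec$high_hz &
                  freqs <= fs / 2)
  if (length(band) == 0L) stop("no FFT bin falls inside the pass band")
  peak <- band[apply(mag[band, , drop = FALSE], 2L, which.max)]
  fmap <- matrix(0, d[2], d[3])
  fmap[sel] <- freqs[peak]
  structure(list(freq_hz = fmap, valid = (skin_mask_lowres != 0) * 1L,
                 fs = fs, n_samples = d[1], spec = spec),
            class = "frequency_map")
}

#' Heart-rate estimate
#'
#' @param f_hr heart-rate frequency in Hz; must lie in `band`.
#' @param band admissible frequency band in Hz.
#' @return An object of class `ehr_result` with `f_hr` (Hz), `bpm`
#'   (`60 * f_hr`) and `t_hr` (`1 / f_hr`, seconds).
#' @export
ehr_result <- function(f_hr, band = c(0.75, 3.5)) {
  if (f_hr < band[1] - 1e-9 || f_hr > band[2] + 1e-9) {
    stop("f_hr = ", f_hr, " Hz is outside the admissible band [",
         band[1], ", ", band[2], "] Hz")
  }
  structure(list(f_hr = f_hr, bpm = 60 * f_hr, t_hr = 1 / f_hr),
            class = "ehr_result")
}

#' @export
print.ehr_result <- function(x, ...) {
  cat(sprintf("<ehr_result> %.3f Hz = %.1f bpm (T_HR = %.3f s)\n",
              x$f_hr, x$bpm, x$t_hr))
  invisible(x)
}

#' Clip-level heart rate from a frequency map
#'
#' Applies a spatial median filter (zero-excluding by default) to the
#' dominant-frequency map and returns the median of all non-zero filtered
#' values as the estimated heart rate.  Even-count medians use the
#' lower-median convention, so the estimate is always an observed FFT bin
#' frequency.
#'
#' @param fmap a `frequency_map`.
#' @param median_kernel side of the spatial median window.
#' @param exclude_zeros logical; drop zero (non-skin) neighbours from each
#'   median window.
#' @return An `ehr_result`.
#' @export
estimate_heart_rate <- function(fmap, median_kernel = 3L,
                                exclude_zeros = TRUE) {
  sm <- median_filter(fmap$freq_hz, median_kernel,
                      exclude_zeros = exclude_zeros)
  vals <- sm[sm != 0]
  if (length(vals) == 0L) {
    stop_pulsemap("frequency map has no non-zero values after median filtering",
                  "pulsemap_empty_map")
  }
  ehr_result(lower_median(vals),
             band = c(fmap$spec$low_hz, fmap$spec$high_hz))
}

#' Full heart-rate estimation for a masked clip
#'
#' Convenience wrapper: block-downsamples the green channel of a
#' skin-masked clip together with the mask, builds the dominant-frequency
#' map and estimates the heart rate.  A downsampled pixel is valid when at
#' least half of its source block is skin.
#'
#' @param masked_clip a skin-masked `video_clip` (see [apply_mask()]).
#' @param skin a `skin_mask` or binary `H x W` matrix.
#' @param block downsampling block side.
#' @param spec a [bandpass_spec()].
#' @param channel wavelength used for the pulsatile signal.
#' @return An `ehr_result`.
#' @export
estimate_clip_heart_rate <- function(masked_clip, skin, block = 10L,
                                     spec = bandpass_spec(),
                                     channel = "G") {
  m <- if (inherits(skin, "skin_mask")) skin$mask else skin
  green <- get_channel(masked_clip, channel)
  small <- block_downsample(green, block)
  mask_small <- block_downsample(m, block) >= 0.5
  fmap <- dominant_frequency_map(small, masked_clip$fps, spec,
                                 mask_small * 1L)
  estimate_heart_rate(fmap)
}
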