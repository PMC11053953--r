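# Brute-force reference implementations used as independent oracles.
# Each one favours the most literal formulation over efficiency.

# Otsu: exhaustive search over all candidate thresholds (the distinct
# values), maximizing between-class variance computed from the raw pixels.
oracle_otsu <- function(x) {
  v <- sort(unique(as.numeric(x)))
  best <- -Inf; best_t <- v[1]
  for (t in v[-length(v)]) {
    lo <- x[x <= t]; hi <- x[x > t]
    w0 <- length(lo) / length(x); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

# 1-D 2-means: exhaustive over all split points of the sorted values,
# minimizing within-cluster sum of squares.
oracle_two_means_split <- function(v) {
  s <- sort(unique(v))
  best <- Inf; best_split <- s[1]
  for (t in s[-length(s)]) {
    a <- v[v <= t]; b <- v[v > t]
    wss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (wss < best) { best <- wss; best_split <- t }
  }
  best_split  # cluster 1 = values <= split
}

# Naive k x k median filter (lower-median, optional zero exclusion).
oracle_median_filter <- function(img, k = 3L, exclude_zeros = TRUE) {
  r <- (k - 1L) %/% 2L
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  lower_med <- function(v) sort(v)[ceiling(length(v) / 2)]
  for (i in seq_len(H)) for (j in seq_len(W)) {
    v <- as.numeric(img[max(1, i - r):min(H, i + r),
                        max(1, j - r):min(W, j + r)])
    if (exclude_zeros) v <- v[v != 0]
    out[i, j] <- if (length(v) == 0) 0 else lower_med(v)
  }
  out
}

# Naive set-theoretic opening: union of all fully contained k x k blocks.
oracle_opening <- function(mask, k) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(0L, H, W)
  if (k > H || k > W) return(out)
  for (i in seq_len(H - k + 1L)) for (j in seq_len(W - k + 1L)) {
    blk <- mask[i:(i + k - 1L), j:(j + k - 1L)]
    if (all(blk == 1L)) out[i:(i + k - 1L), j:(j + k - 1L)] <- 1L
  }
  out
}

# Greedy min-distance extremum selection: all strict local maxima, kept in
# decreasing height order (earlier sample wins ties) subject to pairwise
# separation >= d; at most n_keep earliest survivors, 1-based indices.
oracle_peak_select <- function(x, d, n_keep = 5L) {
  T <- length(x)
  cand <- which(diff(sign(diff(x))) < 0) + 1L
  cand <- cand[x[cand] > x[cand - 1L] & x[cand] > x[cand + 1L]]
  kept <- integer(0)
  for (p in cand[order(-x[cand], cand)]) {
    if (all(abs(kept - p) >= d)) kept <- c(kept, p)
  }
  kept <- sort(kept)
  if (length(kept) > n_keep) kept <- kept[seq_len(n_keep)]
  kept
}

# Periodogram argmax restricted to a band (ties -> lowest frequency).
oracle_dominant_freq <- function(x, fs, low, high) {
  T <- length(x)
  freqs <- (seq_len(T) - 1) * fs / T
  keep <- freqs >= low & freqs <= high & freqs <= fs / 2
  p <- Mod(fft(x - mean(x)))^2
  band_f <- freqs[keep]; band_p <- p[keep]
  band_f[which.max(band_p)]
}

# Analog 6th-order Butterworth band-pass magnitude response (prewarped to
# match the bilinear-transform digital design at sampling rate fs).
butter_bandpass_gain <- function(f, low, high, fs, order = 6L) {
  warp <- function(fr) tan(pi * fr / fs)  # prewarped analog frequency
  w <- warp(f); wl <- warp(low); wh <- warp(high)
  w0sq <- wl * wh; bw <- wh - wl
  n <- order %/% 2L
  sqrt(1 / (1 + ((w^2 - w0sq) / (w * bw))^(2 * n)))
}

# Small sinusoidal single-channel clip built directly (no generator).
make_sine_clip <- function(f0, T = 120L, fps = 30, h = 6L, w = 6L,
                           amp = 2, base = 120, phase = 0, noise_sd = 0,
                           seed = 1L, channel = "G") {
  set.seed(seed)
  tt <- (seq_len(T) - 1) / fps
  s <- sin(2 * pi * f0 * tt + phase)
  fr <- array(base, c(T, h, w, 1L)) +
    array(rep(s * amp, h * w), c(T, h, w, 1L))
  if (noise_sd > 0) fr <- fr + array(rnorm(length(fr), 0, noise_sd), dim(fr))
  video_clip(fr, fps = fps, channels = channel)
}
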