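# Dual-resolution representation, per-pixel heartbeat peak/trough
# detection and extraction of the pulsatile image stacks I_max / I_min.

#' Reshape a square clip to the low (56 x 56) analysis resolution
#'
#' Block-average downsampling (10 x 10 for 3-channel RGB clips, 5 x 5 for
#' single-channel NIR whose native resolution is smaller) to suppress
#' quantization noise in the per-pixel time series, followed by bicubic
#' interpolation to exactly `target x target`.
#'
#' @param clip a square-cropped `video_clip`.
#' @param target output side in pixels.
#' @param block override of the averaging block side; default 10 for
#'   3-channel clips and 5 for single-channel clips.
#' @return A `target x target` `video_clip`.
#' @export
reshape_low_res <- function(clip, target = 56L, block = NULL) {
  reshape_clip(clip, target,
               block %||% if (length(clip$channels) == 3L) 10L else 5L)
}

#' Reshape a square clip to the high (224 x 224) classifier resolution
#'
#' 2 x 2 block averaging for 3-channel RGB clips (no averaging for the
#' other modalities), then bicubic interpolation to `target x target`,
#' preserving the spatial detail the classifier consumes.
#'
#' @inheritParams reshape_low_res
#' @return A `target x target` `video_clip`.
#' @export
reshape_high_res <- function(clip, target = 224L, block = NULL) {
  reshape_clip(clip, target,
               block %||% if (length(clip$channels) == 3L) 2L else 1L)
}

reshape_clip <- function(clip, target, block) {
  d <- dim(clip$frames)
  if (d[2] != d[3]) {
    stop("clip must be square-cropped before reshaping (got ", d[2], " x ",
         d[3], ")")
  }
  # fused operator: bicubic weights composed with the block pooling
  pool_rows <- function(n) pool_matrix(rep(seq_len(ceiling(n / block)),
                                           each = block, length.out = n))
  R <- if (block > 1L) {
    P <- pool_rows(d[2])
    bicubic_weights(nrow(P), target) %*% P
  } else bicubic_weights(d[2], target)
  C <- if (block > 1L) {
    P <- pool_rows(d[3])
    bicubic_weights(nrow(P), target) %*% P
  } else bicubic_weights(d[3], target)
  out <- array(0, c(d[1], target, target, d[4]))
  for (ch in seq_len(d[4])) {
    out[, , , ch] <- apply_separable(clip$frames[, , , ch], R, C)
  }
  video_clip(out, fps = clip$fps, channels = clip$channels,
             source_id = clip$source_id)
}

# Strict local maxima of the columns of X selected scipy-style: candidates
# are ordered by height (descending) and accepted when at least `d` samples
# from every already-accepted peak; ties in height break toward earlier
# time.  Returns 1-based sample indices, in time order.
select_peaks <- function(x, d) {
  T <- length(x)
  if (T < 3L) return(integer(0))
  cand <- which(x[2:(T - 1L)] > x[1:(T - 2L)] & x[2:(T - 1L)] > x[3:T]) + 1L
  if (length(cand) == 0L) return(integer(0))
  ord <- cand[order(-x[cand], cand)]
  kept <- integer(0)
  for (p in ord) {
    if (all(abs(kept - p) >= d)) kept <- c(kept, p)
  }
  sort(kept)
}

#' Per-pixel heartbeat peak and trough indices
#'
#' Band-pass filters every pixel's time series of the requested channel
#' (same specification as the heart-rate stage, recomputed at the low
#' resolution), then detects local maxima under a minimum separation of
#' `d = floor(3/4 * T_HR / T_S)` samples -- three quarters of a heartbeat
#' period -- and local minima via the same procedure on the negated
#' series.  At most `max_count` extrema are stored per pixel (the first
#' `max_count` in time by default); shorter lists are padded.
#'
#' @param lowres_clip the 56 x 56 `video_clip` from [reshape_low_res()].
#' @param channel wavelength tag to analyse.
#' @param ehr an `ehr_result` (the clip-level heart rate sets `d` for all
#'   pixels).
#' @param spec a [bandpass_spec()].
#' @param max_count stored extrema per pixel.
#' @param keep `"first"` keeps the earliest `max_count` detections,
#'   `"highest"` the largest-amplitude ones.
#' @return An object of class `peak_trough_index`: `peak_idx` and
#'   `trough_idx` (`h x w x max_count`, 0-based frame indices with pad
#'   sentinel -1 -- frame 0 is a legal extremum time, so the exported
#'   zero-padding convention is recovered via the validity masks
#'   `peak_valid` / `trough_valid`), plus `d`.
#' @export
detect_peaks_troughs <- function(lowres_clip, channel = "G", ehr,
                                 spec = bandpass_spec(), max_count = 5L,
                                 keep = c("first", "highest")) {
  keep <- match.arg(keep)
  d_sep <- peak_min_distance(ehr, lowres_clip$fps)
  X <- get_channel(lowres_clip, channel)
  dd <- dim(X)
  T <- dd[1]
  if (T < 2L * d_sep) {
    stop("clip too short: T = ", T, " < 2 * d = ", 2L * d_sep)
  }
  dim(X) <- c(T, dd[2] * dd[3])
  Xf <- bandpass_filter(X, lowres_clip$fps, spec)
  npix <- ncol(Xf)
  peak <- matrix(-1L, npix, max_count)
  trough <- matrix(-1L, npix, max_count)
  fill <- function(x, d) {
    s <- select_peaks(x, d)
    if (length(s) > max_count) {
      s <- if (keep == "first") s[seq_len(max_count)] else
        sort(s[order(-x[s], s)][seq_len(max_count)])
    }
    s
  }
  active <- which(colSums(abs(Xf)) > 0)  # all-zero series have no extrema
  for (p in active) {
    xs <- Xf[, p]
    pk <- fill(xs, d_sep)
    tr <- fill(-xs, d_sep)
    if (length(pk)) peak[p, seq_along(pk)] <- pk - 1L
    if (length(tr)) trough[p, seq_along(tr)] <- tr - 1L
  }
  dim(peak) <- c(dd[2], dd[3], max_count)
  dim(trough) <- c(dd[2], dd[3], max_count)
  structure(list(peak_idx = peak, trough_idx = trough,
                 peak_valid = (peak >= 0L) * 1L,
                 trough_valid = (trough >= 0L) * 1L,
                 d = d_sep, pad_value = -1L, fps = lowres_clip$fps,
                 channel = channel),
            class = "peak_trough_index")
}

#' Minimum peak separation from the heart rate
#'
#' `d = floor(3/4 * T_HR / T_S)`: three quarters of a heartbeat period in
#' samples, floored, and never below 1.
#'
#' @param ehr an `ehr_result`.
#' @param fps frame rate in Hz.
#' @return Integer separation in samples.
#' @export
peak_min_distance <- function(ehr, fps) {
  max(1L, as.integer(floor(0.75 * ehr$t_hr * fps)))
}

#' Upsample peak/trough index arrays to the high resolution
#'
#' Nearest-neighbour interpolation: each low-resolution location's index
#' vector is repeated `factor` times along each row and column, giving
#' piecewise-constant `factor^2` blocks on the high-resolution grid.
#'
#' @param idx a `peak_trough_index`.
#' @param factor spatial repetition factor (4 maps 56 to 224).
#' @return List with `peak_idx` and `trough_idx`
#'   (`(factor*h) x (factor*w) x n` arrays, pad sentinel preserved).
#' @export
upsample_indices <- function(idx, factor = 4L) {
  up <- function(a) {
    d <- dim(a)
    out <- array(a[rep(seq_len(d[1]), each = factor),
                   rep(seq_len(d[2]), each = factor), ],
                 c(d[1] * factor, d[2] * factor, d[3]))
    out
  }
  list(peak_idx = up(idx$peak_idx), trough_idx = up(idx$trough_idx),
       pad_value = idx$pad_value)
}

#' Extract the pulsatile image stacks I_max and I_min
#'
#' Pure index lookup: `I_max(x, y, n)` is the high-resolution frame value
#' at pixel `(x, y)` at that pixel's `n`-th peak time, `I_min` likewise at
#' trough times; padded positions are 0 in both stacks.
#'
#' @param highres_clip the 224 x 224 `video_clip` from
#'   [reshape_high_res()].
#' @param idx224 upsampled indices from [upsample_indices()].
#' @param channel wavelength tag to sample.
#' @return An object of class `pulsatile_stack`: `i_max`, `i_min`
#'   (`H x W x n` gray levels), matching validity masks, and the channel
#'   tag.
#' @export
extract_stacks <- function(highres_clip, idx224, channel = "G") {
  fr <- get_channel(highres_clip, channel)
  d <- dim(fr)  # T x H x W
  gather <- function(ia) {
    di <- dim(ia)
    if (di[1] != d[2] || di[2] != d[3]) {
      stop("index array is ", di[1], " x ", di[2], " but frames are ",
           d[2], " x ", d[3])
    }
    if (any(ia >= d[1])) stop("peak/trough index out of range (>= T)")
    out <- array(0, di)
    valid <- ia >= 0L
    pix <- arrayInd(which(valid), di)
    lin <- (ia[valid] + 1L) + (pix[, 1L] - 1L) * d[1] +
      (pix[, 2L] - 1L) * d[1] * d[2]
    out[valid] <- fr[lin]
    out
  }
  structure(list(i_max = gather(idx224$peak_idx),
                 i_min = gather(idx224$trough_idx),
                 peak_valid = (idx224$peak_idx >= 0L) * 1L,
                 trough_valid = (idx224$trough_idx >= 0L) * 1L,
                 channel = channel),
            class = "pulsatile_stack")
}

#' Uniform five-frame sampling for the thermal modality
#'
#' The thermal channel carries no heartbeat information, so instead of
#' extrema sampling the clip is reduced to five uniformly spaced frames at
#' 0-based indices `0, floor(T/4), floor(T/2), floor(3T/4), T-1`.
#'
#' @param clip a single-channel `video_clip` with `T >= 5`.
#' @return `H x W x 5` array of the sampled frames.
#' @export
lwir_uniform_stack <- function(clip) {
  d <- dim(clip$frames)
  if (d[4] != 1L) stop("thermal stack expects a single-channel clip")
  T <- d[1]
  if (T < 5L) stop("need at least 5 frames, got ", T)
  idx <- c(0L, floor(T / 4), floor(T / 2), floor(3 * T / 4), T - 1L) + 1L
  sel <- clip$frames[idx, , , 1L, drop = FALSE]
  dim(sel) <- c(5L, d[2], d[3])
  aperm(sel, c(2, 3, 1))
}
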