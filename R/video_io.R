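# Video clips: the uniform in-memory representation used by every stage.

#' Construct a video clip
#'
#' A video clip is a `T x H x W x C` numeric array of gray levels (8-bit
#' range semantics, values nominally in `[0, 255]`) together with its frame
#' rate and an ordered set of wavelength-channel labels.  The temporal axis
#' comes first so that the per-pixel time series -- the quantity every
#' photoplethysmographic stage operates on -- is contiguous in memory.
#'
#' @param frames numeric array, `T x H x W x C` (or `T x H x W`, promoted to
#'   a single channel).
#' @param fps frame rate in Hz; must be positive.
#' @param channels character vector of wavelength tags, one per channel,
#'   e.g. `c("B", "G", "R")`, `"NIR"` or `"LWIR"`.
#' @param source_id free-form identifier carried through the pipeline.
#' @return An object of class `video_clip` with fields `frames`, `fps`,
#'   `channels` and `source_id`.
#' @examples
#' clip <- video_clip(array(128, c(4, 8, 8, 1)), fps = 30, channels = "G")
#' n_frames(clip)
#' @export
video_clip <- function(frames, fps, channels, source_id = "") {
  if (length(dim(frames)) == 3L) dim(frames) <- c(dim(frames), 1L)
  d <- dim(frames)
  if (length(d) != 4L) stop("`frames` must be a T x H x W x C array")
  if (any(d[1:3] < 1L)) stop("frames array must have T, H, W >= 1")
  if (!d[4] %in% c(1L, 3L)) stop("channel count must be 1 or 3, got ", d[4])
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop("`fps` must be a positive scalar")
  }
  channels <- as.character(channels)
  if (length(channels) != d[4]) {
    stop("length(channels) [", length(channels),
         "] must equal the channel count [", d[4], "]")
  }
  structure(list(frames = frames, fps = fps, channels = channels,
                 source_id = as.character(source_id)),
            class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<video_clip> %d frames, %d x %d px, channels [%s], %.6g fps (T_S = %.4g s)\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ","), x$fps,
              1 / x$fps))
  if (nzchar(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' Number of frames in a clip
#' @param clip a `video_clip`.
#' @return Integer frame count `T`.
#' @export
n_frames <- function(clip) dim(clip$frames)[1]

#' Sampling period of a clip
#' @param clip a `video_clip`.
#' @return `T_S = 1/fps` in seconds.
#' @export
sampling_period <- function(clip) 1 / clip$fps

#' Extract one wavelength channel as a `T x H x W` array
#' @param clip a `video_clip`.
#' @param channel a channel label present in `clip$channels`, or a channel
#'   index.
#' @return Numeric `T x H x W` array.
#' @export
get_channel <- function(clip, channel) {
  i <- if (is.numeric(channel)) as.integer(channel) else
    match(channel, clip$channels)
  if (is.na(i) || i < 1L || i > length(clip$channels)) {
    stop("channel '", channel, "' not present; clip has [",
         paste(clip$channels, collapse = ","), "]")
  }
  clip$frames[, , , i, drop = TRUE]
}

#' Keep only the initial frames of a clip
#'
#' Clips are standardised to a fixed duration by keeping the first
#' `n_frames` frames (for the 30 fps recordings used here, 120 frames = 4 s).
#' A clip shorter than the requested length raises an error so the caller
#' can exclude it, mirroring the exclusion of too-short recordings.
#'
#' @param clip a `video_clip`.
#' @param n_frames number of initial frames to keep.
#' @return A `video_clip` with `T = n_frames`; metadata preserved.
#' @export
slice_initial <- function(clip, n_frames) {
  T <- dim(clip$frames)[1]
  if (n_frames < 1L) stop("`n_frames` must be >= 1")
  if (T < n_frames) {
    stop_pulsemap(sprintf("clip has %d frames, fewer than the requested %d: exclude it",
                          T, n_frames), "pulsemap_short_clip")
  }
  video_clip(clip$frames[seq_len(n_frames), , , , drop = FALSE],
             fps = clip$fps, channels = clip$channels,
             source_id = clip$source_id)
}

#' Write a clip as a lossless multi-page TIFF with a JSON sidecar
#'
#' Each frame becomes one TIFF page.  Clips whose values are all integers in
#' `[0, 255]` are stored at 8 bits per sample (bit-exact round trip);
#' anything else is stored as 32-bit float.  Frame rate, channel labels and
#' source id go to `<path>.json`.
#'
#' @param clip a `video_clip`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_clip <- function(clip, path) {
  fr <- clip$frames
  d <- dim(fr)
  int8 <- all(fr >= 0) && all(fr <= 255) && all(fr == round(fr))
  pages <- lapply(seq_len(d[1]), function(t) {
    pg <- fr[t, , , , drop = TRUE]
    if (length(dim(pg)) < 2L) dim(pg) <- d[2:3]
    pg / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = if (int8) 8L else 32L,
                  compression = "none", reduce = FALSE)
  meta <- list(fps = clip$fps, channels = as.list(clip$channels),
               source_id = clip$source_id, n_frames = d[1])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a clip written by [write_clip()]
#'
#' @param path TIFF path produced by [write_clip()].
#' @param expected_channels optional character vector; if given, the decoded
#'   channel count and labels must match.
#' @param fps optional frame-rate override; by default taken from the JSON
#'   sidecar.
#' @return A `video_clip`.
#' @export
read_clip <- function(path, expected_channels = NULL, fps = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  fps <- fps %||% meta$fps
  if (is.null(fps)) stop("no fps in sidecar and no override supplied")
  p1 <- pages[[1]]
  C <- if (length(dim(p1)) == 3L) dim(p1)[3] else 1L
  channels <- as.character(unlist(meta$channels %||% as.list(seq_len(C))))
  if (!is.null(expected_channels)) {
    if (length(expected_channels) != C) {
      stop("channel-count mismatch: file has ", C, " channel(s), expected ",
           length(expected_channels))
    }
    channels <- as.character(expected_channels)
  }
  H <- dim(p1)[1]; W <- dim(p1)[2]
  fr <- array(0, c(length(pages), H, W, C))
  for (t in seq_along(pages)) {
    pg <- pages[[t]] * 255
    if (length(dim(pg)) == 2L) dim(pg) <- c(H, W, 1L)
    fr[t, , , ] <- pg
  }
  video_clip(fr, fps = as.numeric(fps), channels = channels,
             source_id = as.character(meta$source_id %||% path))
}

#' Frame indices sampled at a fixed stride
#'
#' Frame indexing is 0-based throughout the package, so "every 10th frame"
#' of a 120-frame clip is the 12 indices 0, 10, ..., 110.
#'
#' @param n_frames clip length `T`.
#' @param stride sampling stride in frames.
#' @return Integer vector of 0-based frame indices.
#' @examples
#' sampled_frame_indices(120, 10)  # 12 indices
#' @export
sampled_frame_indices <- function(n_frames, stride = 10L) {
  if (stride < 1L) stop("`stride` must be >= 1")
  seq.int(0L, n_frames - 1L, by = as.integer(stride))
}
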