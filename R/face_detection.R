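# Facial region-of-interest cropping.  Reflective modalities (RGB, NIR)
# use a pluggable per-frame face detector whose boxes are averaged over
# sampled frames; the thermal modality separates the warm face from the
# background by Otsu thresholding of an averaged, blurred frame.

#' Rectangular region of interest
#'
#' @param x0,y0 top-left corner, 0-based pixel coordinates.
#' @param width,height box size in pixels (>= 1).
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(x0, y0, width, height) {
  if (width < 1 || height < 1) stop("ROI width and height must be >= 1")
  structure(list(x0 = as.integer(round(x0)), y0 = as.integer(round(y0)),
                 width = as.integer(round(width)),
                 height = as.integer(round(height))),
            class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> x0=%d y0=%d %dx%d px\n", x$x0, x$y0, x$width,
              x$height))
  invisible(x)
}

#' Built-in brightness-based face detector
#'
#' A deliberately simple detector for synthetic scenes and smoke tests: it
#' Otsu-thresholds the mean-over-channels image and returns the bounding
#' box of the bright region, or no box when thresholding is degenerate.
#' Production use is expected to inject a trained detector (any function
#' `frame -> list of roi_box`).
#'
#' @param frame `H x W x C` (or `H x W`) numeric array.
#' @return List of `roi_box` (possibly empty).
#' @export
brightness_face_detector <- function(frame) {
  g <- channel_mean(frame)
  thr <- tryCatch(otsu_threshold(g), pulsemap_degenerate_image = function(e) NULL)
  if (is.null(thr)) return(list())
  m <- g > thr
  if (!any(m)) return(list())
  rows <- range(which(apply(m, 1, any)))
  cols <- range(which(apply(m, 2, any)))
  list(roi_box(cols[1] - 1L, rows[1] - 1L, diff(cols) + 1L, diff(rows) + 1L))
}

#' Average face box over sampled frames (RGB / NIR path)
#'
#' Runs `detector` on every `sample_stride`-th frame; within a frame the
#' largest returned box is kept (a single subject is assumed).  The final
#' ROI is the arithmetic mean of each box coordinate over the frames with
#' a detection, rounded to the nearest integer and clipped to the frame.
#'
#' @param clip a `video_clip` (reflective modality).
#' @param sample_stride frame sampling stride (default every 10th frame).
#' @param detector function `frame -> list of roi_box`.
#' @return An averaged `roi_box`.
#' @export
detect_face_roi_reflective <- function(clip, sample_stride = 10L,
                                       detector = brightness_face_detector) {
  d <- dim(clip$frames)
  idx <- sampled_frame_indices(d[1], sample_stride) + 1L
  boxes <- list()
  for (t in idx) {
    found <- detector(clip$frames[t, , , , drop = TRUE])
    if (length(found) > 0L) {
      areas <- vapply(found, function(b) b$width * b$height, numeric(1))
      boxes[[length(boxes) + 1L]] <- found[[which.max(areas)]]
    }
  }
  if (length(boxes) == 0L) {
    stop_pulsemap("no face detected on any sampled frame", "pulsemap_no_face")
  }
  mean_of <- function(f) mean(vapply(boxes, `[[`, numeric(1), f))
  b <- roi_box(mean_of("x0"), mean_of("y0"), mean_of("width"),
               mean_of("height"))
  clip_box_to_frame(b, d[2], d[3])
}

clip_box_to_frame <- function(b, H, W) {
  x0 <- clamp(b$x0, 0L, W - 1L)
  y0 <- clamp(b$y0, 0L, H - 1L)
  roi_box(x0, y0, min(b$width, W - x0), min(b$height, H - y0))
}

#' Thermal face mask and ROI via Otsu thresholding (LWIR path)
#'
#' Averages `n_samples` uniformly sampled frames (indices `0`,
#' `floor(T/2)`, `T-1` for the default 3), normalizes to `[0, 1]`, blurs
#' with a 5 x 5 averaging kernel and Otsu-thresholds the result; the warm
#' (upper) class is the face.  A constant image raises an error.
#'
#' @param clip a single-channel `video_clip`.
#' @param n_samples number of uniformly sampled frames to average.
#' @return List with `mask` (binary `H x W`) and `box` (the mask's
#'   bounding `roi_box`).
#' @export
detect_face_roi_thermal <- function(clip, n_samples = 3L) {
  d <- dim(clip$frames)
  if (d[4] != 1L) stop("thermal detection expects a single-channel clip")
  T <- d[1]
  idx <- unique(floor(seq(0, T - 1, length.out = max(n_samples, 2L)))) + 1L
  avg <- apply(clip$frames[idx, , , 1L, drop = FALSE], c(2, 3), mean)
  rng <- range(avg)
  if (rng[1] == rng[2]) {
    stop_pulsemap("thermal frame is constant; Otsu threshold undefined",
                  "pulsemap_degenerate_image")
  }
  norm <- (avg - rng[1]) / (rng[2] - rng[1])
  sm <- box_blur(norm, 5L)
  thr <- otsu_threshold(sm)
  mask <- (sm > thr) * 1L
  rows <- range(which(apply(mask == 1L, 1, any)))
  cols <- range(which(apply(mask == 1L, 2, any)))
  list(mask = mask,
       box = roi_box(cols[1] - 1L, rows[1] - 1L, diff(cols) + 1L,
                     diff(rows) + 1L))
}

#' Crop every frame of a clip to an ROI box
#'
#' @param clip a `video_clip`.
#' @param box an `roi_box` (0-based coordinates).
#' @return The cropped `video_clip`.
#' @export
crop_clip <- function(clip, box) {
  d <- dim(clip$frames)
  rows <- (box$y0 + 1L):(box$y0 + box$height)
  cols <- (box$x0 + 1L):(box$x0 + box$width)
  if (max(rows) > d[2] || max(cols) > d[3]) stop("ROI exceeds frame bounds")
  video_clip(clip$frames[, rows, cols, , drop = FALSE], fps = clip$fps,
             channels = clip$channels, source_id = clip$source_id)
}
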