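# Skin segmentation: person/background separation (pluggable backend),
# two-means binarization of the blue channel, chin-stand suppression by a
# static gray-level threshold, an AND across sampled frames, morphological
# opening, and the head-movement rejection rule.

#' Default person segmenter
#'
#' Otsu-based stand-in for a semantic person-segmentation network: any
#' pixel brighter than the Otsu threshold of the frame mean, or belonging
#' to the dark band directly above that bright region (hair), is labelled
#' person.  Real deployments inject a trained backend (any function
#' `frame -> binary H x W mask`).
#'
#' @param frame `H x W x C` (or `H x W`) numeric array.
#' @return Binary `H x W` matrix; 1 = person.
#' @export
default_person_segmenter <- function(frame) {
  g <- channel_mean(frame)
  thr <- otsu_threshold(g)
  bright <- g > thr
  out <- bright * 1L
  # annex darker pixels adjacent (within 6 px) above the bright region so
  # hair-like structures stay inside the person mask
  if (any(bright)) {
    for (j in seq_len(ncol(out))) {
      hits <- which(bright[, j])
      if (length(hits) > 0L) {
        top <- min(hits)
        out[max(1L, top - 6L):top, j] <- 1L
      }
    }
  }
  out
}

#' Person/background segmentation of one frame
#'
#' @param frame `H x W x C` numeric array.
#' @param backend function `frame -> binary H x W mask`; default
#'   [default_person_segmenter()].
#' @return Binary `H x W` matrix; 1 = person, 0 = background.
#' @export
segment_person <- function(frame, backend = default_person_segmenter) {
  if (!is.function(backend)) {
    stop_pulsemap("person-segmentation backend unavailable",
                  "pulsemap_backend_error")
  }
  m <- tryCatch(backend(frame), error = function(e) {
    stop_pulsemap(paste0("person-segmentation backend failed: ",
                         conditionMessage(e)), "pulsemap_backend_error")
  })
  (m != 0) * 1L
}

#' Two-means binarization of the blue channel within the person mask
#'
#' Clusters the blue-channel intensities of person pixels with k-means
#' (k = 2) and labels as skin the cluster with the larger pixel count
#' (facial skin dominates the segmented person area in a chin-mounted
#' setup); an exact tie goes to the brighter cluster.
#'
#' @param frame_blue `H x W` blue-channel image.
#' @param person_mask binary `H x W` person mask.
#' @param seed RNG seed for the k-means initialization (1-D two-means on
#'   separated modes is effectively deterministic; the seed is recorded
#'   for reproducibility).
#' @return Binary `H x W` skin mask.
#' @export
binarize_skin_kmeans <- function(frame_blue, person_mask, seed = 1L) {
  sel <- which(person_mask != 0)
  if (length(sel) == 0L) stop("`person_mask` is empty")
  v <- frame_blue[sel]
  if (length(unique(v)) < 2L) {
    stop_pulsemap("fewer than 2 distinct intensities in the person region; k-means (k = 2) is degenerate",
                  "pulsemap_degenerate_clustering")
  }
  km <- with_seed(seed, stats::kmeans(v, centers = 2L, nstart = 5L,
                                      iter.max = 50L))
  counts <- tabulate(km$cluster, 2L)
  skin_cl <- if (counts[1] != counts[2]) which.max(counts) else
    which.max(km$centers[, 1])
  out <- matrix(0L, nrow(frame_blue), ncol(frame_blue))
  out[sel[km$cluster == skin_cl]] <- 1L
  out
}

#' Chin-stand suppression mask
#'
#' The chin stand is a bright mount visible at the frame bottom; pixels at
#' or above the static threshold are treated as chin stand.  The returned
#' mask is 1 where the pixel is *kept* (`< threshold`), so multiplying it
#' into a skin mask removes the stand.
#'
#' @param frame_ref `H x W` reference-channel image (the blue channel in
#'   the standard pipeline).
#' @param threshold static gray-level threshold; a pixel exactly at the
#'   threshold counts as chin stand.
#' @return Binary `H x W` keep-mask.
#' @export
chin_stand_mask <- function(frame_ref, threshold = 185) {
  (frame_ref < threshold) * 1L
}

#' Final skin mask of a clip
#'
#' For every sampled frame (stride 10: 12 frames of a 120-frame clip) the
#' person region is segmented and its blue channel binarized with
#' two-means; the per-frame skin masks are combined with a logical AND,
#' multiplied by the chin-stand keep-mask (computed on the first sampled
#' frame), and smoothed by a morphological opening with a square block.
#'
#' @param clip a `video_clip` with a blue channel (or single-channel NIR,
#'   in which case that channel is used).
#' @param sample_stride frame sampling stride.
#' @param opening_size side of the square opening block.
#' @param seed RNG seed forwarded to the k-means step.
#' @param person_backend pluggable person segmenter.
#' @param chin_threshold static chin-stand gray-level threshold.
#' @return An object of class `skin_mask`: `mask` (binary `H x W`),
#'   `frame_indices_used` (0-based), `H`, `W`, and `per_frame_masks` (the
#'   post-chin-stand, pre-opening masks used by [motion_filter()]).
#' @export
combine_skin_mask <- function(clip, sample_stride = 10L, opening_size = 10L,
                              seed = 1L, person_backend = default_person_segmenter,
                              chin_threshold = 185) {
  d <- dim(clip$frames)
  ch <- if ("B" %in% clip$channels) match("B", clip$channels) else 1L
  idx0 <- sampled_frame_indices(d[1], sample_stride)
  chin <- NULL
  per_frame <- vector("list", length(idx0))
  acc <- NULL
  for (k in seq_along(idx0)) {
    t <- idx0[k] + 1L
    frame <- clip$frames[t, , , , drop = TRUE]
    if (length(dim(frame)) < 2L) dim(frame) <- d[2:3]
    blue <- if (length(dim(frame)) == 3L) frame[, , ch] else frame
    person <- segment_person(frame, person_backend)
    skin <- binarize_skin_kmeans(blue, person, seed = seed)
    if (is.null(chin)) chin <- chin_stand_mask(blue, chin_threshold)
    skin <- skin * chin
    per_frame[[k]] <- skin
    acc <- if (is.null(acc)) skin else acc * skin
  }
  opened <- morph_open(acc, opening_size)
  if (!any(opened == 1L)) {
    stop_pulsemap("final skin mask is empty", "pulsemap_empty_skin")
  }
  structure(list(mask = opened, frame_indices_used = idx0,
                 H = d[2], W = d[3], per_frame_masks = per_frame),
            class = "skin_mask")
}

#' @export
print.skin_mask <- function(x, ...) {
  cat(sprintf("<skin_mask> %d x %d px, %d skin pixels (%.1f%%), %d sampled frames\n",
              x$H, x$W, sum(x$mask), 100 * mean(x$mask),
              length(x$frame_indices_used)))
  invisible(x)
}

#' Head-movement rejection rule
#'
#' The overlap mask is the AND of the per-frame skin masks; a clip is
#' rejected when the overlap covers less than `threshold` of the frame
#' area (`sum(mask) / (H * W) < threshold`), indicating significant head
#' movement during the recording.
#'
#' @param masks list of >= 2 binary `H x W` per-frame skin masks.
#' @param H,W frame size in pixels.
#' @param threshold minimum overlap ratio; the default 0.35 rejects clips
#'   whose stable skin area is under 35% of the frame.
#' @return List with `keep` (logical), `ratio` and `overlap_mask`.
#' @export
motion_filter <- function(masks, H, W, threshold = 0.35) {
  if (length(masks) < 2L) stop("`masks` must contain at least 2 masks")
  acc <- Reduce(`*`, masks)
  ratio <- sum(acc != 0) / (H * W)
  list(keep = ratio >= threshold, ratio = ratio, overlap_mask = (acc != 0) * 1L)
}

#' Zero out non-skin pixels of a clip
#'
#' @param clip a `video_clip`.
#' @param mask a `skin_mask` or binary `H x W` matrix.
#' @return The masked `video_clip`.
#' @export
apply_mask <- function(clip, mask) {
  m <- if (inherits(mask, "skin_mask")) mask$mask else mask
  d <- dim(clip$frames)
  if (!all(dim(m) == d[2:3])) {
    stop("mask is ", nrow(m), " x ", ncol(m), " but frames are ",
         d[2], " x ", d[3])
  }
  keep <- which(m != 0)
  out <- array(0, d)
  # copy only skin columns of the T x (H*W) slab per channel
  for (ch in seq_len(d[4])) {
    slab <- clip$frames[, , , ch]
    dim(slab) <- c(d[1], d[2] * d[3])
    z <- matrix(0, d[1], d[2] * d[3])
    z[, keep] <- slab[, keep]
    out[, , , ch] <- array(z, d[1:3])
  }
  video_clip(out, fps = clip$fps, channels = clip$channels,
             source_id = clip$source_id)
}
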