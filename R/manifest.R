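# Dataset bookkeeping over recording manifests.  A manifest is a plain
# data frame with one row per facial-video recording (columns
# `subject_id`, `video_id`, `label`), so retention and exclusion rules
# are ordinary row filters whose arithmetic can be audited.

#' Mock recording manifest
#'
#' One row per (subject, stimulus video): `n_subjects * 5 * videos_per_class`
#' recordings, labels cycling through the five emotion classes.
#'
#' @param n_subjects number of subjects.
#' @param videos_per_class stimulus videos per emotion class.
#' @return Data frame with columns `subject_id`, `video_id`, `label`.
#' @export
mock_manifest <- function(n_subjects = 110L, videos_per_class = 30L) {
  classes <- EMOTION_CLASSES
  video_id <- seq_len(length(classes) * videos_per_class)
  label <- rep(classes, each = videos_per_class)
  out <- expand.grid(video_id = video_id,
                     subject_id = sprintf("subj%03d", seq_len(n_subjects)),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$label <- label[out$video_id]
  out[, c("subject_id", "video_id", "label")]
}

#' Retain only validated stimulus videos
#'
#' Stimulus-level retention: for each class, the first `retained_counts[class]`
#' video ids of that class are kept for every subject (a stimulus video
#' excluded for one subject is excluded for all).
#'
#' @param manifest a manifest data frame.
#' @param retained_counts named integer vector of videos kept per class;
#'   the default keeps 27 + 30 + 26 + 22 + 25 = 130 of the original 150.
#' @return The filtered manifest.
#' @export
retain_stimulus_videos <- function(manifest,
                                   retained_counts = c(S = 27L, N = 30L,
                                                       D = 26L, F = 22L,
                                                       A = 25L)) {
  keep_ids <- integer(0)
  for (cl in names(retained_counts)) {
    ids <- sort(unique(manifest$video_id[manifest$label == cl]))
    keep_ids <- c(keep_ids, ids[seq_len(min(retained_counts[[cl]],
                                            length(ids)))])
  }
  manifest[manifest$video_id %in% keep_ids, , drop = FALSE]
}

#' Remove recordings flagged for head movement
#'
#' @param manifest a manifest data frame.
#' @param moved_rows row indices (into `manifest`) of recordings whose
#'   skin-mask overlap failed the [motion_filter()] rule.
#' @return The manifest without the flagged rows.
#' @export
remove_moved_recordings <- function(manifest, moved_rows) {
  if (length(moved_rows) == 0L) return(manifest)
  manifest[-moved_rows, , drop = FALSE]
}

#' Summary counts of a manifest
#'
#' @param manifest a manifest data frame.
#' @return List with `n_recordings`, `n_subjects`,
#'   `videos_per_subject` (unique video count per subject; scalar when
#'   uniform, else a table) and `class_counts`.
#' @export
manifest_summary <- function(manifest) {
  per_subj <- tapply(manifest$video_id, manifest$subject_id,
                     function(v) length(unique(v)))
  vps <- if (length(unique(per_subj)) == 1L) unname(per_subj[1]) else
    table(per_subj)
  list(n_recordings = nrow(manifest),
       n_subjects = length(unique(manifest$subject_id)),
       videos_per_subject = vps,
       class_counts = table(manifest$label))
}
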