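# End-to-end convenience wrappers: clip -> skin mask -> heart rate ->
# pulsatile stacks -> feature block, and cohort -> labelled feature set.

#' Compute one physiological feature block from a square-cropped clip
#'
#' Runs the full reflective-modality pipeline: skin segmentation,
#' head-movement check, masking, green-channel heart-rate estimation,
#' low-resolution peak/trough detection on the requested channel,
#' nearest-neighbour index upsampling, pulsatile stack extraction at the
#' high resolution and the requested feature map.  Only the
#' high-resolution frames actually indexed by an extremum are
#' interpolated, which leaves the result unchanged.
#'
#' @param clip a square-cropped reflective `video_clip`.
#' @param channel wavelength tag for the pulsatile stacks (the heart rate
#'   always comes from the green channel when present).
#' @param feature `"AC"` or `"R"`.
#' @param spec a [bandpass_spec()].
#' @param skin optional precomputed `skin_mask`; computed via
#'   [combine_skin_mask()] otherwise.
#' @param person_backend pluggable person segmenter.
#' @param check_motion logical; apply the [motion_filter()] rejection
#'   rule to the per-frame masks and raise a `pulsemap_motion_reject`
#'   error on failure.
#' @param seed forwarded to the k-means binarization.
#' @param lowres,highres analysis and classifier resolutions.
#' @return List with `feature` (a `feature_block`), `ehr`, `skin` and
#'   `overlap_ratio`.
#' @export
clip_feature_block <- function(clip, channel = "R", feature = c("AC", "R"),
                               spec = bandpass_spec(), skin = NULL,
                               person_backend = default_person_segmenter,
                               check_motion = TRUE, seed = 1L,
                               lowres = 56L, highres = 224L) {
  feature <- match.arg(feature)
  if (is.null(skin)) {
    skin <- combine_skin_mask(clip, seed = seed,
                              person_backend = person_backend)
  }
  ratio <- NA_real_
  if (check_motion && length(skin$per_frame_masks) >= 2L) {
    mf <- motion_filter(skin$per_frame_masks, skin$H, skin$W)
    ratio <- mf$ratio
    if (!mf$keep) {
      stop_pulsemap(sprintf("head movement: skin overlap ratio %.3f < 0.35",
                            mf$ratio), "pulsemap_motion_reject")
    }
  }
  masked <- apply_mask(clip, skin)
  hr_channel <- if ("G" %in% clip$channels) "G" else clip$channels[1]
  ehr <- estimate_clip_heart_rate(masked, skin, spec = spec,
                                  channel = hr_channel)
  # reshape only the analysed channel; single-channel subclips keep the
  # RGB block sizes of the full-clip path
  rgb <- length(clip$channels) == 3L
  one_channel <- function(src) {
    video_clip(src$frames[, , , match(channel, src$channels), drop = FALSE],
               fps = src$fps, channels = channel, source_id = src$source_id)
  }
  low <- reshape_low_res(one_channel(masked), target = lowres,
                         block = if (rgb) 10L else 5L)
  pt <- detect_peaks_troughs(low, channel = channel, ehr = ehr, spec = spec)
  idx <- upsample_indices(pt, factor = highres %/% lowres)

  # interpolate only the frames an extremum points at, then remap indices
  needed <- sort(unique(c(pt$peak_idx[pt$peak_idx >= 0L],
                          pt$trough_idx[pt$trough_idx >= 0L])))
  remap <- function(a) {
    out <- a
    pos <- a >= 0L
    out[pos] <- match(a[pos], needed) - 1L
    out
  }
  if (length(needed) == 0L) {
    # no extremum anywhere (e.g. zero pulsatile amplitude): all-padded stacks
    zed <- array(0, dim(idx$peak_idx))
    stack <- structure(list(i_max = zed, i_min = zed,
                            peak_valid = zed, trough_valid = zed,
                            channel = channel),
                       class = "pulsatile_stack")
  } else {
    sub <- one_channel(video_clip(masked$frames[needed + 1L, , , ,
                                                drop = FALSE],
                                  fps = masked$fps,
                                  channels = masked$channels,
                                  source_id = masked$source_id))
    high <- reshape_high_res(sub, target = highres,
                             block = if (rgb) 2L else 1L)
    stack <- extract_stacks(high, list(peak_idx = remap(idx$peak_idx),
                                       trough_idx = remap(idx$trough_idx),
                                       pad_value = -1L),
                            channel = channel)
  }
  fb <- if (feature == "AC") feature_ac(stack) else feature_ratio(stack)
  list(feature = fb, ehr = ehr, skin = skin, overlap_ratio = ratio)
}

#' Extract feature blocks and labels for a synthetic cohort
#'
#' Applies [clip_feature_block()] to every clip of a
#' [generate_cohort()] result and assembles the surviving clips into a
#' [labeled_feature_set()].  Clips rejected by the head-movement rule
#' are skipped and counted.
#'
#' @param cohort list of `list(clip, truth)` pairs.
#' @param channel,feature,spec,person_backend,seed forwarded to
#'   [clip_feature_block()].
#' @param highres classifier resolution.
#' @return A `labeled_feature_set` with attribute `n_rejected`.
#' @export
extract_cohort_features <- function(cohort, channel = "R", feature = "AC",
                                    spec = bandpass_spec(),
                                    person_backend = default_person_segmenter,
                                    seed = 1L, highres = 224L) {
  blocks <- list(); labels <- character(0); subjects <- character(0)
  rejected <- 0L
  for (item in cohort) {
    res <- tryCatch(
      clip_feature_block(item$clip, channel = channel, feature = feature,
                         spec = spec, person_backend = person_backend,
                         seed = seed, highres = highres),
      pulsemap_motion_reject = function(e) NULL)
    if (is.null(res)) {
      rejected <- rejected + 1L
      next
    }
    blocks[[length(blocks) + 1L]] <- res$feature$values
    labels <- c(labels, item$truth$class_label)
    subjects <- c(subjects, item$truth$subject_id)
  }
  out <- labeled_feature_set(blocks, labels, subjects)
  attr(out, "n_rejected") <- rejected
  out
}

#' Heart-rate parameter-recovery experiment
#'
#' Generates `n_clips` synthetic clips with pulse frequencies drawn
#' uniformly from `hr_range` at roughly 0 dB pixel-level signal-to-noise
#' ratio, runs the heart-rate estimator on each (using the ground-truth
#' skin mask, so the experiment isolates the estimator), and tabulates
#' the recovery error against the one-FFT-bin resolution limit
#' `fs / T` (0.25 Hz for 4 s at 30 fps).
#'
#' @param n_clips number of clips.
#' @param hr_range true-frequency range in Hz.
#' @param noise_sd camera noise in gray levels.
#' @param seed master seed.
#' @param geometry scene geometry (a modest 60 x 60 face by default).
#' @param duration_frames,fps clip length and frame rate.
#' @return Data frame with columns `f0`, `ehr` and `abs_error` plus
#'   attribute `bin_hz`.
#' @export
run_hr_recovery_experiment <- function(n_clips = 50L,
                                       hr_range = c(0.9, 3.0),
                                       noise_sd = 0.7, seed = 1L,
                                       geometry = face_geometry(60, 60),
                                       duration_frames = 120L, fps = 30) {
  draws <- with_seed(seed, list(
    f0 = stats::runif(n_clips, hr_range[1], hr_range[2]),
    phase = stats::runif(n_clips, 0, 2 * pi),
    cs = sample.int(.Machine$integer.max - 1L, n_clips)))
  out <- data.frame(f0 = draws$f0, ehr = NA_real_)
  for (i in seq_len(n_clips)) {
    g <- generate_synthetic_clip(
      skin_model(f0 = draws$f0[i], phase = draws$phase[i],
                 noise_sd = noise_sd),
      geometry, duration_frames, fps, seed = draws$cs[i])
    masked <- apply_mask(g$clip, g$truth$skin_mask)
    out$ehr[i] <- estimate_clip_heart_rate(masked, g$truth$skin_mask)$f_hr
  }
  out$abs_error <- abs(out$ehr - out$f0)
  attr(out, "bin_hz") <- fps / duration_frames
  out
}

#' Subject-grouped classifier-recovery experiment
#'
#' Generates a synthetic cohort, extracts I_AC feature blocks on the red
#' channel through the full video pipeline, and evaluates the tiny-CNN
#' backbone under leave-`group_size`-subjects-out cross-validation.  With
#' `null = TRUE` every class uses the same amplitude template, so there
#' is no class signal and accuracy should sit at the 20% chance level;
#' otherwise the disjoint ring templates make the classes separable.
#'
#' @param n_subjects,clips_per_subject cohort size.
#' @param null logical; run the no-signal control cohort.
#' @param seed master seed.
#' @param group_size test-fold size in subjects.
#' @param noise_sd camera noise in gray levels.
#' @param hp training hyperparameters.
#' @return The `eval_report`, with attributes `n_clips` and
#'   `n_rejected`.
#' @export
run_cohort_experiment <- function(n_subjects = 20L, clips_per_subject = 5L,
                                  null = FALSE, seed = 1L, group_size = 5L,
                                  noise_sd = 0.5,
                                  hp = default_hyperparameters()) {
  geometry <- face_geometry()
  effect <- if (null) {
    uni <- matrix(1, geometry$height, geometry$width)
    stats::setNames(rep(list(uni), 5L), c("A", "D", "F", "S", "N"))
  } else {
    ring_class_templates(geometry, boost = 4)
  }
  # stream one clip at a time: a full cohort of frame stacks would not fit
  # comfortably in memory, and only the 224 x 224 x 5 features are needed
  specs <- cohort_clip_specs(n_subjects, clips_per_subject, effect, seed,
                             geometry, hr_range = c(0.9, 2.5),
                             noise_sd = noise_sd)
  blocks <- list(); labels <- character(0); subjects <- character(0)
  rejected <- 0L
  for (sp in specs) {
    item <- generate_cohort_clip(sp, geometry)
    res <- tryCatch(
      clip_feature_block(item$clip, channel = "R", feature = "AC"),
      pulsemap_motion_reject = function(e) NULL)
    if (is.null(res)) {
      rejected <- rejected + 1L
      next
    }
    blocks[[length(blocks) + 1L]] <- res$feature$values
    labels <- c(labels, item$truth$class_label)
    subjects <- c(subjects, item$truth$subject_id)
  }
  feats <- labeled_feature_set(blocks, labels, subjects)
  attr(feats, "n_rejected") <- rejected
  plan <- make_cv_splits(unique(feats$subject_ids), group_size = group_size,
                         seed = seed + 1L)
  report <- train_and_evaluate(feats, plan, hp = hp, seed = seed + 2L)
  attr(report, "n_clips") <- length(feats$blocks)
  attr(report, "n_rejected") <- attr(feats, "n_rejected")
  report
}
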