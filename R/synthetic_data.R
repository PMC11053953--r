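# Synthetic facial-video generator.
#
# Emulates the optical situation of a camera viewing facial skin: the
# observed intensity is incident light times (diffuse Beer-Lambert
# reflectance + specular reflectance),
#
#   I(lambda, t) = I0(lambda) * ( exp(-(A_DC(lambda)
#                    + A_pulse(lambda, x, y) * s(t))) + R_S(lambda) ),
#
# where s(t) is a unit periodic pulse waveform at the heart-rate frequency
# f0 and A_pulse is the per-pixel pulsatile absorbance amplitude.  Non-skin
# regions (background, hair, chin stand) carry no pulsatile component.
# Camera noise and 8-bit quantization are applied last.

#' Optical skin model for synthetic clips
#'
#' Parameters are per wavelength channel.  The defaults describe a
#' visible-light (B, G, R) skin patch whose pulsatile absorbance is
#' strongest in the green channel, with a realistic pulsatile intensity
#' swing of roughly 2 gray levels on an 8-bit scale.
#'
#' @param channels `"BGR"`, `"NIR"` or `"LWIR"`.
#' @param incident incident-light intensity `I0` per channel (gray levels).
#' @param a_dc static absorbance `A_DC` per channel (unitless).
#' @param specular specular fraction `R_S` per channel, in `[0, 1)`.
#' @param pulse_amp baseline pulsatile absorbance amplitude (unitless);
#'   multiplied by `amp_ratio` per channel and by the per-pixel amplitude
#'   template.
#' @param amp_ratio per-channel multiplier of `pulse_amp`; green strongest
#'   by default.
#' @param f0 pulse frequency in Hz.  Valid heart-rate fixtures use
#'   `[0.75, 3.5]` Hz; out-of-band values are allowed for negative tests.
#' @param phase pulse phase offset in radians.
#' @param noise_sd camera noise standard deviation in gray levels.
#' @param quantize logical; round to integer gray levels and clip to
#'   `[0, 255]` after adding noise (8-bit camera output).
#' @param waveform `"sine"` for a pure sinusoid, `"ppg"` for an asymmetric
#'   waveform with a fast systolic rise and a dicrotic shoulder.
#' @return An object of class `skin_model`.
#' @export
skin_model <- function(channels = c("BGR", "NIR", "LWIR"),
                       incident = NULL, a_dc = NULL, specular = NULL,
                       pulse_amp = 0.008, amp_ratio = NULL,
                       f0 = 1.2, phase = 0, noise_sd = 0.5,
                       quantize = TRUE, waveform = c("sine", "ppg")) {
  channels <- match.arg(channels)
  waveform <- match.arg(waveform)
  labs <- switch(channels, BGR = c("B", "G", "R"), NIR = "NIR", LWIR = "LWIR")
  nc <- length(labs)
  defaults <- switch(channels,
    BGR = list(incident = c(B = 250, G = 252, R = 252),
               a_dc = c(B = 0.80, G = 0.60, R = 0.42),
               specular = c(B = 0.04, G = 0.04, R = 0.04),
               amp_ratio = c(B = 0.8, G = 1.0, R = 0.5)),
    NIR = list(incident = c(NIR = 250), a_dc = c(NIR = 0.45),
               specular = c(NIR = 0.04), amp_ratio = c(NIR = 0.4)),
    LWIR = list(incident = c(LWIR = 200), a_dc = c(LWIR = 0),
                specular = c(LWIR = 0), amp_ratio = c(LWIR = 0)))
  incident <- incident %||% defaults$incident
  a_dc <- a_dc %||% defaults$a_dc
  specular <- specular %||% defaults$specular
  amp_ratio <- amp_ratio %||% defaults$amp_ratio
  for (v in list(incident, a_dc, specular, amp_ratio)) {
    if (length(v) != nc) stop("per-channel parameters must have length ", nc)
  }
  if (any(specular < 0 | specular >= 1)) stop("specular fraction must be in [0, 1)")
  if (f0 <= 0) stop("`f0` must be positive")
  structure(list(channel_labels = labs, incident = incident, a_dc = a_dc,
                 specular = specular, pulse_amp = pulse_amp,
                 amp_ratio = amp_ratio, f0 = f0, phase = phase,
                 noise_sd = noise_sd, quantize = quantize,
                 waveform = waveform),
            class = "skin_model")
}

#' Scene geometry for synthetic clips
#'
#' The default scene is a centred circular/elliptical face on a dark
#' background with a dark "hair" crescent above the face (so that k-means
#' binarization of the person region has a genuine two-mode problem to
#' solve) and an optional bright chin-stand rectangle at the bottom edge
#' (gray level >= 200, to exercise the static-threshold removal rule).
#'
#' @param width,height frame size in pixels.
#' @param face_center `c(x, y)` centre in pixels (1-based); default slightly
#'   above frame centre.
#' @param face_radius `c(rx, ry)` ellipse semi-axes in pixels; default a
#'   circle of radius `0.42 * min(width, height)`.
#' @param hair logical; add the dark hair crescent.
#' @param chin_stand logical; add the bright chin-stand rectangle.
#' @param hair_level,chin_level,background_level gray levels of the
#'   non-skin regions.
#' @param motion `c(dx, dy)`: total rigid translation in pixels ramped
#'   linearly over the clip (rounded to integer offsets per frame);
#'   `c(0, 0)` disables motion.
#' @return An object of class `face_geometry`.
#' @export
face_geometry <- function(width = 112L, height = 112L,
                          face_center = NULL, face_radius = NULL,
                          hair = TRUE, chin_stand = FALSE,
                          hair_level = 30, chin_level = 230,
                          background_level = 50, motion = c(0, 0)) {
  face_center <- face_center %||% c(width / 2 + 0.5, height / 2 - 0.02 * height)
  r <- 0.42 * min(width, height)
  face_radius <- face_radius %||% c(r, r)
  structure(list(width = as.integer(width), height = as.integer(height),
                 face_center = face_center, face_radius = face_radius,
                 hair = hair, chin_stand = chin_stand,
                 hair_level = hair_level, chin_level = chin_level,
                 background_level = background_level,
                 motion = motion),
            class = "face_geometry")
}

# Normalised elliptical radius of every pixel, as an H x W matrix.
# Pixel centres are at integer coordinates (col x, row y), 1-based.
elliptical_radius <- function(geom, dx = 0, dy = 0) {
  x <- matrix(seq_len(geom$width), geom$height, geom$width, byrow = TRUE)
  y <- matrix(seq_len(geom$height), geom$height, geom$width)
  cx <- geom$face_center[1] + dx
  cy <- geom$face_center[2] + dy
  sqrt(((x - cx) / geom$face_radius[1])^2 + ((y - cy) / geom$face_radius[2])^2)
}

# Region labels for one frame offset: 0 background, 1 skin, 2 hair, 3 chin.
scene_regions <- function(geom, dx = 0, dy = 0) {
  rho <- elliptical_radius(geom, dx, dy)
  lab <- matrix(0L, geom$height, geom$width)
  if (geom$hair) {
    y <- matrix(seq_len(geom$height), geom$height, geom$width)
    crescent <- rho <= 1.18 & rho > 1 & y < geom$face_center[2] + dy
    lab[crescent] <- 2L
  }
  lab[rho <= 1] <- 1L
  if (geom$chin_stand) {
    w0 <- round(geom$width * 0.25); w1 <- round(geom$width * 0.75)
    h0 <- geom$height - round(geom$height * 0.10)
    lab[h0:geom$height, w0:w1] <- 3L
  }
  lab
}

# Unit pulse waveform evaluated at phase fraction u in [0, 1).
pulse_waveform <- function(u, kind) {
  if (kind == "sine") return(sin(2 * pi * u))
  raw <- function(v) exp(-(v - 0.30)^2 / (2 * 0.09^2)) +
    0.45 * exp(-(v - 0.58)^2 / (2 * 0.11^2))
  g <- raw(seq(0, 1, length.out = 2048))
  2 * (raw(u) - min(g)) / (max(g) - min(g)) - 1
}

# Frame indices (0-based) of waveform extrema for the truth record.
waveform_extrema_frames <- function(model, duration_frames, fps) {
  u_grid <- seq(0, 1, length.out = 4096)[-4096]
  s <- pulse_waveform(u_grid, model$waveform)
  u_peak <- u_grid[which.max(s)]
  u_trough <- u_grid[which.min(s)]
  # time t has phase fraction (f0 * t + phase/(2*pi)) mod 1
  frames_at <- function(u_star) {
    k <- -2:ceiling(model$f0 * duration_frames / fps + 2)
    t_star <- (u_star - model$phase / (2 * pi) + k) / model$f0
    idx <- round(t_star * fps)
    sort(unique(idx[idx >= 0 & idx <= duration_frames - 1]))
  }
  list(peaks = frames_at(u_peak), troughs = frames_at(u_trough))
}

#' Generate one synthetic facial clip with ground truth
#'
#' Skin pixels follow the Beer-Lambert reflectance model with a periodic
#' pulsatile absorbance at `model$f0`; background, hair and chin-stand
#' pixels are static.  Identical seeds and parameters reproduce the clip
#' bit for bit.
#'
#' @param model a [skin_model()].
#' @param geometry a [face_geometry()].
#' @param duration_frames number of frames (>= 2).
#' @param fps frame rate in Hz; must exceed `2 * model$f0` (Nyquist).
#' @param seed integer RNG seed for the noise; the caller's RNG state is
#'   left untouched.
#' @param amp_template optional `H x W` multiplier of the pulsatile
#'   amplitude (1 = baseline); used to paint class-dependent spatial
#'   patterns.
#' @param class_label one of `"A", "D", "F", "S", "N"` recorded in the
#'   truth.
#' @param subject_id identifier recorded in the truth.
#' @return A list with elements `clip` (a [video_clip()]) and `truth`
#'   (class `synthetic_clip_truth`: `true_hr_hz`, `skin_mask`,
#'   `peak_times`, `trough_times` (0-based frame indices), `amp_map`,
#'   `class_label`, `subject_id`).
#' @export
generate_synthetic_clip <- function(model, geometry = face_geometry(),
                                    duration_frames = 120L, fps = 30,
                                    seed = 1L, amp_template = NULL,
                                    class_label = "N", subject_id = "s01") {
  if (duration_frames < 2L) stop("`duration_frames` must be >= 2")
  if (fps <= 2 * model$f0) {
    stop("fps = ", fps, " violates the Nyquist condition fps > 2 * f0 = ",
         2 * model$f0)
  }
  H <- geometry$height; W <- geometry$width
  nc <- length(model$channel_labels)
  T <- as.integer(duration_frames)
  tt <- (seq_len(T) - 1) / fps
  u <- (model$f0 * tt + model$phase / (2 * pi)) %% 1
  s <- pulse_waveform(u, model$waveform)

  off <- cbind(round(geometry$motion[1] * (seq_len(T) - 1) / max(T - 1, 1)),
               round(geometry$motion[2] * (seq_len(T) - 1) / max(T - 1, 1)))
  moving <- any(geometry$motion != 0)

  regions0 <- scene_regions(geometry)
  if (!any(regions0 == 1L)) stop("empty skin geometry")
  amp_template <- amp_template %||% matrix(1, H, W)

  frames <- array(0, c(T, H, W, nc))
  base_level <- function(lab, ch) {
    out <- matrix(geometry$background_level, H, W)
    out[lab == 2L] <- geometry$hair_level
    out[lab == 3L] <- geometry$chin_level
    if (model$channel_labels[ch] == "LWIR") {
      out[lab == 1L] <- model$incident[ch]  # warm face, static
    }
    out
  }
  fill_static_skin <- function(lab, ch, frame_rows) {
    # skin pixels: Beer-Lambert with pulsatile absorbance
    skin <- which(lab == 1L)
    if (model$channel_labels[ch] == "LWIR" || length(skin) == 0L) return(NULL)
    ampv <- model$pulse_amp * model$amp_ratio[ch] * amp_template[skin]
    # (frames x skin pixels) absorbance swing
    swing <- outer(s[frame_rows], ampv)
    vals <- model$incident[ch] *
      (exp(-(model$a_dc[ch] + swing)) + model$specular[ch])
    list(skin = skin, vals = vals)
  }

  if (!moving) {
    for (ch in seq_len(nc)) {
      bg <- base_level(regions0, ch)
      frames[, , , ch] <- rep(bg, each = T)
      sk <- fill_static_skin(regions0, ch, seq_len(T))
      if (!is.null(sk)) {
        # linear indices of (t, pixel) positions within the T x H x W slab
        pos <- outer(seq_len(T), (sk$skin - 1L) * T, `+`) + (ch - 1L) * T * H * W
        frames[pos] <- sk$vals
      }
    }
  } else {
    for (t in seq_len(T)) {
      lab <- scene_regions(geometry, off[t, 1], off[t, 2])
      for (ch in seq_len(nc)) {
        fr <- base_level(lab, ch)
        skin <- which(lab == 1L)
        if (model$channel_labels[ch] != "LWIR" && length(skin) > 0L) {
          ampv <- model$pulse_amp * model$amp_ratio[ch] * amp_template[skin]
          fr[skin] <- model$incident[ch] *
            (exp(-(model$a_dc[ch] + ampv * s[t])) + model$specular[ch])
        }
        frames[t, , , ch] <- fr
      }
    }
  }

  if (model$noise_sd > 0) {
    frames <- frames + with_seed(seed, array(
      stats::rnorm(length(frames), 0, model$noise_sd), dim(frames)))
  }
  if (model$quantize) frames <- clamp(round(frames), 0, 255)

  ext <- waveform_extrema_frames(model, T, fps)
  clip <- video_clip(frames, fps = fps, channels = model$channel_labels,
                     source_id = sprintf("%s/%s", subject_id, class_label))
  truth <- structure(list(true_hr_hz = model$f0,
                          skin_mask = (regions0 == 1L) * 1L,
                          peak_times = ext$peaks, trough_times = ext$troughs,
                          amp_map = model$pulse_amp * amp_template *
                            (regions0 == 1L),
                          class_label = class_label,
                          subject_id = subject_id),
                     class = "synthetic_clip_truth")
  list(clip = clip, truth = truth)
}

#' Disjoint ring-shaped class amplitude templates
#'
#' Five concentric elliptical bands of the face, one per emotion class, in
#' which the pulsatile amplitude is multiplied by `boost`.  Rings are
#' invariant under 90/180/270-degree rotations of a circular face, so the
#' class signal survives the rotation augmentation used in training.
#'
#' @param geometry a [face_geometry()] (the rings follow its ellipse).
#' @param boost amplitude multiplier inside the class band.
#' @param classes class labels, outermost band first.
#' @return Named list of `H x W` multiplier templates (baseline 1).
#' @export
ring_class_templates <- function(geometry = face_geometry(), boost = 4,
                                 classes = c("A", "D", "F", "S", "N")) {
  rho <- elliptical_radius(geometry)
  edges <- seq(0.90, 0, length.out = length(classes) + 1)
  out <- list()
  for (i in seq_along(classes)) {
    tpl <- matrix(1, geometry$height, geometry$width)
    tpl[rho < edges[i] & rho >= edges[i + 1]] <- boost
    out[[classes[i]]] <- tpl
  }
  out
}

#' Generate a cohort of synthetic clips across subjects and classes
#'
#' Emulates the structure of a multi-subject recording campaign: each
#' subject has an individual baseline skin tone and heart rate drawn from
#' configured ranges, and records `clips_per_subject` clips whose class
#' labels are balanced up to remainder.  Class identity enters only through
#' the spatial amplitude template in `class_effect`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param clips_per_subject clips recorded per subject.
#' @param class_effect named list mapping each class label in
#'   `c("A","D","F","S","N")` to an `H x W` amplitude template; default
#'   [ring_class_templates()].  Mapping every class to the same template
#'   produces a null cohort with no class signal.
#' @param seed master RNG seed; the cohort is deterministic given it.
#' @param geometry,fps,duration_frames,hr_range,noise_sd generation
#'   settings; each subject's `f0` is uniform on `hr_range`.
#' @return List of `list(clip, truth)` pairs of length
#'   `n_subjects * clips_per_subject`.
#' @export
generate_cohort <- function(n_subjects, clips_per_subject = 5L,
                            class_effect = NULL, seed = 1L,
                            geometry = face_geometry(), fps = 30,
                            duration_frames = 120L,
                            hr_range = c(0.9, 2.5), noise_sd = 0.5) {
  specs <- cohort_clip_specs(n_subjects, clips_per_subject, class_effect,
                             seed, geometry, hr_range, noise_sd)
  lapply(specs, function(sp) {
    generate_cohort_clip(sp, geometry = geometry, fps = fps,
                         duration_frames = duration_frames)
  })
}

# Deterministic per-clip generation plan for a cohort: subject-level heart
# rate and skin-tone draws, per-clip phase and noise seed, balanced class
# labels.  Splitting the plan from the generation lets large cohorts be
# processed one clip at a time without holding all frames in memory.
cohort_clip_specs <- function(n_subjects, clips_per_subject, class_effect,
                              seed, geometry, hr_range, noise_sd) {
  if (n_subjects < 2L) stop("`n_subjects` must be >= 2")
  classes <- c("A", "D", "F", "S", "N")
  class_effect <- class_effect %||% ring_class_templates(geometry)
  if (!all(classes %in% names(class_effect))) {
    stop("`class_effect` must provide a template for each of ",
         paste(classes, collapse = ", "))
  }
  if (!all(names(class_effect) %in% classes)) {
    stop("unknown class label(s) in `class_effect`: ",
         paste(setdiff(names(class_effect), classes), collapse = ", "))
  }
  draws <- with_seed(seed, {
    list(hr = stats::runif(n_subjects, hr_range[1], hr_range[2]),
         tone = stats::rnorm(n_subjects, 0, 0.06),
         phase = stats::runif(n_subjects * clips_per_subject, 0, 2 * pi),
         clip_seed = sample.int(.Machine$integer.max - 1L,
                                n_subjects * clips_per_subject))
  })
  out <- vector("list", n_subjects * clips_per_subject)
  k <- 0L
  for (i in seq_len(n_subjects)) {
    for (j in seq_len(clips_per_subject)) {
      k <- k + 1L
      out[[k]] <- list(subject_id = sprintf("subj%03d", i),
                       class_label = classes[(j - 1L) %% length(classes) + 1L],
                       f0 = draws$hr[i], phase = draws$phase[k],
                       tone = draws$tone[i], clip_seed = draws$clip_seed[k],
                       noise_sd = noise_sd,
                       template = class_effect[[
                         classes[(j - 1L) %% length(classes) + 1L]]])
    }
  }
  out
}

generate_cohort_clip <- function(sp, geometry, fps = 30,
                                 duration_frames = 120L) {
  base <- skin_model()
  mod <- skin_model(f0 = sp$f0, phase = sp$phase, noise_sd = sp$noise_sd,
                    a_dc = base$a_dc + sp$tone)
  generate_synthetic_clip(mod, geometry,
                          duration_frames = duration_frames, fps = fps,
                          seed = sp$clip_seed, amp_template = sp$template,
                          class_label = sp$class_label,
                          subject_id = sp$subject_id)
}
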