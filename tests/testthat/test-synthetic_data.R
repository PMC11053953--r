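geom_small <- face_geometry(64, 64)

test_that("zero pulsatile amplitude and zero noise give a constant video", {
  g <- generate_synthetic_clip(skin_model(pulse_amp = 0, noise_sd = 0),
                               geom_small, duration_frames = 10, fps = 30,
                               seed = 1)
  for (t in 2:10) {
    expect_identical(g$clip$frames[t, , , ], g$clip$frames[1, , , ])
  }
})

test_that("mean skin signal has its FFT maximum at the bin nearest f0", {
  g <- generate_synthetic_clip(skin_model(f0 = 1.2, noise_sd = 0),
                               geom_small, duration_frames = 120, fps = 30,
                               seed = 1)
  G <- get_channel(g$clip, "G")
  dim(G) <- c(120, 64 * 64)
  sig <- rowMeans(G[, g$truth$skin_mask == 1])
  mag <- Mod(fft(sig - mean(sig)))[2:60]       # positive frequencies
  f_peak <- which.max(mag) * 30 / 120
  bins <- (1:59) * 30 / 120
  expect_equal(f_peak, bins[which.min(abs(bins - 1.2))])
})

test_that("with no specular term the log-intensity swing is 2 * A_pulse", {
  A <- 0.05
  mod <- skin_model(f0 = 1.25, noise_sd = 0, quantize = FALSE,
                    pulse_amp = A, amp_ratio = c(B = 1, G = 1, R = 1),
                    specular = c(B = 0, G = 0, R = 0))
  g <- generate_synthetic_clip(mod, geom_small, duration_frames = 120,
                               fps = 30, seed = 1)
  px <- which(g$truth$skin_mask == 1)[1]
  series <- get_channel(g$clip, "G")[, arrayInd(px, c(64, 64))[1],
                                     arrayInd(px, c(64, 64))[2]]
  swing <- diff(range(log(series)))
  # extrema of the sampled sinusoid sit within half a sample of +-1
  expect_equal(swing, 2 * A, tolerance = 0.01)
})

test_that("identical seeds reproduce clips bit for bit", {
  a <- generate_synthetic_clip(skin_model(), geom_small, 30, 30, seed = 9)
  b <- generate_synthetic_clip(skin_model(), geom_small, 30, 30, seed = 9)
  c <- generate_synthetic_clip(skin_model(), geom_small, 30, 30, seed = 10)
  expect_identical(a$clip$frames, b$clip$frames)
  expect_false(identical(a$clip$frames, c$clip$frames))
})

test_that("generation rejects aliasing and empty skin geometry", {
  expect_error(generate_synthetic_clip(skin_model(f0 = 3), geom_small,
                                       duration_frames = 30, fps = 5),
               "Nyquist")
  tiny <- face_geometry(20, 20, face_center = c(100, 100),
                        face_radius = c(2, 2))
  expect_error(generate_synthetic_clip(skin_model(), tiny, 30, 30),
               "empty skin")
})

test_that("noiseless sinusoidal skin series are spectrally pure", {
  # f0 on an FFT bin (k * fs / T) so rectangular-window leakage does not
  # enter; the check isolates generator purity (no harmonics, no noise)
  mod <- skin_model(f0 = 1.75, noise_sd = 0, quantize = FALSE)
  g <- generate_synthetic_clip(mod, geom_small, 120, 30, seed = 1)
  skin_px <- which(g$truth$skin_mask == 1)
  G <- get_channel(g$clip, "G")
  dim(G) <- c(120, 64 * 64)
  freqs <- (0:119) * 30 / 120
  target_bin <- which.min(abs(freqs[2:61] - 1.75)) + 1L
  for (px in skin_px[c(1, 250, 700)]) {
    p <- Mod(fft(G[, px] - mean(G[, px])))^2
    ac <- sum(p[2:120])
    near <- sum(p[c(target_bin - 1, target_bin, target_bin + 1)]) +
      sum(p[120 + 2 - c(target_bin - 1, target_bin, target_bin + 1)])
    expect_gte(near / ac, 0.99)
  }
})

test_that("non-skin pixels carry only the configured noise variance", {
  mod <- skin_model(f0 = 1.3, noise_sd = 2, quantize = FALSE)
  g <- generate_synthetic_clip(mod, geom_small, 120, 30, seed = 5)
  G <- get_channel(g$clip, "G")
  dim(G) <- c(120, 64 * 64)
  bg <- which(g$truth$skin_mask == 0)
  v <- apply(G[, bg[1:200]], 2, var)
  expect_equal(mean(v), 4, tolerance = 0.15)
})

test_that("truth peak and trough frame indices interleave strictly", {
  g <- generate_synthetic_clip(skin_model(f0 = 1.25, noise_sd = 0),
                               geom_small, 120, 30, seed = 1,
                               class_label = "F", subject_id = "s9")
  pk <- g$truth$peak_times; tr <- g$truth$trough_times
  expect_gt(length(pk), 0)
  merged <- sort(c(pk, tr))
  kinds <- c(rep("p", length(pk)), rep("t", length(tr)))[order(c(pk, tr))]
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))
  expect_equal(g$truth$class_label, "F")
})

test_that("cohorts are balanced, subject-tagged and deterministic", {
  coh <- generate_cohort(10, 5, seed = 3, geometry = geom_small,
                         duration_frames = 12)
  expect_length(coh, 50L)
  subj <- vapply(coh, function(x) x$truth$subject_id, character(1))
  expect_true(all(table(subj) == 5))
  labs <- vapply(coh, function(x) x$truth$class_label, character(1))
  expect_true(all(table(labs) == 10))
  coh2 <- generate_cohort(10, 5, seed = 3, geometry = geom_small,
                          duration_frames = 12)
  expect_identical(coh[[17]]$clip$frames, coh2[[17]]$clip$frames)
})

test_that("cohort generation rejects incomplete class maps", {
  bad <- ring_class_templates(geom_small)[1:4]
  expect_error(generate_cohort(2, 5, class_effect = bad, seed = 1,
                               geometry = geom_small, duration_frames = 12),
               "template for each")
  worse <- c(ring_class_templates(geom_small),
             list(X = matrix(1, 64, 64)))
  expect_error(generate_cohort(2, 5, class_effect = worse, seed = 1,
                               geometry = geom_small, duration_frames = 12),
               "unknown class")
})

test_that("class templates with disjoint regions separate mean amplitudes", {
  tpl <- ring_class_templates(geom_small, boost = 4)
  mod_a <- skin_model(f0 = 1.25, noise_sd = 0, quantize = FALSE)
  ga <- generate_synthetic_clip(mod_a, geom_small, 120, 30, seed = 1,
                                amp_template = tpl[["A"]])
  gn <- generate_synthetic_clip(mod_a, geom_small, 120, 30, seed = 1,
                                amp_template = tpl[["N"]])
  region_a <- tpl[["A"]] > 1 & ga$truth$skin_mask == 1
  swing <- function(g) {
    G <- get_channel(g$clip, "G"); dim(G) <- c(120, 64 * 64)
    mean(apply(G[, region_a], 2, function(x) diff(range(x))))
  }
  expect_gt(swing(ga), 3 * swing(gn))
})
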