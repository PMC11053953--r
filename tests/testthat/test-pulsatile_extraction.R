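test_that("reshaping preserves constants and requires square input", {
  clip <- video_clip(array(77, c(4, 120, 120, 3)), 30, c("B", "G", "R"))
  low <- reshape_low_res(clip)
  expect_equal(dim(low$frames), c(4L, 56L, 56L, 3L))
  expect_true(all(abs(low$frames - 77) < 1e-9))
  high <- reshape_high_res(clip)
  expect_equal(dim(high$frames), c(4L, 224L, 224L, 3L))
  expect_true(all(abs(high$frames - 77) < 1e-9))
  bad <- video_clip(array(0, c(2, 30, 40, 1)), 30, "G")
  expect_error(reshape_low_res(bad), "square")
})

test_that("10x10 averaging reduces white-noise temporal variance ~100-fold", {
  set.seed(13)
  fr <- array(rnorm(60 * 120 * 120), c(60, 120, 120, 1))
  clip <- video_clip(fr, 30, "NIR")
  low <- reshape_low_res(clip, block = 10)
  v <- apply(low$frames[, 20:36, 20:36, 1], c(2, 3), var)
  # bicubic weights renormalize but the pooled variance scale survives
  expect_lt(mean(v), 1 / 50)
  expect_gt(mean(v), 1 / 300)
})

test_that("spatial rescaling leaves the dominant temporal bin unchanged", {
  fs <- 30; T <- 120
  tt <- (seq_len(T) - 1) / fs
  base <- array(rep(120 + 4 * sin(2 * pi * 1.5 * tt), 120 * 120),
                c(T, 120, 120, 1))
  clip <- video_clip(base, fs, "G")
  low <- reshape_low_res(clip, block = 10)
  x <- low$frames[, 28, 28, 1]
  expect_equal(oracle_dominant_freq(x, fs, 0.75, 3.5), 1.5)
})

test_that("d follows floor(3/4 T_HR / T_S) and peak counts match the sinusoid", {
  ehr <- ehr_result(1.25)   # T_HR / T_S = 24 samples at 30 fps
  expect_equal(peak_min_distance(ehr, 30), 18L)
  clip <- make_sine_clip(1.25, T = 120, fps = 30, h = 4, w = 4, amp = 3)
  pt <- detect_peaks_troughs(clip, channel = "G", ehr = ehr)
  expect_equal(pt$d, 18L)
  expect_true(all(pt$peak_valid == 1))   # 5 peaks in 4 s at 1.25 Hz
  expect_true(all(pt$trough_valid == 1))
  # within a pixel, consecutive stored peaks are >= d apart
  idx <- pt$peak_idx[1, 1, ]
  expect_true(all(diff(idx) >= 18))
})

test_that("constant pixels yield fully padded index arrays", {
  clip <- video_clip(array(100, c(120, 3, 3, 1)), 30, "G")
  pt <- detect_peaks_troughs(clip, channel = "G", ehr = ehr_result(1.25))
  expect_true(all(pt$peak_idx == -1L))
  expect_true(all(pt$trough_valid == 0))
})

test_that("peaks and troughs of a sinusoid interleave", {
  clip <- make_sine_clip(1.6, T = 120, fps = 30, h = 2, w = 2, amp = 2,
                         phase = 0.7)
  pt <- detect_peaks_troughs(clip, channel = "G", ehr = ehr_result(1.6))
  pk <- pt$peak_idx[1, 1, ][pt$peak_valid[1, 1, ] == 1]
  tr <- pt$trough_idx[1, 1, ][pt$trough_valid[1, 1, ] == 1]
  merged <- order(c(pk, tr))
  kinds <- c(rep("p", length(pk)), rep("t", length(tr)))[merged]
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))
})

test_that("peak/trough detection equals the greedy min-distance oracle per pixel", {
  set.seed(31)
  fs <- 30; T <- 120
  tt <- (seq_len(T) - 1) / fs
  for (rep_i in 1:3) {
    arr <- array(0, c(T, 6, 6, 1))
    for (i in 1:6) for (j in 1:6) {
      arr[, i, j, 1] <- 120 +
        3 * sin(2 * pi * runif(1, 0.9, 3.0) * tt + runif(1, 0, 2 * pi)) +
        rnorm(T, 0, 1)
    }
    clip <- video_clip(arr, fs, "G")
    ehr <- ehr_result(runif(1, 1.0, 2.5))
    pt <- detect_peaks_troughs(clip, channel = "G", ehr = ehr)
    d <- pt$d
    for (i in 1:6) for (j in 1:6) {
      x <- bandpass_filter(arr[, i, j, 1], fs)
      want_pk <- oracle_peak_select(x, d) - 1L
      want_tr <- oracle_peak_select(-x, d) - 1L
      got_pk <- pt$peak_idx[i, j, ][pt$peak_valid[i, j, ] == 1]
      got_tr <- pt$trough_idx[i, j, ][pt$trough_valid[i, j, ] == 1]
      expect_equal(got_pk, want_pk)
      expect_equal(got_tr, want_tr)
    }
  }
})

test_that("index upsampling repeats each location over its 4x4 block", {
  idx <- array(-1L, c(6, 6, 5))
  set.seed(2)
  vals <- array(sample(c(-1L, 0L, 3L, 17L, 119L), 6 * 6 * 5, TRUE),
                c(6, 6, 5))
  pt <- list(peak_idx = vals, trough_idx = idx, pad_value = -1L)
  up <- upsample_indices(pt, factor = 4L)
  expect_equal(dim(up$peak_idx), c(24L, 24L, 5L))
  for (i in 1:6) for (j in 1:6) {
    blk <- up$peak_idx[(4 * i - 3):(4 * i), (4 * j - 3):(4 * j), ]
    for (n in 1:5) expect_true(all(blk[, , n] == vals[i, j, n]))
  }
  expect_true(all(up$trough_idx == -1L))  # all-padded input stays padded
})

test_that("stack extraction is pure index lookup with zero padding", {
  T <- 20; H <- 8; W <- 8
  set.seed(4)
  fr <- array(runif(T * H * W, 0, 255), c(T, H, W, 1))
  clip <- video_clip(fr, 30, "G")
  pk <- array(sample(0:(T - 1), H * W * 5, TRUE), c(H, W, 5))
  tr <- array(sample(0:(T - 1), H * W * 5, TRUE), c(H, W, 5))
  pk[1, 1, ] <- -1L   # fully padded pixel
  st <- extract_stacks(clip, list(peak_idx = pk, trough_idx = tr,
                                  pad_value = -1L), channel = "G")
  expect_true(all(st$i_max[1, 1, ] == 0))
  for (n in 1:5) {
    expect_equal(st$i_max[3, 5, n], fr[pk[3, 5, n] + 1, 3, 5, 1])
    expect_equal(st$i_min[8, 2, n], fr[tr[8, 2, n] + 1, 8, 2, 1])
  }
  bad <- pk; bad[2, 2, 1] <- T
  expect_error(extract_stacks(clip, list(peak_idx = bad, trough_idx = tr),
                              channel = "G"), "out of range")
})

test_that("noiseless sinusoids give I_max > I_min at every valid position", {
  clip <- make_sine_clip(1.25, T = 120, fps = 30, h = 8, w = 8, amp = 3)
  pt <- detect_peaks_troughs(clip, channel = "G", ehr = ehr_result(1.25))
  up <- upsample_indices(pt, factor = 1L)
  st <- extract_stacks(clip, up, channel = "G")
  both <- st$peak_valid == 1 & st$trough_valid == 1
  expect_true(all(st$i_max[both] > st$i_min[both]))
})

test_that("thermal clips reduce to five uniformly sampled frames", {
  fr <- array(rep(1:120, 6 * 6), c(120, 6, 6, 1))
  clip <- video_clip(fr, 30, "LWIR")
  st <- lwir_uniform_stack(clip)
  expect_equal(dim(st), c(6L, 6L, 5L))
  expect_equal(st[1, 1, ], c(0, 30, 60, 90, 119) + 1)
  tiny <- video_clip(array(1:5, c(5, 1, 1, 1)), 30, "LWIR")
  expect_equal(lwir_uniform_stack(tiny)[1, 1, ], 1:5)
  const <- video_clip(array(9, c(12, 2, 2, 1)), 30, "LWIR")
  expect_true(all(lwir_uniform_stack(const) == 9))
  short <- video_clip(array(0, c(4, 2, 2, 1)), 30, "LWIR")
  expect_error(lwir_uniform_stack(short), "at least 5")
})
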