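# Beer-Lambert conversion, filtering, screening, motion rejection,
# segmentation.

make_raw <- function(n = 400, nc = 4, i0 = 1000, jitter = 0, seed = 1,
                     markers = NULL) {
  set.seed(seed)
  i730 <- matrix(i0 + rnorm(n * nc, 0, jitter), n, nc)
  i850 <- matrix(i0 + rnorm(n * nc, 0, jitter), n, nc)
  stol_raw("T01", i730, i850, markers = markers)
}

test_that("constant intensities convert to zero concentration change", {
  hb <- intensities_to_hb(make_raw(jitter = 0))
  expect_true(all(abs(hb$oxy) < 1e-12))
  expect_true(all(abs(hb$deoxy) < 1e-12))
})

test_that("total hemoglobin is oxy + deoxy and pathlength scales linearly", {
  raw <- make_raw(jitter = 3)
  hb <- intensities_to_hb(raw)
  expect_true(all(abs(hb$total - (hb$oxy + hb$deoxy)) <
                    1e-9 * max(1, max(abs(hb$total)))))
  hb2 <- intensities_to_hb(raw, dpf = 12)  # doubled pathlength
  expect_equal(hb2$oxy, hb$oxy / 2)
  expect_equal(hb2$deoxy, hb$deoxy / 2)
})

test_that("conversion inverts the forward model exactly", {
  oxy <- matrix(c(0, 2.5, -1.2, 0.4), 4, 1)
  deoxy <- matrix(c(0, -0.8, 0.3, -0.1), 4, 1)
  ints <- hb_to_intensities(oxy, deoxy)
  raw <- stol_raw("T01", ints$i730, ints$i850)
  hb <- intensities_to_hb(raw, reference = c(0, 0.5))  # first sample as ref
  expect_equal(hb$oxy, oxy, ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(hb$deoxy, deoxy, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("conversion errors name the offending channel and bad config", {
  raw <- make_raw(n = 10, nc = 3)
  raw$i850[4, 2] <- -1
  expect_error(intensities_to_hb(raw), "channel 2.*sample 4")
  bad <- matrix(c(1, 2, 2, 4), 2, 2,
                dimnames = list(c("730", "850"), c("oxy", "deoxy")))
  expect_error(intensities_to_hb(make_raw(), coefficients = bad), "singular")
})

test_that("the FIR filter preserves DC and matches its design response", {
  b <- lowpass_coefficients()
  expect_length(b, 21L)
  expect_lt(abs(sum(b) - 1), 1e-12)  # unit DC gain
  x <- rep(2.75, 300)
  expect_lt(max(abs(lowpass_filter(x) - 2.75)), 1e-6)
  # forward-backward pass attenuates by the squared design magnitude
  t <- seq(0, 600, by = 0.5)
  for (f in c(0.05, 0.2, 0.5)) {
    x <- sin(2 * pi * f * t)
    y <- lowpass_filter(x)
    gain <- sqrt(mean(y[400:800]^2) / mean(x[400:800]^2))
    expect_equal(gain, oracle_fir_gain(b, f)^2, tolerance = 1e-3)
  }
  expect_identical(length(lowpass_filter(rnorm(100))), 100L)
  expect_error(lowpass_filter(rnorm(15)), "too short")
})

test_that("filtering commutes with channel selection", {
  set.seed(3)
  m <- matrix(rnorm(200 * 3), 200, 3)
  fm <- lowpass_filter(m)
  expect_equal(fm[, 2], lowpass_filter(m[, 2]))
})

test_that("channel screening flags low signal, saturation and manual picks", {
  raw <- make_raw(nc = 6, jitter = 1)
  q0 <- screen_channels(raw)
  expect_true(all(q0$included))
  raw$i730[, 2] <- 4500       # clamped at the ceiling
  raw$i850[, 5] <- 0.5        # very low signal
  q <- screen_channels(raw, manual = 6L)
  expect_identical(q$included, c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(q$reason[c(2, 5, 6)], c("saturation", "low_signal", "manual"))
})

test_that("planted bad channels are recovered exactly", {
  raw <- make_raw(nc = 16, jitter = 2, seed = 9)
  bad <- c(3L, 11L, 14L)
  raw$i850[, 3] <- 4100
  raw$i730[, 11] <- 2
  raw$i850[, 14] <- 5000
  q <- screen_channels(raw)
  expect_identical(q$channel[!q$included], bad)
})

test_that("motion rejection masks planted spikes but leaves clean series alone", {
  set.seed(21)
  x <- rnorm(600, 0, 0.3)
  expect_false(any(reject_motion_windows(x)))
  xs <- x
  xs[300] <- xs[300] + 10 * 0.3   # 10-SD spike
  mask <- reject_motion_windows(xs)
  expect_true(mask[300])
  expect_lt(mean(mask), 0.1)      # rejection stays local
  expect_error(reject_motion_windows(rnorm(10), window_s = 10), "window longer")
})

test_that("masking never alters unmasked values through segmentation", {
  cfg <- generator_config(n_subjects = 2, seed = 14)
  coh <- simulate_cohort(cfg, channels = 1:2)
  su <- coh$subjects[[1]]
  hb <- su$hb
  hb$oxy <- lowpass_filter(hb$oxy)
  mask <- matrix(FALSE, nrow(hb$oxy), 2)
  mask[, 1] <- reject_motion_windows(hb$oxy[, 1])
  seg_m <- segment_blocks(hb, mask = mask)
  seg_0 <- segment_blocks(hb)
  merged <- merge(seg_m, seg_0,
                  by = c("channel", "block", "time"))
  # rows surviving the mask must carry identical values unless their
  # block baseline changed; channel 2 is unmasked so values match exactly
  ch2 <- merged[merged$channel == 2, ]
  expect_equal(ch2$y.x, ch2$y.y)
})

test_that("segmentation produces 120 baseline-referenced rows per block", {
  cfg <- generator_config(n_subjects = 2, seed = 15)
  coh <- simulate_cohort(cfg, channels = 1:3)
  hb <- coh$subjects[[1]]$hb
  seg <- segment_blocks(hb)
  expect_identical(nrow(seg), 12L * 3L * 120L)
  # each block contributes exactly 60 s at 2 Hz and 20 baseline samples
  cnt <- table(seg$block, seg$channel)
  expect_true(all(cnt == 120L))
  base_cnt <- tapply(seg$baseline, list(seg$block, seg$channel), sum)
  expect_true(all(base_cnt == 20L))
  # baseline mean is zero by construction, per block and channel
  bmeans <- tapply(seg$y[seg$baseline],
                   list(seg$block[seg$baseline], seg$channel[seg$baseline]),
                   mean)
  expect_true(all(abs(bmeans) < 1e-12))
  # effect codes alternate -1 / +1 starting +1 (MM first)
  first_block <- seg[seg$block == 1, ]
  expect_true(all(first_block$code == 1))
  codes <- tapply(seg$code, seg$block, unique)
  expect_identical(as.numeric(codes), rep(c(1, -1), 6))
})

test_that("segmentation validates markers against the series", {
  cfg <- generator_config(n_subjects = 2, seed = 16)
  hb <- simulate_cohort(cfg, channels = 1)$subjects[[1]]$hb
  bad <- hb
  bad$markers$onset <- bad$markers$onset + 500  # pushes blocks off the end
  expect_error(stol_raw("x", matrix(1, 100, 1), matrix(1, 100, 1),
                        markers = data.frame(onset = 40, duration = 20,
                                             label = "block_MM")),
               "beyond the recording span")
  expect_error(segment_blocks(bad), "beyond the series|alternate")
  short <- hb
  short$markers$duration[1] <- 5  # shorter than the 10-s baseline
  expect_error(segment_blocks(short), "shorter than the baseline")
  swapped <- hb
  swapped$markers$label <- sub("block_MM", "block_XX", swapped$markers$label)
  swapped$markers$label <- sub("block_ZM", "block_MM", swapped$markers$label)
  expect_error(segment_blocks(swapped), "alternate")
})

test_that("the preprocessing pipeline is deterministic", {
  cfg <- generator_config(n_subjects = 2, seed = 17)
  coh <- simulate_cohort(cfg, channels = 1:2)
  s1 <- preprocess_cohort(coh)
  s2 <- preprocess_cohort(coh)
  expect_identical(s1$y, s2$y)
  expect_identical(dim(s1), dim(s2))
})

test_that("raw and segmented TSV round-trips preserve the data", {
  cfg <- generator_config(n_subjects = 2, seed = 18)
  coh <- simulate_cohort(cfg, output = "raw", channels = 1:16)
  raw <- coh$subjects[[1]]$raw
  f <- withr::local_tempfile(fileext = ".tsv")
  write_raw(raw, f)
  raw2 <- read_raw(f, subject = raw$subject, markers = raw$markers)
  expect_equal(raw2$i730, raw$i730, ignore_attr = TRUE, tolerance = 1e-6)
  seg <- segment_blocks(intensities_to_hb(raw), channels = 1:2)
  g <- withr::local_tempfile(fileext = ".tsv")
  write_segmented(seg, g)
  seg2 <- read_segmented(g)
  expect_equal(seg2$y, seg$y, tolerance = 1e-9)
  expect_equal(seg2$code, seg$code, ignore_attr = TRUE)
})
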