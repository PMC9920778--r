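# STFT preprocessing: framing, transform vs naive DFT, magnitudes,
# harmonic bin removal, spectrogram assembly.

test_that("framing covers 2112 samples with 32 half-overlapping frames", {
  fr <- segment_frames(1:2112)
  expect_identical(dim(fr), c(128L, 32L))
  expect_identical(fr[, 1], as.numeric(1:128))
  expect_identical(fr[, 32], as.numeric(1985:2112))  # ends on the last sample
  expect_identical(fr[65:128, 1], fr[1:64, 2])        # 50% overlap
  expect_error(segment_frames(1:2000), "not hop")
})

test_that("windowed transform matches the naive DFT oracle", {
  cfg <- stft_config()
  # impulse through a rectangular window: flat unit magnitude
  rect <- stft_config(window = rep(1, 128))
  z <- stft_frame(c(1, rep(0, 127)), rect)
  expect_equal(Mod(z), rep(1, 64), tolerance = 1e-12)
  # 62.5 Hz tone sits exactly on bin 8 and dominates bins 2..62
  tone <- cos(2 * pi * 62.5 * (0:127) / 1000)
  zt <- Mod(stft_frame(tone, cfg))
  expect_identical(which.max(zt[3:63]) + 2L, 9L)  # 0-based bin 8
  # random frames: exact agreement with the O(N^2) oracle
  set.seed(42)
  for (i in 1:5) {
    fr <- runif(128, 0, 1023)
    z <- stft_frame(fr, cfg)
    zo <- naive_dft(cfg$window * fr)[1:64]
    expect_lt(max(Mod(z - zo)) / max(Mod(zo)), 1e-9)
  }
  expect_error(stft_frame(1:64, cfg), "128")
})

test_that("windowed transform preserves energy (Parseval, full spectrum)", {
  set.seed(11)
  fr <- runif(128, 0, 1023)
  cfg <- stft_config()
  xw <- cfg$window * fr
  Xfull <- naive_dft(xw)
  expect_equal(sum(Mod(Xfull)^2), 128 * sum(xw^2), tolerance = 1e-6)
  # the 64 reported bins are the oracle's non-negative-frequency half
  expect_lt(max(Mod(stft_frame(fr, cfg) - Xfull[1:64])), 1e-6)
})

test_that("simplified magnitude obeys the L1/L2 relationship", {
  expect_equal(spectral_magnitude(3 + 4i, "simplified"), 7)
  expect_equal(spectral_magnitude(3 + 4i, "exact"), 5)
  expect_equal(spectral_magnitude(5 + 0i, "simplified"), 5)
  expect_equal(spectral_magnitude(5 + 0i, "exact"), 5)
  expect_equal(spectral_magnitude(1 + 1i, "simplified") /
                 spectral_magnitude(1 + 1i, "exact"), sqrt(2))
  set.seed(9)
  z <- complex(real = rnorm(500), imaginary = rnorm(500))
  ratio <- spectral_magnitude(z, "simplified") / spectral_magnitude(z, "exact")
  expect_true(all(ratio >= 1 - 1e-12 & ratio <= sqrt(2) + 1e-12))
})

test_that("default harmonic filter removes 32 bins in valid groups", {
  spec <- harmonic_filter_spec()
  sizes <- lengths(spec$removed_groups)
  expect_identical(unname(sizes), c(4L, 4L, 3L, 3L, 4L, 3L, 3L, 4L, 4L))
  expect_true(all(sizes >= 2 & sizes <= 6))
  expect_identical(sum(sizes), 32L)
  expect_length(spec$retained_bins, 32)
  expect_identical(spec$retained_bins,
                   c(4L, 5L, 10L, 11L, 12L, 13L, 17L, 18L, 19L, 20L, 21L,
                     25L, 26L, 27L, 28L, 33L, 34L, 35L, 36L, 40L, 41L, 42L,
                     43L, 44L, 48L, 49L, 50L, 51L, 56L, 57L, 58L, 59L))
  # selection semantics on an identity ramp
  expect_identical(apply_harmonic_filter(0:63, spec), spec$retained_bins)
  # each group contains the bin nearest its center (7.8125 Hz bin width)
  for (i in seq_along(spec$centers_hz)) {
    expect_true(round(spec$centers_hz[i] / 7.8125) %in% spec$removed_groups[[i]])
  }
})

test_that("invalid filter specifications are rejected", {
  g <- default_removed_groups()
  g$`60` <- 6:12                                  # 7 bins
  expect_error(harmonic_filter_spec(g), "2\\.\\.6")
  g <- default_removed_groups()
  g$`60` <- c(6L, 8L, 9L, 10L)                    # not adjacent
  expect_error(harmonic_filter_spec(g), "adjacent")
  g <- default_removed_groups()
  g$`60` <- 2:5                                   # misses bin 8
  expect_error(harmonic_filter_spec(g), "contain bin")
  g <- default_removed_groups()
  g$`0` <- 0:2                                    # total 31, not 32
  expect_error(harmonic_filter_spec(g), "32")
  expect_error(apply_harmonic_filter(0:31, harmonic_filter_spec()), "64")
})

test_that("spectrogram assembly composes the stages and is 32x32", {
  tr <- generate_trial(default_gesture_templates()[[6]], seed = 21L)
  s <- make_spectrogram(tr)
  expect_identical(dim(s), c(32L, 32L))
  expect_true(all(s >= 0))
  expect_identical(attr(s, "label"), 6L)
  # stage-by-stage composition with the naive DFT oracle
  cfg <- stft_config()
  fspec <- harmonic_filter_spec()
  frames <- segment_frames(tr$samples, cfg)
  ref <- sapply(seq_len(32), function(j) {
    z <- naive_dft(cfg$window * frames[, j])[1:64]
    (abs(Re(z)) + abs(Im(z)))[fspec$retained_bins + 1]
  })
  expect_equal(unclass(s), ref, tolerance = 1e-9, ignore_attr = TRUE)
  # magnitude-then-filter commutes with filter-then-magnitude
  z <- naive_dft(cfg$window * frames[, 1])[1:64]
  expect_equal(apply_harmonic_filter(spectral_magnitude(z), fspec),
               spectral_magnitude(apply_harmonic_filter(z, fspec)))
})

test_that("constant trials leave only window leakage in retained bins", {
  tr <- raw_trial(rep(512L, 2112), 1)
  s <- make_spectrogram(tr)
  dc_mag <- 512 * sum(hamming_window(128))
  # DC is removed; what remains is Hamming sidelobe leakage (< -43 dB)
  expect_lt(max(s), 1e-3 * dc_mag)
})

test_that("exact-magnitude and table-quantized modes stay consistent", {
  tr <- generate_trial(default_gesture_templates()[[1]], seed = 31L)
  s_l1 <- make_spectrogram(tr, stft_config(magnitude = "simplified"))
  s_l2 <- make_spectrogram(tr, stft_config(magnitude = "exact"))
  ratio <- (s_l1 / s_l2)[s_l2 > 1e-6]
  expect_true(all(ratio >= 1 - 1e-9 & ratio <= sqrt(2) + 1e-9))
  s_hw <- make_spectrogram(tr, stft_config(hw_emulation = TRUE))
  expect_identical(dim(s_hw), c(32L, 32L))
  expect_gt(cor(c(s_hw), c(s_l1)), 0.999)  # table quantization is mild
})
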