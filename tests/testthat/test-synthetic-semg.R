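# Synthetic sEMG generator: determinism, quantization, spectral content, IO.

test_that("trial generation is deterministic and respects the ADC contract", {
  cfg <- acquisition_config()
  tpl <- default_gesture_templates()
  t1 <- generate_trial(tpl[[4]], cfg, seed = 99L)
  t2 <- generate_trial(tpl[[4]], cfg, seed = 99L)
  expect_identical(t1$samples, t2$samples)
  expect_false(identical(t1$samples,
                         generate_trial(tpl[[4]], cfg, seed = 100L)$samples))
  for (g in c(1, 5, 9)) {
    tr <- generate_trial(tpl[[g]], cfg, seed = g)
    expect_length(tr$samples, 2112)
    expect_true(all(tr$samples >= 0 & tr$samples <= 1023))
    expect_identical(tr$label, as.integer(g))
  }
  # saturating clip: absurd gain still yields in-range codes
  loud <- acquisition_config(gain_codes = 5000)
  tr <- generate_trial(tpl[[2]], loud, seed = 7L)
  expect_true(all(tr$samples >= 0 & tr$samples <= 1023))
  expect_true(any(tr$samples == 0) || any(tr$samples == 1023))
})

test_that("hum-only trials concentrate energy at the configured harmonics", {
  # only the 60 Hz fundamental: periodogram peak must sit on 60 Hz
  cfg <- acquisition_config(
    hum_harmonic_amplitudes = c(10, 0, 0, 0, 0, 0, 0, 0))
  quiet <- gesture_template(1,
    data.frame(onset_s = numeric(0), duration_s = numeric(0),
               band_low_hz = numeric(0), band_high_hz = numeric(0),
               amplitude = numeric(0)),
    rest_noise_amplitude = 0)
  tr <- generate_trial(quiet, cfg, seed = 12L)
  x <- tr$samples[1:1000] - cfg$adc_midscale
  mag <- Mod(naive_dft(x))[1:501]      # bins 0..500 Hz at 1 Hz resolution
  expect_equal(which.max(mag) - 1L, 60L)
  # two harmonics: both stand far above any other bin
  cfg2 <- acquisition_config(
    hum_harmonic_amplitudes = c(10, 0, 8, 0, 0, 0, 0, 0))
  tr2 <- generate_trial(quiet, cfg2, seed = 12L)
  mag2 <- Mod(naive_dft(tr2$samples[1:1000] - cfg2$adc_midscale))[1:501]
  others <- mag2[-c(1, 61, 181)]
  expect_gt(mag2[61], 10 * max(others))
  expect_gt(mag2[181], 10 * max(others))
})

test_that("datasets are balanced, seed-derived and reproducible", {
  ds <- generate_dataset(2, master_seed = 5L)
  expect_length(ds, 18)
  labs <- vapply(ds, `[[`, integer(1), "label")
  expect_true(all(table(labs) == 2))
  # per-trial seeds follow the documented derivation
  expect_identical(ds[[1]]$seed, trial_seed(5L, 1L, 1L))
  expect_identical(ds[[4]]$seed, trial_seed(5L, 2L, 2L))
  ds2 <- generate_dataset(2, master_seed = 5L)
  expect_identical(lapply(ds, `[[`, "samples"), lapply(ds2, `[[`, "samples"))
  # a regenerated single trial matches its in-dataset copy
  solo <- generate_trial(default_gesture_templates()[[2]],
                         seed = trial_seed(5L, 2L, 2L))
  expect_identical(solo$samples, ds[[4]]$samples)
})

test_that("template and trial validation rejects bad configurations", {
  expect_error(gesture_template(0, data.frame(
    onset_s = 0.1, duration_s = 0.1, band_low_hz = 20, band_high_hz = 100,
    amplitude = 1)), "class_id")
  expect_error(gesture_template(1, data.frame(
    onset_s = 2.0, duration_s = 0.5, band_low_hz = 20, band_high_hz = 100,
    amplitude = 1)), "fit within")
  expect_error(gesture_template(1, data.frame(
    onset_s = 0.1, duration_s = 0.5, band_low_hz = 5, band_high_hz = 100,
    amplitude = 1)), "10 <= low")
  expect_error(raw_trial(rep(0L, 100), 1), "2112")
  expect_error(raw_trial(rep(2000L, 2112), 1), "codes")
})

test_that("trial text formats round-trip", {
  ds <- generate_dataset(1, master_seed = 8L)
  f1 <- tempfile(fileext = ".txt")
  write_trial(ds[[3]], f1)
  back <- read_trial(f1)
  expect_identical(back$samples, ds[[3]]$samples)
  expect_identical(back$label, ds[[3]]$label)
  expect_identical(back$seed, ds[[3]]$seed)
  f2 <- tempfile(fileext = ".tsv")
  write_trials(ds, f2)
  back2 <- read_trials(f2)
  expect_length(back2, 9)
  expect_identical(lapply(back2, `[[`, "samples"), lapply(ds, `[[`, "samples"))
  expect_identical(vapply(back2, `[[`, integer(1), "label"),
                   vapply(ds, `[[`, integer(1), "label"))
})
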