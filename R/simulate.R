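#' Acquisition configuration for synthetic sEMG trials
#'
#' Describes the acquisition front end being emulated: a single dry-electrode
#' surface-EMG channel sampled at 1000 Hz for 2.112 s and digitized by a
#' unipolar 10-bit ADC (codes 0..1023, midscale 512), with additive powerline
#' hum at 60 Hz and its harmonics up to 480 Hz.
#'
#' `hum_harmonic_amplitudes` are peak amplitudes in ADC code units, one per
#' harmonic (60, 120, ..., 480 Hz).  `gain_codes` converts the dimensionless
#' burst/rest amplitudes of a [gesture_template()] into ADC codes: an
#' amplitude of 1 produces band-limited activity with a standard deviation of
#' `gain_codes` codes.
#'
#' @param sample_rate_hz sampling rate in Hz.
#' @param duration_s trial duration in seconds.
#' @param adc_bits ADC resolution in bits.
#' @param adc_midscale ADC code of the zero-signal baseline.
#' @param hum_freq_hz powerline fundamental in Hz.
#' @param hum_harmonic_amplitudes peak hum amplitude per harmonic, ADC codes.
#' @param gain_codes codes per unit of template amplitude (RMS).
#' @param noise_band_hz two-element band, in Hz, of the background muscle
#'   noise floor (the sEMG band).
#' @param filter_order order of the Butterworth band-pass used to band-limit
#'   Gaussian noise.
#' @return an object of class `acquisition_config`.
#' @export
acquisition_config <- function(sample_rate_hz = 1000,
                               duration_s = 2.112,
                               adc_bits = 10,
                               adc_midscale = 512,
                               hum_freq_hz = 60,
                               hum_harmonic_amplitudes = c(10, 5, 3.5, 3, 2.5, 2, 1.5, 1.2),
                               gain_codes = 110,
                               noise_band_hz = c(10, 500),
                               filter_order = 4) {
  n_samples <- round(sample_rate_hz * duration_s)
  if (abs(sample_rate_hz * duration_s - n_samples) > 1e-9) {
    stop_config("sample_rate_hz * duration_s must be an integer sample count")
  }
  if (adc_bits < 1) stop_config("adc_bits must be >= 1")
  if (adc_midscale < 0 || adc_midscale > 2^adc_bits - 1) {
    stop_config("adc_midscale outside the ADC code range")
  }
  if (length(noise_band_hz) != 2 || noise_band_hz[1] >= noise_band_hz[2]) {
    stop_config("noise_band_hz must be an increasing pair")
  }
  structure(list(
    sample_rate_hz = sample_rate_hz,
    duration_s = duration_s,
    n_samples = as.integer(n_samples),
    adc_bits = as.integer(adc_bits),
    adc_midscale = as.integer(adc_midscale),
    hum_freq_hz = hum_freq_hz,
    hum_harmonic_amplitudes = hum_harmonic_amplitudes,
    gain_codes = gain_codes,
    noise_band_hz = noise_band_hz,
    filter_order = as.integer(filter_order)
  ), class = "acquisition_config")
}

#' Gesture template for the synthetic generator
#'
#' A dynamic gesture is modelled as a rest--motion--rest process: a low-level
#' background muscle noise floor plus one or more activity bursts.  Each burst
#' is band-limited Gaussian noise (the stochastic character of interference
#' sEMG) shaped by a Hann envelope over `[onset_s, onset_s + duration_s]`.
#' Bursts differ across gestures in onset, duration and frequency-band
#' emphasis, which is what the downstream time-frequency classifier keys on.
#'
#' @param class_id gesture class label, integer 1..9.
#' @param bursts data.frame with columns `onset_s`, `duration_s`,
#'   `band_low_hz`, `band_high_hz`, `amplitude`.
#' @param rest_noise_amplitude relative amplitude of the always-on background
#'   activity (1 = `gain_codes` ADC codes RMS).
#' @param trial_duration_s trial length used to validate burst placement.
#' @return an object of class `gesture_template`.
#' @export
gesture_template <- function(class_id, bursts,
                             rest_noise_amplitude = 0.05,
                             trial_duration_s = 2.112) {
  if (!(is.numeric(class_id) && length(class_id) == 1 &&
        class_id == round(class_id) && class_id >= 1 && class_id <= 9)) {
    stop_config("class_id must be an integer in 1..9")
  }
  bursts <- as.data.frame(bursts)
  needed <- c("onset_s", "duration_s", "band_low_hz", "band_high_hz", "amplitude")
  if (!all(needed %in% names(bursts))) {
    stop_config("bursts must have columns %s", paste(needed, collapse = ", "))
  }
  if (nrow(bursts) > 0) {
    if (any(bursts$onset_s < 0) ||
        any(bursts$onset_s + bursts$duration_s > trial_duration_s + 1e-9)) {
      stop_config("every burst must fit within [0, %.3f] s", trial_duration_s)
    }
    if (any(bursts$band_low_hz < 10) || any(bursts$band_high_hz > 500) ||
        any(bursts$band_low_hz >= bursts$band_high_hz)) {
      stop_config("burst bands must satisfy 10 <= low < high <= 500 Hz")
    }
    if (any(bursts$amplitude < 0)) stop_config("burst amplitudes must be >= 0")
  }
  structure(list(
    class_id = as.integer(class_id),
    bursts = bursts,
    rest_noise_amplitude = rest_noise_amplitude
  ), class = "gesture_template")
}

#' Default nine-gesture template set
#'
#' Nine templates that differ in the number of bursts (one or two), burst
#' onset/duration, and frequency-band emphasis within the 10--500 Hz sEMG
#' band, so that classes are learnable from the 32x32 spectrogram but not
#' trivially separable by a single feature.  These defaults define the study
#' conditions of the synthetic benchmark; they make no claim of matching any
#' particular subject's recordings.
#'
#' @return a list of nine [gesture_template()] objects, indexed by class.
#' @export
default_gesture_templates <- function() {
  b <- function(onset, dur, lo, hi, amp = 1) {
    data.frame(onset_s = onset, duration_s = dur,
               band_low_hz = lo, band_high_hz = hi, amplitude = amp)
  }
  lapply(1:9, function(g) {
    bursts <- switch(g,
      rbind(b(0.30, 0.45, 20, 120), b(1.20, 0.45, 20, 120)),      # double low-band
      b(0.40, 1.20, 20, 120),                                      # long low-band
      rbind(b(0.30, 0.45, 120, 250), b(1.20, 0.45, 120, 250)),    # double mid-band
      b(0.40, 1.20, 120, 250),                                     # long mid-band
      rbind(b(0.30, 0.45, 250, 450), b(1.20, 0.45, 250, 450)),    # double high-band
      b(0.40, 1.20, 250, 450),                                     # long high-band
      b(0.20, 0.60, 20, 450),                                      # broadband early
      b(1.25, 0.60, 20, 450),                                      # broadband late
      rbind(b(0.25, 0.50, 20, 120), b(1.30, 0.50, 250, 450))      # low then high
    )
    gesture_template(g, bursts)
  })
}

# Unit-variance Gaussian noise band-limited with a zero-phase Butterworth
# band-pass.  Band edges are clamped just inside (0, Nyquist).
band_limited_noise <- function(n, fs, band, order) {
  nyq <- fs / 2
  lo <- max(band[1], 1e-3 * nyq) / nyq
  hi <- min(band[2], 0.999 * nyq) / nyq
  bf <- signal::butter(order, c(lo, hi), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  s <- sd(x)
  if (s > 0) x / s else x
}

# Hann envelope on [onset, onset + dur], zero elsewhere.
burst_envelope <- function(t, onset, dur) {
  u <- (t - onset) / dur
  e <- numeric(length(t))
  inside <- u >= 0 & u <= 1
  e[inside] <- 0.5 * (1 - cos(2 * pi * u[inside]))
  e
}

#' Construct a raw sEMG trial
#'
#' @param samples integer ADC codes, length `n_samples`.
#' @param label gesture class, integer 1..9.
#' @param seed the RNG seed the trial was generated with (or `NA`).
#' @param config the [acquisition_config()] the samples conform to.
#' @return an object of class `raw_trial`.
#' @export
raw_trial <- function(samples, label, seed = NA_integer_,
                      config = acquisition_config()) {
  samples <- as.integer(samples)
  if (length(samples) != config$n_samples) {
    stop_config("trial must have exactly %d samples", config$n_samples)
  }
  cmax <- 2^config$adc_bits - 1
  if (anyNA(samples) || any(samples < 0) || any(samples > cmax)) {
    stop_config("ADC codes must lie in [0, %d]", cmax)
  }
  if (!(label %in% 1:9)) stop_config("label must be an integer in 1..9")
  structure(list(samples = samples, label = as.integer(label),
                 seed = as.integer(seed)),
            class = "raw_trial")
}

#' Generate one synthetic sEMG trial
#'
#' Builds the continuous-domain signal as background band-limited noise plus
#' Hann-enveloped band-limited bursts plus powerline hum (60 Hz and
#' harmonics, random phase per trial), then models the ADC: offset to
#' midscale, saturating clip, round to integer codes.  Deterministic for a
#' given `(template, config, seed)`.
#'
#' @param template a [gesture_template()].
#' @param config an [acquisition_config()].
#' @param seed integer RNG seed for this trial.
#' @return a [raw_trial()].
#' @export
generate_trial <- function(template, config = acquisition_config(), seed) {
  if (!inherits(template, "gesture_template")) {
    stop_config("template must be a gesture_template")
  }
  if (!inherits(config, "acquisition_config")) {
    stop_config("config must be an acquisition_config")
  }
  n <- config$n_samples
  fs <- config$sample_rate_hz
  t <- (seq_len(n) - 1) / fs
  if (nrow(template$bursts) > 0 &&
      any(template$bursts$onset_s + template$bursts$duration_s >
          config$duration_s + 1e-9)) {
    stop_config("burst extends beyond the %.3f s trial", config$duration_s)
  }
  x <- with_seed(seed, {
    sig <- config$gain_codes * template$rest_noise_amplitude *
      band_limited_noise(n, fs, config$noise_band_hz, config$filter_order)
    bs <- template$bursts
    for (i in seq_len(nrow(bs))) {
      env <- burst_envelope(t, bs$onset_s[i], bs$duration_s[i])
      sig <- sig + config$gain_codes * bs$amplitude[i] * env *
        band_limited_noise(n, fs, c(bs$band_low_hz[i], bs$band_high_hz[i]),
                           config$filter_order)
    }
    amps <- config$hum_harmonic_amplitudes
    for (h in seq_along(amps)) {
      f <- h * config$hum_freq_hz
      phi <- runif(1, 0, 2 * pi)
      sig <- sig + amps[h] * sin(2 * pi * f * t + phi)
    }
    sig
  })
  cmax <- 2^config$adc_bits - 1
  codes <- pmin(pmax(round(x + config$adc_midscale), 0), cmax)
  raw_trial(codes, template$class_id, seed, config)
}

#' Generate a balanced labeled dataset of synthetic trials
#'
#' Produces `9 * n_per_class` trials, `n_per_class` for each gesture class,
#' with per-trial seeds derived from `master_seed` via [trial_seed()], so
#' the dataset is reproducible as a whole and trial by trial.
#'
#' @param n_per_class trials per gesture class (>= 1).
#' @param config an [acquisition_config()].
#' @param master_seed integer master seed.
#' @param templates list of nine gesture templates, default
#'   [default_gesture_templates()].
#' @return a list of [raw_trial()] objects, class-blocked
#'   (class 1 replicates first), with class `semg_trials`.
#' @export
generate_dataset <- function(n_per_class, config = acquisition_config(),
                             master_seed = 1L,
                             templates = default_gesture_templates()) {
  if (n_per_class < 1) stop_config("n_per_class must be >= 1")
  if (length(templates) != 9) stop_config("need nine gesture templates")
  trials <- vector("list", 9 * n_per_class)
  idx <- 1
  for (g in 1:9) {
    for (r in seq_len(n_per_class)) {
      trials[[idx]] <- generate_trial(templates[[g]], config,
                                      trial_seed(master_seed, g, r))
      idx <- idx + 1
    }
  }
  structure(trials, class = "semg_trials")
}

#' @export
print.raw_trial <- function(x, ...) {
  cat(sprintf("<raw_trial> label=%d seed=%d n=%d codes in [%d, %d]\n",
              x$label, x$seed, length(x$samples),
              min(x$samples), max(x$samples)))
  invisible(x)
}

#' @export
print.semg_trials <- function(x, ...) {
  labs <- vapply(x, function(tr) tr$label, integer(1))
  cat(sprintf("<semg_trials> %d trials, classes: %s\n", length(x),
              paste(sprintf("%d x %d", sort(unique(labs)),
                            as.integer(table(labs))), collapse = ", ")))
  invisible(x)
}
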