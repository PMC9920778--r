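#' Symmetric Hamming window
#'
#' `w[k] = 0.54 - 0.46 cos(2 pi k / (n - 1))`, `k = 0..n-1`.
#'
#' @param n window length (default 128).
#' @return numeric vector of `n` coefficients in `[0, 1]`.
#' @export
hamming_window <- function(n = 128) {
  k <- seq_len(n) - 1
  0.54 - 0.46 * cos(2 * pi * k / (n - 1))
}

#' STFT configuration
#'
#' A 128-point FFT with a Hamming window and 50% overlap (hop 64) turns a
#' 2112-sample trial into exactly 32 frames: `(2112 - 128) / 64 + 1 = 32`.
#' `magnitude` selects between the exact complex modulus and the
#' hardware-friendly L1 magnitude `|Re| + |Im|` (the default, matching the
#' implemented datapath).  `hw_emulation` replaces the float window and
#' twiddle factors by quantized lookup tables (8-bit window, 10-bit
#' twiddles), emulating table quantization only, not fixed-point butterfly
#' arithmetic.
#'
#' @param n_fft FFT length (128).
#' @param hop frame hop in samples; must equal `n_fft / 2`.
#' @param window window coefficients, length `n_fft`.
#' @param magnitude `"simplified"` (L1) or `"exact"` (modulus).
#' @param hw_emulation use quantized window/twiddle tables.
#' @param sample_rate_hz sampling rate, for the frequency axis.
#' @return an object of class `stft_config`.
#' @export
stft_config <- function(n_fft = 128, hop = n_fft / 2,
                        window = hamming_window(n_fft),
                        magnitude = c("simplified", "exact"),
                        hw_emulation = FALSE,
                        sample_rate_hz = 1000) {
  magnitude <- match.arg(magnitude)
  if (hop != n_fft / 2) stop_config("hop must be n_fft / 2 (50%% overlap)")
  if (length(window) != n_fft) stop_config("window must have n_fft coefficients")
  if (any(window < 0) || any(window > 1)) {
    stop_config("window coefficients must lie in [0, 1]")
  }
  structure(list(
    n_fft = as.integer(n_fft),
    hop = as.integer(hop),
    window = window,
    window_q8 = as.integer(round(window * 255)),
    magnitude = magnitude,
    hw_emulation = isTRUE(hw_emulation),
    sample_rate_hz = sample_rate_hz
  ), class = "stft_config")
}

#' Split a trial into 50%-overlapping frames
#'
#' Frame `i` (0-based) covers samples `[hop*i, hop*i + n_fft)`; for the
#' default geometry, 2112 samples yield 32 frames of 128 and frame 31 ends on
#' the final sample.
#'
#' @param samples numeric or integer vector whose length must be
#'   `hop * (n_frames - 1) + n_fft` for an integer `n_frames`.
#' @param config an [stft_config()].
#' @return `n_fft x n_frames` matrix, one frame per column.
#' @export
segment_frames <- function(samples, config = stft_config()) {
  n <- length(samples)
  n_frames <- (n - config$n_fft) / config$hop + 1
  if (n_frames != round(n_frames) || n_frames < 1) {
    stop_config("length %d is not hop*(m-1) + n_fft for integer m", n)
  }
  idx <- outer(seq_len(config$n_fft), (seq_len(n_frames) - 1) * config$hop, "+")
  matrix(as.numeric(samples)[idx], nrow = config$n_fft)
}

# Quantized-table DFT used by hw_emulation mode: 8-bit window, 10-bit
# twiddles, rescaled back to the float magnitude range.
hw_dft64 <- function(frame, config) {
  n <- config$n_fft
  xq <- config$window_q8 * frame
  k <- 0:(n / 2 - 1)
  ang <- -2 * pi * outer(k, 0:(n - 1)) / n
  cq <- round(cos(ang) * 511)
  sq <- round(sin(ang) * 511)
  (cq %*% xq + 1i * (sq %*% xq)) / (511 * 255)
}

#' Windowed 128-point transform of one frame
#'
#' Multiplies the frame by the configured window and returns the 64
#' non-negative-frequency bins (DC through one below Nyquist) of its
#' 128-point discrete Fourier transform; the input being real, the upper 64
#' bins are the conjugate mirror and carry no extra information.
#'
#' @param frame numeric vector of length `n_fft`.
#' @param config an [stft_config()].
#' @return complex vector of length `n_fft / 2` (bins 0..63).
#' @export
stft_frame <- function(frame, config = stft_config()) {
  if (length(frame) != config$n_fft) {
    stop_config("frame must have %d samples", config$n_fft)
  }
  if (config$hw_emulation) {
    return(as.complex(hw_dft64(frame, config)))
  }
  x <- fft(config$window * frame)
  x[seq_len(config$n_fft / 2)]
}

#' Spectral magnitude, exact or hardware-simplified
#'
#' The exact mode is the complex modulus `sqrt(Re^2 + Im^2)`; the simplified
#' mode is the L1 magnitude `|Re| + |Im|`, which avoids squaring and square
#' roots.  For any nonzero input the simplified value over-estimates the
#' exact one by a factor in `[1, sqrt(2)]`.
#'
#' @param z complex vector.
#' @param mode `"simplified"` or `"exact"`.
#' @return non-negative numeric vector.
#' @export
spectral_magnitude <- function(z, mode = c("simplified", "exact")) {
  mode <- match.arg(mode)
  if (mode == "simplified") abs(Re(z)) + abs(Im(z)) else Mod(z)
}

#' Default hum-harmonic removal table
#'
#' One group of adjacent bins per center (DC and multiples of 60 Hz up to
#' 480 Hz); bin width is 1000/128 = 7.8125 Hz and each group contains the
#' bin nearest its center.  Group sizes are 4,4,3,3,4,3,3,4,4 -- 32 bins in
#' total, leaving 32 of 64.
#'
#' @return named list of 0-based bin index vectors, named by center Hz.
#' @export
default_removed_groups <- function() {
  list(`0` = 0:3, `60` = 6:9, `120` = 14:16, `180` = 22:24,
       `240` = 29:32, `300` = 37:39, `360` = 45:47, `420` = 52:55,
       `480` = 60:63)
}

#' Hum-harmonic bin-removal specification
#'
#' Powerline hum contaminates the spectrogram at DC and at every multiple of
#' 60 Hz up to 480 Hz.  The filter removes a group of 2--6 adjacent bins
#' around each of those nine centers -- 32 bins in total -- leaving 32 of the
#' 64 non-negative-frequency bins, which fixes the spectrogram height at 32.
#' Each group must contain the bin nearest its center (bin width
#' `sample_rate / n_fft` = 7.8125 Hz for the default geometry).
#'
#' @param removed_groups named list, one integer vector of adjacent 0-based
#'   bin indices per center; names are the center frequencies in Hz.
#' @param n_bins number of non-negative-frequency bins (64).
#' @param sample_rate_hz,n_fft geometry used to locate each center's bin.
#' @return an object of class `harmonic_filter_spec` with elements
#'   `removed_bins`, `retained_bins` (both 0-based, ascending) and
#'   `centers_hz`.
#' @export
harmonic_filter_spec <- function(removed_groups = default_removed_groups(),
                                 n_bins = 64, sample_rate_hz = 1000,
                                 n_fft = 128) {
  centers <- as.numeric(names(removed_groups))
  if (anyNA(centers)) stop_config("removed_groups must be named by center Hz")
  bin_width <- sample_rate_hz / n_fft
  for (i in seq_along(removed_groups)) {
    g <- sort(as.integer(removed_groups[[i]]))
    if (length(g) < 2 || length(g) > 6) {
      stop_config("group at %g Hz has %d bins; must be 2..6", centers[i], length(g))
    }
    if (any(diff(g) != 1)) {
      stop_config("group at %g Hz is not a run of adjacent bins", centers[i])
    }
    nearest <- round(centers[i] / bin_width)
    if (!(nearest %in% g)) {
      stop_config("group at %g Hz must contain bin %d", centers[i], nearest)
    }
    removed_groups[[i]] <- g
  }
  removed <- sort(unlist(removed_groups, use.names = FALSE))
  if (anyDuplicated(removed)) stop_config("removal groups overlap")
  if (any(removed < 0) || any(removed >= n_bins)) {
    stop_config("removed bins must lie in [0, %d]", n_bins - 1)
  }
  if (length(removed) != 32) {
    stop_config("exactly 32 bins must be removed (got %d)", length(removed))
  }
  structure(list(
    removed_groups = removed_groups,
    removed_bins = removed,
    retained_bins = setdiff(0:(n_bins - 1), removed),
    centers_hz = centers,
    n_bins = as.integer(n_bins)
  ), class = "harmonic_filter_spec")
}

#' Select the retained bins of a 64-bin spectrum
#'
#' Pure selection in ascending bin order; no rescaling.
#'
#' @param spectrum vector of length `n_bins` (64), magnitudes or complex.
#' @param spec a [harmonic_filter_spec()].
#' @return the 32 retained values.
#' @export
apply_harmonic_filter <- function(spectrum, spec = harmonic_filter_spec()) {
  if (length(spectrum) != spec$n_bins) {
    stop_config("spectrum must have %d bins", spec$n_bins)
  }
  spectrum[spec$retained_bins + 1L]
}

#' Compute the 32x32 filtered magnitude spectrogram of a trial
#'
#' The classifier input: frames (50% overlap) -> windowed 128-point
#' transform -> magnitude (simplified by default) -> hum-harmonic bin
#' removal.  Rows are the 32 retained frequency bins in ascending bin order;
#' columns are the 32 frames in time order.
#'
#' @param trial a [raw_trial()] or a numeric vector of 2112 samples.
#' @param config an [stft_config()].
#' @param spec a [harmonic_filter_spec()].
#' @return a 32x32 matrix of class `spectrogram32` with attributes
#'   `retained_bins` (0-based), `freq_hz` and `label` (if the input carried
#'   one).
#' @export
make_spectrogram <- function(trial, config = stft_config(),
                             spec = harmonic_filter_spec()) {
  label <- NA_integer_
  if (inherits(trial, "raw_trial")) {
    label <- trial$label
    samples <- trial$samples
  } else {
    samples <- trial
  }
  frames <- segment_frames(samples, config)
  out <- matrix(0, nrow = length(spec$retained_bins), ncol = ncol(frames))
  for (j in seq_len(ncol(frames))) {
    z <- stft_frame(frames[, j], config)
    mag <- spectral_magnitude(z, config$magnitude)
    out[, j] <- apply_harmonic_filter(mag, spec)
  }
  structure(out,
            retained_bins = spec$retained_bins,
            freq_hz = spec$retained_bins * config$sample_rate_hz / config$n_fft,
            label = label,
            class = c("spectrogram32", "matrix", "array"))
}

#' Spectrograms for a whole trial set
#'
#' @param trials a `semg_trials` list (see [generate_dataset()]).
#' @param config an [stft_config()].
#' @param spec a [harmonic_filter_spec()].
#' @return list with `x`, a `32 x 32 x N` array (frequency x time x trial),
#'   and `labels`, an integer vector of length `N`.
#' @export
spectrogram_dataset <- function(trials, config = stft_config(),
                                spec = harmonic_filter_spec()) {
  n <- length(trials)
  nb <- length(spec$retained_bins)
  x <- array(0, dim = c(nb, (length(trials[[1]]$samples) - config$n_fft) /
                              config$hop + 1, n))
  labels <- integer(n)
  for (i in seq_len(n)) {
    s <- make_spectrogram(trials[[i]], config, spec)
    x[, , i] <- s
    labels[i] <- attr(s, "label")
  }
  list(x = x, labels = labels)
}
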