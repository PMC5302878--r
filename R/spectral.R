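#' Coherently sum aligned strike windows
#'
#' Pointwise sum with no normalisation: for time-aligned near-identical
#' transients the signal amplitude grows with the number of strikes while
#' uncorrelated noise grows only as its square root, so summation raises the
#' spectral SNR before the FFT.
#'
#' @param windows Strike-window tibble (ideally from [align_windows()]), or a
#'   plain list of equal-length numeric vectors.
#' @return Numeric vector: the composite waveform.
#' @export
#' @examples
#' sum_windows(list(c(1, 2), c(3, 4)))
sum_windows <- function(windows) {
  vecs <- if (is.data.frame(windows)) windows$samples else windows
  if (length(vecs) == 0L) {
    abort("Need at least one window to sum.", class = "stemsound_empty_error")
  }
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1L) {
    abort("All windows must have identical length.", class = "stemsound_structure_error")
  }
  Reduce(`+`, vecs)
}

#' FFT magnitude spectrum in dB
#'
#' Computes the discrete Fourier transform of the (rectangular- or
#' Hann-windowed) samples, zero-padded to the next power of two at least
#' `pad` times the input length, and returns one-sided magnitudes in dB
#' relative to full-scale amplitude 1.0 (a unit-amplitude sine at a bin
#' frequency reads 0 dB). With the default `pad = 4` at 40 kHz the bin
#' spacing is at most 40 Hz, enough to resolve peaks "near 7 kHz" from
#' those "near 4 kHz". Only dB differences are used downstream, so the
#' reference cancels out of every statistic.
#'
#' Magnitudes are floored at `db_floor` (all-zero input yields a flat
#' spectrum at the floor rather than -Inf).
#'
#' @param samples Numeric waveform (>= 64 samples, all finite).
#' @param rate Sampling rate (Hz).
#' @param pad Zero-padding factor before rounding up to a power of two;
#'   `pad = 0` disables padding (FFT length = input length).
#' @param window `"rectangular"` (default: the transient decays naturally
#'   inside the window, and a taper would attenuate the energetic early
#'   samples) or `"hann"`.
#' @param db_floor Lower clamp for the dB magnitudes.
#' @return A tibble of class `impact_spectrum` with columns `frequency_hz`
#'   (0 to Nyquist, strictly increasing) and `magnitude_db`, plus attributes
#'   `rate` and `nfft`.
#' @export
#' @examples
#' x <- sin(2 * pi * 1000 * (0:999) / 40000)
#' spec <- compute_spectrum(x, 40000)
#' spec[which.max(spec$magnitude_db), ]
compute_spectrum <- function(samples, rate, pad = 4,
                             window = c("rectangular", "hann"),
                             db_floor = -300) {
  window <- match.arg(window)
  n <- length(samples)
  if (n < 64) abort("Need at least 64 samples.", class = "stemsound_data_error")
  if (!all(is.finite(samples))) {
    abort("Samples must all be finite.", class = "stemsound_data_error")
  }
  x <- samples
  if (window == "hann") {
    x <- x * 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  }
  nfft <- if (pad > 0) 2^ceiling(log2(pad * n)) else n
  if (nfft > n) x <- c(x, rep(0, nfft - n))
  mag <- Mod(fft(x))[seq_len(nfft %/% 2 + 1L)] * 2 / n
  db <- 20 * log10(pmax(mag, 10^(db_floor / 20)))
  out <- tibble(
    frequency_hz = (seq_len(nfft %/% 2 + 1L) - 1) * rate / nfft,
    magnitude_db = db
  )
  class(out) <- c("impact_spectrum", class(out))
  attr(out, "rate") <- rate
  attr(out, "nfft") <- nfft
  out
}

check_band <- function(spectrum, low, high) {
  nyq <- max(spectrum$frequency_hz)
  if (!(low >= 0 && low < high)) {
    abort("Band must satisfy 0 <= low < high.", class = "stemsound_config_error")
  }
  if (high > nyq + 1e-9) {
    abort(sprintf("Band [%g, %g] Hz exceeds Nyquist (%g Hz).", low, high, nyq),
          class = "stemsound_config_error")
  }
  idx <- which(spectrum$frequency_hz >= low & spectrum$frequency_hz <= high)
  if (length(idx) == 0L) {
    abort("Band contains no spectrum bins.", class = "stemsound_config_error")
  }
  idx
}

#' Peak of a frequency band
#'
#' Returns the bin of maximum magnitude within `[low, high]`; ties break
#' toward the lower frequency.
#'
#' @param spectrum An `impact_spectrum` from [compute_spectrum()] (any tibble
#'   with `frequency_hz` and `magnitude_db` columns works).
#' @param low,high Band edges (Hz), `0 <= low < high <= ` Nyquist.
#' @param label Band label carried into the result.
#' @return One-row tibble: `band`, `band_low_hz`, `band_high_hz`,
#'   `peak_frequency_hz`, `peak_db`.
#' @export
band_peak <- function(spectrum, low, high, label = sprintf("%g-%g Hz", low, high)) {
  idx <- check_band(spectrum, low, high)
  best <- idx[which.max(spectrum$magnitude_db[idx])]
  tibble(
    band = label,
    band_low_hz = low,
    band_high_hz = high,
    peak_frequency_hz = spectrum$frequency_hz[best],
    peak_db = spectrum$magnitude_db[best]
  )
}

#' The band-peak difference statistic (delta dB)
#'
#' The statistic at the heart of the acoustic pattern assessment: the peak
#' level (dB) in the primary band around the hammer's ~7 kHz resonance minus
#' the peak level in the secondary band around ~4 kHz. Positive values mean
#' the hammer band dominates — the signature of a well-seated stem. Default
#' bands are 6–8 kHz and 3–5 kHz (the two reported frequencies, ±1 kHz).
#'
#' Because both terms are dB levels of the same spectrum, the statistic is
#' invariant to global amplitude scaling of the input.
#'
#' @param spectrum An `impact_spectrum`.
#' @param primary_band,secondary_band Length-2 numeric vectors `c(low, high)`
#'   in Hz; must be disjoint.
#' @return One-row tibble: `delta_db`, `primary_peak_hz`, `primary_peak_db`,
#'   `secondary_peak_hz`, `secondary_peak_db`.
#' @export
#' @examples
#' x <- sin(2 * pi * 7000 * (0:999) / 40000) + 0.1 * sin(2 * pi * 4000 * (0:999) / 40000)
#' delta_db(compute_spectrum(x, 40000))
delta_db <- function(spectrum, primary_band = c(6000, 8000),
                     secondary_band = c(3000, 5000)) {
  if (max(min(primary_band), min(secondary_band)) <
      min(max(primary_band), max(secondary_band))) {
    abort("Primary and secondary bands must be disjoint.",
          class = "stemsound_config_error")
  }
  p <- band_peak(spectrum, primary_band[1], primary_band[2], "primary")
  s <- band_peak(spectrum, secondary_band[1], secondary_band[2], "secondary")
  tibble(
    delta_db = p$peak_db - s$peak_db,
    primary_peak_hz = p$peak_frequency_hz,
    primary_peak_db = p$peak_db,
    secondary_peak_hz = s$peak_frequency_hz,
    secondary_peak_db = s$peak_db
  )
}

#' Identify the natural oscillation frequency from a tap spectrum
#'
#' Bench modal testing: strike the instrument once and read off the dominant
#' spectral peak. The peak must stand at least `min_prominence` dB above the
#' spectrum's median level (the noise floor) to count.
#'
#' @param spectrum An `impact_spectrum`.
#' @param min_prominence Required prominence above the median level (dB).
#' @return Peak frequency in Hz, or `NA_real_` when no sufficiently prominent
#'   peak exists.
#' @export
identify_natural_frequency <- function(spectrum, min_prominence = 10) {
  floor_ <- median(spectrum$magnitude_db)
  best <- which.max(spectrum$magnitude_db)
  if (spectrum$magnitude_db[best] >= floor_ + min_prominence) {
    spectrum$frequency_hz[best]
  } else {
    NA_real_
  }
}

#' Measure an instrument's natural frequency from a tap recording
#'
#' Full bench modal-test analysis: detects the tap transient, computes the
#' spectrum of its window and reads off the prominent peak. Restricting the
#' FFT to the detected transient (rather than the whole recording) keeps
#' background noise from biasing the peak location.
#'
#' @param rec A tap [recording()], e.g. from [simulate_modal_test()].
#' @param min_prominence Passed to [identify_natural_frequency()].
#' @param window_length Analysis window (s), see [detect_strikes()].
#' @return Peak frequency (Hz), or `NA_real_` when no transient or no
#'   prominent peak is found.
#' @export
#' @examples
#' tap <- simulate_modal_test(modal_components()[1, ], seed = 1)
#' measure_natural_frequency(tap)
measure_natural_frequency <- function(rec, min_prominence = 10,
                                      window_length = 0.025) {
  det <- detect_strikes(rec, window_length = window_length)
  if (nrow(det) == 0L) return(NA_real_)
  spec <- compute_spectrum(det$samples[[1]], rec$rate)
  identify_natural_frequency(spec, min_prominence = min_prominence)
}

#' Write a spectrum to CSV
#'
#' Two columns, `frequency_hz` and `magnitude_db`.
#'
#' @param spectrum An `impact_spectrum`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  readr::write_csv(as_tibble(spectrum)[, c("frequency_hz", "magnitude_db")], path)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.impact_spectrum <- function(object, primary_band = c(6000, 8000),
                                     secondary_band = c(3000, 5000), ...) {
  bands <- tibble(
    band = c("primary (~7 kHz)", "secondary (~4 kHz)"),
    low = c(primary_band[1], secondary_band[1]),
    high = c(primary_band[2], secondary_band[2])
  )
  ggplot2::ggplot(object) +
    ggplot2::geom_rect(
      data = bands,
      ggplot2::aes(xmin = .data$low, xmax = .data$high,
                   ymin = -Inf, ymax = Inf, fill = .data$band),
      alpha = 0.15, inherit.aes = FALSE
    ) +
    ggplot2::geom_line(ggplot2::aes(x = .data$frequency_hz, y = .data$magnitude_db),
                       linewidth = 0.3) +
    ggplot2::labs(x = "Frequency [Hz]", y = "Magnitude [dB re full scale]",
                  fill = NULL)
}
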