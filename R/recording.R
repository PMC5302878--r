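#' Construct a mono audio recording
#'
#' Light container for a sampled pressure waveform. All analysis functions in
#' the package accept this object; [read_wav()] and the simulators return it.
#'
#' @param samples Numeric vector of linear amplitudes (full scale is 1.0).
#' @param rate Sampling rate in Hz. Intraoperative recordings in this setting
#'   are sampled at 40 kHz, the package default throughout.
#' @param source_label Free-text provenance label (file name, case id, ...).
#'
#' @return An object of class `impact_recording`: a list with elements
#'   `samples`, `rate` and `source_label`.
#' @export
#' @examples
#' r <- recording(sin(2 * pi * 440 * seq(0, 0.01, by = 1 / 40000)), 40000)
#' r
recording <- function(samples, rate, source_label = "unnamed") {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    abort("`rate` must be a single positive number (Hz).", class = "stemsound_config_error")
  }
  if (length(samples) && !all(is.finite(samples))) {
    abort("Recording samples must all be finite.", class = "stemsound_data_error")
  }
  structure(
    list(samples = samples, rate = as.numeric(rate),
         source_label = as.character(source_label)[1L]),
    class = "impact_recording"
  )
}

#' @export
print.impact_recording <- function(x, ...) {
  cat(sprintf("<impact_recording> %s: %d samples @ %g Hz (%.3f s)\n",
              x$source_label, length(x$samples), x$rate,
              length(x$samples) / x$rate))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.impact_recording <- function(x, ...) {
  tibble(
    time = (seq_along(x$samples) - 1L) / x$rate,
    amplitude = x$samples
  )
}

#' @export
length.impact_recording <- function(x) length(x$samples)

#' @rdname recording
#' @param x Object to test.
#' @export
is_recording <- function(x) inherits(x, "impact_recording")

#' @exportS3Method ggplot2::autoplot
autoplot.impact_recording <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "Time [s]", y = "Amplitude (full scale = 1)",
                  title = object$source_label)
}
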