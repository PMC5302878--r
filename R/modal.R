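#' Modal component table for impact-sound synthesis
#'
#' Each sound source involved in stem impaction rings at its own natural
#' oscillation frequency when struck: the surgical hammer near 7 kHz, the
#' femoral stem near 3 kHz, the final impactor near 3.1 kHz, plus a secondary
#' construct resonance near 4 kHz whose physical origin is left open and which
#' is therefore exposed as a free parameter. A strike is synthesised as the sum
#' of exponentially damped sinusoids, one per row of this table.
#'
#' The `fixation_coupled` column encodes the assumed mechanism: as the stem
#' seats and its movement decreases, energy shifts toward the hammer mode.
#' Amplitudes are crossfaded linearly with the fixation parameter
#' \eqn{\lambda \in [0,1]}: coupled modes scale as \eqn{\lambda \cdot a}, the
#' remaining modes as \eqn{(1-\lambda) \cdot a}.
#'
#' @param hammer_hz,stem_hz,impactor_hz,construct_hz Natural frequencies (Hz).
#' @param hammer_amp,stem_amp,impactor_amp,construct_amp Base linear amplitudes
#'   (unitless, full scale 1.0).
#' @param hammer_decay_s Exponential amplitude time constant of the hammer
#'   mode (s). Default 3 ms, so the transient dies well inside a 25 ms window.
#' @param other_decay_s Time constant for the remaining modes (s); default 6 ms.
#'
#' @return A tibble with columns `mode`, `frequency_hz`, `decay_s`,
#'   `amplitude`, `fixation_coupled`.
#' @export
#' @examples
#' modal_components()
modal_components <- function(hammer_hz = 7000, stem_hz = 3000,
                             impactor_hz = 3100, construct_hz = 4000,
                             hammer_amp = 1.0, stem_amp = 0.9,
                             impactor_amp = 0.85, construct_amp = 0.7,
                             hammer_decay_s = 0.003, other_decay_s = 0.006) {
  tibble(
    mode = c("hammer", "stem", "impactor", "construct"),
    frequency_hz = c(hammer_hz, stem_hz, impactor_hz, construct_hz),
    decay_s = c(hammer_decay_s, other_decay_s, other_decay_s, other_decay_s),
    amplitude = c(hammer_amp, stem_amp, impactor_amp, construct_amp),
    fixation_coupled = c(TRUE, FALSE, FALSE, FALSE)
  )
}

validate_components <- function(components, rate) {
  req <- c("mode", "frequency_hz", "decay_s", "amplitude")
  if (!is.data.frame(components) || !all(req %in% names(components))) {
    abort("`components` must be a data frame with columns mode, frequency_hz, decay_s, amplitude.",
          class = "stemsound_config_error")
  }
  if (!"fixation_coupled" %in% names(components)) {
    components$fixation_coupled <- components$mode == "hammer"
  }
  if (any(components$frequency_hz <= 0) || any(components$decay_s <= 0) ||
      any(components$amplitude < 0)) {
    abort("Modal components need frequency_hz > 0, decay_s > 0, amplitude >= 0.",
          class = "stemsound_config_error")
  }
  if (any(components$frequency_hz >= rate / 2)) {
    abort(sprintf("Modal frequency at or above Nyquist (%g Hz) for rate %g Hz.",
                  rate / 2, rate),
          class = "stemsound_config_error")
  }
  components
}

# amplitude of each mode at fixation level lambda (linear crossfade)
mode_amplitudes <- function(components, lambda) {
  ifelse(components$fixation_coupled,
         lambda * components$amplitude,
         (1 - lambda) * components$amplitude)
}

#' Synthesise one impact transient
#'
#' Generates \eqn{s(t) = \sum_k a_k(\lambda)\, e^{-t/\tau_k} \sin(2\pi f_k t)}
#' plus additive white Gaussian noise, where \eqn{a_k(\lambda)} is the linear
#' fixation crossfade described in [modal_components()].
#'
#' Uses the current RNG stream for the noise; seed upstream (see
#' [simulate_procedure()]) for reproducibility.
#'
#' @param components Modal component table, see [modal_components()].
#' @param lambda Degree of stem fixation in \[0, 1\]; 0 = loose, 1 = seated.
#' @param duration Transient duration in seconds (default 25 ms).
#' @param rate Sampling rate in Hz.
#' @param noise RMS amplitude of the additive Gaussian noise (0 = clean).
#' @return Numeric vector of `duration * rate` samples.
#' @export
#' @examples
#' s <- simulate_strike(modal_components(), lambda = 0.9)
#' length(s)
simulate_strike <- function(components, lambda, duration = 0.025,
                            rate = 40000, noise = 0) {
  components <- validate_components(components, rate)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
    abort("`lambda` must be a single value in [0, 1].", class = "stemsound_config_error")
  }
  n <- round(duration * rate)
  if (n < 64) {
    abort("duration * rate must give at least 64 samples.", class = "stemsound_config_error")
  }
  t <- (seq_len(n) - 1) / rate
  amps <- mode_amplitudes(components, lambda)
  s <- numeric(n)
  for (k in seq_len(nrow(components))) {
    if (amps[k] == 0) next
    s <- s + amps[k] * exp(-t / components$decay_s[k]) *
      sin(2 * pi * components$frequency_hz[k] * t)
  }
  if (noise > 0) s <- s + rnorm(n, sd = noise)
  s
}

#' Simulate a bench modal test (single tap)
#'
#' Emulates striking a single instrument with an impact hammer on the bench to
#' measure its natural oscillation frequency: one damped-sinusoid transient in
#' a short noise recording, with a 10 ms pre-roll.
#'
#' @param component One-row modal component table (a row of
#'   [modal_components()], or any table with the same columns).
#' @param rate Sampling rate (Hz).
#' @param duration Total recording length (s).
#' @param noise Background-noise RMS amplitude.
#' @param seed Optional integer seed for the noise.
#' @return An [recording()] object containing the single transient.
#' @export
#' @examples
#' tap <- simulate_modal_test(modal_components()[1, ], seed = 1)
#' spec <- compute_spectrum(tap$samples, tap$rate)
#' identify_natural_frequency(spec)
simulate_modal_test <- function(component, rate = 40000, duration = 0.1,
                                noise = 0.001, seed = NULL) {
  component <- validate_components(component, rate)
  if (nrow(component) != 1L) {
    abort("`component` must be a single modal component (one row).",
          class = "stemsound_config_error")
  }
  gen <- function() {
    n <- round(duration * rate)
    onset <- round(0.010 * rate)
    tap_len <- min(round(0.025 * rate), n - onset)
    t <- (seq_len(tap_len) - 1) / rate
    s <- if (noise > 0) rnorm(n, sd = noise) else numeric(n)
    s[onset + seq_len(tap_len)] <- s[onset + seq_len(tap_len)] +
      component$amplitude * exp(-t / component$decay_s) *
        sin(2 * pi * component$frequency_hz * t)
    s
  }
  samples <- if (is.null(seed)) gen() else with_seed(seed, gen())
  recording(samples, rate, sprintf("modal_test_%s", component$mode[1L]))
}
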