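#' Describe a simulated implantation procedure
#'
#' A scenario fixes everything about one synthetic case: how many strikes,
#' their spacing, the per-strike fixation trajectory \eqn{\lambda_i}, an
#' optional intraoperative fracture (an abrupt drop in \eqn{\lambda}), the
#' background-noise level and the seed. The default noise RMS of
#' \eqn{10^{-30/20} \approx 0.032} gives 30 dB SNR against a unit-amplitude
#' strike.
#'
#' @param n_strikes Number of impactor strikes.
#' @param strike_interval Time between consecutive strike onsets (s). Must
#'   exceed `strike_duration` so transients do not overlap.
#' @param lambda Fixation trajectory: vector of values in \[0, 1\], one per
#'   strike. Defaults to a linear ramp 0.2 to 0.9 (progressive seating).
#'   Must be non-decreasing up to `fracture_at` and drop strictly after it.
#' @param fracture_at Strike index after which the fracture manifests, or
#'   `NULL` for none.
#' @param noise_level Background-noise RMS (linear, relative to unit strike).
#' @param seed Integer seed; the same scenario and seed give bit-identical
#'   recordings.
#' @param sample_rate Sampling rate (Hz).
#' @param strike_duration Length of each synthesised transient (s).
#' @param amplitude_jitter Half-width of the per-strike uniform amplitude
#'   jitter (0.2 = strikes scaled by U(0.8, 1.2)), emulating a
#'   non-standardised impact technique.
#' @param lead_in Silence (noise only) before the first strike (s).
#'
#' @return A `procedure_scenario` list, accepted by [simulate_procedure()].
#' @seealso [fracture_scenario()] for a ready-made fracture trajectory.
#' @export
#' @examples
#' procedure_scenario(n_strikes = 12, seed = 1)
procedure_scenario <- function(n_strikes = 12, strike_interval = 0.1,
                               lambda = NULL, fracture_at = NULL,
                               noise_level = 10^(-30 / 20), seed = 1,
                               sample_rate = 40000, strike_duration = 0.025,
                               amplitude_jitter = 0.2, lead_in = 0.05) {
  if (n_strikes < 0) abort("`n_strikes` must be >= 0.", class = "stemsound_config_error")
  if (is.null(lambda)) {
    lambda <- if (n_strikes > 1) seq(0.2, 0.9, length.out = n_strikes)
              else rep(0.9, n_strikes)
  }
  if (length(lambda) != n_strikes) {
    abort("`lambda` must have one value per strike.", class = "stemsound_config_error")
  }
  if (n_strikes > 0 && (any(lambda < 0) || any(lambda > 1))) {
    abort("`lambda` values must lie in [0, 1].", class = "stemsound_config_error")
  }
  if (!is.null(fracture_at)) {
    if (fracture_at < 1 || fracture_at >= n_strikes) {
      abort("`fracture_at` must name a strike before the last one.",
            class = "stemsound_config_error")
    }
    pre <- lambda[seq_len(fracture_at)]
    if (is.unsorted(pre)) {
      abort("`lambda` must be non-decreasing up to the fracture.",
            class = "stemsound_config_error")
    }
    if (lambda[fracture_at + 1L] >= lambda[fracture_at]) {
      abort("`lambda` must drop strictly after the fracture.",
            class = "stemsound_config_error")
    }
  } else if (n_strikes > 1 && is.unsorted(lambda)) {
    abort("`lambda` must be non-decreasing when no fracture is scheduled.",
          class = "stemsound_config_error")
  }
  if (strike_interval <= strike_duration) {
    abort("`strike_interval` must exceed `strike_duration` (windows would overlap).",
          class = "stemsound_config_error")
  }
  structure(
    list(n_strikes = as.integer(n_strikes), strike_interval = strike_interval,
         lambda = as.numeric(lambda), fracture_at = fracture_at,
         noise_level = noise_level, seed = as.integer(seed),
         sample_rate = sample_rate, strike_duration = strike_duration,
         amplitude_jitter = amplitude_jitter, lead_in = lead_in),
    class = "procedure_scenario"
  )
}

#' @export
print.procedure_scenario <- function(x, ...) {
  cat(sprintf(
    "<procedure_scenario> %d strikes @ %g s, lambda %.2f -> %.2f%s, noise %.4g, seed %d\n",
    x$n_strikes, x$strike_interval,
    if (x$n_strikes) x$lambda[1] else NA, if (x$n_strikes) x$lambda[x$n_strikes] else NA,
    if (is.null(x$fracture_at)) "" else sprintf(", fracture after strike %d", x$fracture_at),
    x$noise_level, x$seed))
  invisible(x)
}

#' Scenario with an intraoperative fracture
#'
#' Builds the canonical fracture trajectory: fixation ramps up, holds at
#' `lambda_pre` for the final strikes before the fracture, then drops abruptly
#' to `lambda_post` — the acoustic signature reverting from Pattern A to
#' Pattern B the moment the femur cracks. The hold guarantees that the strikes
#' immediately before the fracture are unambiguously Pattern A, so the
#' transition sits at `fracture_at` rather than wherever a straight ramp
#' happens to cross the classification threshold.
#'
#' @inheritParams procedure_scenario
#' @param lambda_start Fixation at the first strike.
#' @param lambda_pre Plateau fixation reached before the fracture.
#' @param lambda_post Fixation after the fracture.
#' @param hold Number of pre-fracture strikes held at `lambda_pre`.
#' @param ... Passed on to [procedure_scenario()].
#' @return A `procedure_scenario`.
#' @export
#' @examples
#' fracture_scenario(fracture_at = 8, seed = 3)
fracture_scenario <- function(n_strikes = 12, fracture_at = 8,
                              lambda_start = 0.3, lambda_pre = 0.9,
                              lambda_post = 0.2, hold = 2, seed = 1, ...) {
  if (fracture_at <= hold) {
    abort("`fracture_at` must exceed `hold`.", class = "stemsound_config_error")
  }
  ramp_len <- fracture_at - hold
  lam <- c(seq(lambda_start, lambda_pre, length.out = ramp_len + 1L)[-(ramp_len + 1L)],
           rep(lambda_pre, hold),
           rep(lambda_post, n_strikes - fracture_at))
  procedure_scenario(n_strikes = n_strikes, lambda = lam,
                     fracture_at = fracture_at, seed = seed, ...)
}

# analytic energy of one damped sinusoid ~ a^2 * tau / 4 (integral of
# a^2 e^{-2t/tau} sin^2); used for the ground-truth pattern rule
hammer_energy_share <- function(components, lambda) {
  amps <- mode_amplitudes(components, lambda)
  e <- amps^2 * components$decay_s / 4
  if (sum(e) == 0) return(NA_real_)
  sum(e[components$fixation_coupled]) / sum(e)
}

#' Simulate a full implantation procedure
#'
#' Renders the scenario into a noise recording with one synthetic strike
#' transient per scheduled onset, each scaled by a per-strike amplitude jitter,
#' and returns the ground truth needed to score downstream detection and
#' classification. The true final pattern is "A" exactly when the analytic
#' hammer-mode energy share at the final fixation level exceeds 0.5.
#'
#' @param scenario A [procedure_scenario()].
#' @param components Modal component table; defaults to [modal_components()].
#' @return A list of class `procedure_sim` with elements:
#'   \describe{
#'     \item{recording}{[recording()] with the full strike train.}
#'     \item{truth}{Tibble: `strike`, `onset_sample`, `onset_time`, `lambda`,
#'       `amp_scale`, `fractured`, plus a list-column `amplitudes` with the
#'       per-strike modal amplitude mixture.}
#'     \item{final_pattern}{"A" or "B" (ground truth), NA for zero strikes.}
#'     \item{fracture_at}{Scenario fracture index or NULL.}
#'   }
#' @export
#' @examples
#' sim <- simulate_procedure(procedure_scenario(n_strikes = 6, seed = 2))
#' sim$truth
simulate_procedure <- function(scenario, components = modal_components()) {
  stopifnot(inherits(scenario, "procedure_scenario"))
  components <- validate_components(components, scenario$sample_rate)
  rate <- scenario$sample_rate
  n_total <- round((scenario$lead_in +
                      max(scenario$n_strikes, 1) * scenario$strike_interval +
                      0.05) * rate)
  strike_len <- round(scenario$strike_duration * rate)
  onsets <- round((scenario$lead_in +
                     (seq_len(scenario$n_strikes) - 1) * scenario$strike_interval) * rate) + 1L

  sim <- with_seed(scenario$seed, {
    samples <- if (scenario$noise_level > 0) {
      rnorm(n_total, sd = scenario$noise_level)
    } else numeric(n_total)
    scale <- if (scenario$n_strikes > 0) {
      runif(scenario$n_strikes, 1 - scenario$amplitude_jitter,
            1 + scenario$amplitude_jitter)
    } else numeric(0)
    for (i in seq_len(scenario$n_strikes)) {
      w <- simulate_strike(components, scenario$lambda[i],
                           duration = scenario$strike_duration,
                           rate = rate, noise = 0)
      idx <- onsets[i] + seq_along(w) - 1L
      samples[idx] <- samples[idx] + scale[i] * w
    }
    list(samples = samples, scale = scale)
  })

  fractured <- if (is.null(scenario$fracture_at)) {
    rep(FALSE, scenario$n_strikes)
  } else {
    seq_len(scenario$n_strikes) > scenario$fracture_at
  }
  truth <- tibble(
    strike = seq_len(scenario$n_strikes),
    onset_sample = onsets,
    onset_time = (onsets - 1L) / rate,
    lambda = scenario$lambda,
    amp_scale = sim$scale,
    fractured = fractured,
    amplitudes = map(scenario$lambda, function(l) {
      setNames(mode_amplitudes(components, l), components$mode)
    })
  )
  final_pattern <- if (scenario$n_strikes == 0) {
    NA_character_
  } else if (hammer_energy_share(components, scenario$lambda[scenario$n_strikes]) > 0.5) {
    "A"
  } else "B"

  structure(
    list(
      recording = recording(sim$samples, rate,
                            sprintf("sim_seed%d", scenario$seed)),
      truth = truth,
      final_pattern = final_pattern,
      fracture_at = scenario$fracture_at
    ),
    class = "procedure_sim"
  )
}

#' @export
print.procedure_sim <- function(x, ...) {
  cat(sprintf("<procedure_sim> %d strikes, true final pattern %s%s\n",
              nrow(x$truth), x$final_pattern,
              if (is.null(x$fracture_at)) ""
              else sprintf(", fracture after strike %d", x$fracture_at)))
  print(x$recording)
  invisible(x)
}
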