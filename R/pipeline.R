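#' Pipeline run configuration
#'
#' One object carries every tunable the pipeline uses, so simulation,
#' analysis and evaluation cannot silently drift apart. Serialises to YAML
#' losslessly via [write_config()] / [read_config()].
#'
#' @param sample_rate Expected sampling rate (Hz).
#' @param threshold_factor,refractory,window_length,smooth Strike-detection
#'   parameters, see [detect_strikes()].
#' @param n_final_strikes Number of final-phase strikes summed (default 5).
#' @param primary_band,secondary_band Band edges (Hz) for [delta_db()].
#' @param tau Pattern A/B threshold (dB), see [classify_final_phase()].
#' @param min_freq Lower bound (Hz) of the global-maximum check.
#' @param transition_m Run length for [detect_transition()].
#' @param ci_method Confidence-interval method for [accuracy()].
#' @param seed Integer seed used by simulation commands.
#' @return A named list of class `stemsound_config`.
#' @export
run_config <- function(sample_rate = 40000, threshold_factor = 8,
                       refractory = 0.05, window_length = 0.025,
                       smooth = 5e-4, n_final_strikes = 5,
                       primary_band = c(6000, 8000),
                       secondary_band = c(3000, 5000), tau = 7.6,
                       min_freq = 1000, transition_m = 2,
                       ci_method = "wilson", seed = 1) {
  structure(
    list(sample_rate = sample_rate, threshold_factor = threshold_factor,
         refractory = refractory, window_length = window_length,
         smooth = smooth, n_final_strikes = as.integer(n_final_strikes),
         primary_band = as.numeric(primary_band),
         secondary_band = as.numeric(secondary_band), tau = tau,
         min_freq = min_freq, transition_m = as.integer(transition_m),
         ci_method = ci_method, seed = as.integer(seed)),
    class = "stemsound_config"
  )
}

#' @rdname run_config
#' @param config A `stemsound_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Analyse one recording end to end
#'
#' Runs the full single-case chain: detect strikes, select and align the
#' final-phase strikes, sum them, compute the spectrum and the delta-dB
#' statistic, assign Pattern A or B, and scan the per-strike series for an
#' A-to-B fracture transition. A recording with no detectable strikes is
#' reported as `"indeterminate"` rather than as an error.
#'
#' @param rec An [recording()].
#' @param config A [run_config()].
#' @param case_id Case identifier; defaults to the recording's source label.
#' @return One-row case-report tibble: `case_id`, `n_strikes`,
#'   `final_delta_db`, `pattern`, `transition_strike` (NA if none),
#'   `short_final_phase`, and list-column `series` with the
#'   [per_strike_series()] result.
#' @export
#' @examples
#' sim <- simulate_procedure(procedure_scenario(n_strikes = 8, seed = 4))
#' analyze_recording(sim$recording)
analyze_recording <- function(rec, config = run_config(),
                              case_id = rec$source_label) {
  stopifnot(is_recording(rec))
  windows <- detect_strikes(rec, threshold_factor = config$threshold_factor,
                            refractory = config$refractory,
                            window_length = config$window_length,
                            smooth = config$smooth)
  if (nrow(windows) == 0L) {
    return(tibble(case_id = case_id, n_strikes = 0L,
                  final_delta_db = NA_real_, pattern = "indeterminate",
                  transition_strike = NA_integer_, short_final_phase = FALSE,
                  series = list(tibble())))
  }
  short <- nrow(windows) < config$n_final_strikes
  final <- withCallingHandlers(
    select_final_phase(windows, n = config$n_final_strikes),
    warning = function(w) invokeRestart("muffleWarning")
  )
  composite <- sum_windows(align_windows(final))
  spec <- compute_spectrum(composite, rec$rate)
  cls <- classify_final_phase(spec, tau = config$tau,
                              primary_band = config$primary_band,
                              secondary_band = config$secondary_band,
                              min_freq = config$min_freq)
  series <- per_strike_series(windows, tau = config$tau,
                              primary_band = config$primary_band,
                              secondary_band = config$secondary_band,
                              min_freq = config$min_freq)
  trans <- if (nrow(series) >= 2 * config$transition_m) {
    detect_transition(series, m = config$transition_m)
  } else {
    tibble(strike_index = integer(0))
  }
  tibble(
    case_id = case_id,
    n_strikes = nrow(windows),
    final_delta_db = cls$delta_db,
    pattern = cls$label,
    transition_strike = if (nrow(trans)) trans$strike_index[1] else NA_integer_,
    short_final_phase = short,
    series = list(series)
  )
}

#' Evaluate pattern labels against clinical outcomes
#'
#' Reproduces the two clinical 2x2 analyses from per-case labels and
#' outcome flags:
#' \describe{
#'   \item{adverse}{Pattern A as the test predicting a clinical course
#'     *without* adverse events (intraoperative fracture or subsidence);
#'     all cases included.}
#'   \item{subsidence}{Pattern B as the test predicting subsidence;
#'     intraoperative-fracture cases are excluded first.}
#' }
#' Each analysis carries its table, the four accuracy metrics with CIs, and
#' the chi-squared and Fisher p-values.
#'
#' @param reports Data frame with `case_id` and `pattern` ("A"/"B") — e.g.
#'   rows from [analyze_recording()], or a pre-assigned label table.
#' @param outcomes Data frame with `case_id`, `fracture` and `subsidence`
#'   logical (or 0/1) flags.
#' @param config A [run_config()] (supplies the CI method).
#' @param allow_partial Keep going when some case ids do not match
#'   (default FALSE: unmatched ids abort with a listing).
#' @return List of class `stemsound_evaluation`: elements `adverse` and
#'   `subsidence`, each a list with `table` (`contingency_2x2`), `metrics`
#'   (the [accuracy()] tibble) and `tests` (chi-squared + Fisher rows);
#'   plus `n_cases` and `n_excluded_fracture`.
#' @export
evaluate_outcomes <- function(reports, outcomes, config = run_config(),
                              allow_partial = FALSE) {
  for (col in c("case_id", "pattern")) {
    if (!col %in% names(reports)) {
      abort(sprintf("`reports` lacks column '%s'.", col),
            class = "stemsound_structure_error")
    }
  }
  for (col in c("case_id", "fracture", "subsidence")) {
    if (!col %in% names(outcomes)) {
      abort(sprintf("`outcomes` lacks column '%s'.", col),
            class = "stemsound_structure_error")
    }
  }
  if (nrow(outcomes) == 0L) {
    abort("`outcomes` is empty.", class = "stemsound_empty_error")
  }
  unmatched <- c(
    setdiff(reports$case_id, outcomes$case_id),
    setdiff(outcomes$case_id, reports$case_id)
  )
  if (length(unmatched) && !allow_partial) {
    abort(sprintf("Unmatched case ids: %s", paste(unmatched, collapse = ", ")),
          class = "stemsound_data_error")
  }
  cases <- dplyr::inner_join(
    as_tibble(reports)[, c("case_id", "pattern")],
    as_tibble(outcomes)[, c("case_id", "fracture", "subsidence")],
    by = "case_id"
  )
  cases$fracture <- as.logical(cases$fracture)
  cases$subsidence <- as.logical(cases$subsidence)
  cases$adverse <- cases$fracture | cases$subsidence

  adverse_tab <- build_table(cases, .data$pattern, .data$adverse,
                             test_positive = "A", condition_positive = FALSE)
  no_fracture <- cases[!cases$fracture, ]
  subsidence_tab <- build_table(no_fracture, .data$pattern, .data$subsidence,
                                test_positive = "B", condition_positive = TRUE)
  wrap <- function(tab) {
    list(table = tab,
         metrics = accuracy(tab, ci_method = config$ci_method),
         tests = bind_rows(
           chi_squared(tab)[, c("method", "statistic", "p.value")],
           dplyr::mutate(fisher_exact(tab), statistic = NA_real_)[,
             c("method", "statistic", "p.value")]
         ))
  }
  structure(
    list(adverse = wrap(adverse_tab), subsidence = wrap(subsidence_tab),
         n_cases = nrow(cases), n_excluded_fracture = sum(cases$fracture)),
    class = "stemsound_evaluation"
  )
}

#' @export
print.stemsound_evaluation <- function(x, ...) {
  cat(sprintf("<stemsound_evaluation> %d cases (%d fracture cases excluded from subsidence analysis)\n",
              x$n_cases, x$n_excluded_fracture))
  for (nm in c("adverse", "subsidence")) {
    cat(sprintf("\n-- %s --\n", nm))
    print(x[[nm]]$table)
    print(as.data.frame(x[[nm]]$metrics[, c("metric", "estimate", "conf.low", "conf.high")]),
          digits = 3, row.names = FALSE)
    print(as.data.frame(x[[nm]]$tests), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.stemsound_evaluation <- function(x, ...) {
  bind_rows(
    dplyr::mutate(x$adverse$metrics, analysis = "adverse"),
    dplyr::mutate(x$subsidence$metrics, analysis = "subsidence")
  )
}
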