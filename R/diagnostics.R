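#' Build an oriented 2x2 contingency table from per-case data
#'
#' The orientation must be declared explicitly: which value of the test
#' column counts as test-positive and which value of the truth column counts
#' as condition-positive. In the clinical analyses here, Pattern A is the
#' test-positive label predicting a course *without* adverse events, while
#' Pattern B is the test-positive label predicting subsidence — the same
#' classifier read in the two opposite orientations.
#'
#' @param data Data frame with one row per case.
#' @param test,truth Columns (tidy-eval) holding the classifier label and the
#'   outcome.
#' @param test_positive Value of `test` counted as test-positive.
#' @param condition_positive Value of `truth` counted as condition-positive.
#' @return A `contingency_2x2` object (counts `tp`, `fp`, `fn`, `tn` plus the
#'   declared orientation).
#' @export
#' @examples
#' cases <- tibble::tibble(pattern = c("A", "A", "B"), event = c(FALSE, TRUE, TRUE))
#' build_table(cases, pattern, event, test_positive = "A", condition_positive = FALSE)
build_table <- function(data, test, truth, test_positive, condition_positive) {
  if (missing(test_positive) || missing(condition_positive)) {
    abort("Declare the orientation: `test_positive` and `condition_positive`.",
          class = "stemsound_config_error")
  }
  test_v <- eval_tidy(enquo(test), data)
  truth_v <- eval_tidy(enquo(truth), data)
  if (length(test_v) == 0L) {
    abort("No cases supplied.", class = "stemsound_empty_error")
  }
  if (length(test_v) != length(truth_v)) {
    abort("`test` and `truth` must be aligned per case.",
          class = "stemsound_structure_error")
  }
  if (anyNA(test_v) || anyNA(truth_v)) {
    abort("Missing labels or outcomes; apply exclusions before building the table.",
          class = "stemsound_data_error")
  }
  tpos <- test_v == test_positive
  cpos <- truth_v == condition_positive
  contingency_table(
    tp = sum(tpos & cpos), fp = sum(tpos & !cpos),
    fn = sum(!tpos & cpos), tn = sum(!tpos & !cpos),
    test_positive = as.character(test_positive),
    condition_positive = as.character(condition_positive)
  )
}

#' @rdname build_table
#' @param tp,fp,fn,tn Cell counts (test+/condition+, test+/condition-,
#'   test-/condition+, test-/condition-).
#' @export
contingency_table <- function(tp, fp, fn, tn, test_positive = "positive",
                              condition_positive = "positive") {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || sum(counts) == 0) {
    abort("Counts must be non-negative with a positive total.",
          class = "stemsound_config_error")
  }
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         test_positive = test_positive, condition_positive = condition_positive),
    class = "contingency_2x2"
  )
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<contingency_2x2> test+ = '%s', condition+ = '%s'\n",
              x$test_positive, x$condition_positive))
  m <- as.matrix(x)
  print(m)
  invisible(x)
}

#' @export
as.matrix.contingency_2x2 <- function(x, ...) {
  matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
         dimnames = list(test = c("positive", "negative"),
                         condition = c("positive", "negative")))
}

#' @exportS3Method generics::tidy
tidy.contingency_2x2 <- function(x, ...) {
  tibble(
    cell = c("tp", "fp", "fn", "tn"),
    test = c("positive", "positive", "negative", "negative"),
    condition = c("positive", "negative", "positive", "negative"),
    count = c(x$tp, x$fp, x$fn, x$tn)
  )
}

#' @exportS3Method generics::glance
glance.contingency_2x2 <- function(x, ...) {
  acc <- accuracy(x)
  est <- setNames(acc$estimate, acc$metric)
  tibble(
    n = x$tp + x$fp + x$fn + x$tn,
    sensitivity = est[["sensitivity"]],
    specificity = est[["specificity"]],
    ppv = est[["ppv"]],
    npv = est[["npv"]],
    chisq_p = chi_squared(x)$p.value,
    fisher_p = fisher_exact(x)$p.value
  )
}

wilson_ci <- function(x, n, conf_level) {
  if (n == 0) return(c(NA_real_, NA_real_))
  # only the score interval is used; prop.test's small-count warning about
  # its chi-squared statistic does not apply to the interval
  suppressWarnings(
    as.numeric(prop.test(x, n, conf.level = conf_level, correct = FALSE)$conf.int)
  )
}

clopper_pearson_ci <- function(x, n, conf_level) {
  if (n == 0) return(c(NA_real_, NA_real_))
  as.numeric(binom.test(x, n, conf.level = conf_level)$conf.int)
}

#' Diagnostic accuracy metrics with confidence intervals
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`, each with a
#' binomial confidence interval. Wilson score intervals by default: the
#' original report does not identify its interval method, so the package
#' declares its own. A metric whose denominator is zero is returned as `NA`
#' with `defined = FALSE` and a warning — never silently dropped.
#'
#' @param table A `contingency_2x2`.
#' @param ci_method `"wilson"` (score interval, default) or
#'   `"clopper-pearson"` (exact).
#' @param conf_level Confidence level (default 0.95).
#' @return Tibble with columns `metric`, `estimate`, `conf.low`, `conf.high`,
#'   `numerator`, `denominator`, `defined`, `method`.
#' @export
#' @examples
#' accuracy(contingency_table(36, 6, 16, 13))
accuracy <- function(table, ci_method = c("wilson", "clopper-pearson"),
                     conf_level = 0.95) {
  stopifnot(inherits(table, "contingency_2x2"))
  ci_method <- match.arg(ci_method)
  ci_fun <- if (ci_method == "wilson") wilson_ci else clopper_pearson_ci
  spec_ <- list(
    sensitivity = c(table$tp, table$tp + table$fn),
    specificity = c(table$tn, table$tn + table$fp),
    ppv = c(table$tp, table$tp + table$fp),
    npv = c(table$tn, table$tn + table$fn)
  )
  rows <- map(names(spec_), function(metric) {
    x <- spec_[[metric]][1]
    n <- spec_[[metric]][2]
    if (n == 0) {
      warn(sprintf("%s undefined: zero denominator.", metric))
      return(tibble(metric = metric, estimate = NA_real_, conf.low = NA_real_,
                    conf.high = NA_real_, numerator = x, denominator = n,
                    defined = FALSE, method = ci_method))
    }
    ci <- ci_fun(x, n, conf_level)
    tibble(metric = metric, estimate = x / n, conf.low = ci[1], conf.high = ci[2],
           numerator = x, denominator = n, defined = TRUE, method = ci_method)
  })
  bind_rows(rows)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Uncorrected (no Yates continuity correction):
#' \eqn{\chi^2 = n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))} with 1 degree of
#' freedom. The continuity correction is deliberately off — the uncorrected
#' statistic is what reproduces the reported p-values from the reported
#' counts.
#'
#' @param table A `contingency_2x2`.
#' @return One-row tibble: `statistic`, `df`, `p.value`, `method`. A zero
#'   marginal yields `NA` with a warning.
#' @export
#' @examples
#' chi_squared(contingency_table(36, 6, 16, 13))
chi_squared <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$tp; b <- table$fp; c_ <- table$fn; d <- table$tn
  n <- a + b + c_ + d
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) {
    warn("Chi-squared undefined: zero marginal.")
    return(tibble(statistic = NA_real_, df = 1L, p.value = NA_real_,
                  method = "Pearson chi-squared (uncorrected)"))
  }
  stat <- n * (a * d - b * c_)^2 / prod(margins)
  tibble(statistic = stat, df = 1L,
         p.value = pchisq(stat, df = 1, lower.tail = FALSE),
         method = "Pearson chi-squared (uncorrected)")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test: sums the hypergeometric probabilities of all tables
#' with the observed margins whose probability does not exceed the observed
#' table's.
#'
#' @param table A `contingency_2x2`.
#' @return One-row tibble: `p.value`, `method`.
#' @export
fisher_exact <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  tibble(p.value = fisher.test(as.matrix(table))$p.value,
         method = "Fisher exact (two-sided)")
}

#' Welch's two-sample t-test from summary statistics
#'
#' Group comparisons here arrive as published summaries (mean, SD, n per
#' group), so the Welch statistic and Satterthwaite degrees of freedom are
#' computed directly from them:
#' \deqn{t = (m_1 - m_2) / \sqrt{s_1^2/n_1 + s_2^2/n_2}}
#'
#' @param mean1,sd1,n1 First group's mean, standard deviation and size.
#' @param mean2,sd2,n2 Second group's summary statistics.
#' @return One-row tibble: `estimate` (mean difference), `statistic`, `df`
#'   (Satterthwaite), `p.value` (two-sided), `method`.
#' @export
#' @examples
#' welch_t(10.2, 5.3, 42, 5.1, 6.8, 29)
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) abort("Each group needs n >= 2.", class = "stemsound_config_error")
  if (sd1 <= 0 || sd2 <= 0) abort("Standard deviations must be positive.",
                                  class = "stemsound_config_error")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t_stat <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble(estimate = mean1 - mean2, statistic = t_stat, df = df,
         p.value = 2 * pt(-abs(t_stat), df),
         method = "Welch two-sample t-test (summary statistics)")
}
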