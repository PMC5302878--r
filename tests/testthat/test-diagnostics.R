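test_that("tables built from the published per-case counts match the reported cells", {
  cases <- published_cases()
  cases$adverse <- cases$fracture | cases$subsidence

  adverse <- build_table(cases, pattern, adverse,
                         test_positive = "A", condition_positive = FALSE)
  expect_equal(c(adverse$tp, adverse$fp, adverse$fn, adverse$tn),
               c(36, 6, 16, 13))

  no_fracture <- cases[!cases$fracture, ]
  subsidence <- build_table(no_fracture, pattern, subsidence,
                            test_positive = "B", condition_positive = TRUE)
  expect_equal(c(subsidence$tp, subsidence$fp, subsidence$fn, subsidence$tn),
               c(11, 16, 6, 36))

  expect_error(build_table(cases[0, ], pattern, adverse,
                           test_positive = "A", condition_positive = FALSE),
               class = "stemsound_empty_error")
  expect_error(build_table(cases, pattern, adverse),
               class = "stemsound_config_error")
})

test_that("accuracy metrics reproduce the published values", {
  adverse <- accuracy(contingency_table(36, 6, 16, 13))
  est <- setNames(adverse$estimate, adverse$metric)
  expect_equal(round(100 * est[["sensitivity"]], 1), 69.2)
  expect_equal(round(100 * est[["specificity"]], 1), 68.4)
  expect_equal(round(100 * est[["ppv"]], 1), 85.7)
  expect_equal(round(100 * est[["npv"]], 1), 44.8)

  subsidence <- accuracy(contingency_table(11, 16, 6, 36))
  est2 <- setNames(subsidence$estimate, subsidence$metric)
  expect_equal(round(100 * est2[["sensitivity"]], 1), 64.7)
  expect_equal(round(100 * est2[["specificity"]], 1), 69.2)
  expect_equal(round(100 * est2[["ppv"]], 1), 40.7)
  expect_equal(round(100 * est2[["npv"]], 1), 85.7)

  perfect <- accuracy(contingency_table(7, 0, 0, 7))
  expect_true(all(perfect$estimate == 1))

  # zero denominator: flagged NA, never dropped
  expect_warning(deg <- accuracy(contingency_table(0, 5, 0, 5)), "sensitivity")
  expect_equal(nrow(deg), 4)
  expect_false(deg$defined[deg$metric == "sensitivity"])
  expect_true(is.na(deg$estimate[deg$metric == "sensitivity"]))
})

test_that("every defined estimate lies inside its own confidence interval", {
  set.seed(51)
  for (i in 1:25) {
    counts <- rpois(4, 10) + 1
    for (m in c("wilson", "clopper-pearson")) {
      acc <- accuracy(do.call(contingency_table, as.list(counts)), ci_method = m)
      expect_true(all(acc$conf.low <= acc$estimate & acc$estimate <= acc$conf.high))
      expect_true(all(acc$conf.low >= 0 & acc$conf.high <= 1))
    }
  }
})

test_that("orientation swap exchanges sensitivity/specificity and ppv/npv", {
  set.seed(52)
  for (i in 1:20) {
    k <- rpois(4, 8) + 1
    tab <- contingency_table(k[1], k[2], k[3], k[4])
    swapped <- contingency_table(tp = k[4], fp = k[3], fn = k[2], tn = k[1])
    a <- setNames(accuracy(tab)$estimate, accuracy(tab)$metric)
    b <- setNames(accuracy(swapped)$estimate, accuracy(swapped)$metric)
    expect_equal(a[["sensitivity"]], b[["specificity"]])
    expect_equal(a[["ppv"]], b[["npv"]])
  }
})

test_that("chi-squared matches the closed 2x2 form and the published p-values", {
  adverse <- chi_squared(contingency_table(36, 6, 16, 13))
  expect_equal(adverse$statistic, 8.17, tolerance = 0.001)
  expect_equal(round(adverse$p.value, 3), 0.004)

  subsidence <- chi_squared(contingency_table(36, 6, 16, 11))
  expect_equal(subsidence$statistic, 6.20, tolerance = 0.001)
  expect_equal(round(subsidence$p.value, 3), 0.013)

  # independent cross-check against stats::chisq.test on random tables
  set.seed(53)
  for (i in 1:20) {
    k <- rpois(4, 12) + 1
    tab <- contingency_table(k[1], k[2], k[3], k[4])
    ref <- suppressWarnings(
      stats::chisq.test(as.matrix(tab), correct = FALSE)
    )
    got <- chi_squared(tab)
    expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }

  # ad = bc -> statistic 0, p = 1
  null_tab <- chi_squared(contingency_table(6, 3, 4, 2))
  expect_equal(null_tab$statistic, 0)
  expect_equal(null_tab$p.value, 1)

  expect_warning(bad <- chi_squared(contingency_table(0, 0, 3, 4)), "marginal")
  expect_true(is.na(bad$statistic))
})

test_that("fisher_exact agrees with full hypergeometric enumeration", {
  expect_equal(fisher_exact(contingency_table(1, 0, 0, 1))$p.value, 1)
  expect_equal(fisher_exact(contingency_table(5, 0, 0, 5))$p.value, 1 / 126,
               tolerance = 1e-12)
  expect_equal(fisher_exact(contingency_table(4, 4, 4, 4))$p.value, 1)

  set.seed(54)
  for (i in 1:30) {
    repeat {
      k <- rpois(4, 5) + 1
      if (sum(k) <= 60) break
    }
    got <- fisher_exact(contingency_table(k[1], k[2], k[3], k[4]))$p.value
    expect_equal(got, fisher_enum_p(k[1], k[2], k[3], k[4]), tolerance = 1e-9)
  }
})

test_that("welch_t reproduces published group comparisons and basic invariances", {
  res <- welch_t(10.2, 5.3, 42, 5.1, 6.8, 29)
  expect_equal(res$statistic, 3.39, tolerance = 0.005)
  expect_equal(res$p.value, 0.0014, tolerance = 0.05)
  expect_lt(res$p.value, 0.05)

  # cross-check against t.test on raw data with matching summaries
  set.seed(55)
  x <- rnorm(30); y <- rnorm(25, mean = 1)
  ref <- t.test(x, y)
  got <- welch_t(mean(x), sd(x), 30, mean(y), sd(y), 25)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(got$p.value, ref$p.value, tolerance = 1e-10)

  ident <- welch_t(5, 2, 10, 5, 2, 10)
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)

  # translation invariance
  shifted <- welch_t(15.2, 5.3, 42, 10.1, 6.8, 29)
  expect_equal(shifted$statistic, res$statistic, tolerance = 1e-12)

  expect_error(welch_t(1, 1, 1, 2, 1, 10), class = "stemsound_config_error")
  expect_error(welch_t(1, 0, 10, 2, 1, 10), class = "stemsound_config_error")
})

test_that("tidy and glance summarise contingency tables", {
  tab <- contingency_table(36, 6, 16, 13)
  td <- generics::tidy(tab)
  expect_equal(sum(td$count), 71)
  gl <- generics::glance(tab)
  expect_equal(gl$n, 71)
  expect_equal(round(100 * gl$sensitivity, 1), 69.2)
  expect_lt(gl$chisq_p, 0.05)
})
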