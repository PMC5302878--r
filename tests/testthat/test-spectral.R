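sine <- function(freq, n = 1024, rate = 40000, amp = 1) {
  amp * sin(2 * pi * freq * (0:(n - 1)) / rate)
}

test_that("window summation is a pure pointwise sum", {
  w <- sine(3000, n = 500)
  expect_identical(sum_windows(list(w)), w)

  five <- sum_windows(replicate(5, w, simplify = FALSE))
  expect_equal(five, 5 * w)
  # +20*log10(5) = +13.98 dB at the peak
  s1 <- compute_spectrum(w, 40000)
  s5 <- compute_spectrum(five, 40000)
  expect_equal(max(s5$magnitude_db) - max(s1$magnitude_db),
               20 * log10(5), tolerance = 1e-9)

  expect_error(sum_windows(list(w, w[-1])), class = "stemsound_structure_error")
  expect_error(sum_windows(list()), class = "stemsound_empty_error")
})

test_that("summing independent noise windows multiplies power by n", {
  set.seed(99)
  n_rep <- 1000
  ratio <- vapply(seq_len(n_rep), function(i) {
    ws <- replicate(5, rnorm(256), simplify = FALSE)
    mean(sum_windows(ws)^2) / mean(ws[[1]]^2)
  }, numeric(1))
  # expected power gain 5x (+7 dB), Monte-Carlo tolerance on the mean
  expect_equal(mean(ratio), 5, tolerance = 0.05)
})

test_that("spectrum peaks sit at injected frequencies with correct dB ratios", {
  # exact-bin sine, amplitude 1 -> 0 dB global peak at that bin
  n <- 1024
  f_bin <- 40000 * 128 / n
  spec <- compute_spectrum(sine(f_bin, n = n), 40000, pad = 0)
  peak <- which.max(spec$magnitude_db)
  expect_equal(spec$frequency_hz[peak], f_bin)
  expect_equal(spec$magnitude_db[peak], 0, tolerance = 1e-9)

  # amplitudes 1.0 and 0.1 at separated bins -> 20 dB level difference
  x <- sine(40000 * 64 / n, n = n) + sine(40000 * 192 / n, n = n, amp = 0.1)
  spec2 <- compute_spectrum(x, 40000, pad = 0)
  lev <- function(f) spec2$magnitude_db[which.min(abs(spec2$frequency_hz - f))]
  expect_equal(lev(40000 * 64 / n) - lev(40000 * 192 / n), 20, tolerance = 0.1)

  # all-zero input floors at db_floor instead of -Inf
  z <- compute_spectrum(rep(0, 256), 40000, db_floor = -300)
  expect_true(all(z$magnitude_db == -300))
  expect_error(compute_spectrum(c(rep(0, 100), NA), 40000),
               class = "stemsound_data_error")
})

test_that("compute_spectrum matches a brute-force DFT to 1e-9", {
  set.seed(7)
  for (n in c(64, 128, 500, 512)) {
    x <- rnorm(n)
    spec <- compute_spectrum(x, 40000, pad = 0)
    got <- 10^(spec$magnitude_db / 20)
    want <- naive_dft_mag(x) * 2 / n
    big <- want > 1e-12 * max(want)
    expect_lt(max(abs(got[big] - want[big]) / want[big]), 1e-9)
  }
})

test_that("total spectral power matches time-domain power (Parseval)", {
  set.seed(8)
  for (n in c(256, 1000)) {
    x <- rnorm(n)
    spec <- compute_spectrum(x, 40000, pad = 0)
    mag <- 10^(spec$magnitude_db / 20) * n / 2          # back to |X_k|
    k <- seq_along(mag) - 1
    weight <- ifelse(k == 0 | (n %% 2 == 0 & k == n %/% 2), 1, 2)
    expect_equal(sum(weight * mag^2) / n, sum(x^2), tolerance = 1e-6)
  }
})

test_that("band peaks honour band limits and tie-breaks", {
  sim <- simulate_modal_test(modal_components(construct_hz = 7200)[4, ], seed = 21)
  spec <- compute_spectrum(sim$samples, sim$rate)
  binw <- spec$frequency_hz[2] - spec$frequency_hz[1]
  bp <- band_peak(spec, 6000, 8000)
  expect_lt(abs(bp$peak_frequency_hz - 7200), binw + 1e-9)
  expect_true(bp$peak_frequency_hz >= 6000 && bp$peak_frequency_hz <= 8000)
  expect_equal(bp$peak_db, max(spec$magnitude_db[spec$frequency_hz >= 6000 &
                                                   spec$frequency_hz <= 8000]))

  # flat spectrum: tie broken toward the lower frequency
  flat <- compute_spectrum(rep(0, 256), 40000)
  expect_equal(band_peak(flat, 3000, 5000)$peak_frequency_hz,
               min(flat$frequency_hz[flat$frequency_hz >= 3000]))

  expect_error(band_peak(spec, 19000, 30000), class = "stemsound_config_error")
  expect_error(band_peak(spec, 5000, 4000), class = "stemsound_config_error")
})

test_that("delta_db has the declared sign convention and scale invariance", {
  # exact-bin tones near 7 and 4 kHz (179/1024 and 102/1024 of 40 kHz)
  f7 <- 40000 * 179 / 1024
  f4 <- 40000 * 102 / 1024
  x_eq <- sine(f7) + sine(f4)
  expect_equal(delta_db(compute_spectrum(x_eq, 40000))$delta_db, 0, tolerance = 0.05)

  x_10 <- sine(f7) + sine(f4, amp = 0.1)
  expect_equal(delta_db(compute_spectrum(x_10, 40000))$delta_db, 20, tolerance = 0.1)

  # global scaling cancels out of the dB difference
  set.seed(12)
  y <- sine(7000, amp = 0.5) + sine(4200, amp = 0.2) + rnorm(1024, sd = 0.01)
  d1 <- delta_db(compute_spectrum(y, 40000))$delta_db
  d2 <- delta_db(compute_spectrum(y * 37.5, 40000))$delta_db
  expect_equal(d1, d2, tolerance = 1e-9)

  expect_error(delta_db(compute_spectrum(y, 40000),
                        primary_band = c(4000, 8000),
                        secondary_band = c(3000, 5000)),
               class = "stemsound_config_error")
})

test_that("synthetic cohorts separate in the expected direction", {
  # well-seated (lambda -> 0.9) vs poorly-seated (lambda -> 0.3) cohorts:
  # mean final delta-dB must be higher in the first, matching the direction
  # of the reported group means (10.2 vs 5.1 dB)
  d <- vapply(1:10, function(s) {
    a <- analyze_recording(simulate_procedure(cohort_scenario(0.9, s))$recording)
    b <- analyze_recording(simulate_procedure(cohort_scenario(0.3, 500 + s))$recording)
    c(a$final_delta_db, b$final_delta_db)
  }, numeric(2))
  expect_gt(mean(d[1, ]), mean(d[2, ]))
})

test_that("pure noise has no prominent natural frequency", {
  set.seed(31)
  spec <- compute_spectrum(rnorm(4096, sd = 0.1), 40000)
  expect_true(is.na(identify_natural_frequency(spec, min_prominence = 20)))
})
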