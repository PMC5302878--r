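test_that("silent and single-mode strikes behave analytically", {
  comps <- modal_components()

  zero <- comps
  zero$amplitude <- 0
  expect_equal(simulate_strike(zero, lambda = 0.5, noise = 0),
               rep(0, 1000))

  # single 7 kHz component, no noise: exact damped sinusoid at every index
  one <- comps[comps$mode == "hammer", ]
  s <- simulate_strike(one, lambda = 1, duration = 0.025, rate = 40000, noise = 0)
  t <- (0:999) / 40000
  expect_equal(s, 1.0 * exp(-t / 0.003) * sin(2 * pi * 7000 * t),
               tolerance = 1e-12)

  # dominant FFT bin at 7 kHz +/- one bin
  spec <- compute_spectrum(s, 40000)
  binw <- spec$frequency_hz[2] - spec$frequency_hz[1]
  expect_lt(abs(spec$frequency_hz[which.max(spec$magnitude_db)] - 7000), binw + 1e-9)
})

test_that("modal frequencies at or above Nyquist are rejected", {
  bad <- modal_components(hammer_hz = 21000)
  expect_error(simulate_strike(bad, lambda = 1, rate = 40000),
               class = "stemsound_config_error")
})

test_that("hammer-band energy share increases with fixation", {
  comps <- modal_components()
  # brute-force band integration of the periodogram as the oracle
  shares <- vapply(seq(0, 1, by = 0.2), function(lam) {
    hammer_band_share(simulate_strike(comps, lam, noise = 0), 40000)
  }, numeric(1))
  expect_true(all(diff(shares) > 0))
  expect_gt(shares[length(shares)], shares[1])
})

test_that("simulated procedures are deterministic and honour their schedule", {
  sc <- procedure_scenario(n_strikes = 12, seed = 71)
  sim1 <- simulate_procedure(sc)
  sim2 <- simulate_procedure(sc)
  expect_identical(sim1$recording$samples, sim2$recording$samples)
  expect_identical(sim1$truth, sim2$truth)

  expect_equal(nrow(sim1$truth), 12)
  # scheduled onsets recoverable within 2 ms by the segmentation module
  det <- detect_strikes(sim1$recording)
  expect_equal(nrow(det), 12)
  expect_lt(max(abs(det$onset - sim1$truth$onset_sample)) / 40000, 0.002)
})

test_that("fracture scenarios drop the hammer-band share after the fracture", {
  sim <- simulate_procedure(fracture_scenario(n_strikes = 12, fracture_at = 8, seed = 5))
  rec <- sim$recording
  win <- round(0.025 * rec$rate)
  share_at <- function(i) {
    o <- sim$truth$onset_sample[i]
    hammer_band_share(rec$samples[o:(o + win - 1)], rec$rate)
  }
  expect_gt(share_at(8), share_at(9))
  expect_true(all(sim$truth$fractured == (sim$truth$strike > 8)))
})

test_that("zero-strike scenarios give pure noise and empty ground truth", {
  sim <- simulate_procedure(procedure_scenario(n_strikes = 0, seed = 9))
  expect_equal(nrow(sim$truth), 0)
  expect_true(is.na(sim$final_pattern))
  expect_lt(max(abs(sim$recording$samples)), 0.5)
  expect_equal(nrow(detect_strikes(sim$recording)), 0)
})

test_that("invalid scenarios are rejected", {
  expect_error(procedure_scenario(n_strikes = 3, lambda = c(0.2, 0.4)),
               class = "stemsound_config_error")
  expect_error(procedure_scenario(n_strikes = 5, strike_interval = 0.01),
               class = "stemsound_config_error")
  expect_error(procedure_scenario(n_strikes = 4, lambda = c(0.5, 0.4, 0.6, 0.7)),
               class = "stemsound_config_error")
  # lambda must drop strictly after a fracture
  expect_error(procedure_scenario(n_strikes = 4, lambda = c(0.5, 0.6, 0.7, 0.8),
                                  fracture_at = 2),
               class = "stemsound_config_error")
})

test_that("modal taps recover the instrument frequencies", {
  comps <- modal_components()
  binw <- 40000 / 4096   # 25 ms window padded to 4096 bins
  for (i in seq_len(nrow(comps))) {
    tap <- simulate_modal_test(comps[i, ], seed = 100 + i)
    expect_lt(abs(measure_natural_frequency(tap) - comps$frequency_hz[i]),
              binw + 1e-9)
  }

  # zero amplitude: no peak above the noise floor
  silent <- comps[1, ]
  silent$amplitude <- 0
  tap <- simulate_modal_test(silent, seed = 11)
  expect_true(is.na(measure_natural_frequency(tap)))
})
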