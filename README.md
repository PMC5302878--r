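# stemsound

Acoustic monitoring of cementless femoral-stem implantation in total hip
arthroplasty.

During cementless THA the stem is hammered into the femur and the surgeon
must judge, by ear and feel, when press-fit fixation is adequate — stopping
too early risks postoperative subsidence, hammering on risks intraoperative
fracture. The impaction sound carries objective information: each instrument
rings at its natural oscillation frequency (hammer ≈ 7 kHz, stem ≈ 3 kHz,
final impactor ≈ 3.1 kHz), and as the stem seats, spectral energy shifts
toward the hammer mode. `stemsound` is an R package for surgeons and
biomedical signal-processing researchers that quantifies this shift and
evaluates its diagnostic value.

## The method

For a recording sampled at 40 kHz the pipeline:

1. detects hammer-strike transients with a robust envelope threshold;
2. aligns and coherently sums the waveforms of the **last five strikes**
   (signal grows ∝ n, incoherent noise ∝ √n);
3. computes the FFT magnitude spectrum in dB and the band-peak difference

   **Δ dB = peak(6–8 kHz) − peak(3–5 kHz)**;

4. labels the case **Pattern A** (7 kHz accentuated; Δ dB ≥ τ = 7.6 dB and
   the 7 kHz-band peak is the global spectral maximum above 1 kHz) or
   **Pattern B** (no accentuation), and scans the per-strike Δ series for
   an abrupt A→B reversal — the acoustic signature of an intraoperative
   fracture;
5. evaluates labels against outcomes: oriented 2×2 tables, sensitivity /
   specificity / PPV / NPV with Wilson 95 % intervals, uncorrected Pearson
   chi-squared, Fisher's exact test, and a summary-statistics Welch t-test.

A seeded damped-sinusoid generator (`simulate_procedure()`,
`simulate_modal_test()`) produces strike trains and bench modal taps with
known ground truth, standing in for non-deposited operating-room audio.
See the methods vignette (`vignettes/acoustic-monitoring.Rmd`) for the
signal model, parameter defaults and limitations.

## Worked example

```r
library(stemsound)

# a progressively seated implantation (fixation 0.6 -> 0.9) ...
sim <- simulate_procedure(procedure_scenario(
  n_strikes = 12, lambda = seq(0.6, 0.9, length.out = 12), seed = 1))
analyze_recording(sim$recording)
#>     case_id n_strikes final_delta_db pattern transition_strike
#> 1 sim_seed1        12          9.651       A                NA

# ... and one that fractures after strike 8
simF <- simulate_procedure(fracture_scenario(n_strikes = 12, fracture_at = 8, seed = 3))
analyze_recording(simF$recording)
#>     case_id n_strikes final_delta_db pattern transition_strike
#> 1 sim_seed3        12         -10.49       B                 8
```

The seated case sums to a spectrum whose 7 kHz band peak stands 9.7 dB above
the 4 kHz band — Pattern A. The fracture case ends at Δ = −10.5 dB
(Pattern B) and the per-strike series pinpoints the A→B transition at
strike 8, where the fracture occurred.

Evaluating a labelled 71-case cohort (42 Pattern A, 29 Pattern B; 6 vs 13
adverse events; fracture cases excluded from the subsidence analysis):

```r
ev <- evaluate_outcomes(reports, outcomes)
ev$adverse$metrics
#>       metric estimate conf.low conf.high
#>  sensitivity    0.692    0.557     0.801
#>  specificity    0.684    0.460     0.846
#>          ppv    0.857    0.722     0.933
#>          npv    0.448    0.284     0.625
ev$adverse$tests
#>                             method statistic p.value
#>  Pearson chi-squared (uncorrected)      8.16 0.00427
#>           Fisher exact (two-sided)        NA 0.00629
```

Pattern A predicts a course without fracture or subsidence with 69.2 %
sensitivity and 68.4 % specificity (PPV 85.7 %, NPV 44.8 %); the
pattern–outcome association is significant (χ² p = 0.004). The subsidence
analysis gives sensitivity 64.7 %, specificity 69.2 %, PPV 40.7 %,
NPV 85.7 % (p = 0.013).

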