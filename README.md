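# strawtrack

Movement analysis for RFID-tracked pigs in deep-straw housing: from raw
signal-strength detections to hourly movement and longitudinal
mixed-model inference.

## The problem

Continuous monitoring of individual animal movement is a cornerstone of
precision livestock farming: sustained departures from an animal's
typical pattern can flag illness or welfare problems before clinical
signs appear. A practical indoor setup is a single wall-mounted RFID
receiver logging passive ear-tag detections with timestamps and
received signal strength (RSSI, dBm). Turning that stream into
inference raises three questions this package answers:

1. **Sensing.** How far is the tag from the receiver? The log-distance
   path-loss model gives
   `distance = 10^((TxPower − RSSI) / (10 n))`, with `TxPower` the
   expected signal strength at 1 m and `n` the path-loss exponent,
   both calibrated from measurements at known distances
   (`fit_path_loss()`, `distance_from_rssi()`).
2. **Metric.** How much did the pig move? Absolute changes in estimated
   distance between consecutive detections are summed within clock
   hours (a 4 m → 2 m → 5 m sequence is 5 m moved), giving hourly
   movement in cm·h⁻¹; hours without any detection are excluded as
   uninformative rather than counted as inactivity
   (`aggregate_hourly()`, `analysis_table()`).
3. **Inference.** How is movement structured? A linear mixed model

   ```
   y_idh = μ + Day_d + Hour_h + (Day×Hour)_dh + b_i + ε_idh,
   b_i ~ N(0, σ²_pig),   cor(ε_idh, ε_idh') = ρ^|h−h'|
   ```

   fitted by REML with an AR(1) residual structure within each pig-day,
   yields hourly/daily least-squares means, Type-3 F tests with
   containment denominator df, the intraclass correlation
   ICC = σ²_pig / (σ²_pig + σ²_res) quantifying persistent between-pig
   differences, and per-pig BLUPs with intervals (`fit_lmm()`,
   `lsmeans()`, `type3_tests()`, `icc()`, `blups()`, `slice_tests()`).
   A second weighted mixed model relates block-averaged movement to
   barn-environment covariates (temperature, humidity, PM2.5 after a
   collinearity screen of the PM fractions) with crossed random
   intercepts for pig and day-by-timeline (`aggregate_env()`,
   `pm_screen()`, `movement_to_blocks()`, `fit_env_model()`).

Because event-level farm datasets of this kind are rarely shareable,
the package includes a synthetic data generator
(`generative_truth()`, `simulate_trajectory()`, `simulate_detections()`,
`simulate_hourly()`, `simulate_env()`) that reproduces the statistical
structure of a monitored deep-straw pen — a diurnal rhythm with a
night trough and afternoon peak, pig-level baseline heterogeneity,
hour-to-hour residual autocorrelation, detection dropout and
near-collinear PM fractions — so every stage is testable end to end.
The REML engine itself is written from first principles (sparse AR(1)
whitening plus Sherman–Morrison absorption of the pig intercept) and is
verified in the test suite against dense brute-force oracles and an
independent `nlme` implementation.

## Worked example

Simulate a full 16-pig, 20-day study at the default generative truth
(ICC ≈ 0.29, AR(1) ≈ 0.19, afternoon-peak diurnal profile), discard
20% of hours at random, and refit:

```r
library(strawtrack)
truth  <- generative_truth(seed = 42)
hourly <- simulate_hourly(truth, n_pigs = 16, n_days = 20,
                          missing_prob = 0.2, seed = 42)
valid  <- analysis_table(hourly)   # 6,093 of 7,680 possible cells
fit    <- fit_lmm(valid)
fit
#> Linear mixed model of hourly movement (REML)
#>   6093 observations, 16 pigs, rank(X) = 480
#>   sigma2_pig = 14920.5 (SD 122.1 cm/h)
#>   sigma2_res = 38682.3 (SD 196.7 cm/h)
#>   AR(1) rho  = 0.180   ICC = 0.278
#>   -2 restricted log-likelihood = 76365.51
```

The recovered components sit close to the generating truth
(σ²_pig 15,773; σ²_res 38,884; ρ 0.19; ICC 0.289). Hourly LSMeans show
the diurnal span between the 01:00 trough and 15:00 peak:

```r
lsm <- lsmeans(fit, "hour")
lsm[lsm$level %in% c(1, 15), c("level", "estimate", "se", "lower", "upper")]
#>  level estimate     se   lower   upper
#>      1   729.68 33.046  664.89  794.46
#>     15  1076.75 33.004 1012.05 1141.45

type3_tests(fit)
#>    effect num_df den_df     F         p
#>       day     19   5598 16.39 3.886e-53
#>      hour     23   5598 97.18 0.000e+00
#>  day:hour    437   5598  1.67 1.581e-15

head(blups(fit), 3)
#>  pig_id deviation    se   lower  upper n_obs_pig
#>   pig01    101.19 32.66   37.15 165.23       351
#>   pig02   -133.80 32.54 -197.60 -70.01       381
#>   pig03    -15.38 32.51  -79.11  48.34       390
```

Each BLUP is a pig's persistent deviation (cm·h⁻¹) from the fitted
day-by-hour means; the Type-3 table shows strong hour and day effects
and a day-specific modulation of the diurnal profile (day × hour), all
at the containment denominator df.

`run_pipeline(pipeline_config(), "out/")` chains everything — simulate
(event-level or hourly), calibrate, aggregate, both model fits and a
descriptive report — into CSV outputs, fully determined by the seeds in
the config. A thin command-line wrapper lives at
`inst/scripts/strawtrack.R` (subcommands `run`, `calibrate`,
`movement`, `fit-lmm`, `fit-env`).

See the vignette (`vignettes/movement-methods.Rmd`) for the models,
assumptions, numerical methods and the generator's scope.

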