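# batmoth

Analysis tools for field-recorded interactions between echolocating bats
and sound-producing tiger moths (Erebidae: Arctiinae). Tiger moths answer
bat attacks with ultrasonic tymbal clicks that can act as acoustic
warnings of chemical defence (acoustic aposematism); some species pair the
clicks with evasive dives. Given synchronized 3-D flight trajectories and
acoustic event tables for each encounter, `batmoth` quantifies who did
what and whether the sounds worked — for behavioural ecologists and
bioacousticians analysing predator–prey trials.

## What it computes

* **Attack-phase acoustics.** The inter-pulse interval (IPI) between
  onsets of sequential bat calls classifies the attack phase: buzz
  (< 8 ms), late approach (8–20 ms), early approach (21–49 ms), search
  (≥ 50 ms). The package derives IPI series, pulse repetition rates
  (1000 / IPI), the IPI immediately preceding the first moth click, and
  the number of calls a bat produces between search phases (a proxy for
  aborted attacks).
* **Sonar-jamming critical windows.** For every attack-phase call, the
  echo returns after `2 d / c` (speed of sound c = 343 m/s, bat–moth
  distance d at the call midpoint). A moth click whose one-way arrival
  falls inside the ±2 ms critical window around the echo return could
  interfere with ranging; the per-interaction report gives the fraction
  of unaffected echoes.
* **3-D kinematics.** Least-squares smoothing splines (tolerance-budgeted,
  in the spirit of MATLAB's `spaps`) turn noisy 60 Hz tracks into
  differentiable paths; the package finds the minimum bat–moth distance
  (mBMD, with a 3.7 cm reconstruction-error contact floor), the mean
  moth z-speed over the 0–333 ms before closest approach (a dive proxy),
  and an evasion label (dive / turn-away / no evasion).
* **Exact outcome statistics.** 2×2 non-capture vs captured tables per
  tymbal treatment (T+ intact, T− ablated, S sham), relative risks of
  capture, Fisher's exact test with the conditional-MLE odds ratio
  (root of the noncentral hypergeometric score equation) and exact
  conditional 95% CIs, one-sided exact binomial (Clopper–Pearson)
  palatability bounds, plus Welch t, Mann–Whitney–Wilcoxon, K–S,
  Levene-after-log-outlier-removal, Bonferroni capping and a
  first-interaction pseudoreplication filter.
* **Synthetic interaction generator.** A seeded simulator emulating the
  structure of such field data (phase-structured call sequences,
  species-specific click triggering at ~44 / ~21 ms IPI, ≤ 6% duty-cycle
  click bursts, pure-pursuit bat flight, −1.01 m/s dives, 3.7 cm-scale
  positional noise, treatment-conditional outcomes) with per-interaction
  ground truth for parameter-recovery testing.

## Worked example

```r
library(batmoth)

cfg <- simulationConfig(seed = 7L)     # study-condition defaults
ds  <- generateDataset(60, cfg)        # 60 seeded interactions
m   <- runAnalyze(ds)                  # per-interaction metrics

head(m[, c("species", "treatment", "outcome", "ipi_before_first_click_ms",
           "mbmd_m", "contact", "mean_z_speed_mps", "fraction_unaffected")])
```

```
         species treatment      outcome ipi_before_first_click_ms      mbmd_m
1 P_roseicapitis        T+ capture_drop                  41.91712 0.020086047
2 P_roseicapitis        T+ capture_drop                  39.32648 0.010722141
3      C_martini        T+  non_capture                  28.34168 0.300866098
4 P_roseicapitis        T+      consume                  42.78210 0.005087242
5 P_roseicapitis        T+  non_capture                  44.88769 0.361473204
6      C_martini        T+ capture_drop                  23.62078 0.012302326
  contact mean_z_speed_mps fraction_unaffected
1    TRUE      -0.68885208           0.8000000
2    TRUE      -0.03636917           0.8055556
3   FALSE       0.00167139           0.7666667
4    TRUE      -0.86135823           0.8115942
5   FALSE      -0.00106547           0.7419355
6    TRUE       0.01596159           0.8309859
```

Row 5 is the story in miniature: a tymbaled *P. roseicapitis* clicked in
early approach (IPI ≈ 45 ms) and escaped (mBMD ≈ 0.36 m, well above the
3.7 cm contact floor), while about 74% of the bat's echoes were
unaffected by its clicks. Captured moths sit below the contact floor
(`contact = TRUE`), and the dive proxy (mean z-speed over the 333 ms
before closest approach) separates divers (row 1, −0.69 m/s) from level
flyers (row 6, ≈ 0).

Exact statistics work directly from counts:

```r
tab <- contingencyTable2x2(25, 25, 3, 22, groups = c("T+", "T-"))
relativeRiskCapture(tab)     # 1.76: ablated moths ~1.8x more likely captured
fisherExact(tab)
#> Fisher exact: p = 0.001983, OR (CMLE) = 7.153, 95% CI [1.806, 42.04]
exactBinomialRejection(14, 22)
#> Exact binomial: 14/22 = 64%, one-sided p = 0, 95% CI [0.44, 1.0] (degenerate null p0 = 0)
```

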