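---
title: "Methods: quantifying acoustic aposematism in bat-moth interactions"
author: "batmoth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying acoustic aposematism in bat-moth interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batmoth)
```

# The problem

Tiger moths (Erebidae: Arctiinae) answer attacking, echolocating bats
with trains of ultrasonic clicks produced by thoracic tymbal organs. In
chemically defended species these clicks can work as acoustic warnings
(aposematism); some species additionally perform evasive dives. A field
trial releases moths whose tymbals are intact (T+), surgically ablated
(T−) or sham-operated (S) into a bat foraging area, records each
encounter with synchronized ultrasonic microphones and 60 Hz infrared
cameras, and scores the outcome as non-capture, capture-then-drop, or
consume. `batmoth` implements the quantitative analysis of such trials:
acoustic attack-phase measures, a sonar-jamming plausibility check,
3-D flight kinematics, and exact outcome statistics — plus a seeded
generator of synthetic encounters so the entire pipeline can be
exercised and validated with known ground truth.

# Acoustic measures

The inter-pulse interval (IPI) is the time between the onsets of two
sequential bat calls; it shortens as an attack progresses. Phases are
assigned from the IPI in milliseconds:

| phase | IPI (ms) |
|---|---|
| terminal buzz | < 8 |
| late approach | [8, 21) |
| early approach | [21, 50) |
| search | ≥ 50 |

The field-reported phase ranges leave the
values 7–8, 20–21 and 49–50 ms unassigned; `classifyPhase()` closes the
gaps with half-open intervals so that every positive IPI has exactly one
label, consistent with the approach phase being defined as IPI below
50 ms. All IPIs below 8 ms count as buzz; whether 5 ms is a hard floor
in the field convention is ambiguous, and we treat it as descriptive.

The moth's *reaction IPI* is the IPI of the last call pair ending at or
before the first detected click (`ipiBeforeFirstClick()`); a call onset
exactly at the click time counts as preceding. Bats that abort an
attack return to search-phase IPIs without a buzz and therefore produce
fewer calls; `countCallsBetweenSearchPhases()` counts calls from the
first call terminating a sub-50 ms interval (inclusive) until the
preceding IPI first returns to ≥ 50 ms. Inclusivity of the first call
is our convention (the verbal definition does not fix it) and is pinned
by a brute-force reference walk in the tests.

# Critical-window jamming assessment

Clicks could in principle interfere with the bat's ranging if they
arrive during the narrow window in which the bat expects the echo. For
every call produced between search phases, the echo of a call emitted
at its midpoint returns after $2d/c$ (distance $d$ from the smoothed
paths at the midpoint, $c = 343$ m/s); the critical window is the
return time ±2 ms (total width 4 ms; the
closed interval is our convention). A click emitted at time $t$ and
distance $d_t$ arrives at $t + d_t/c$; an echo is scored as potentially
jammed iff any click arrival falls inside its window. The fraction of
unaffected echoes summarizes each interaction. Calls (or clicks)
without 3-D coverage at their instant are excluded with a recorded
reason rather than extrapolated, and an interaction with zero usable
echoes reports an `NA` fraction rather than failing. By default only
the first attack bout is assessed (matching single-bout analysis);
`allBouts = TRUE` pools bouts.

# Kinematics

Raw 60 Hz tracks carry reconstruction error; the calibrated volume's
maximum spatial error of 3.7 cm anchors all noise reasoning in the
package. `smoothTrajectory()` fits, per axis, a least-squares smoothing
spline whose residual sum of squares meets a tolerance (the `spaps`
idea): the smoothing parameter is found by root-finding on
RSS(λ) = tol, with tolerance 0 reducing to cubic interpolation. The
default budget is $n\sigma^2$ per axis with $\sigma = 0.037/\sqrt{3}$ m,
i.e. the per-axis noise implied if the 3.7 cm error floor were spread
isotropically. The smoothing parameter search is capped at λ = 100
because the penalized solve degrades numerically beyond that, and a
straight-line fit is already reached well before.

The minimum bat–moth distance (mBMD) is found on a dense 1 ms grid and
refined by golden-section optimization, robust to the multiple local
minima of pursuit geometries. Distances below the 3.7 cm floor are
reported with a `contact` flag — bat and moth cannot be distinguished
at that scale, so the numeric value should be read as "≤ 3.7 cm".

The dive proxy is the time-averaged vertical speed of the moth over the
0–333 ms before the minimum distance, computed from the smoothed path
(smoothed rather than raw positions, the defensible choice given the
error floor).
Negative is downward. `classifyEvasion()` labels an interaction a
*dive* when this proxy is at or below −0.5 m/s, a *turn away* when the
horizontal heading rotates by ≥ 90° within the window without the dive
criterion, else *no evasion*. Field scoring of evasion is done by eye;
these thresholds are this package's explicit, configurable conventions,
not a field procedure — −0.5 m/s sits halfway between level flight
and the ~−1 m/s dives of diving moths, and the turn criterion is a
convention because turn-aways are rare enough to be excluded from the
comparisons anyway.

# Outcome statistics

Statistical comparisons pool "capture, drop" and "consume" into
*captured*. For a 2×2 table of non-capture vs captured across two
treatment groups the package reports:

* the relative risk of capture (unprotected over protected group,
  reported to one decimal),
* Fisher's exact two-sided p (total hypergeometric mass of tables no
  more probable than the observed one — the convention of R's standard
  implementation; other two-sided rules exist),
* the conditional-MLE odds ratio, i.e. the $\psi$ solving
  $E_\psi[A \mid \text{margins}] = a$ under the noncentral
  hypergeometric law, with exact conditional 95% bounds from inverting
  the one-sided tests at 2.5% each side (0 and ∞ at boundary tables).

This machinery is implemented directly on the conditional likelihood
(log-scale, root-finding), and is cross-checked in the tests against
both `stats::fisher.test` and a brute-force enumeration oracle over all
tables with the observed margins.

Palatability uses the one-sided exact binomial test of the rejection
rate of captured moths with null p₀ = 0 ("perfectly palatable"). That
null is degenerate — any rejection refutes it trivially — so the result
carries a flag and the informative output is the exact one-sided 95%
lower (Clopper–Pearson) confidence bound, $q_{Beta}(0.05;\,x,\,n-x+1)$.

Supporting tests are delegated to the standard implementations (Welch
t, Mann–Whitney–Wilcoxon, Kolmogorov–Smirnov, Levene via `car`), with
the Levene variant first log₁₀-transforming and removing values more
than 1.5 IQR above the 75th percentile — upper side only, exactly as
the field outlier rule is phrased. Bonferroni adjustment multiplies
by the family size and caps at 1; the per-species treatment comparisons
form one family (m = 3). Pseudoreplication is controlled by keeping
only each moth's first interaction (earliest timestamp, deterministic
tie-break by interaction id).

Two field-reported sham-group odds ratios (9.44 and 13.35) do not
follow from the underlying 5/12 and 16/30 counts under the conditional-MLE
convention (we compute 4.97 for the first); the pooling behind them is
unclear, so the package makes no attempt to reproduce them. Whether the
field-reported Fisher p-values are pre- or post-Bonferroni is likewise
ambiguous; the report emits both.

# The synthetic generator

`simulationConfig()` defaults encode the study conditions the analysis
should recover:

| parameter | default | source of the value |
|---|---|---|
| phase IPI ranges (ms) | search 50–120, early 21–49, late 8–20, buzz 5–7 | phase definitions; 120 ms observed wild-bat maximum |
| trigger IPI (ms) | 44 (*P. roseicapitis*), 21 (*C. martini*) | mean reaction IPIs |
| response SD (ms) | 3 | modest between-moth variation (our choice) |
| click train | 8 clicks/cycle, 12 Hz, 0.5 ms clicks, burst over 15% of cycle | arctiine-scale clustering; duty cycle 4.8% < 6% cap |
| dive z-speed (m/s) | −1.01 ± 0.25 SD | mean diving speed |
| p(evasion) | 0.43 / 0.17 | hand-scored dive rates |
| outcome table | non-capture 50/12/42% etc. | outcome tabulation; capture split by rejection rates 14/22, 15/16 |
| speeds (m/s) | bat 5, moth 1.5 | typical vespertilionid / moth flight (our choice) |
| position noise (m/axis) | 0.037/√3 | 3-D error floor |
| non-capture standoff (m) | 0.33 | mean escape mBMD |
| frame rate (Hz) | 60 | camera rate |
| abort probability given clicks | 0.5 | our choice; escapes of clicking moths split between deterrence and evasion |

Within a phase, IPIs are drawn i.i.d. uniformly over the configured
range — field descriptions give ranges, not distributions, and the
uniform is the simplest consistent choice. Phase dwell times for wild
*Myotis* are not well characterized; the defaults (1.0, 0.5, 0.25, 0.25 s) are
placeholders at the scale of complete attack sequences and are
configurable. Aborted attacks (drawn with the configured probability
when a clicking moth escapes) skip the buzz and return to search-range
IPIs, which is what makes deterred bats produce fewer calls.

One generator subtlety matters for parameter recovery. If clicks simply
started at the first i.i.d.-uniform IPI below the trigger threshold,
the *measured* reaction IPI would be biased low (the first uniform draw
below 44 averages ≈ 32, not 44). The generator therefore draws each
moth's response threshold from a normal around the species mean (SD
3 ms, clamped into the phase ranges) and warps the single triggering
interval so it realizes the drawn value exactly (nudged just below so
the strict `<` trigger rule fires there; earlier intervals exceed the
threshold by construction). The measured reaction IPI then equals the
drawn truth and its sample mean is an unbiased estimate of the
configured trigger — which is what the recovery tests assert.

Trajectories use pure pursuit (bat heads toward the moth's current
position) with regulated encounter timing: captures close at the end of
the attack — the bat trails its target and accelerates smoothly rather
than teleporting, keeping the path continuous for the spline — and
failed attacks shadow outside the standoff distance until at least
350 ms after the dive trigger, then veer off tangentially. The
regulation guarantees the 333 ms pre-encounter window falls inside the
dive segment, so the z-speed proxy measures the configured dive speed
rather than a mixture with level flight. At capture the bat holds the
moth's exact coordinates for ~10 frames (shared noise draw), which
keeps smoothed capture mBMDs below the 3.7 cm floor.

## What the generator does and does not emulate

It emulates event timing, not waveforms: no spectra, no call detection,
no intensities. The bat does not learn; moths do not steer toward or
away from the bat in the horizontal plane; click detectability can be
degraded via a miss probability (field microphones missed about half of
real click responses) but defaults to perfect detection. Passing the
recovery tests shows the pipeline measures what the generator encodes
at field-realistic noise; it does not show the generator reproduces
every feature of real encounters. Quantities that depend on the actual
field recordings — unaffected-echo percentages, absolute call counts,
first-click distances and the field test statistics — are checked only
for qualitative sanity (e.g. the unaffected fraction lands in the
weak-jamming regime, around 0.8 with these click-train defaults,
near but a little below the ~0.86 reported from field audio).

# Numerical choices and problem sizes

Exact p-values compare hypergeometric masses with a relative slack of
1e−7 (ties at the observed probability count); conditional roots are
found on the log-odds scale over ±40 with tolerance 1e−10. The mBMD
grid step is 1 ms. Degenerate inputs are first-class: empty click
trains, single-call streams, zero-margin tables and zero-echo
interactions all return typed, flagged results rather than errors,
while impossible requests (negative distances, non-monotone onsets,
probability rows that do not sum to 1) fail validation with the
offending record named.

The test suite exercises exhaustive Fisher enumeration up to table
total 20 plus 300 random tables to total 60, and parameter recovery on
500 simulated interactions (the acceptance script uses 400); these
sizes keep a full run in a few minutes on a laptop while leaving the
Monte-Carlo bands meaningful. Recovery assertions use two standard
errors (or exact binomial 95% bands), so each is an honest 95% check
against the configured truth.

# Known limitations

* The evasion thresholds are conventions; hand-scored field labels
  should be preferred when available (the stats stage accepts them).
* The smoothing tolerance is tied to a global error floor, not
  per-interaction reconstruction residuals.
* Multi-bat recordings and multi-bout pooling are supported only
  mechanically (`allBouts`); the analysis was designed for single-bout,
  single-bat encounters.
* The generator's pursuit regulation trades kinematic realism near the
  encounter for measurement validity of the dive proxy; bat flight in
  the last 100 ms of real captures is not modelled.
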