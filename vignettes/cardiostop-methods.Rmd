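---
title: "Models and methods behind cardiostop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cardiostop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiostop)
```

`cardiostop` implements, end to end, the computational machinery of a
cardiac-gated stop signal experiment: stimulus delivery locked to the
cardiac cycle, adaptive stop-signal-delay (SSD) staircases, race-model
behaviour, integration-method SSRT estimation, exclusion filtering, resting
heart-rate-variability and interoception indices, and the statistics layer
that compares conditions and screens individual-difference correlations.
Because human data for such a task are not redistributable, the package is
built around a synthetic cohort generator whose defaults encode the study
conditions the analysis chain is calibrated to. This vignette documents the
models, the tunable parameters, and the design decisions taken where the
procedure left genuine freedom.

## The task and its timing model

Each trial is scheduled off the participant's (simulated) ECG. Before a
trial, the R-peak stream is monitored for three fresh inter-beat intervals
(IBIs); the next R-peak is predicted as

> last R-peak + median(last 3 IBIs),

the median giving robustness to a single ectopic-like interval. Systole is
operationalised as R + 290 ms (near the T-wave peak, when aortic/carotid
baroreceptors fire); diastole as R − 10 ms (the quiescent period). On stop
trials the *stop* cue is phase-timed and the go cue precedes it by the
current SSD; on phase-timed go trials the go cue itself lands on the phase;
control go trials place the go cue at phase-minus-tracker-SSD with no stop
cue, so that go-onset position within the cycle cannot act as a subliminal
cue for trial type. If a large SSD would schedule a go cue before the
scheduling moment, the whole event rolls to the next predicted beat — never
a negative wait. Trials are separated by a 1000-ms inter-trial interval plus
the 3-beat monitoring period.

A session is 360 trials in four blocks of 90: 60 each of stop-systole,
stop-diastole, go-systole, go-diastole, and control go trials drawing from
the systole and diastole trackers (240 go, 120 stop). These counts are exact
for every seed, and blocks are bookkeeping only (no behavioural block
effects are modelled).

*Timing precision.* For every event we report the signed offset from the
phase-anchored event time to the *nearest* true R-peak. The reference beat
is chosen by minimising the absolute offset because the anchoring beat is
not otherwise identifiable post hoc. Precision is summarised per trial type
and per intended phase as the fraction of events within 200 ms of their
per-event target (exactly +290/−10 ms for phase-timed events; phase minus
SSD for control go cues), plus a histogram in 50-ms bins spanning
[−500, 800] ms by default (wide enough to cover a full cycle at the default
58 bpm; the range extends automatically if events fall outside it).

## Behaviour: the independent race

A response is produced on a stop trial iff the go process finishes before
the stop process:

> respond ⇔ T_go < SSD + L(phase) + ε,  ε ~ N(0, 20 ms).

Go finishing times are ex-Gaussian (the standard positively skewed RT
model), with population defaults μ = 370 ms, σ = 50 ms, τ = 100 ms — a mean
go RT of 470 ms. True stop latencies are phase-specific: 203 ms when the
stop cue lands at systole and 221 ms at diastole, with a 25-ms
between-participant SD. The 20-ms within-trial stop noise is a deliberate
choice: a perfectly deterministic stop latency makes the one-up/one-down
staircase oscillate degenerately around a knife-edge. Go finishing times
beyond the 1000-ms response window are omissions, as are rare attentional
lapses (2% of trials by default). Choice errors (wrong arrow direction) are
not modelled.

The staircase starts at 200 ms and moves ±50 ms (down after a failed stop,
up after a successful one), floored at 0 ms with no ceiling — a negative
delay is physically meaningless, and the race model needs no upper bound.
The rule converges on the 50% inhibition point; consequently the
equilibrium delay sits near `median(go RT) − stop latency`, so a *shorter*
stop latency is expressed as a *longer* tolerated SSD. The package's tests
verify both the 50% convergence (±2 percentage points over the final 9,000
of 10,000 simulated stop trials) and the monotone *decrease* of equilibrium
SSD as true stop latency rises.

## SSRT estimation

SSRT is estimated by the integration method: omissions are appended to the
go-RT pool as 1000-ms entries (the response-window maximum, the consensus
replacement rule), the pool is rank-ordered, the RT at rank
⌈n · p(respond|stop)⌉ (1-based, clamped to [1, n]) is read off, and the
condition's mean SSD — the mean of the delays actually in force across that
condition's stop trials, the conventional reading of "the tracker's SSD
value" — is subtracted. `p(respond) = 0` leaves the estimate undefined;
`p(respond) = 1` is computed at the top rank but flagged unreliable.

Two readings of "the n go reaction times" are computable. The default pools
all responded go trials of the session (phase-timed and control), because
the go process is common to both stop conditions and the phase manipulation
produces no go-RT effect; `ssrt_go_pool = "per_phase"` restricts the pool to
go trials whose onset came from that phase's timing or tracker, for users
who prefer phase-matched go distributions.

## Exclusion rules

The cohort filter runs in two ordered passes. Pass 1 removes strategic
waiters: anyone whose mean go RT or mean SSD, in either cardiac condition,
exceeds the entrant-group mean by more than 2 SD. The rule is one-sided
because only *long* RTs and delays indicate waiting. Pass 2, computed only
over pass-1 survivors, removes participants whose per-tracker inhibition
success deviates from the survivors' mean by more than 2 SD in either
direction — a staircase can fail to converge from above or below. Reasons
are recorded per exclusion, and pass-2 statistics never include pass-1
exclusions.

Two pathological phenotypes exercise these rules. *Waiters* have their go-RT
location parameter inflated by 3 between-participant SDs. *Non-convergers*
draw their stop latency from an asymmetric bimodal mixture: the stop process
engages at the profile latency on only 15% of trials and is effectively
absent (latency ~ N(1200, 100) ms) otherwise. The asymmetry is essential: a
symmetric bimodal mixture merely widens the psychometric function and the
staircase still finds a 50% point, whereas with an engagement probability
below one half the 50% point falls below the 0-ms SSD floor and mean
inhibition success stalls far beneath 50% — the phenotype the convergence
filter exists to catch. A caveat follows from the rule itself: with 2-SD
thresholds computed on contaminated groups, a simulated 60-entrant cohort
does not retain *exactly* its compliant membership in every replicate
(outliers inflate the group SD and can mask each other); the package's
deterministic check of the 60 → 52 → 46 flow therefore uses a constructed
summary-level fixture, while simulated phenotypes are tested as enrichment
properties.

## The synthetic cohort

Per-participant traits are drawn through a Gaussian copula over five
latents — resting heart rate, true RMSSD, interoceptive sensibility, and the
two phase latencies — with pairwise targets in `effect_structure`. Defaults:
heart rate 58 bpm (SD 10.05) anticorrelated with RMSSD (−0.54); RMSSD
correlated with sensibility (0.32) and with the diastole stop latency
(0.31); sensibility with the systole stop latency (0.37); and a 0.6 trait
correlation between the two latencies. RMSSD is mapped uniformly onto
[20, 60] ms (mean ≈ 40 ms). Questionnaire scores use instrument
conventions, since no numeric ranges are part of the task design itself:
45 body-perception items on an ordinal 1–5 scale around the sensibility
latent; a trait-impulsivity total on the 30–120 range (N(62, 9), rounded
and clamped); confidence on a continuous 0–100 visual-analogue scale.

RR-interval series are lag-1 autoregressive Gaussian IBIs (φ = 0.8, a value
giving sinus-like smoothness) scaled so that the expected root mean square
of successive differences equals the participant's target: for an AR(1)
process, Var(ΔIBI) = 2σ²(1 − φ), so σ = RMSSD/√(2(1 − φ)). IBIs are clamped
to the physiological band [300, 2000] ms. This is deliberately the simplest
process with a controllable RMSSD; it does not model respiratory sinus
arrhythmia as an oscillation, ectopy, or non-stationarity, so timing
precision on real ECG (movement artefact, drifting rate) will be worse than
the >99% the generator yields — the tests establish the machinery's
correctness at its design point (≥90% within 200 ms), not field
performance. The rendered ECG is likewise minimal: Gaussian R (tall,
narrow) and T (lower, wider, +290 ms) deflections — exactly enough to make
threshold detection, its T-wave confusability, and the 250-ms refractory
window (chosen to sit beyond the physiological QT interval) testable.

Heartbeat counting uses six windows of 25–50 s presented in random order;
the reported count is a binomial thinning of the true count at the
participant's perceptual ability plus integer noise, floored at zero, and
confidence is constructed to correlate with realised per-trial accuracy at
the participant's metacognitive coupling, drawn from U(−0.9, 0.9) — a wide
heterogeneity chosen so that six-trial awareness estimates remain
informative at the cohort level (the recovery test demands rank correlation
above 0.8 at n = 200). Interoceptive accuracy uses the canonical
heartbeat-tracking score, `1 − |actual − counted|/actual` per trial,
unclipped — wild overcounting legitimately scores negative.

## Statistics layer

Two-level repeated-measures comparisons are reported as paired t-tests with
95% CIs of the mean difference (mathematically equivalent to the two-level
ANOVA; η² is derived as t²/(t² + df)). Regressions are ordinary least
squares with an intercept and an overall F test. The individual-differences
screen computes two-sided Pearson correlations over all 45 pairs of the 10
indices (both SSRTs, both SSDs, RMSSD, bpm, trait impulsivity, and the
three interoception dimensions) with pairwise deletion (≥4 complete cases),
then applies Benjamini–Hochberg adjustment — step-up with cumulative
minimum, capped at 1 — across the pairs actually tested; missing awareness
values simply propagate as missing. Tests cross-check the adjustment
against an independently coded step-up oracle, and SSRT against an
independently coded rank-walk oracle.

## Numerical and scale choices

Everything stochastic is reproducible: a `seed` argument (or `config$seed`)
scopes a private RNG stream without disturbing the caller's. Problem sizes
in the test suite are chosen for desk-scale verification: staircase
convergence over 10,000 stop trials; timing precision pooled over a
46-participant cohort (16,560 events); SSRT-vs-oracle agreement on 1,000
random instances; parameter recovery and the systole < diastole direction
over 100 replicate 46-participant cohorts; type-I calibration of the phase
contrast over 200 null cohorts, with the ~5% rejection rate accepted inside
a 3-standard-error binomial band fixed in advance. A run of the full suite
takes on the order of two minutes on one core.

## Known limitations

- The ECG and RR models are minimal by design (no PQRST morphology beyond R
  and T, no respiratory oscillation, no ectopy); detection thresholds are
  automated stand-ins for an operator-set interactive threshold.
- The integration estimator carries the method's small finite-sample bias
  (here about −7 ms at the design point, well inside the 25-ms recovery
  tolerance); no parametric or Bayesian SSRT estimators are provided.
- Frequency-domain HRV, heartbeat-discrimination tasks, and
  mixed-effects/Bayesian reanalyses are out of scope.
- Published group-level values from any real cohort depend on that cohort's
  unreleased data; the package's generator targets the same design
  parameters, so agreement is directional and calibrational, not numeric
  reproduction.
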