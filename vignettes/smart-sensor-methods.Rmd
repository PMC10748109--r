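---
title: "Smart-sensor monitoring of cell-expansion batch runs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smart-sensor monitoring of cell-expansion batch runs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smartsensr)
```

## The monitoring problem

Automated perfusion bioreactors for T-cell expansion log a small set of hard
sensors at high frequency — here eight channels polled every 10 s:
temperature (`T`, °C), dissolved oxygen (`DO`, % air saturation), `pH`, gas
flow (`GasFL`, mL/min), glucose and lactate concentration (`Glu`, `Lac`, mM,
enzymatic in-line sensors), and exhaust O₂/CO₂ (%). Perfusion (media
exchange) is driven by a PID controller reading the glucose signal, so
non-biological artefacts on that signal — transient bubbles in the sensing
line, door openings, mechanical outages — can trigger spurious feeding
responses. The operator needs a layer above the raw signals that (i) flags
such artefacts, (ii) scores overall process stability, and (iii) fuses the
individual indicators into a single, higher-confidence recommendation.

`smartsensr` implements that layer as six *smart sensors* plus a consensus
vote, along with a seeded synthetic batch-run generator, because the
historical platform data the calibration derives from are proprietary.

## The six smart sensors

All rolling statistics use a trailing window of `window_min` minutes
(default 30, matching the platform's sliding data buffer) and a population
standard deviation (dividing by *n*; the window statistic is descriptive,
not inferential — the sample form is available via `estimator = "sample"`).
No smart sensor emits output before one full window has elapsed ("warm-up").

### Signal disturbance indicator (SDI)

At sample *i*, with trailing window mean *m* and standard deviation *σ*
computed over the window **excluding** sample *i*, a *disturbance* is
recorded when both

&nbsp;&nbsp;Glu_i < m_G − κ·σ_G  and  Lac_i < m_L − κ·σ_L

hold for κ = 2, graded small/medium/large by the largest κ ∈ {2, 3, 4}
satisfied. The band is one-sided (below) because the event of interest is a
simultaneous *drop*; the conjunction of the two single-channel conditions is
the simultaneity ("covariance") requirement — an explicit rolling covariance
is attached to the output only as a diagnostic. The SDI alert fires when at
least `min_count` disturbances (default 3 "bubbles") fall inside one
trailing 30 min window; the counting horizon is not fixed by the source
calibration, so it is config-exposed (per-window counting is the default
rather than cumulative per-run counting, which would latch permanently).

### Bollinger-band monitors (glucose, lactate)

Over the same trailing window, bands are placed at `K` rolling standard
deviations around the moving average (default `K = 8`, the platform
calibration; the window length for the band statistics is not separately
specified, so it shares the 30 min default). The proximity of the reading to
the nearer band, as a percentage of the band width,

&nbsp;&nbsp;DVp = 100 · min(upper − x, x − lower) / (upper − lower),

is 50 at the moving average, 0 on a band, negative outside. The alert fires
at `DVp ≤ threshold`. One printed calibration gives glucose 15% in the
narrative but 25% in the threshold table; the table value (25%) ships as the
default and 15% is retained as `boll_glu_text_preset`. A zero-width window
(flat signal) leaves DVp undefined; the default policy is *no alert* — a
perfectly flat signal is maximally stable — and is config-exposed because
the degenerate case is a convention, not physics. The printed minimum
formula for the smallest distance contains an obvious typo (a difference
where a two-argument minimum is meant); the percentage definition and the
stated intent force `min(DV_iu, DV_il)`.

### Weighted weighted average (WWA)

Sensors are split into a setpoint group (SP: Glu, O₂, CO₂, T, GasFL) and a
non-setpoint group (NSP: Lac, pH, DO, compared to reference values). Per
group,

&nbsp;&nbsp;WWA = (1/n) Σᵢ sᵢ · vᵢ · wᵢ,

with sᵢ a distance of sensor *i* from its reference, vᵢ a static scaling
weight (0.5 for Glu and DO, 1 otherwise), and wᵢ ∈ {0, 1} a criticality gate
that opens when the **raw channel-unit** distance reaches the critical range
distance (Glu 0.8, O₂/CO₂/T 0.5, GasFL 0.2, Lac 3, pH 0.35, DO 27.5).
Two points were genuinely open and are resolved as follows:

* **Distance measure sᵢ.** The source never states whether sᵢ is raw or
  normalized. Raw distances are incommensurable with the printed unitless
  alert thresholds (0.1 SP, 0.35 NSP) — a DO excursion of 27.5 %-points
  would dominate any glucose term — so the default is the relative distance
  |x − ref|/|ref|, with raw distance available via
  `wwa_distance = "raw"`. When a scheduled reference is exactly 0 (the CO₂
  setpoint steps to 0 in one historical run) the relative form is undefined
  and that sensor falls back to its raw distance.
* **n.** Taken as the count of *active* sensors in the evaluated group (5
  SP / 3 NSP when all are online), not all eight; an offline channel is
  dropped and n reduced, so dropout does not bias the average downward.

Mid-run setpoint changes (the CO₂ schedules "5, 0" and "5, 1.9") are
stepwise reference schedules; the change time is not printed and defaults to
day 3 (mid-run), exposed as `co2_change_day`. The alert is strict:
score > threshold.

### Fuzzy stability controller

Process stability is graded on the absolute distance of glucose from its
setpoint through two complementary piecewise-linear fuzzy sets: "normal"
with support [0, 1.2] and "alert" with support [0.4, ∞). Full normal
membership up to 0.4, full alert membership from 1.2, linear in between —
the three printed worked examples (distance 0.8 → 0.5/0.5, 1.0 → 0.25/0.75,
1.5 → 0.0/1.0) fix the interpolation uniquely and are reproduced to within
1e-12 (floating point on the breakpoint differences; the saturated cases are
exact). The alert fires when the alert membership strictly exceeds 0.45.
Only the glucose pair ships enabled; `membership()` accepts any pair for
other channels.

### Consensus

The six binary alert streams are summed per timestamp; a *consensus event*
is a maximal run of counts ≥ 3 (of 6). Because the published per-run event
counts are small integers over multi-day runs, above-threshold episodes are
merged into one event when separated by less than a merge gap
(default 30 min) — the gap is a declared convention, the source does not
define how close two episodes must be to count as one point. An optional
minimum-duration filter (default off) anticipates a duration-based upgrade
of the consensus rule. Per-sensor *coincidence* counts an event as detected
by a sensor if the sensor alerts for at least one in-event timestamp.

`summarize_coincidence()` derives the full undetected-event table:
per-sensor undetected totals Σb and fractions %Σb = Σb / (total events), and
per-run totals Σs with %Σs = Σs / (grand total of undetected counts). The
published table's footnote describes the %Σs denominator as the total event
count (57), but the printed values are consistent only with the grand
undetected total (122); the implementation follows the printed numbers.
Percentages round half-up to the printed precision. The published
six-sensor average consensus (65%) is reproducible only as the mean of the
*integer-rounded* per-sensor percentages ((25+72+42+74+86+88)/6 = 64.5 → 65);
the unrounded average is 64.3. The implementation therefore averages the
rounded figures, for both the per-sensor and per-run averages (the per-run
average is exactly 80 either way).

```{r summary}
s <- reported_alert_summary()
summarize_coincidence(s$totals, s$detected)
```

## The synthetic generator: what it emulates, and what a green test means

The historical batch data are proprietary, so `generate_run()` draws runs
with the *qualitative* structure described for them: a pre-stabilization
phase (default 12 h, noise inflated 3×) while channels converge to their set
conditions, then a stable perfusion phase. Each channel follows

&nbsp;&nbsp;x(t) = target + (init − target)·e^(−t/τ) + drift·t +
A·sin(2πt/P) + ε,  ε ~ N(0, σ²),

which encodes: glucose converging exponentially to its setpoint, lactate
drifting upward from fresh-media levels toward its 10 mM reference, DO
declining from ~90 toward 72.5 % a.s. with a daily oscillation, pH declining
from 7.4 to 7.1, temperature oscillating ±0.08 °C about 37, and tightly
fluctuating exhaust gases and gas flow. The trend forms and all absolute
noise scales (e.g. Glu 0.15 mM, pH 0.004) are the package's own declared
conventions — the source figures fix signs and shapes, not magnitudes — they
were chosen once for plausibility and are not tuned against test outcomes.
Injectable disturbances reproduce the described anomalies: `bubble_drop`
(simultaneous Glu+Lac dip, amplitude in local-σ multiples),
`shutdown` (Glu/Lac ramp to ~0 and recover, all other sensors offline — the
~8 h mid-run mechanical outage of one historical run), `channel_dropout`,
and `temperature_dip`. Shipped profiles `run1_like` … `run5_like` mirror the
five historical regimes (run 2: CO₂ offline, constant gas-flow reading;
run 3: the day-3 shutdown; run 5: glucose setpoint 19 mM, slower
stabilization, lower pH).

A green synthetic test therefore establishes that the *detectors recover
events the generator's stated world contains* (e.g. ≥95% of 5σ bubbles
within one window; a shutdown produces a consensus event; a stable run does
not), and that all derived arithmetic matches its oracles. It does **not**
establish detection performance on real runs: real sensor noise is neither
Gaussian nor stationary, real glucose dynamics include PID feedback
structure the generator deliberately omits (no mechanistic
growth/metabolism model), and the published per-run alert counts from the
proprietary data are not reproducible and are not targets.

## Numerical choices and degenerate inputs

* Rolling moments use exact-summation rolling means of the centred series
  (`data.table::frollmean(..., algo = "exact")` on x − x̄); variance is
  clamped at 0 before the square root. Equivalence with naive per-window
  recomputation is property-tested.
* Warm-up samples carry `NA` scores and never alert (no evidence → no
  alert); the same rule applies to timestamps where a required channel is
  inactive.
* Zero-variance windows: SDI conditions use strict inequalities, so a flat
  pair of channels never fires; Bollinger follows the degenerate policy
  above.
* Time is stored in days (matching run plots) but indexed by sample count;
  window lengths in minutes are converted by rounding to the nearest whole
  number of samples and must span ≥ 2 samples.
* Resampling to a coarser grid (`align_runs()`) requires an integer interval
  ratio and aggregates by trailing means, stamping each block with its last
  source timestamp; a block is active if any source sample is active.
* Half-up rounding (`round_half_up()`) is used for all printed-precision
  summary figures, since banker's rounding would break the published 64.5 →
  65 average.
* The generator saves and restores the caller's RNG state, so seeded
  simulation does not perturb a surrounding analysis.

## Limitations

* Thresholds and weights ship as the published calibration and are fully
  config-exposed (`pipeline_config()`), but no recalibration/learning from
  data is provided.
* The fuzzy layer is a membership threshold, not a rule-base inference
  engine; no defuzzification beyond the single threshold.
* The consensus merge gap and the CO₂ setpoint change day are conventions;
  analyses sensitive to either should vary them explicitly.
* No live acquisition, streaming, or control-system integration: input is
  the batch-run CSV contract (`time_days,T,DO,pH,GasFL,Glu,Lac,O2,CO2`,
  empty cells = inactive).
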