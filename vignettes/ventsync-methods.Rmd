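---
title: "Models and methods behind ventsync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ventsync}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventsync)
```

`ventsync` implements the computational chain of a pediatric
pressure-support ventilation (PSV) synchronization study: waveform
simulation with injectable patient–ventilator asynchronies, breath-by-breath
event detection, Asynchrony Index (AI) outcomes, and the paired crossover
statistics and power calculations used to design and analyze such trials.
This vignette explains the models, the detection rules, the tunable
parameters, and the design decisions a maintainer should know about.

## 1. The respiratory model

Each simulated patient is a single-compartment system with resistance `R`
(cmH2O·s/L) and compliance `C` (mL/cmH2O):

\[
\dot V = \frac{P_{aw} + P_{mus} - \mathrm{PEEP} - V/C}{R}, \qquad
P_{es} = P_{es,0} + E_{cw} V - P_{mus} .
\]

`R`/`C` defaults by lung-physiology profile (normal 25/15, obstructive
60/14, restrictive 30/8, mixed 45/9) span the ranges seen in invasively
ventilated infants and young children; cohort generation draws profiles
with mixed/restrictive predominating, as in typical PICU case mixes. The
volume dynamics are linear, so the simulator integrates them with an exact
exponential step at the 50 Hz sampling rate (the recurrence
\(v_{k+1} = a\,v_k + (1-a)\,C P_k\) with \(a = e^{-\Delta t/RC}\)), evaluated
as a recursive filter — there is no accumulation of Euler error.

The inspiratory muscle pressure `Pmus` is a raised cosine: it rises over
the neural inspiratory time `Ti` (default 0.7 s at 28 breaths/min, scaled
with the breath period in cohorts) and releases over `Ti/2`. Two analytic
landmarks of this pulse anchor all timing:

- the **observable effort onset**: the instant the Pes deflection reaches
  `pes_onset_frac` (default 0.12) of its amplitude — the same convention
  the effort detector uses, so simulated latencies and measured response
  times refer to the same origin;
- the **neural inspiratory termination**: the midpoint of the release limb
  — the point the Pes-based detector estimates as the midpoint of the
  post-nadir rapid rise, against which cycling errors are measured.

A smooth (differentiable) pulse was chosen deliberately: sharp-cornered
efforts produce spurious failures of the expiratory exponential-decay fits
that the classifier relies on.

## 2. The ventilator state machine and event injection

The simulator is *schedule-driven*: a breath-by-breath planner realizes
triggering and cycling as explicit times, then waveforms are synthesized
from those times. For a conventional arm the trigger time is computed
analytically as the moment the effort-driven flow crosses the flow-trigger
setting, plus a valve latency (~35 ms); the realized response time is
logged, and its ground-truth label (normal / trigger delay / ineffective
effort) is assigned from the same 117/234 ms bins the classifier uses. The
emulated closed-loop arm triggers ~45 ms after the observable effort onset
and cycles tightly at neural termination; it is an idealized,
oracle-synchronized stand-in and reconstructs no proprietary controller.
Pressurization follows an exponential approach to PEEP + PS with the
P-ramp time constant (default 50 ms) and a fast (~45 ms) release.

Asynchronies are injected by per-breath Bernoulli thinning of per-minute
target rates, at most one anomaly per neural breath, so every event has an
unambiguous ground-truth record:

- **IE**: a weak effort (40% amplitude) with no machine breath;
- **AT**: an extra machine cycle inserted in a quiet expiratory window,
  with no Pmus activity, and spacing constraints so it cannot satisfy the
  double-breath rule;
- **TD**: trigger latency drawn from 150–200 ms — inside the 118–234 ms
  diagnostic band with margin for the ~10 ms timing jitter of the
  detectors;
- **EC / LC**: forced cycling 150–350 ms before / after neural
  termination (beyond the ±100 ms diagnostic threshold);
- **DB**: the first cycle is cut at 45% of its expected inspiratory time,
  the effort is prolonged, and a re-trigger follows after a gap of 35% of
  the first cycle's inspiratory time;
- **cough**: a positive expiratory flow spike with a positive Pes
  transient, only on otherwise-normal breaths.

Default conventional-arm rates (IE 0.60, AT 0.42, DB 0.27, TD 1.17,
EC 0.95, LC 0.24 per minute; jittered log-normally per patient) put the
ground-truth AI near 12–13% at 28 breaths/min; the stand-alone profile
default is scaled to a mid-teens AI. The closed-loop arm multiplies these
by per-type factors (defaults: large reductions in AT/DB/TD/EC, no change
in IE, an increase in LC), reproducing the directionality such controllers
show — they cannot rescue efforts that never move the sensors (IE), and
their cycling criteria tend to lengthen inspiration slightly (LC).

Leak is a constant fractional loss (default 6%) applied to expiratory
flow; EtCO2 and SpO2 are slow AR(1) drifts around session means (43/42
mmHg and 96% for the conventional/closed-loop arms) — they are inputs to
summaries, not mechanistically modeled. Comfort-B is a per-session integer
draw (means 14/13). Cohorts randomize intervention order in blocks of
four, and per-patient/per-arm random substreams are derived by
counter-based seed splitting so that growing a cohort does not reshuffle
existing patients.

One cohort-level choice deserves emphasis: the per-patient flow trigger is
scaled inversely with resistance (clinician-tailored triggering). Without
it, high-resistance (obstructive) patients build inspiratory flow so slowly
that their *natural* response times pile up around the 117 ms boundary, and
per-session AI becomes irreducibly ambiguous — any two legitimate response
time estimators then disagree on tens of breaths per session.

## 3. Detection rules

**Breaths.** Machine cycles are found from the pressurization of the
airway-pressure channel. The onset is the interpolated start of
pressurization (Paw crossing PEEP + 0.12·PS): its latency is a property of
the ventilator (P-ramp), not of patient mechanics, whereas a flow-threshold
onset is late by tens of ms in obstructive patients. The flow-deflection
crossing remains as the fallback when the pressure channel is flat. The
inspiration→expiration transition is the interpolated fall of Paw below
PEEP + 0.8·PS, with flow-based fallbacks (expiratory-decay onset at the
peak expiratory flow, then the downward zero-crossing). Phase volumes are
trapezoidal flow integrals; passivity of each phase is assessed by a
log-linear decay fit (passive if r² ≥ 0.95 and the time constant lies in
0.05–1.5 s — a pediatric range; samples below 2 L/min are excluded as
noise-dominated).

**Efforts.** A centered rolling median (4 s) of Pes finds contiguous
negative deflections; each candidate's amplitude, onset and termination
are then measured against a *local* baseline obtained by linear
extrapolation of the preceding quiet window. The rolling median alone is
biased low when efforts occupy much of its window, and with slow mechanics
Pes drifts through late expiration (incomplete lung emptying); both biases
shifted onsets by 10–30 ms — enough to flip trigger-timing bins — and the
local fit removes them. Onset is the interpolated crossing at 12% of
amplitude (~1 cmH2O on a typical pediatric effort: the smallest deflection
clearly outside signal noise, and a steep enough point of the pulse for
low-jitter timing); termination is the midpoint crossing of the post-nadir
rise. Efforts below 1 cmH2O amplitude are discarded.

**Matching.** Greedy chronological one-to-one matching links each effort
to the earliest unmatched breath within
[onset − 80 ms, onset + 600 ms]. The 600 ms window is roughly one breath
period at the fastest pediatric rates; the 80 ms pre-trigger tolerance
absorbs the relative jitter of two independent onset estimators (a breath
onset slightly preceding its effort's detected onset is physiologic —
flow-triggering can fire before the Pes deflection reaches its detection
threshold). Greedy matching on same-width windows with sorted onsets
attains the maximum matching cardinality; the test suite verifies this
against exhaustive enumeration.

**Labels and precedence.** Response times bin as (0, 117] normal,
(117, 234] TD, above 234 IE (half-open realization of the published
integer bands). Unmatched efforts are IE; each IE counts once per effort
cycle. Unmatched breaths are AT only if neither channel shows a pre-onset
inspiratory deflection (Paw dip ≥ 0.25 cmH2O below the pre-window median,
or Pes ≥ 0.5 cmH2O below its rolling baseline). Consecutive cycles with
interposed expiratory time ≤ half the first cycle's inspiratory time are
DB (attached to the second cycle). Cycling offsets (effort termination
minus breath cycle time) of ≥ +100 ms are EC, ≤ −100 ms LC: the EC
threshold is the published one, and the LC threshold adopts its mirror
image since only EC is quantified in the source convention. Precedence: AT
and TD are mutually exclusive by construction; DB suppresses EC on the
first cycle of its pair (early cycling against a continuing effort *is*
the double-breath mechanism) and AT on its second cycle; an effort counted
IE is never also TD. One trigger-phase plus one cycling-phase minor event
may coexist on a breath. With Pes present the Pes-based rules take
priority; flow-only fallbacks (expiratory notch + ≥ 0.5 cmH2O Paw drop for
IE; an early expiratory deviation bump for EC) operate otherwise and are
documented as less specific — notably, flow-only AT confirmation is weak
because a small pre-trigger Paw dip can drown in noise.

**Artifacts.** Cough and active expiration are masked (expiratory flow
spikes > 10 L/min outside dilated pressurization windows; positive Pes
transients > 3 cmH2O above baseline; ±0.3 s padding). Masked samples and
breaths are excluded from event counting, numerator and denominator alike.

## 4. Outcomes

`compute_ai()` tallies events over the denominator *machine breaths + IE*;
Major AI (AT+DB+IE) and Minor AI (TD+EC+LC) share that denominator and the
total is computed as their sum, so the additivity identity holds to the
last floating-point bit. Period summaries average SpO2/EtCO2 over unmasked
samples, take the mean breath-by-breath leak
(`100·(Vinsp − Vexp)/Vinsp`, clamped to [0, 100] — the standard displayed
quantity; the clamp absorbs measurement noise), and band Comfort-B scores
(< 10 possible over-sedation, 12–17 adequate, > 17 agitation; 10–11 is
reported `indeterminate` since the published bands leave it unnamed).

## 5. Statistics

Normality routing uses Shapiro–Wilk (α = 0.05) together with screens on
|skewness| ≤ 2 and |excess kurtosis| ≤ 7 (type-2, the convention of common
clinical statistics packages; at n = 3 the kurtosis screen is skipped as
undefined). Parametric pairs go to the paired t-test with its t-interval;
nonparametric pairs to the Wilcoxon signed-rank test (zeros dropped,
mid-ranks for ties, exact distribution when n ≤ 25 without ties) with the
Hodges–Lehmann estimate — the median of the n(n+1)/2 Walsh averages — and
confidence limits at Walsh-average order statistics from the exact
signed-rank quantiles (n ≤ 50) or their normal approximation.
`analyze_crossover()` reports, per outcome, per-arm median (IQR) or mean
(SD) according to the route, the paired difference (closed-loop minus
conventional) with its interval, and the p-value. Period/sequence effects
are deliberately not modeled and no multiplicity adjustment is applied —
matching the simple paired analysis such trials report; both points are
stated here rather than silently assumed.

**Power.** The Wilcoxon signed-rank power uses the asymptotic relative
efficiency (ARE) method: deflate the sample size by the normal-parent ARE
3/π ≈ 0.9549, then apply noncentral-t machinery with *continuous* degrees
of freedom df = 0.9549·n − 1 and noncentrality δ = dz·√(0.9549·n):

```{r power}
wilcoxon_power(dz = 0.86, n_pairs = 21)
required_pairs(dz = 0.86, alpha = 0.05, target_power = 0.95)
```

With dz = 0.86 this yields a critical t of 2.0926 and power 0.9546 at 21
pairs, the minimum n reaching 95%. Note δ computes to 3.851; planning
tools that print δ = 3.84 for this configuration have rounded the pilot
effect size before δ (an unrounded dz ≈ 0.8576 reproduces 3.84, and with
it power 0.9535). We document the discrepancy rather than patch either
number; the ARE and the parent-distribution convention are exposed as
parameters.

## 6. Calibration and recovery studies

Two properties are verified by simulation in the test suite, at problem
sizes chosen to characterize the estimators well while keeping the default
test run brief:

- **Parameter recovery** (full pipeline): 25-patient crossover cohorts
  with 10-minute sessions per arm, across a fixed 20-seed panel. The
  conventional arm's ground-truth AI median falls in 10–16% and the
  closed-loop arm's in 4–7%; detected per-session AI tracks ground truth
  within ±2 percentage points, and the paired analysis returns a negative
  AI median difference with p < 0.05 on every seed. Per-type detection
  sensitivity and precision exceed 0.9 at default injection magnitudes.
- **Type-I calibration** (statistics layer): 200 zero-effect cohorts of 25
  pairs, generated in `null_mode` — both arms drawn from the identical
  conventional-arm distribution, which is the exchangeable null. (Setting
  the arm-effect multipliers to 1 alone is *not* a null: the two modes
  differ in natural trigger-latency distributions.) These replicates use
  the planner without waveform synthesis: the event-scheduling code path is
  identical, only the (statistically irrelevant, expensive) waveform
  rendering is skipped. The AI comparison rejects at α = 0.05 in 5% ± 2
  points of replicates, and the p-value distribution is uniform by a
  Kolmogorov–Smirnov check at smaller n.

## 7. What the simulator does and does not emulate

Simulated sessions reproduce the *timing structure* of pediatric PSV
asynchrony — trigger latencies, cycling offsets, effort/breath
correspondence, leak, slow gas-exchange drifts, cough artifacts — with
known ground truth, which is what detection and trial-statistics code can
be validated against. They do not emulate: real Pes artifacts (cardiac
oscillations, peristalsis, balloon positioning error), secretions or
circuit condensation noise, time-varying mechanics, neural phenomena such
as reverse triggering or entrainment, or any actual closed-loop
controller's behavior. Passing recovery tests therefore demonstrates the
correctness of the analysis chain under the stated generative model, not
detector performance on clinical recordings; thresholds are exposed in
`classifier_config()` precisely because clinical data would require
re-tuning.

## 8. Numerical and degenerate-input choices

- Event times are continuous seconds obtained by linear interpolation of
  threshold crossings: the ms-scale diagnostic thresholds are not
  multiples of the 20 ms sampling step.
- Decay fits run on log|flow| with a 2 L/min floor and require 8 usable
  samples; fewer is a fit failure (`is_passive = FALSE`, `tau` absent),
  never an error.
- An all-false artifact mask, an empty event list, and a record with no
  detectable breaths are all legal; a fully masked record propagates to a
  zero AI denominator, which `compute_ai()` refuses loudly.
- Readers reject missing mandatory columns and (in strict mode) time bases
  whose step deviates by ≥ 10%; units are fixed (cmH2O, L/min, mL, mmHg,
  %) and never converted silently.
- Waveform CSVs are written with 17 significant digits so read/write round
  trips are exact.
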