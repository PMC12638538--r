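---
title: "Methods: simulating and analysing bilateral pre/post motor-unit studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing bilateral pre/post motor-unit studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`crossmu` implements the full analysis chain of an acute cross-limb
(cross-education) resistance-exercise study at the motor-unit level:
13 older adults, both legs (one exercised to failure, one control),
assessed immediately before and after the bout. The chain is

1. **simulate** — a synthetic bilateral pre/post cohort with known
   injected effects (`generate_cohort()`),
2. **extract** — force metrics (MVC, force steadiness), HDsEMG
   spike-train metrics (phase firing rates, ISI variability,
   recruitment/derecruitment thresholds, cumulative spike train) and
   intramuscular MUP morphology (area, turns, negative-peak ratio,
   near-fibre jiggle),
3. **stats** — leg x time linear mixed models with estimated marginal
   means, Cohen's d, Nakagawa R², a repeated-measures t on cumulative
   spike-train deltas, and the delta-FR vs delta-MVC Pearson
   correlation,
4. **report** — publication-style tables.

The package consumes decomposed spike trains and MUP trains; the
decomposition algorithms themselves (convolution-kernel compensation
for surface grids, template matching for needle recordings) are out of
scope, as are ultrasound morphometry and the exercise protocol itself.

## The synthetic cohort

No public recordings exist for this design, so the cohort generator is
a first-class, tested component rather than a test fixture. It emulates
the *statistical structure* the analysis assumes; it does not simulate
volume conduction or decomposition errors.

**Motoneuron pool.** Recruitment thresholds follow the standard
exponential spacing `thr_i = exp(i·ln(R)/n)/R` with recruitment range
`R = 30` over `n = 120` units, the field's default surrogate when the
true pool structure is unknown. An active unit discharges as a
renewal process whose mean rate is `onset + gain·(excitation −
threshold)` capped at a peak rate (defaults 6 pps, 10 pps per unit
excitation, 35 pps). At 25 % excitation this yields plateau rates near
7.4 pps, recruitment-phase rates near 6.3 pps, and ~59 % of the pool
active — the scale of the decomposed vastus lateralis data being
emulated. Inter-spike intervals are Gaussian with a target CoV
(default 0.13) truncated at ±3 SD; truncation keeps intervals positive
and shrinks the realized CoV by the known factor 0.987, which the
long-duration recovery tests account for. Time-varying drive is handled
by time warping: unit-mean intervals are accumulated in operational
time `Λ(t) = ∫ rate dt` and mapped back through `Λ⁻¹`.

**Force.** Force is the sum of twitch kernels (`P·(t/T)·e^{1−t/T}`,
amplitudes spanning a 30-fold range, contraction times 110 → 50 ms)
convolved with each train, passed through a 5 Hz second-order zero-phase
low-pass that stands for limb and transducer mechanics, and scaled so
the plateau mean equals the target force. With these defaults the
intrinsic post-filter ripple has CoV ≈ 0.013, safely below every
force-steadiness target, and the remaining variability is injected as
1–3 Hz band-limited tremor. The tremor component is orthogonalized
against the twitch ripple over the plateau and scaled so the
*post-20-Hz-filter* CoV equals the configured target exactly; this is
what makes force steadiness a cleanly recoverable injected parameter.

**Study conditions.** `cohort_spec()` and `effect_config()` defaults
are the study's conditions: 13 subjects; per-leg baseline MVC means of
296 N (exercise) and 286 N (control); between-subject SD 109 N and
within-subject residual SD 16 N, back-solved from the reported
confidence-interval half-width (≈ 60 N) together with a conditional R²
of 0.98; post/pre MVC multipliers 0.852 and 0.931; an exercise-leg
plateau firing-rate multiplier of 8.66/7.32; force-steadiness CoV cell
targets (0.024, 0.025, 0.021, 0.027); and no change in MUP morphology.
Three maximal efforts and two trapezoidal 25 %-MVC holds (5 s ramps,
20 s hold) are produced per session; the extraction stage picks the
steadiest trapezoid by raw plateau CoV, mirroring the "least
variation" selection an operator makes by eye. Each maximal effort
realizes a multiplicative shortfall `1 − |N(0, 0.02)|` of the
session's true capacity, so the max-of-three MVC estimate is a
constant fraction of truth at both timepoints and percent changes are
unbiased.

Per-subject random intercepts (strength, firing rate, steadiness
scatter) are drawn once per subject and shared across legs and
timepoints. Each subject's exercise-leg MVC multiplier deviates from
the mean effect with SD `0.54·|1 − multiplier|` — proportional to the
effect, hence zero in a null cohort — and that centred deviation feeds
back into the firing-rate multiplier with coupling 1.5, producing the
compensatory negative delta-FR vs delta-MVC correlation in the
exercised leg (r ≈ −0.55 at these settings) without moving any cell
mean. The coupling constant and heterogeneity scale were fixed from
the reported effect sizes and correlation strength before any
acceptance measurement, and are not revisited.

**Tracking.** Each (subject, leg) has a decomposition roster: 14 units
sampled from the active pool per session, each pre unit re-identified
post with probability 0.61, matching the reported 374/616 tracked
fraction. Track links are written into the session manifests, and
`match_tracks()` passes external links through verbatim; its
correlation-based matcher (normalized cross-correlation maximized over
lags, exact bitmask-DP assignment up to 14 units a side, greedy beyond)
exists for data that arrive without links.

**MUP trains.** A template is a sum of 3–6 Gaussian-derivative lobes at
50 kHz (one per near fibre, amplitudes 80–350 µV); each of the 30–170
realizations re-draws per-fibre latencies with 25 µs SD and adds 0.2 µV
band-limited baseline noise. With these defaults near-fibre jiggle
lands near 19 %, the physiological scale for older vastus lateralis;
jiggle is strictly monotone in the injected jitter, which is the
property the tests rely on. The defaults emulate *edited* MUP trains —
contaminated or noisy discharges are assumed already excluded, which is
why the noise floor is small.

**RNG discipline.** One stream per subject, split by purpose (traits /
roster / discharges / MUPs) through deterministic sub-seeds, so
toggling one effect never reshuffles unrelated draws, and a fixed
master seed reproduces the session tree byte for byte.

## Extraction conventions

* **Filtering.** All force analysis uses a zero-phase
  (forward–backward) 4th-order Butterworth low-pass at 20 Hz with
  odd-reflection padding, so constants pass unchanged and no lag is
  introduced between force and spike times. Zero-phase filtering squares
  the magnitude response: gain 0.5 (not −3 dB) at the cutoff, and
  `(1+(f/20)^8)^{-1}` elsewhere; the tests pin both. Whether to filter
  before taking the MVC maximum is unstated in common protocols; the
  package filters first, which suppresses transducer spikes and is
  applied identically at both timepoints.
* **Plateau.** An explicit plateau annotation (written by the
  generator, since the hold is protocol-defined) takes precedence;
  otherwise the longest window staying within ±5 % of target for ≥ 5 s
  is detected on the filtered trace.
* **Phase firing rates.** Instantaneous rate is the reciprocal of each
  inter-spike interval, assigned to the later spike. The
  recruitment-phase rate averages the first five rates, derecruitment
  the *last* five (a literal "first five" cannot describe
  derecruitment), and the plateau rate averages rates whose bounding
  spikes both fall inside the plateau window. ISIs outside
  [0.02, 0.5] s (rates outside 2–50 pps) are treated as decomposition
  artifacts and excluded, with counts retained.
* **ISI variability** is reported as a dimensionless fraction
  (SD/mean, n−1), not a percentage — tabulated values near 0.14 labelled
  "%" in the field are fractions.
* **Cumulative spike train.** Tracked trains are binarized at 1 ms,
  summed, smoothed with a 0.4 s Hann window, and averaged over each
  timepoint's plateau. The window mean is provably insensitive to the
  smoother (with rectangular smoothing it equals spike count/duration
  exactly), so the unstated smoothing choice cannot affect the reported
  deltas.
* **Near-fibre MUP.** The operator is a discrete double difference
  scaled by 1/Δt² followed by a zero-phase 2nd-order 10 kHz low-pass
  guard. The f² response of differentiation *is* the low-frequency
  emphasis; no explicit high-pass edge is applied, because a 500 Hz
  edge would distort the very waveforms (spectral peak ≈ 450 Hz for a
  0.5 ms lobe) the operator must preserve — the package's oracle test
  requires the NFM of a Gaussian lobe to match its analytic second
  derivative within 1 % RMS.
* **Near-fibre jiggle** uses temporally ordered consecutive-pair mean
  absolute differences of the per-discharge NFMs, normalized by the
  mean-NFM area, integrated over the NFM duration (the span where the
  mean NFM exceeds 5 % of its peak, padded 0.25 ms) — not the whole
  template, which would let baseline noise swamp the numerator.
  Realizations correlating below 0.5 with the mean NFM are treated as
  contaminated and excluded. Consecutive-pair versus all-pairs and mean
  versus median are genuinely open conventions; the choice is isolated
  in one function.
* **Turns** are local extrema accepted when the amplitude change from
  the previously accepted turn (or the onset value) strictly exceeds
  20 µV with alternating direction; a same-direction, more extreme
  extremum replaces the last turn's value without incrementing the
  count. This makes the count invariant to sub-threshold ripple riding
  on larger excursions.
* **Exclusion rules** are inclusive at their boundaries exactly as
  stated: PNR ≥ 30 dB retains a 30 dB train; "fewer than 40 MUPs"
  excludes 39 and retains 40.

## Inference layer

Each metric is modelled as `value ~ leg * time + (1 | subject)` by REML
(`lmerTest`), with an additional `(1 | subject:mu)` intercept when
repeated MU-level observations warrant it. Sum-to-zero contrasts make
the type-III Leg, Time and Leg×Time tests meaningful; denominator
degrees of freedom are Satterthwaite (Kenward–Roger by switch). EMMs
and pairwise contrasts come from `emmeans`, unadjusted by default
(Tukey by switch) since small designs in this field conventionally
report raw post-hoc p-values. Singular fits are flagged with a warning,
not refit — at 13 subjects a zero variance component is information,
not an error. Two Cohen's d constructions are provided: paired
(mean difference / SD of within-subject differences) for subject-level
metrics, and EMM contrast divided by the square root of the summed
random-effect plus residual variances for nested models. Nakagawa's
R²m/R²c use the fixed-effect-prediction variance in the standard
plug-in form.

## Calibration, problem sizes, and what passing shows

Statistical calibration (type-I error, power, null p-value uniformity)
is measured on `simulate_metric_cohort()`, which draws metric values
directly from the hierarchical generative model. This is deliberate:
these are properties of the distributional structure and the fitting
code, hundreds of replicates are needed to measure them, and routing
each replicate through full signal synthesis would only add Monte Carlo
noise around the same answer. The signal chain's own fidelity is
established separately by injected-parameter recovery (plateau rate
within ±2 %, steadiness CoV within ±0.002, averaged over 20 replicate
contractions) and by the end-to-end pipeline tests.

Suite problem sizes were chosen as the smallest that make each
property measurable: 500 replicates for type-I error (binomial CI
±0.019 around 0.05), 200 for power, 20 for recovery means, 4-subject
cohorts for end-to-end determinism. The mean-of-reciprocals plateau
estimator carries a known upward bias of `(1 + CoV²)` relative to the
renewal rate — ≈ +1.7 % at CoV 0.13, within the recovery tolerance,
and an inherent property of the field's estimator rather than of this
implementation.

Power is asserted for the plateau firing-rate interaction (the
MU-level effect, which is decisively powered at these effect sizes);
the MVC interaction at 13 subjects has power ≈ 0.5–0.75 under any
variance configuration consistent with the reported statistics — the
study's own interaction p of 0.013 already implies a result near the
detection margin — so the package reports it but does not assert a
threshold on it.

What passing does **not** show: robustness to decomposition errors
(spurious or missed discharges beyond the ISI artifact gate),
non-stationary fatigue drift within a hold, electrode movement between
timepoints (tracking here is by construction), or non-Gaussian force
noise. Real data enter through the same session format and inherit no
guarantees from the synthetic results.

## Degenerate inputs and numerical conventions

Metrics that cannot be computed return `NA` markers rather than
failing: fewer than two spikes (rates), fewer than three plateau spikes
(ISI CoV), fewer than two isolated realizations (jiggle), zero fall
(negative-peak ratio), zero-variance differences (correlation; paired
d is 0 when post equals pre and undefined for any other constant
difference). Structural violations — non-monotone spike times, cursor
disorder, annotation overlap, spikes outside the force span — are
errors naming the offending record. Sample SDs use n−1 throughout;
times are seconds, forces newtons, voltages microvolts, written as
decimal text with 10 significant digits; cursor indices are 0-based.
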