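---
title: "Methods: premotor selectivity analysis for cued vocal and manual responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: premotor selectivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The scientific question and the pipeline

Single neurons in the primate inferior frontal cortex can signal the
*impending* initiation of a volitional action. In a go/nogo detection task
in which a monkey alternates between cued vocalizations and cued hand
(bar-release) movements, the question is whether the same neurons prepare
both action types or whether largely separate populations carry vocal and
manual motor plans — and whether that preparatory activity is specific to
*volitional* (cued) responses as opposed to spontaneous ones.

`premovoc` implements the full analysis chain from raw per-session spike
times, behavioral events, and eye traces to:

1. behavioral performance (hit/false-alarm rates, d′ sensitivity, reaction
   times),
2. eye-movement confound screening (saccade-direction tuning, fixation
   responses),
3. premotor response-type classification with signs and PSTH latencies,
4. time-resolved coding quality (sliding AUROC with a permutation null),
5. population-overlap statistics per area, and
6. Gaussian-process factor analysis (GPFA) of pseudo-population activity
   with within-/cross-response trajectory distances.

Because the recorded sessions are not redistributable at desk scale, the
package includes a first-class synthetic-session generator with ground-truth
labels; every stage is validated against that truth and against exact
statistical oracles.

## Task and behavior model

A trial starts with a pre-cue (nogo) stimulus shown for a uniformly random
1–5 s. In 80% of trials a go cue (one of two arbitrary stimuli per response
type) follows for 3 s, during which the response must occur; the remaining
20% are catch trials in which any response is a false alarm. Blocks of
vocal and manual trials alternate after 25 correctly performed go trials.

Sensitivity is `d' = z(HR) − z(FA)` with standard-normal quantiles and a
detection threshold of 1.5. Because a session can yield degenerate rates
(e.g. a 100% manual hit rate), the package offers three corrections:
log-linear (default: add 0.5 to event counts and 1 to trial counts), rate
clipping to `[1/(2n), 1 − 1/(2n)]`, and none (errors on degenerate input).
The correction used is recorded in the output. False-alarm opportunities
for a response type are that block's catch trials plus all trials of the
other block, which is the only reading consistent with the published
example session's 4/179 manual false alarms among vocal-block trials.

## The synthetic-session generator

The generator's defaults encode the study conditions: vocal hit rate 0.5
versus manual 1.0; lognormal reaction times with natural-scale means 1.8 s
(vocal) and 0.52 s (manual); call durations 97 ± 40 ms; eight alternating
blocks; spontaneous calls and bar releases as Poisson events (0.5/min each)
in inter-trial intervals.

Units are inhomogeneous Poisson processes generated by thinning. The rate
is `baseline × m(t)`, where `m(t)` ramps linearly from 1 to the unit's gain
between `response − ramp_onset` and response onset for cued responses of a
preferred type, then returns to 1 over the response duration. Ramp onsets
default to 1.0 s before calls and 0.3 s before bar releases, mirroring the
long, continuously rising vocal preparatory activity versus the brief
pre-release build-up. Suppressed units use the reciprocal gain (clipped at
zero). Spontaneous responses carry **no** premotor modulation — this is the
generative version of the volitional/spontaneous dissociation that the
classification and contrast stages must recover. Saccade-locked units gain
only for saccades within 90° of a preferred direction (otherwise a
direction-*untuned* gain would be invisible to the Kruskal–Wallis screen,
which tests direction dependence); fixation-locked units gain in a
0.05–0.25 s window after fixation onset, modeling a short visual response
latency that the 100–200 ms post-onset test window straddles.

Eye traces are piecewise fixations (Gaussian jitter, default SD 0.1°)
interrupted by minimum-jerk saccades with amplitudes 4.5–15°. Saccade
durations scale with amplitude (`max(4 ms, 0.8·A ms)`) so that **every**
true saccade displaces gaze by more than 4° within 4 ms at peak velocity.
This is faster than typical primate saccade kinematics; the choice is
deliberate, because the downstream detector — displacement > 4° within
4 ms — is the only property of saccades any analysis consumes, and slower
kinematics would make true saccades undetectable by that rule. During cue
epochs gaze lands on the cue with probability 0.8.

What the generator does **not** emulate: sensory responses to cue onset
(cue-preference exclusion is exercised via an optional cue-gain knob),
motivational or fatigue dynamics across trials (vocal misses are i.i.d.
Bernoulli), bursting/refractory spike statistics, electrode drift, and
main-sequence saccade kinematics. Passing tests therefore demonstrate the
pipeline's correctness on Poisson-like preparatory modulation, not
robustness to every physiological nuisance in real recordings.

## Eye screening

Saccade onsets are the first samples whose Euclidean displacement over the
following 4 ms exceeds 4°; candidates within 20 ms of an ongoing event are
merged (one physical saccade, one detection). The direction vector compares
gaze 50 ms before and after onset and is binned into eight 45° sectors with
bin 1 centered on rightward. Per-saccade firing rates in a 200 ms window
*centered* on onset (`[−100, +100) ms`, reading "within 200 ms around
onset" as centered) are compared across direction bins with a tie-corrected
Kruskal–Wallis test. Units not flagged are tested for fixation responses:
rates 100–200 ms after fixation onset versus the 100 ms before, one-sided
(increase) signed-rank, paired over fixation epochs of at least 200 ms
during cue presentation in which gaze stays within 2.0° of the cue (the
spatial criterion is our choice; the tolerance is configurable). At least
five epochs are required — the exact test cannot reach p < 0.05 below that.
The signed-rank tail is computed exactly (by sign-pattern convolution over
midranks, valid under ties) up to 25 nonzero differences, with a
tie-corrected normal approximation above.

## Premotor classification

Units qualify with a mean rate above 1 Hz, at least 7 hit trials per block
(after discarding trials with reaction times under 450 ms), and no eye
exclusion. Per block, premotor rates (450 ms before response onset) are
compared to baseline rates (450 ms before go-cue onset) with a two-sided
Wilcoxon signed-rank test at p < 0.05; the sign of the median paired
difference labels the unit excited or suppressed. Units preferring one of
the two go cues (Mann–Whitney on premotor rates, p < 0.05) are excluded for
that block only — the least destructive reading of "excluded from further
analysis"; a global-exclusion switch exists. No multiple-testing correction
is applied anywhere, matching the source analysis conventions.

The PSTH latency rule is implemented literally: response-aligned 50 ms
bins, threshold band = baseline mean ± 3 SD, where the SD is taken across
the nine 50 ms bin means of the baseline window (the source does not state
across what the SD is computed). The latency is the start of the earliest
run of ≥ 20 consecutive out-of-band bins on the unit's sign side that
begins before response onset (runs may extend past it). Twenty bins is a
full second of sustained deviation; with ramping activity that returns to
baseline shortly after the response — as the generator produces — the rule
frequently yields no latency. That is the honest behavior of the literal
rule (the source likewise reports units without determinable latency); the
run length is a configurable knob. Population curves z-normalize each
unit's PSTH by its baseline bin mean/SD and *reflect* (not clip) suppressed
units about zero before averaging, so magnitudes are preserved.

## Sliding ROC

AUROC between vocal (positive class) and manual hit-trial rates in 200 ms
windows stepped 10 ms over [−2, +1] s around response onset, computed via
the rank-sum identity with half-credit ties; windows where all trials tie
return 0.5 (complete overlap). The null shuffles condition labels once per
permutation across the *whole* time course (preserving within-trial
temporal correlation) and recomputes the full trace 1000 times; per-window
2.5th/97.5th percentiles give two-sided significance, with the
three-consecutive-window rule as the cluster criterion for latency. Coding
strength is the mean |AUROC − 0.5| over windows whose centers fall in the
premotor epoch [−0.45, 0) s — the epoch is a documented choice, as the
averaging window is not stated in the source.

## Population overlap

Chance dual-selectivity is the product of the per-area vocal and hand
proportions; a direction-matched variant further multiplies by the
probability that independently signed units share a modulation direction.
Both are always reported, because the published numbers are consistent with
different variants in different areas, and the observed dual-selective
count is tested with a one-sided (greater) exact binomial test by default.
Proportions are compared with Pearson χ² without continuity correction.

## GPFA state-space analysis

The model is `y_t = C x_t + d + ε`, `ε ~ N(0, R)` with diagonal `R`; each
latent is an independent zero-mean Gaussian process with squared-
exponential covariance `(1 − σ_n²)·exp(−Δt²/(2τ_k²)) + σ_n²·1[Δt = 0]`,
`σ_n² = 10⁻³` fixed so the latent scale is absorbed into `C` (the standard
identifiability convention). Binned spike counts (20 ms, response-aligned
over [−2, +1] s) are square-root transformed by default. The E-step is the
exact joint Gaussian posterior over all latents and time points (computed
once per iteration and shared across trials of equal length, using the
Woodbury identity for the marginal likelihood); the M-step updates `C, d,
R` in closed form and each `τ_k` by one-dimensional maximization of the
expected complete-data log-likelihood over `τ ∈ [5 ms, 3 s]`. `C, d, R`
start from a factor analysis fitted by EM from a seed-determined random
start; `τ` starts at 0.1 s. The marginal log-likelihood is non-decreasing
across iterations (an invariant the tests assert). EM for this model has
local optima in which latents with different timescales stay mixed;
`n_restarts` runs independent initializations and keeps the highest
likelihood, which the timescale-recovery analyses use (3 restarts, up to
300 iterations).

Trajectories are orthonormalized through the SVD of `C` and ordered by
explained covariance; the top three dimensions feed the distance analysis.
Each condition's trials are randomly split into halves; the Euclidean
distance between same-condition half averages is the within-response
coding, and the mean over the four vocal×manual half pairs the
cross-response coding. The baseline — the 100–600 ms window before go-cue
onset — lives on a go-aligned clock, so it is mapped onto the
response-aligned grid via the condition's mean reaction time, keeping grid
bins with at least 50% coverage; with long vocal reaction times the mapped
window can leave the grid entirely, in which case the earliest 0.5 s of the
grid serves as baseline. The whole procedure (trial sampling → fit →
split → distances) repeats `n_repeats` times and curves are averaged with a
SEM.

## Numerical and problem-size choices

Observation noise variances are floored at 10⁻⁴; Kruskal–Wallis on
all-identical rates returns H = 0, p = 1 without calling the test; empty
event lists yield empty (not error) alignments; windows are half-open
`[lo, hi)` everywhere, with trailing partial bins dropped, and all times
are seconds from recording start. The test-suite and acceptance analyses
use deliberately scaled problem sizes — e.g. 16-block sessions (~200 vocal
hits) for recovery, 500 units for null calibration, 4–10 GPFA repeats on
populations of ~20 units, and 300-permutation ROC nulls — chosen so the
statistical claims they check (binomial 99% calibration bands, ≥ 0.9
sensitivity, < 15° subspace angles, τ within 30%) are well powered while
the whole suite stays desk-sized. The sliding-ROC latency recovery uses
strongly coding units (gain 6, 50 trials per condition): detection latency
necessarily lags ramp onset by the time the accumulating effect first
clears the permutation band, and a priori power analysis puts that lag
within the 150 ms criterion only when coding is strong — for weak
modulation, latency is simply identified later, which is a property of the
method, not a defect of the implementation.

## Known limitations

The synthetic generator's linear multiplicative ramp is the simplest shape
matching "continuously rising" preparatory activity; real profiles are
heterogeneous. The literal 20-bin PSTH latency rule rarely fires on
transient modulation (see above). The published overlap binomial p-values
are not jointly reproducible under a single null construction, so the
package reports both chance variants rather than matching any one printed
p-value. Published area-level AUROC strengths, latency medians, selective
proportions, and the 58% explained-covariance figure depend on the
recorded data and are reported by the pipeline but are not reproduction
targets.
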