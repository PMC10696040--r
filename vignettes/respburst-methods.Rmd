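---
title: "Methods: quantifying respiratory motor output from nerve recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying respiratory motor output from nerve recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respburst)
```

## The measurement problem

In arterially perfused (in situ) rodent preparations, the respiratory
central pattern generator can be read out from two motor nerves: the
phrenic nerve (PNA), whose rhythmic multiunit bursts drive the diaphragm
and define inspiration, and the central vagus nerve (VNA), which carries an
inspiratory component plus a *post-inspiratory* decrementing discharge in
early expiration. A pharmacological microinjection into a medullary
respiratory nucleus (Bötzinger complex, pre-Bötzinger complex, or rostral
ventral respiratory group) perturbs this pattern for a few minutes, and the
analysis must turn the raw multiunit traces into a small set of
interpretable quantities:

* the **integrated** traces ∫PNA and ∫VNA — rectified signal smoothed with
  a 0.05-s moving average;
* per-cycle **phase durations**: inspiratory duration Ti (burst onset to
  the onset of the sharp terminal decrease), cycle duration Ttot (offset to
  next offset), expiratory duration Te = Ttot − Ti, inspiratory ratio
  Ti/Ttot, and instantaneous frequency 60/Ttot (cycles/min);
* **burst amplitudes**, measured not from single cycles but from
  phrenic-burst-triggered average waveforms computed in 20-s windows
  advanced in 10-s steps;
* **drug responses**: every metric expressed as percent of its mean over
  the 100 s preceding the injection (= 100%), summarized as a *change
  rate* (mean percent over a post-injection analysis window) and tested
  with one-sample t (vs 100%), paired t, or repeated-measures ANOVA with
  Dunnett many-to-one comparisons against the last pre-injection bin,
  at p < 0.05, reported as means ± SEMs.

No raw recordings of this kind are publicly deposited, so the package
includes a synthetic generator with full ground truth. Every stage of the
chain is validated against that truth or against brute-force oracles.

## The synthetic generator

`simulate_subject()` builds a session cycle by cycle. Each cycle draws Ti,
Te and a burst amplitude factor lognormally around the current targets with
coefficient of variation `cv_cycle` (lognormal keeps durations positive; at
`cv_cycle = 0` the draws collapse to the exact means, giving a fully
deterministic session). The PNA envelope is an augmenting linear ramp over
Ti — starting at `onset_frac` (default 0.25) of the peak, so onsets are
crisp — ending in an abrupt fall, the "sharp decrease" that defines the
inspiratory offset. The VNA envelope adds, after the phrenic offset, a
decrementing exponential with time constant `0.4 * Te0`, confined to early
expiration: it is silenced `pi_gap` (default 0.6) seconds before the next
onset, reflecting that post-inspiration is an early-expiratory phenomenon
and keeping the pre-trigger baseline span free of the decaying tail.

Nerve channels are emitted as envelope × N(0, 1) noise plus a tonic noise
floor. This amplitude-modulated-noise model was chosen because
rectification + smoothing then recovers the envelope up to the analytic
constant E|X| = σ√(2/π), making amplitude recovery checkable in closed
form. Setting `carrier = FALSE` emits the envelope itself — the
deterministic mode used by the regression fixtures. The ECG is an R-wave
train at `hr0` (default 320 beats/min, a realistic rate for a perfused rat
preparation) with 2% R-R jitter; perfusion pressure is a slowly varying
baseline, stored but never analyzed.

Drug effects are multiplicative. The kernel `effect_kernel()` rises
linearly from injection to 1 at `t_peak = 120` s and recovers as
exp(−(t − t_peak)/`tau_rec`) with `tau_rec = 150` s, so the effect peaks
around 2 minutes and is below 5% of peak by 10 minutes. The multiplier
applied to a parameter with peak factor m at time t is 1 + w(t)(m − 1).
When several injections overlap, the weight is the *maximum* of the
individual kernels (effects saturate rather than add). Baseline timing
defaults Ti0 = 0.9 s and Te0 = 3.1 s give a eupnea-like rhythm of ~15
cycles/min with an inspiratory ratio of ~0.22, matching the regime the
pipeline is meant for.

Cohorts jitter each subject's baseline parameters lognormally with CV
`cv_subject` (default 0.1). Subject seeds derive from the master seed via
an integer mix that is exact in double precision (`subject_seed()`), so
cohorts are bit-reproducible and order-stable.

What the generator deliberately does **not** emulate: spike-train
structure within bursts (only the envelope statistics matter to the
integrated trace), augmenting-then-plateau envelope shapes, apneas or
sighs, slow drifts in baseline excitability, and movement or stimulation
artifacts. Passing tests on synthetic data therefore demonstrates that the
*chain of definitions* is implemented correctly and recovers known ground
truth at realistic noise levels — not that detection parameters are tuned
for any particular experimental rig.

## Conditioning

`integrate_trace()` implements the integrated waveform literally: |x|
averaged over a centered window of `round(window * fs)` samples (0.05 s
default). Centering avoids a systematic half-window lag in onset times,
which matters because triggered averages must be phase-faithful. Edges use
shrinking windows (mean over available samples) so records do not acquire
artificial zeros at their boundaries. The implementation is a cumulative-sum
sliding mean; tests compare it at 1e-12 relative error against a
per-sample brute-force mean.

`bandpass_trace()` (zero-phase Butterworth, corner frequencies as in the
acquisition band 100–5000 Hz) is provided for completeness but is not part
of the default pipeline: synthetic signals are generated in band, and
amplification gain is irrelevant because every downstream result is a
percent change.

R waves are detected as local maxima above `k` (default 4) robust SDs with
a 0.15-s refractory period resolved in favor of the larger peak;
instantaneous heart rate 60/RR is assigned to interval midpoints and
averaged into the common 10-s grid.

## Burst detection and phase segmentation

Detection runs on the integrated trace. The onset threshold is a rolling
low-quantile baseline (10th percentile over 5-s windows) plus
`k_on = 3` robust SDs of the between-burst noise, with a floor of 10% of
the trace's dynamic range so the rule also works on noise-free envelopes.
Candidate bursts must stay above threshold for `min_dur = 0.1` s;
candidates closer than 0.3 × the median cycle duration are merged (two
passes: a provisional merge, then one using the estimated rhythm).

Two refinements remove resolution artifacts that a plain threshold rule
would leave in:

* **Onset**: a fixed threshold is reached *later* on smaller bursts
  (the smoothed rising edge is shallower), which would leak amplitude
  changes into measured Ti. The onset is therefore refined to the crossing
  of half the local burst level (estimated `onset_refine = 0.1` s ahead of
  the raw crossing), which is invariant to the burst's amplitude scale.
* **Offset** ("onset of the sharp decrease"): the smoothed derivative must
  fall below −`d_frac` × (peak − baseline)/Ti (default `d_frac = 0.5`),
  which localizes the steep terminal fall; within that fall the offset is
  the half-amplitude crossing, which for an abrupt fall recovers the true
  fall time to within about one sample, because the centered smoothing is
  symmetric around a step. If no steep fall exists the threshold
  down-crossing is used instead.

Neither rule is specified numerically in the experimental literature this
emulates; both are exposed in `burst_params()` and validated against
generator ground truth (onsets and offsets within one smoothing window on
clean envelopes; ≥95% of bursts matched at default noise).

Cycles span offset to offset. The Ti assigned to a cycle is, by default,
that of the inspiration **terminating** it, so Te = Ttot − Ti is the
expiratory pause actually contained in the cycle; the opposite convention
is available (`ti_convention = "opening"`) since the subtraction rule
admits either reading. Cycles with non-positive Te are excluded with a
warning and counted, never silently dropped. Per-bin respiratory frequency
is 60/mean(Ttot) by default; a count-based variant (cycles per bin scaled
to per-minute) is available because the two conventions differ in
short-cycle-weighted regimes. Empty bins propagate as gaps, never zeros.

## Triggered averaging and amplitudes

`triggered_average()` aligns the integrated channels on burst *onsets*
(onset rather than peak, because phase durations are defined from onset)
and averages pointwise within each 20-s window, stepped by 10 s. The lag
span defaults to [−1 s, 1.5 × median Ttot] so one full cycle is visible.
Windows without triggers yield gaps; triggers whose lag segment leaves the
record are skipped and counted. ∫PNA amplitude is the peak of the averaged
waveform in the burst interval minus the pre-trigger baseline (mean over
lag [−0.5, −0.1] s, ending before the trigger so the previous burst's tail
cannot contaminate it). Post-inspiratory ∫VNA amplitude is the maximum in
the interval starting one smoothing margin after the phrenic offset lag
(so the smeared inspiratory edge cannot leak in) and extending half the
median Te, minus the same pre-trigger baseline.

## Response quantification and statistics

`percent_of_baseline()` fixes the mean over the 100 s before the injection
at 100%; the whole analysis is invariant to rescaling raw amplitudes by
any positive constant. The *change rate* is the mean percent over a
post-injection window. The default window is [60, 180] s, but the window
is a per-experiment choice (the published "gray areas" differ between
experiments); the package's own validation runs use [90, 150] s, which
brackets the kernel peak — over that window the mean effect weight is
≈ 0.88, so an injected multiplier of 0.80 should be recovered as a change
rate near 82%, and 0.70 near 73%.

`one_sample_t()` and `paired_t()` are the classical two-sided tests
(validated to 1e-8 against `stats::t.test`). Zero-variance inputs are
handled explicitly: all values equal to the reference give t = 0, p = 1;
all values equal to some other constant give an infinite statistic flagged
degenerate with p reported as 0. "Equal to the reference" is judged at 1%
relative tolerance: exactly constant samples only arise from noise-free
synthetic input, where sub-percent offsets are timing-resolution artifacts
of the measurement chain (e.g. a measured inspiratory ratio of 99.6% under
exact proportional rescaling of both phases), two orders of magnitude
below the smallest effects the pipeline is used to detect.

`rm_anova_dunnett()` fits the one-way repeated-measures ANOVA
(`aov(y ~ time + Error(subject))`) and compares every timepoint against
the control timepoint — the last pre-injection bin — using the
within-subject mean square with (S−1)(T−1) degrees of freedom. Adjusted
p-values come from the exact balanced two-sided Dunnett distribution
(equicorrelated multivariate t, pairwise correlation 1/2), evaluated by
`pdunnett_abs()` as a deterministic two-dimensional Gauss quadrature over
the common-factor representation (48 Hermite × 64 Legendre nodes; agreement
with randomized quasi-Monte-Carlo integration of the full multivariate t is
~1e-4, and the deterministic evaluation keeps pipeline outputs
byte-reproducible). Subjects with missing bins are dropped listwise from
this test and counted; the simple tests use whatever values exist. Tests
are two-sided throughout, and no multiplicity correction is applied across
*metrics* — Dunnett adjusts within a time course only.

## Pipeline, formats, determinism

`run_pipeline()` ties the stages together and writes CSV tables (cycles,
time courses, change rates, group statistics, Dunnett comparisons) plus a
JSON manifest carrying the full effective configuration and a
fingerprint. Outputs are deliberately timestamp-free: the same
configuration and seed produce byte-identical bundles, and the CLI
composition `simulate` → `analyze` equals `run` exactly. Sessions are
stored as plain-text containers — one CSV per channel plus a JSON sidecar
with sampling metadata, events and protocol — with samples written as
shortest-exact decimals (`%.17g`) so a save/load round trip reproduces the
arrays bit for bit. Times are seconds from session start and all intervals
are half-open [start, end).

The command-line interface exposes `simulate`, `analyze` and `run`
(`inst/cli/respburst.R`); the intermediate stages are deliberately not
separate subcommands, since each would need its own interchange format,
and the R functions are the primary interface.

## Problem sizes used in validation

The shipped tests scale the simulations for a desk run, as the package's
own choice of validation size: sampling rates of 250–1000 Hz (the envelope
metrics are insensitive to carrier bandwidth), sessions of 3–6 minutes,
a 20-subject recovery cohort at 500 Hz, 500 truth-level replicate cohorts
of 6 subjects for null calibration of the test sizes, and nine noise-free
direction-regression fixtures (5 subjects each at 400 Hz). The direction
fixtures are noise-free on purpose: a regression test should be
deterministic, and with noisy fixtures every truly null cell would flip to
"significant" with exactly the test's 5% level no matter the sample size.
Calibration of that 5% level is done separately, on the 500 noisy
replicates.

## Known limitations

* Burst detection assumes a single dominant burst per cycle; biphasic or
  fractionated bursts (e.g. gasping patterns) are out of scope.
* The offset rule targets abrupt terminal falls; for slowly decrementing
  bursts it falls back to the threshold crossing, which is conservative.
* The Dunnett implementation assumes a balanced complete matrix (hence
  listwise deletion) and compound symmetry of the within-subject errors;
  strong sphericity violations would make it conservative or liberal as in
  any classical RM-ANOVA.
* Amplitudes are in arbitrary units throughout; only percent changes are
  meaningful, mirroring how such recordings are reported.
* The generator's drug-effect kernel is a stylized rise-and-decay; real
  washout kinetics may be multiphasic.
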