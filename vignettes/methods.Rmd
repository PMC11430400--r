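---
title: "Methods: multi-modal analysis of short- vs long-duration taVNS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal analysis of short- vs long-duration taVNS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tavnspipe)
```

## Scope

`tavnspipe` implements the analysis chain of a sham-controlled crossover
experiment comparing two transcutaneous auricular vagus nerve stimulation
(taVNS) protocols — short 3.4 s ON cycles and conventional 30 s ON/OFF
cycles — across the outcome families that index locus coeruleus /
norepinephrine activity: salivary alpha-amylase (sAA) and cortisol, pupil
size at rest, the pupillary light reflex (PLR), EEG alpha/theta band power,
the No-Go P300, and inhibition performance (Go/No-Go and stop-signal
tasks). Both stimulation arms use 25 Hz pulses of 250 µs width, a duty
cycle of 25 Hz × 250 µs = 0.625% ON period.

Raw recordings of this kind are rarely publicly archived, so the package
ships a synthetic-data module that generates each modality with known
ground truth. Every preprocessing and inference stage is exercised against
those generators; what that does and does not demonstrate about real data
is discussed at the end.

## Resting-pupil preprocessing

Recordings are binocular diameter traces at a nominal 120 Hz with per-eye
tracker confidence. The pipeline cuts one replicate per eye around every
stimulation onset — 2 s baseline + 30 s ON + 28 s post for the long
protocol (60 s), 2 s + 3.4 s + 26.6 s for the short one (32 s) — and then
screens, cleans and normalizes each replicate:

1. **Speed criterion.** Absolute successive differences \(d_i\) are
   thresholded at \(\mathrm{median}(d) + 6\,\mathrm{MAD}(d)\); samples
   arriving after a supra-threshold step become NaN. If more than 2% of a
   replicate is flagged the replicate is excluded. Two interpretation
   points are deliberate: the criterion operates on sample-to-sample
   *differences* (a speed filter — the natural reading of a threshold on
   "the median of the differences"), and the MAD is the bare, unscaled
   median absolute deviation (no 1.4826 consistency factor).
2. **Early invalidity gate.** Replicates already ≥ 60% invalid are dropped
   before any blink handling.
3. **Blink detection.** Blinks are the union of (i) runs with confidence
   below 0.6 and (ii) runs bounded by absolute velocity above 8 mm/s, each
   padded by 100 ms and merged. The thresholds follow common pupillometry
   practice and are exposed in `screen_config()`.
4. **Range filter.** Samples outside 1.5–9 mm are invalid.
5. **Blink/range gate.** If blink + range screening removed more than 5%
   of the replicate, the replicate is excluded.
6. **Interpolation and smoothing.** Remaining gaps are linearly
   interpolated (edge gaps held at the nearest valid value) and a centred
   100-sample rolling mean is applied; the window shrinks at the edges
   rather than truncating the replicate. Centring is a choice — the
   alignment of the rolling average is otherwise unconstrained — because
   it adds no group delay.
7. **Baseline correction.** The mean over \([-2, 0)\) s is subtracted, so
   the corrected baseline mean is exactly zero (a property the tests
   assert to machine precision).
8. **Baseline z-screening.** Each replicate's pre-subtraction baseline
   mean is z-scored against the distribution of baseline means of that
   subject's replicates in the same condition round; \(|z| > 2.5\)
   excludes the replicate. Using the subject's own distribution keeps the
   criterion within-subject, matching a per-subject standardization.
9. **Retention control and downsampling.** If fewer than 10% of a
   subject's initial replicates survive, the subject is dropped for that
   condition; otherwise kept replicates are averaged pointwise and reduced
   to 10 Hz by non-overlapping 12-sample block means (the prior smoothing
   acts as the anti-aliasing stage; plain decimation would alias residual
   noise).

Every exclusion carries a machine-readable reason
(`excluded:mad_nan`, `excluded:blink_range`, …) and `replicate_qc_table()`
reconciles per-rule counts against input totals.

One ambiguity is worth recording: whether the 2% NaN rule counts only
speed-flagged samples or all NaNs present at that point. The pipeline
counts only the speed-flagged samples; recordings with extensive missing
data are instead caught by the 60% gate.

## Pupillary light reflex

PLR sessions present 4 flash intensities repeated 3 times (12 flashes).
Preprocessing: blink removal and interpolation (same detector as above), a
zero-phase third-order low-pass Butterworth filter at 4 Hz, and epoching
from 1 s before to 9 s after each flash. Zero-phase (forward–backward)
filtering is chosen so the smoothing cannot bias the constriction latency;
only the filter order and cut-off are externally fixed.

Quality control uses automated surrogates for the four visual criteria:
baseline SD < 0.25 mm (stable baseline), minimum within 3 s with amplitude
> 0.3 mm (rapid constriction), positive mean post-minimum slope
(re-dilation), and no post-filter step above 1 mm (no non-physiological
fluctuation). The first violated criterion is reported.

Twelve parameters are extracted per epoch: baseline diameter `D1` (mean
over \([-1,0)\)), minimum `D2`, amplitude `AMP = D1 − D2`, relative
amplitude `Rel_AMP = AMP/D1`, latency `T1`, time-of-minimum `T2`,
constriction duration `T3 = T2 − T1`, peak constriction velocity `VCmax`
and acceleration `ACmax` (magnitudes of central finite differences within
\((T1, T2)\)), and redilation times `Redil_25/50/75` (first crossing of
`D2 + q·AMP` after the minimum; missing if not reached within the epoch,
and measured from the minimum rather than from flash onset). `T1` is the
first post-flash time where velocity falls below −3 baseline-velocity SDs
sustained for 50 ms, floored at 2% of the peak constriction speed so a
noiseless baseline (SD → 0) cannot trigger on numerical ripple.
Constriction velocity is negative by convention; `VCmax`/`ACmax` are
reported as positive magnitudes.

On noiseless synthetic reflexes the extracted parameters match the
generator's closed-form values within two sample periods (times) and
0.05 mm (diameters); the test suite asserts this. A known limitation: on
*filtered* traces `ACmax` is biased upward near the constriction onset by
ringing of the 4 Hz zero-phase filter around the velocity discontinuity
(about +25% for a 0.85 s constriction at 120 Hz). This is intrinsic to
band-limiting a kinked trajectory, affects real and synthetic data alike,
and is consistent across conditions, so condition contrasts remain
meaningful.

Parameter aggregation removes values more than 3 SD from their
subject × condition × eye × intensity cell mean in a single pass, then
averages. The "3 SD away" screening is interpreted within-cell, the only
reading that yields a well-defined reference distribution.

## EEG

Raw recordings (10 kHz, 64 channels in the full design) pass through:
average reference; 50 Hz low-pass (4th-order zero-phase Butterworth);
decimation to 1 kHz (the 50 Hz low-pass is the anti-aliasing filter);
per-channel demeaning followed by a 0.1 Hz zero-phase high-pass; a 2nd
order band-stop notch at the 25 Hz stimulation frequency; and
spherical-spline interpolation of caller-listed bad channels (at most 25%)
from the montage geometry. Demeaning before the high-pass is a numerical
choice: a 0.1 Hz filter's edge transients on a large DC offset are long
relative to typical segments, while the offset itself is removed exactly
by subtraction. Manual ICA-based artifact rejection is out of scope (it is
inherently visual); the synthetic path generates data without those
artifacts and the 25 Hz notch stands in for stimulation-artifact removal.

Band power uses complex Morlet wavelets with 6 cycles on a 1 Hz grid
inside the band (alpha 8–13 Hz, theta 4–8 Hz; the grid spacing itself is
unconstrained and 1 Hz is the conventional choice), averaged across
frequencies, baseline-corrected by subtracting the mean over \([-1, 0]\) s
and averaged across epochs. The wavelet is normalized so that a
unit-amplitude sinusoid at the centre frequency yields its mean-square
power (1/2): absolute units cancel in the baseline correction, but
calibrated units make the estimate directly comparable to windowed-FFT
band power, which the tests exploit (agreement within 10% on synthetic
oscillators).

P300: No-Go-locked epochs from −200 to 1500 ms are baseline-corrected on
\([-200, 0]\) ms, averaged, and the peak is the maximum amplitude at Pz
within 250–700 ms — a window bracketing the component's typical latency
around 500 ms, exposed as an argument. The peak is a point maximum, not a
mean around the peak, because the outcome of interest is the peak
amplitude itself.

Channel geometry is an idealized spherical 10-10 construction (outer ring
72° from the vertex at 18° azimuth steps, below-ring row at 90°,
intermediate electrodes evenly spaced along great-circle arcs to the
midline) on a 9 cm head sphere. Channels within 0.04 m are neighbors;
on the 64-channel montage every channel has at least two.

## Cluster-based permutation inference

Subject-level difference data (10 Hz pupil traces: 1 × time; band power:
channels × time) enter a from-scratch one-sample, two-tailed
spatio-temporal cluster permutation test:

1. a one-sample t statistic per datapoint across subjects;
2. candidate clusters = connected components of supra-threshold
   datapoints of equal sign, connected through consecutive time samples
   and neighboring channels at equal time. The cluster-forming threshold
   is the parametric two-sided t critical value at the test's alpha with
   \(n-1\) df (the conventional default where no explicit threshold is
   given); it is exposed as an argument;
3. cluster mass = the sum of member t values;
4. the null distribution is the maximum absolute cluster mass over random
   subject-wise sign flips (both signs pooled, matching the two-tailed
   test), with \(p = (1 + \#\{\text{null} \ge |\text{mass}|\})/
   (n_\text{perm} + 1)\). Including the observed labeling guarantees
   \(p \ge 1/(n_\text{perm}+1)\). A relative tolerance of \(10^{-8}\) in
   the comparison makes sign flips that reproduce the observed labeling
   count as ties rather than falling on either side by floating-point
   accident.

Same-sign cluster membership is the standard choice for two-tailed
max-statistics; an opposite-signed neighbor starts a new candidate
cluster. The test's validity is established empirically: on 500 null
datasets the family-wise false-positive rate stays at the nominal 5%
level (within Monte-Carlo error), and on a 5-subject problem the
permutation p-values match exhaustive enumeration of all \(2^5\) sign
flips. Candidate-cluster *counts* depend on bookkeeping details (threshold,
connectivity radius) and are not a target of the implementation; the
inferential contract — which clusters are significant at which p — is.

## Behavior

**Stop-signal task.** Sessions of 4 × 64 trials with 25% stop trials run
against an independent-race agent: ex-Gaussian go finishing times, a fixed
true stop latency, and a response on a stop trial iff the go process beats
`SSD + SSRT_true`. The SSD starts at 300 ms and moves ±50 ms after every
stop trial (up after successful inhibition), floored at 0 ms with no
ceiling. The staircase converges to 50% inhibition for any continuous RT
distribution, which the acceptance suite verifies over 2000 stop trials.
SSRT is estimated with the integration method with omission replacement:
omitted go responses are replaced by the 1250 ms deadline, and
`SSRT = Q_p(go RT) − mean(SSD)` with `p = P(respond | stop)`. Sessions
where every stop succeeded (or failed) carry no race information and are
flagged rather than estimated. Parameter recovery is within 25 ms of the
generative stop latency at session scale.

**Go/No-Go.** Three blocks of 92 trials with 2/3 Go stimuli (4 Go and 2
No-Go types) and a 1-back rule: left hand if the stimulus repeats the
previous one, right hand otherwise; No-Go stimuli require no response even
on repeats. The first trial of a block has no 1-back and any response is
scored correct. Accuracy = (correct Go responses + correct No-Go
rejections) / all stimuli; error rate = (No-Go commissions + wrong-hand Go
responses) / all stimuli (omissions are neither); mean RT covers correct
Go responses only.

## Saliva

Secretion (U/min) = concentration (U/mL) × flow rate, with flow = sample
weight / collection time at an assumed saliva density of 1 g/mL (the
standard Salivette convention; only weights are recorded). Collection
times map to circadian bins — morning 07:30–10:30, midday 10:35–13:35,
afternoon 13:40–16:30 — with times in the 5-minute gaps assigned to the
later bin so the bins partition the day. Concentrations are treated as raw
(not flow-adjusted) values.

## Statistical layer

Difference scores are condition − session baseline, removing day and
time-of-day level differences. Outlier removal for the statistical layer
uses the consistency-scaled MAD (`stats::mad`, factor 1.4826) with a
threshold of 3 — the standard "MAD method" — unlike the pupil speed
criterion above, which is defined with the bare MAD; the two serve
different roles and are documented separately on purpose.

Paired real-vs-sham comparisons test the pair differences for normality
(Shapiro–Wilk at 0.05) and use a paired t-test when normality is not
rejected, otherwise a Wilcoxon signed-rank test (exact for n < 26, zero
differences dropped — the common convention). The normality gate is the
package's explicit selection rule for the usual "t or Wilcoxon as
appropriate". When significant at 0.05, Cohen's d for paired designs
(mean of pair differences over their SD) is attached; d conventions vary
across reports, so the convention here is declared rather than inferred.

Baseline checks use the Friedman rank-sum test over the four baseline
conditions (df = k − 1 = 3); identical columns are a fully tied degenerate
case where the statistic's limit, 0 with p = 1, is returned explicitly
(the textbook formula is 0/0 there). Significant baseline differences
trigger all pairwise *signed-rank* tests: the baselines are within-subject
measurements, so the paired rank test is the design-appropriate follow-up
even though such follow-ups are often loosely labelled rank-sum tests.
The Wilcoxon and Friedman implementations are checked against exhaustive
enumeration of sign assignments and within-subject rank permutations for
small n.

Mixed models are Gaussian random-intercept models (per subject) fitted by
REML with sum-coded contrasts on all factor predictors, Satterthwaite
approximate degrees of freedom (hence fractional df), and per-family
Bonferroni correction (for the PLR, the family is the 12 parameters). With
zero between-subject variance the fit collapses to OLS, which the tests
assert.

## The synthetic-data module

Generators emulate, with one explicit integer seed per call and no hidden
global state:

- **Resting pupil**: baseline diameter per eye, temporally smoothed
  measurement noise (a ~100 ms moving average of white noise rescaled to
  the target SD — tracker noise is correlated across neighboring samples,
  and white noise would produce non-physiological sample-to-sample
  velocities), V-shaped blink collapses below 1.5 mm with zeroed
  confidence, optional slow drift, and a gamma-shaped (shape 2)
  stimulation-locked dilation transient. Any smooth unimodal bump would
  satisfy the qualitative observation of a slight dilation at stimulation
  onset; the gamma form is chosen for realism, and its default amplitude
  (0.1 mm) is a free parameter of the generator, not an empirical claim.
- **PLR**: flat baseline, raised-cosine constriction from `d1` to `d2`
  between `t_latency` and `t_min`, exponential redilation with constant
  `redil_tau`. The closed-form parameter values (e.g.
  `Redil_50 = tau·ln 2`) are returned as ground truth.
- **Band power**: unit-variance Gaussian cells per subject × channel ×
  time with an optional standardized mean shift in a stated window, plus
  the truth mask — the canonical null/effect input for cluster inference.
- **Behavior**: the independent-race agent above and a GNG agent with
  stated omission, wrong-hand and commission rates.
- **Saliva**: log-normal concentrations around a 75 U/mL geometric mean
  (a realistic adult sAA level) with subject-level variation, a fractional
  circadian increase per hour, a condition effect added to
  real-stimulation cells, and ~1 g sample weights over 2-minute
  collections.
- **ERP**: Gaussian-bump components in noise for P300 recovery tests.

What the generators deliberately do *not* model: biophysical pupil or EEG
dynamics, eye-tracker model-fitting artifacts, ocular/muscle/stimulation
artifacts of the kind ICA removes, luminance effects, circadian EEG
drift, or assay chemistry. Passing tests therefore demonstrate
*algorithmic* correctness (thresholds applied as specified, estimators
recovering known truth, error rates controlled under the stated null) —
not robustness to every failure mode of real laboratory data.

## Problem sizes and runtime choices

The test suite and the analysis scripts run complete but compact studies:
typically 5–12 synthetic subjects, 4–5 stimulation replicates per
condition, 12-flash PLR sessions, 16–32 channel band-power arrays with
50 time points, and 100–1000 permutations per cluster test; the
family-wise error-rate study uses 500 null datasets of 20 × 32 × 50. These
sizes were chosen so every stage, including the Monte-Carlo validity
checks, completes comfortably on a single CPU while keeping the
statistical checks well-powered; all of them scale up by changing
arguments, not code.

## Known limitations

- `ACmax` from 4 Hz-filtered traces carries the ringing bias described
  above.
- The Morlet edge flag marks samples within half a wavelet of the epoch
  boundary, but no taper is applied; epochs are expected to include ≥ 1 s
  of pre-stimulus data.
- The automated PLR quality gates are surrogates for visual inspection;
  they encode the four criteria literally and will not catch every
  artifact a human would.
- The EEG path accepts CSV matrices and in-memory arrays; EDF files are
  not parsed.
- Friedman follow-ups and the t/Wilcoxon gate involve binary decisions at
  0.05; near-threshold data can flip branches across otherwise negligible
  perturbations. The chosen branch is always reported in the result.
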