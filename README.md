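# tavnspipe

Analysis pipeline for sham-controlled transcutaneous auricular vagus nerve
stimulation (taVNS) crossover studies comparing short (3.4 s) and long
(30 s) stimulation protocols.

taVNS stimulates afferent vagal fibers at the cymba conchae (sham: the
earlobe) and is thought to drive the locus coeruleus–norepinephrine
system. Because LC activity is not directly observable in humans, studies
read it out through indirect markers. This package implements the complete
analysis chain for those markers, for researchers who need a tested,
scriptable pipeline rather than a collection of one-off notebooks:

- **Salivary alpha-amylase / cortisol** — flow-rate-independent secretion
  (U/min = concentration × sample weight / collection time), circadian
  binning, condition − baseline difference scores.
- **Resting pupil** — stimulation-locked replicates (2 s baseline + ON +
  post windows), a median + 6·MAD speed criterion with a 2% exclusion
  rule, confidence/velocity blink detection, a 1.5–9 mm range filter with
  5%/60% invalidity gates, interpolation, 100-sample smoothing,
  subtractive baseline correction, ±2.5 SD baseline z-screening, 10%
  subject retention control and 10 Hz downsampling — every exclusion
  logged with its rule.
- **Pupillary light reflex** — zero-phase 3rd-order 4 Hz Butterworth
  smoothing, [−1, 9] s epochs around 12 flashes, automated quality gates,
  and the 12 reflex parameters: D1, D2, AMP, Rel_AMP, T1, T2, T3, VCmax,
  ACmax, Redil_25/50/75.
- **EEG** — 0.1–50 Hz band-pass, 10 kHz → 1 kHz resampling, 25 Hz notch,
  spherical-spline bad-channel interpolation, Morlet band power (6 cycles,
  alpha 8–13 / theta 4–8 Hz, −1–0 s baseline), No-Go P300 peak at Pz.
- **Cluster-based permutation inference** — a from-scratch one-sample,
  two-tailed spatio-temporal cluster test: per-datapoint t values,
  same-sign connected components over temporal + channel adjacency,
  cluster mass = summed t, max-|mass| null from subject-wise sign flips,
  p = (1 + #{null ≥ |mass|}) / (n_perm + 1).
- **Behavior** — Go/No-Go scoring with a 1-back rule (accuracy, error
  rate, Go RT), stop-signal sessions with the ±50 ms SSD staircase from
  300 ms, and SSRT by the integration method with omission replacement:
  SSRT = Q_p(go RT) − mean SSD, p = P(respond | stop).
- **Statistics** — difference scores, 3·MAD outlier removal,
  Shapiro-gated paired t / exact Wilcoxon with paired Cohen's d, Friedman
  baseline checks with signed-rank follow-ups, and random-intercept mixed
  models (REML, sum-coded contrasts, Satterthwaite df, Bonferroni).

A synthetic-data module (`gen_*` functions) generates every input modality
with known ground truth — parametric light reflexes with closed-form
parameter values, an independent-race stop-signal agent, null or
effect-injected band-power arrays — so the full pipeline runs and is
testable without access to raw study recordings.

## Worked example

Score a simulated stop-signal session and estimate the stop-signal
reaction time:

```r
library(tavnspipe)

agent <- race_agent(go_mu = 400, go_sigma = 50, go_tau = 60, ssrt_true = 250)
session <- run_staircase_session(agent, seed = 1)   # 4 blocks x 64 trials
ssrt <- estimate_ssrt(session)
round(as.numeric(ssrt))
#> [1] 255
attr(ssrt, "p_respond")
#> [1] 0.515625
```

The staircase held the agent near 50% inhibition (p_respond ≈ 0.52) and
the integration estimate, 255 ms, recovers the generative 250 ms stop
latency within a few milliseconds.

Detect an injected band-power effect with the cluster permutation test:

```r
g <- gen_eeg_epochs(n_subjects = 20, n_channels = 8, n_times = 40,
                    effect_window = list(channels = 2:6, times = 10:29),
                    effect_size = 2, seed = 11)
adj <- build_adjacency(standard_montage_64()[1:8, ])
res <- cluster_permutation_test(g$data, adj, n_permutations = 500, seed = 12)
subset(res$clusters, significant)
#>   id sign     mass n_members           p significant
#> 3  3    1 962.7129       100 0.001996008        TRUE
```

One positive cluster of exactly the 100 injected datapoints is
significant at p ≈ 0.002; the mass is the summed t over its members.

The numbered scripts under `analysis/` run the full study end to end on
synthetic data — `01_simulate_study.R` materializes raw-level inputs,
`02`–`06` run each modality (saliva, resting pupil, light reflex, EEG,
behavior), `07_full_study.R` runs everything through `run_study()` — and
write their tables under `results/`.

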