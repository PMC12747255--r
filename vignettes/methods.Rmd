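---
title: "Methods: ensemble and population analyses for risky decision-making"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble and population analyses for risky decision-making}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(riskensembles)
```

This vignette is the package's account of its methods: the models behind
each stage, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the numerical decisions taken where the
design was genuinely open. It states no empirical result that the test
suite does not itself compute.

## The task model

The risky-decision test (RDT) runs `n_blocks = 3` blocks of
`trials_per_block = 30` trials, each opening with `forced_per_block = 8`
forced-choice trials (4 per side, pseudorandom order with no side repeated
more than 3 times consecutively) followed by `free_per_block = 22`
free-choice trials. Large-reward selections are punished (0.1 mA footshock)
with per-block probability `block_punish_prob = (0, 0.5, 0.75)`. Forced
large-reward trials carry *exactly* the block proportion —
`forced_shock_counts = (0, 2, 3)` of 4 — because the task guarantees the
animal experiences the programmed rate; free-choice punishments are drawn
i.i.d. Bernoulli at the block probability at choice time. The task
program's wording admits either an i.i.d. or a constrained draw for free
trials; we chose i.i.d. as the simplest reading, and the property tests
check the realized rate only to binomial accuracy. The reward-magnitude
(RM) session is the identical structure with all punishment probabilities
zero.

Two schedule generators are deliberately exact rather than stochastic: the
progressive-ratio requirement for reward *i* is 4·*i*, and the footshock
sensitivity ladder steps 0.02 mA every 10 s. The ladder's printed range
nominally starts at 0.00 mA yet contains 25 shocks; we treat 0.00 as the
pre-test baseline and emit 0.02–0.50, which is the only reading that
reconciles range, step and count.

## The behavioral agent

`agent_policy()` is a softmax value agent: free-choice
P(large) = logistic(β·(v_L − w·p − v_S)) with utilities `value_large = 4`,
`value_small = 1` (the 20:5 µl reward ratio on a unit scale), risk weight
`w = 6` and inverse temperature β = 1. These defaults put free-choice
large-reward preference near 95/50/20% across the 0/50/75% blocks — a
risk-averse animal; they were chosen once from the choice model, not fitted
to any dataset. Choice latencies are lognormal with mean
`2 + 3·p` s; post-ITI initiation delays are lognormal (sdlog 0.8) with mean
`4 + 4·p` s. The long-tailed initiation delays matter beyond realism: they
keep trial timing irregular, which the circular-rotation controls below
require (a metronomic session stays aligned to its own rotation). Aborts
precede a choice with probability 0.05, rising to 0.5 on the trial after a
punishment, with targets biased 3:1 to the large-reward screen.

## The trace generator and its ground truth

`simulate_traces()` plants a known population. Each neuron draws a
remapping status with *exact rounded counts* — `conserved` (event-locked in
all blocks) 12%, `lost` (block 1 only) 26%, `new` (blocks 2–3 only) 20%,
the rest pure noise — and event-locked neurons draw an encoded category
(pre-choice, post-choice rewarded/punished, consumption, abort) from
configurable weights. Transients are double-exponential calcium kernels
(rise 0.2 s, decay 1 s, peak-normalized), one per relevant event, onset
jittered uniformly within the *first half* of the category's epoch window
so that epoch means are robust to alignment choices. Amplitudes are
Normal(1, 0.2) dF/F truncated at zero, scaled by a per-neuron lognormal
factor (sdlog 0.4). The heterogeneity term is essential, not cosmetic:
with identical mean amplitudes the ensemble population vector is nearly
constant across neurons and its correlation with instantaneous activity is
noise-dominated; real populations vary widely in response size. Pre-choice
amplitudes are coupled to choice latency at a target Pearson r (−0.3) via a
Gaussian copula on the standardized latencies. All neurons receive white
noise (SD 0.1 dF/F) plus two slow sinusoids (periods 50–200 s, amplitude
10% of the mean transient) emulating baseline drift.

What the generator does **not** emulate: biophysical spike-to-fluorescence
dynamics, sensor nonlinearity and saturation, correlated (shared) noise
across neurons, bursts and graded event responses, motion artifacts, or
source-extraction crosstalk. Passing recovery tests therefore show the
analysis chain is correct and calibrated on data satisfying its own
assumptions — not that real recordings will yield these sensitivities.

## Peri-event alignment

`extract_peri_event()` slices each neuron around each event with
nearest-sample alignment and half-open bins [t, t + bin); the default full
window is (−10, +10) s, wide enough to contain every epoch sub-window with
margin, and configurable. Events whose window leaves the recording are
dropped with a warning rather than padded. `zscore_per_trial()` normalizes
each (neuron, event) slice by its own window mean and population SD
(ddof 0); constant slices map to zeros and are flagged. We z-score over the
full extraction window rather than a pre-event baseline — the window is a
configuration knob for users who prefer baseline normalization. The
z-scored tensor is the substrate for *every* downstream statistic,
including the decoding feature construction; this uniformity is what makes
slow drift harmless to epoch means.

## Ensemble identification

The membership rule: empirical statistic = across-event mean of the
epoch-window mean of per-trial z-scored activity; null = the same statistic
after shuffling each (neuron, event) slice in time, repeated
`n_shuffle = 1000` times; member iff empirical > null mean + 1.5 × null SD
*and* empirical > 0 (negative deflections are uninterpretable under slow
indicator decay, so only increases count). Open choices resolved here:

- **Shuffle mechanism.** Default is an independent uniform *circular shift*
  per slice, which preserves autocorrelation and is therefore the more
  conservative null; full within-slice permutation is available via
  `shuffle = "permute"`. (Implementation note: a circular shift followed by
  a fixed epoch mean equals the mean of a circularly wrapped window at a
  uniformly random start, so all 1000 shuffles reduce to one cumulative-sum
  pass per slice.)
- **Null SD.** The SD of the 1000 shuffle statistics, not of raw bins.
- **min_events = 5.** Below that the category is "not evaluable" (NA), never
  silently FALSE.

The 1.5-SD rule is a fixed threshold, not a p-value; the suite *documents*
its effective false-positive rate on pure noise (stable across seeds,
bounded near the Gaussian tail expectation) rather than assuming one.

For safe-versus-risky comparisons, blocks 2 and 3 are pooled and then
sub-sampled without replacement (`match_trial_counts()`) to the safe-block
event count, since membership thresholds depend on trial number. Both
denominators for conserved/lost/new fractions are reported: over all imaged
neurons and over safe-identified neurons.

## Population statistics

**PV correlations.** The ensemble population vector is the across-event
mean of epoch means, one entry per member neuron; it is correlated with
session-long activity rebinned to 100 ms (mean of the two native 20-Hz
samples). Per-trial window means of this series, contrasted safe versus
risky, carry the remapping signature; across-subject inference is a paired
t-test on per-subject block means.

**Permutation time-series test.** Group labels are fully re-randomized
(equivalent to row shuffling of the stacked matrix) 1000 times; per-bin
p = fraction of permutations with |Δmean| at least the observed; bins pass
at p < α = 0.001 and must come in runs of ≥ 10 consecutive bins. With
n_perm = 1000 the p floor is exactly α, so strict `<` means only bins with
*zero* exceedances pass; `strict = FALSE` is provided for the non-strict
convention and a warning fires whenever n_perm < 1/α.

**Bootstrap difference-from-zero.** Neurons are resampled with replacement
1000 times; the per-bin percentile interval at α = 10⁻⁴ (effectively the
bootstrap extremes at this resolution — the warning says so) must exclude
zero, again in runs of ≥ 10.

**PCA divergence.** The two event-aligned mean matrices are concatenated in
time, z-scored per neuron, decomposed by PCA; the per-bin |PC1(A) − PC1(B)|
distance is compared with 100 circular-rotation nulls. A 0.001 quantile is
unattainable from 100 draws, so the operational rule is strict exceedance
of the per-bin null maximum, with the effective alpha 1/(n_null + 1)
reported and n_null configurable upward.

**Neutral band.** Pairwise-correlation summaries call |r| < 0.1 "neutral";
the positive/negative/neutral split is otherwise threshold-free.

## Decoding control

Class 0 is the empirical events × neurons matrix of epoch means; class 1 is
the identical extraction after circularly rotating each neuron's
session-long trace by an independent uniform offset. Features are z-scored
per column after stacking; the classifier is a linear SVM (cost = 1, no
hyperparameter search) with stratified 5-fold cross-validation scored by
held-out F1; chance is estimated by decoding two independent rotations of
the same data. Because the source description of the feature geometry is
ambiguous (a literal reading stacks all (neuron, event) scalars into a
single feature), both constructions are implemented — `mode = "matrix"`
(default, standard practice) and `mode = "scalar"` — and neither is claimed
to be the original computation.

A property of this control worth knowing: with a *single* rotation per
neuron per class, the two classes are fixed datasets and a classifier can
exploit chance alignment differences; the baseline F1 therefore sits
slightly above 0.5 and grows with the number of simultaneously event-locked
high-SNR neurons and shrinks with the number of events. The calibration
tests run at per-subject scale (a 12-neuron event-locked ensemble, ~90
events), where the baseline stays within 0.5 ± 0.1 while empirical
ensembles decode near ceiling.

## Photometry

Within each 10-s peri-event window the control channel is regressed onto
the signal channel by OLS and dF = signal − fitted control, z-normalized by
the window's own mean and SD; whole-session fitting and
baseline-sub-window normalization are options. A constant control channel
degenerates the fit and falls back to mean-offset subtraction with a
warning. The regression makes dF invariant to any artifact entering both
channels affinely, and z-normalization makes the pre-choice AUC
(trapezoidal, −4..0 s) scale-free; both invariances are tested. Event-mean
confidence bands are 95% percentile intervals from 1000 event resamples.

## Behavioral statistics

Latency flags follow a mean-referenced bootstrap: 1000 resampled means of
the 30 safe-block latencies give a percentile CI (two-sided level
1 − 0.001), and a trial is flagged when its latency exceeds the upper
bound; flags are upper-sided only because risk slows responding. Note that
this compares a single trial against the CI of a *mean* of ~30 values, so
the rule is deliberately liberal as a per-trial test: under the null a
same-distribution trial exceeds the bound with probability near
P(Z > z₁₋α/₂/√30) ≈ 0.27, not α. It is a screening rule for latency
curves, not a calibrated per-trial test, and the suite measures (rather
than hides) this behavior. Proportion comparisons use the pooled-SE
two-proportion z and the equivalent χ² (z² = χ² on a 2 × 2, verified
against `prop.test`). K-means on the neurons × 3 epoch-mean matrix uses
correlation distance via Lloyd iterations on row-standardized profiles, 20
restarts, empty clusters re-seeded from the farthest point, constant rows
excluded with a warning.

## Problem sizes and determinism

The validation suite uses sizes chosen to exercise each statistic at
realistic scale: 300 neurons × 22 events per block for ensemble recovery
and dynamics (sensitivity/specificity and fraction recovery), 120 neurons ×
5 subjects for the PV remapping signature, 12-neuron ensembles for the
decoding control, 200 repeats for resampling-test calibration, and ≥ 10⁴
simulated free choices for the punishment-rate check. Every stochastic
operation takes an explicit seed; `run_pipeline()` derives per-stage seeds
from a master seed and stable operation tags, and identical configurations
reproduce bit-identical outputs.

## Known limitations

Cross-session neuron registration is out of scope — analyses that span
sessions consume an externally supplied mapping. Inferential ANOVA-style
behavioral statistics are not reimplemented; the package reports
descriptive per-block summaries and the resampling tests described above.
The generator's noise model is white plus sinusoidal drift; heavy-tailed or
shared noise would lower the identification sensitivities the tests
demonstrate, and users applying the pipeline to real recordings should
treat the synthetic calibrations as upper bounds.
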