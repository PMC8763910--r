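---
title: "Methods: multi-modality digital biomarkers for Parkinson's disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modality digital biomarkers for Parkinson's disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Parkinson's disease (PD) expresses itself in motor signals that consumer
smartphones can capture: slowed and irregular finger tapping
(bradykinesia), a 4–6 Hz tremor band in accelerometer streams, degraded
stride regularity during walking, and unstable sustained phonation
(jitter and shimmer).  `pdsense` implements the full analysis pipeline
that turns such per-task sensor *records* into an individual-level PD
score: record simulation, batch-wise normalization and augmentation,
1D convolutional classifiers per modality, individual-level repeated
cross-validation with record pulling, late fusion across modalities, and
comparison against self-reported symptom ratings.

Everything here runs on synthetic cohorts.  The real study populations
that motivate the design live behind governed data portals; the package
is therefore built so that every stage is exercisable, testable and
reproducible without any download, while keeping the interfaces a real
data adapter would plug into (`R/io.R` is the single entry point for an
external record layout).

## The synthetic cohort generator

`cohort_config()` + `simulate_cohort()` draw a cohort of individuals and
their records.  The generator is a first-class, tested component — its
defaults *are* the study conditions, chosen to reproduce the printed
summary statistics of the motivating tapping study population:

* **Labels and demographics.** PD labels are Bernoulli with prevalence
  0.25.  Ages are drawn conditional on the label (PD: Gaussian around 62
  years; controls: a right-skewed 18 + Gamma distribution centered near
  40), which reproduces the steep rise of PD prevalence with age without
  distorting the marginal prevalence.  Gender and smoking are drawn
  independently of the label.
* **Record counts.** Each individual contributes `1 + NB(mu, size)`
  records per modality, capped at 100.  Group means default to 40.2 (PD)
  and 6.06 (control) with dispersion 0.6, giving the heavy right skew of
  records-per-individual seen in volunteer-contributed data (median well
  below the mean).  Because capping lowers the mean of a heavy-tailed
  count, `mu` is calibrated by `uniroot` so the *post-cap* mean equals
  the configured target; the 10% recovery property is asserted at
  n = 2000 in the tests.
* **Severity.** A latent non-negative scalar: exactly 0 for controls,
  Gamma(shape 4, rate 2) for PD (mean 2, sd 1).  Every disease effect is
  linear in severity, so one knob controls task difficulty in recovery
  experiments.
* **Tapping.** Inter-tap intervals are lognormal with healthy mean
  0.13 s (about 153 taps in a 20-s record) and CV 0.12; severity
  multiplies the mean by `1 + 0.3 * severity` and the CV by
  `1 + 0.3 * severity`.  Taps alternate between two target buttons with
  Gaussian positional scatter (10 px healthy sd, times
  `1 + 0.6 * severity`).  The coupled accelerometer stream (100 Hz)
  carries the gravity offset, white noise, a decaying impulse per tap,
  and an additive random-phase sinusoid drawn from the 4–6 Hz tremor
  band with amplitude `0.25 * severity` m/s².  Record durations are
  Gaussian (mean 19.92 s, sd 0.2 s) truncated to [19.4, 20.2] s; the
  truncated-Gaussian jitter model is a stand-in, since only the range and
  mean of real durations are known.
* **Gait.** A stride oscillator (1.9 Hz fundamental plus one harmonic,
  largest on the vertical axis) whose phase performs a random walk; the
  walk's step size grows with severity, flattening the spectral stride
  peak, and the same tremor-band component is added.
* **Voice.** Sustained phonation built cycle by cycle from a 3-harmonic
  stack at a per-record fundamental (110–220 Hz), with cycle-to-cycle
  period perturbation (jitter, 0.4% healthy) and amplitude perturbation
  (shimmer, 3% healthy) growing linearly with severity.  The default
  sampling rate is 4 kHz rather than the 44.1 kHz of real recordings:
  it preserves the fundamental and first harmonics that the jitter and
  shimmer statistics live on while keeping data volumes desk-scale; the
  real rate remains one config entry away.
* **Self-reports.** Part 2 (motor experiences of daily living) is
  `max(0, 8 * severity + N(0, 3))`; the total adds an independent
  `max(0, 14 * severity + N(0, 5))` remainder, so part 2 never exceeds
  the total and a noiseless control reports (0, 0).  The reporting noise
  makes self-report a strong but imperfect separator — the ordering the
  package is designed to probe.

What the generator does *not* emulate: biomechanics, device heterogeneity,
medication ON/OFF session structure, missing-data patterns, or any
correlation between modalities beyond the shared severity.  Passing
recovery tests on these cohorts therefore demonstrates that the pipeline
is correct and leak-free, not that its absolute AUCs transfer to real
populations.

## Normalization and augmentation

All training-time preprocessing is *batch-local*: statistics are computed
on each mini-batch alone, never on the full dataset, so no global
statistic can leak across the train/test boundary.  The operator order is
fixed: normalize → time scale → rotate → magnitude scale.

* `zscore` scales each channel to batch mean 0 and population sd 1 (a
  zero-variance channel keeps a unit divisor with a warning); `center`
  subtracts the per-channel mean — for coordinate batches this centers
  timestamps too; `boundary` re-expresses tap coordinates relative to the
  target-button bounding box.
* Time scaling resamples each item by 1-D linear interpolation with a
  coefficient drawn uniformly from (0.8, 1.2), then refits to the model
  input length.  Linear interpolation with endpoint preservation was
  chosen because it is exactly testable against a closed form.
* 3D rotation applies a quaternion rotation with axis uniform on the unit
  sphere and angle uniform on (0, 2π); it is an isometry on each
  time-sample vector (asserted at 1e-9).  2D rotation of coordinate
  channels pivots about the item centroid so it commutes with centering.
* Magnitude scaling multiplies each channel by an independent uniform
  (0.8, 1.2) coefficient.

Modality defaults follow the best-performing stacks: accelerometer and
gait models use z-score + 3D rotation + time + magnitude; the coordinate
model uses centering with **2D rotation disabled** and **boundary
normalization disabled** — rotating tap positions or normalizing by the
button bounds degrades the coordinate signal, and both are retained only
for ablation studies.  Prediction passes never augment and normalize each
record on its own statistics, making them pure functions of the record.

## The classifiers

Each modality gets a compact 1D convolutional network:
`n` blocks of (same-padded convolution → ReLU → max-pool) followed by one
sigmoid unit. Block counts are fixed — 7 for the accelerometer, gait and
voice stacks, 6 for the coordinate stack — with default input lengths
2500 (accelerometer/gait), 800 (coordinates: x, y and timestamp as three
channels, zero-padded event sequences) and 40000 (voice, pool width 4).
Kernel width 9, pool width 2 and filter counts doubling from 8 (capped at
128) are conventional defaults; the block counts are the architectural
contract, everything else is overridable in `model_spec()`.
Forward and backward passes are implemented in compiled code
(`src/convnet.cpp`) with analytic gradients, verified against central
finite differences at 1e-6 and against an independent pure-R forward
implementation at 1e-12.

Training minimizes the binary cross-entropy
\(H_b(p) = -p\log\hat p - (1-p)\log(1-\hat p)\) (predictions clipped at
1e-7 for the reported loss; the gradient uses the jointly differentiated
sigmoid/cross-entropy form and needs no clipping).  The default optimizer
is a bounded Adam variant: the per-parameter adaptive step is clipped
into the band `final_lr * (1 ± 1/(γt))` (lower bound
`final_lr * (1 - 1/(γt+1))`), which starts wide and pinches onto
`final_lr` so late training behaves like momentum SGD.  Defaults: batch
size 8, learning rate 1e-4, `final_lr` 0.01, γ = 1e-3.  Training runs a
fixed number of epochs with no early stop; the returned parameters are
those of the epoch with the lowest validation loss.

## Cross-validation, pulling, metrics

Individuals contribute many records, so all partitioning is at the
individual level.  The headline protocol draws 5 independent Monte-Carlo
75/25 train/test partitions (a partitioned K-fold mode exists as an
option; repeated 75/25 draws cannot be a standard disjoint 5-fold, and
the repeated-splits reading matches the protocol this package follows).
Within each training side a seeded half/half sub-split (also by
individual) separates fitting from best-epoch validation.  Splits whose
test set or training halves miss a class are redrawn with bounded
retries; a 1-individual test set is exempt from the both-classes
requirement, and when no class-balanced sub-split exists the plan falls
back with a warning rather than failing.

Only test-side predictions are kept.  A record tested by several splits
has its scores averaged into one record score; record scores are then
*pulled* to one score per individual by maximum (default) or mean.
Maximum pulling captures episodic peak abnormalities — PD motor
performance fluctuates — and empirically dominates mean pulling on such
generators, but note it is also inflated when record *counts* differ by
class (see the null-cohort paragraph below).

AUC uses the midrank Mann–Whitney formula (ties count ½), making it
invariant to class prevalence; AUPRC is the step-wise integral of the
precision–recall curve over distinct thresholds.  Both are verified
against brute-force oracles on all small tables.  Subgroup evaluation
strata are gender, smoking and the age bins ≤35, 35–50, 50–65, >65;
single-class strata are reported as undefined rather than dropped.

## Fusion and self-report comparison

Late fusion averages the pulled per-modality scores with equal weights on
the intersection cohort (individuals missing a modality are excluded and
counted).  On generators where components are independently noisy views
of a shared signal, the fused AUC beats each component on average — the
ordering the four-model assembly is designed to exploit.
`compare_self_report()` computes, on the self-report subset, the Pearson
correlations of model score with the total and part-2 symptom scores and
the AUCs of both self-report scores and the model against the PD label.
`benchmark_table()` reports per-split AUC means and spreads, sorted, with
descriptive two-sided t-tests between consecutive rows and no
multiple-testing correction.

## Numerical and design choices

* Zero is the padding value and tail truncation keeps the head of long
  records (`fit_length`), since zero is the neutral element of centered
  data.
* Per-record (rather than per-batch) normalization at prediction time
  makes scores deterministic and independent of batch composition; the
  train/test statistics mismatch this introduces is small at the default
  batch size and is the price of a pure prediction function.
* Determinism: every source of randomness flows through explicit seeds
  mixed per (split, epoch, record); the full simulate → train → evaluate
  pipeline is asserted bit-stable across reruns on one thread.
* The effect-size-zero control used in the acceptance experiments also
  *equalizes record-count means* across groups.  With per-record signals
  silenced but the 40.2 / 6.06 count asymmetry kept, max-pulling alone
  pushes individual AUC well above 0.5 — a real property of the
  generator (record count is itself a disease signal), not leakage — so
  a leakage check must silence it too.
* Desk-scale experiment sizes: the recovery experiments use 300
  individuals with 5-s tapping records (~38 taps, 500 accelerometer
  samples), coordinate input length 64, filters 4–16, and 6–8 epochs;
  the null, pulling, fusion and self-report experiments use 100–150
  individuals over 10–20 seeds.  These sizes are the package's chosen
  defaults for its own experiments; all are plain config arguments.

## Known limitations

The synthetic effects are additive/multiplicative stylizations; absolute
performance numbers on these cohorts say nothing about real-data AUCs.
The voice and gait models share the tapping architecture with adjusted
channel counts and pooling rather than modality-specific designs.  Class
imbalance is handled only through the rank-based metrics (no
reweighting), and fusion is an unweighted mean — weighted fusion is out
of scope.
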