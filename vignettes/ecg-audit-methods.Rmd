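---
title: "Auditing 12-lead ECG classifiers: models, assumptions and design choices"
author: "ecgaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing 12-lead ECG classifiers: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What this package audits, and why

Deep-learning classifiers that screen 12-lead ECGs for left ventricular
systolic dysfunction (LVSD, ejection fraction at or below 40%) are usually
validated on a single number — the AUROC. `ecgaudit` implements the two
complementary audit axes that a clinical validation additionally needs:

* **Transparency** — does the model rely on ECG features clinicians
  recognize? Quantified with concept activation vectors (TCAV) over the
  network's four feature blocks, and with unsupervised phenotype clustering
  of hidden features of positively predicted records.
* **Robustness** — does performance survive the two commonest acquisition
  artifacts, limb-electrode misplacement and additive noise? Quantified by
  re-scoring every record under each of the 12 distinct limb lead-reversal
  morphologies and under six noise models.

Because the original clinical model and cohort are not redistributable, the
package ships a seeded synthetic cohort generator and a small trainable
surrogate network, so that every stage of the audit is executable and
testable end-to-end with no external data. The surrogate documents its own
architecture choices and claims no equivalence with any production model.

## The electrode-potential model

All lead arithmetic in the package runs through electrode potentials rather
than leads. A 12-lead ECG is generated by three limb electrode potentials
$\varphi_{RA}, \varphi_{LA}, \varphi_{LL}$ (the right leg is a driven/ground
electrode) and six chest potentials $v_1 \dots v_6$:

$$ I = \varphi_{LA}-\varphi_{RA},\quad II = \varphi_{LL}-\varphi_{RA},\quad
   III = II - I, $$
$$ aVR = -\tfrac{I+II}{2},\quad aVL = I-\tfrac{II}{2},\quad
   aVF = II-\tfrac{I}{2},\quad V_i = v_i - \mathrm{WCT}, $$

with the Wilson central terminal $\mathrm{WCT} =
(\varphi_{RA}+\varphi_{LA}+\varphi_{LL})/3$. We adopt the WCT-zero gauge
($\varphi_{RA}+\varphi_{LA}+\varphi_{LL} = 0$), which makes the inversion
unique: $\varphi_{RA} = -(I+II)/3$, $\varphi_{LA} = (2I-II)/3$,
$\varphi_{LL} = (2II-I)/3$.

**Equipotential legs.** The single physical assumption is
$\varphi_{RL} = \varphi_{LL}$: both legs ride at the same potential. It is
the standard electrophysiological idealization, and it is the only
assumption that reproduces two published facts simultaneously — that the
LL/RL cable swap is electrically silent, and that the $4! = 24$ limb-cable
placements collapse to exactly **12** distinct lead morphologies.
`enumerate_reversal_classes()` proves the collapse constructively: each
permutation becomes an $8\times 8$ linear map on the channel basis
$(I, II, V_1..V_6)$ (the other four leads are determined), and
deduplication leaves 12 classes of 2 members each. Six classes leave the
precordials untouched — exactly those whose active cables read a
permutation of the three distinct site potentials (unchanged Wilson sum) —
and the same six are the invertible ones; the other six put at least one
active cable on a leg site and annihilate a limb degree of freedom.
`apply_reversal()` never permutes chest electrodes (cable swaps at the
limbs only), but the precordials still move through the recomputed Wilson
terminal.

## The synthetic cohort: a stated world

`simulate_record()` synthesizes a 3-D cardiac dipole as a sum of Gaussian
bumps (P, Q, R, S, T, optional mid-QRS notch and late anterior deflection),
projects it onto nine fixed lead-field vectors (an equilateral Einthoven
triangle in the frontal plane; six chest vectors with independent
leftward/anterior mixes), adds white **electrode** noise, and only then
forms leads from potential differences. Consequences that the tests rely
on:

* Einthoven and augmented-lead identities hold **bitwise** (deviation 0),
  whatever the noise floor — noise enters at the potentials, and the
  derived leads are computed from I and II with the same arithmetic the
  consistency checker uses.
* Chest leads respond to reversals only through the Wilson terminal, which
  is exactly the pathway the reversal module must exercise.

The two-class world (`default_class_configs()`): the LVSD-like class has
wider QRS (135 ± 15 ms vs 90 ± 8 ms), lower QRS amplitude (0.80 vs 1.05),
deeper Q waves, 60% vs 5% T-wave inversion, leftward-shifted axis, more
irregular rhythm and higher heart rate. LVEF is drawn uniform(15, 40) for
LVSD and normal(64, 7) truncated above 40 otherwise, matching the scale of
published cohort tables, so the score–LVEF Pearson correlation stage has a
monotone structure to find. Metadata (age, sex, hypertension, diabetes,
coronary artery disease, chronic kidney disease) are drawn with
class-conditional prevalences at the published cohort's scale; they are
descriptive covariates, not drivers of the signal. What the generator does
**not** emulate: realistic beat-to-beat template variability, respiration,
pacing, conduction physiology beyond template deformation. A green test
therefore establishes that the audit machinery is correct, not that any
model generalizes to patients.

`single_trait_class_configs()` builds cohorts whose classes differ in
exactly one morphology trait — the causal ground truth used to validate
TCAV end-to-end.

Nine concept datasets mirror common ECG interpretation labels: atrial
fibrillation/flutter (irregular RR, absent P), left/right bundle branch
block (QRS ≥ 120 ms with a notched lateral or late anterior V1-dominant
deflection), left/right axis deviation (axis beyond −30°/+90°), prolonged
QT, nonspecific conduction disorder (wide QRS without bundle shape),
abnormal Q wave, abnormal T wave (inversion). Concept positives and cohort
classes are controlled by disjoint parameter distributions.

## The surrogate network

A 1-D pre-activation residual network: stem (15-tap convolution, stride 2,
rectifier, max-pool 4), four feature blocks of exactly three residual
blocks each (two 7-tap convolutions per block, identity shortcut, 1×1
strided projection at each block entry, ×2 temporal downsampling per
block), global average pooling, and a fully connected head. The score is
$100\,\sigma(\text{logit})$, so it lies in [0, 100] by construction, and
the default operating threshold is 9.7 with the boundary inclusive
(score ≥ 9.7 calls high risk), matching the fixed-sensitivity operating
point convention of the audited model family.

Design choices a maintainer should know:

* **No normalization layers.** The published description fixes only the
  block counts. We use He-style initialization, a down-weighted residual
  branch and ReLU; at desk scale (12 residual convolution layers, strongly
  separable classes) this trains stably in a few epochs and keeps the
  forward pass bitwise deterministic with no batch-statistics state. This
  deviates from the "pre-activation normalization" suggestion in the
  build contract; the simpler design was chosen after verifying training
  stability.
* **Pure R with BLAS.** Convolutions are implemented as one GEMM per
  filter tap against a padded, strided column view. With OpenBLAS a
  forward pass on a 12×2500 record costs ~25 ms; training the default
  desk configuration (channels 16/32/64/128, 300 training records, 4
  epochs, Adam, binary cross-entropy) takes under a minute on one CPU and
  reaches held-out AUROC ≥ 0.95. Analytic gradients are verified against
  finite differences in the test suite.
* **Pooled activation space.** `extract_activations()` returns the global
  time-average of a block's output feature map, making CAV and cluster
  dimensions independent of record length. TCAV gradients are taken in the
  same pooled space: the directional derivative of the logit under a
  uniform per-channel shift of the block output (the time-sum of the
  feature-map gradient). Whether a production TCAV pipeline differentiates
  pooled or unpooled maps is implementation-specific; ours is documented
  and self-consistent, and the score only uses the derivative's sign.

## TCAV

A concept activation vector is the unit normal of a ridge-regularized
linear logistic separator (IRLS, λ = 0.01, seeded held-out split for the
reported accuracy) between concept activations and a random pool, oriented
toward the concept. The TCAV score of a concept at a block is the fraction
of class examples whose LVSD logit increases along the CAV — 0.5 is the
uninformative null, and negating the direction maps a score $s$ to $1-s$
exactly. Significance follows the repeated-runs recipe: one CAV per run
against a different random pool; the score is the run mean; the 95% CI is
the empirical 2.5/97.5 percentile across runs; the p-value is a Welch
two-sided test of concept-run scores against matched random-vs-random run
scores (pool $i$ vs pool $i+1$). `rank_blocks()` requires the complete
concepts × blocks grid and returns the block with the highest mean score,
ties broken toward the shallower block (logged).

On surrogates trained on single-trait cohorts, deep blocks (3–4) align
perfectly with the causal concept while shallow blocks may anti-align —
early features are generic and their pooled gradients need not point along
any one concept. This is why the block-ranking step exists; the acceptance
experiment asserts concept dominance *in the ranked best block*.

## Phenotype clustering

Positively predicted records (score ≥ threshold) are clustered on their
pooled activations at the top-ranked block. Features are standardized per
dimension (activation scales differ across channels). K-means uses seeded
greedy-spreading (k-means++-style) initialization with 10 restarts, best
inertia kept; the cluster count comes from the elbow rule, made precise as:
the k maximizing the perpendicular distance to the chord of the
unit-square-normalized **log**-inertia curve, anchored at k = 1 (total sum
of squares). The log scale matters: resolving a true cluster divides the
inertia by a large factor, and on a linear scale the k = 1 → 2 drop
swamps every later knee; the k = 1 anchor keeps the smallest candidate
selectable. The curve is guaranteed non-increasing because each k's
candidate initializations include the previous centroids plus the farthest
point. The 2-D view is an exact O(n²) t-SNE (perplexity-calibrated
affinities, early exaggeration, momentum descent, deterministic PCA
initialization plus seeded jitter) — adequate for the few hundred
positives of an audit. A fitted cluster model stores its standardization
and centroids so it can be fit on a development set and applied to a study
set.

## Noise models

Six seeded generators, all 12 leads, independent per-lead phases/segments,
common amplitude: power line (fixed 50/60 Hz sinusoid, random phase), EMG
(white noise band-passed 20–120 Hz), baseline wander (three sinusoids from
0.05–0.5 Hz), baseline shift (1–3 random switch points, ±0.5 mV steps),
partial white noise (segments covering 20% of samples), and time mask
(zeroing segments covering exactly `round(fraction × N)` samples — the one
non-additive type). Wander and shift are counted as two types to reach the
stated six. Default amplitudes follow ambulatory-artifact magnitudes
(0.25×RMS power line, 0.5×RMS EMG, 0.5 mV wander/shift, 1×RMS partial
white); since the appendix-level parameters of the audited study are not
published, these are declared defaults, exposed in `noise_spec()` and
logged. RMS-relative amplitudes are resolved to absolute mV when the spec
is constructed (reference: median record RMS, or 0.25 mV), so a given spec
injects an input-independent artifact — which is also what makes the
additivity check in the test suite meaningful.

## Statistics

AUROC is the pairwise-comparison probability (ties ½; verified against an
exhaustive oracle), with DeLong confidence intervals by default and a
seeded stratified bootstrap alternative; for a binarized predictor it
equals (Se + Sp)/2 to 1e-12. AUPRC is the step-interpolated
precision–recall area. Operating-point rates carry Wilson 95% intervals;
PPV/NPV with empty denominators are reported absent, never fabricated.
`threshold_for_sensitivity()` returns the largest cutoff whose sensitivity
meets the target. `confusion_from_rates()` reconstructs integer confusion
counts from printed sensitivity/specificity by nearest rounding — with
published group sizes 98/583 and Se 0.898 / Sp 0.940 it reproduces binary
AUROC 0.919, PPV 0.715, NPV 0.982 and 123 positive calls, the internal
consistency check used in acceptance. The CI methods of the original
report are unstated; DeLong/Wilson are this package's declared choices.

## Reproducibility machinery

Every random stage consumes a seed derived deterministically from one
master seed; `with_seed()` restores the caller's RNG state, so library
calls never perturb each other. `run_audit()` writes per-stage seeds,
status and artifact MD5 hashes into `manifest.json`; rerunning the same
configuration reproduces every CSV bitwise (asserted in the acceptance
suite). Serialization choices: JSON for configuration and the manifest,
RDS for checkpoints and the array container, CSV/WFDB for signals. WFDB
round-trips are exact to the ADC step (1/gain mV); CSV and RDS round-trips
are value-exact.

## Known limitations

* The surrogate is a desk-scale stand-in: its robustness profile is a
  property of the surrogate, not of any clinical model. In the default
  audit the surrogate is, for instance, far more sensitive to limb
  reversals than the published clinical system — the harness's job is to
  measure and report that, not to guarantee resilience.
* Quality-screening thresholds (flat lead SD < 0.01 mV, ≥ 10 samples at
  rail, any NaN) are stand-ins for an unpublished screening module.
* Precordial electrode misplacement, reversal detection, denoising and
  multiclass/relative TCAV are out of scope.
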