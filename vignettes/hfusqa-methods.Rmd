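---
title: "Methods: automated quality assessment of HFUS skin frames"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated quality assessment of HFUS skin frames}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

High-frequency ultrasound (HFUS, >20 MHz) examinations of the facial skin
are acquired as series of several dozen B-mode frames per probe sweep. A
large share of those frames is non-informative: the probe lost contact with
the skin (empty, near-uniform frames), the coupling-gel volume or probe
angle degraded the contrast, the geometry of the visualized layers is
disturbed, or classic acoustic artifacts (shadowing, enhancement) dominate.
Any automated downstream analysis — skin-layer segmentation, SLEB
measurement, lesion classification — degrades badly when such frames enter
the statistics, so an automated frame-selection (image quality assessment)
step is needed.

`hfusqa` implements a complete selection framework: multi-annotator label
fusion, CNN classification under a transfer-learning regime, score-level
fusion of per-expert models by majority voting or a Mamdani fuzzy inference
system (FIS), and a cross-validated evaluation harness. A synthetic data
generator emulates the statistical structure of an annotated HFUS cohort so
every stage can be exercised end-to-end without the clinical data.

# Label model

Each frame carries three binary expert annotations (`ok` / `no_ok`,
Expert 1..3; the first two are the same person annotating a week apart, so
their comparison measures intra-observer variability). The annotations are
fused two ways:

* **four-group consensus label**: group 1 — all three said `no_ok`; group 2
  — exactly one `no_ok`; group 3 — exactly two `no_ok`; group 4 — unanimous
  `ok`. The mapping is total on the $2^3$ label combinations with preimage
  sizes 1, 3, 3, 1.
* **binary majority label**: groups {2, 4} collapse to `ok`, {1, 3} to
  `no_ok`; this is identical to a per-frame majority vote.

Inter/intra-observer agreement is quantified with 2×2 confusion matrices
and unweighted Cohen's kappa,
$\kappa = (p_o - p_e)/(1 - p_e)$, interpreted on the Landis–Koch bands
(with the top band called "Perfect"): below 0 Poor, [0, 0.2] Slight,
(0.2, 0.4] Fair, (0.4, 0.6] Moderate, (0.6, 0.8] Substantial, (0.8, 1]
Perfect. Bands are closed on the right, which is the convention that
reproduces the published category calls (0.7822 → Substantial, 0.8214 →
Perfect). For degenerate tables where both raters use a single category,
$\kappa$ is defined as 1 when agreement is perfect; the $p_e = 1, p_o < 1$
case cannot occur for a count matrix (all mass in one cell forces it onto
the diagonal), but the implementation still guards it with an explicit
error rather than returning 0/0.

# The eight processing paths

Four binary paths and four multi-class paths share five training schemes:

| Path | Output | Training | Decision |
|------|--------|----------|----------|
| 1 | binary | reliable frames only (groups 1, 4), unanimous labels | score threshold |
| 2 | binary | all frames, majority-vote labels | score threshold |
| 3 | binary | one model per expert | majority vote of 3 predicted labels |
| 4 | binary | one model per expert | Mamdani FIS on 3 ok-scores, threshold 0.5 |
| 5 | 4-group | all frames, consensus group labels | arg-max of 4 scores |
| 6 | 4-group | as path 1 | ok-score through uniform bins |
| 7 | 4-group | as path 3 | group scheme applied to 3 predicted labels |
| 8 | 4-group | as path 3 | FIS output through uniform bins |

The uniform output bins are: below 0.25 → group 1, [0.25, 0.5) → group 3,
[0.5, 0.75] → group 2, above 0.75 → group 4. The value 0.5 is assigned to
the ok-side group 2, consistent with the upward tie rule of the binary
threshold, so the bins always collapse onto the binary decision
(groups {2,4} ⇔ `ok`). Path 6's binning rule is not spelled out beyond
"uniformly thresholded" in the source material for the framework; the
package reuses the path-8 bins, which are identical in spirit and keep the
two 4-group score paths comparable.

In multi-model paths each expert-specific model is seeded
`base_seed + expert_index`, and all models of a path are trained on the
same cross-validation split, so the voting stage compares like with like.

# The Mamdani voting system

Inputs are the three per-expert model scores for the `ok` class, each in
[0, 1]. The inference scheme is fixed: minimum AND for rule strength,
minimum implication (consequent sets clipped at the rule strength), maximum
aggregation, centroid defuzzification
$\hat y = \int y\,\mu(y)\,dy \big/ \int \mu(y)\,dy$ computed on a uniform
grid of 1001 points over [0, 1]. If the aggregated set is identically zero
the neutral value 0.5 is returned.

Default fuzzy sets (all breakpoints configurable, and the shipped YAML
specifications `inst/extdata/fis_binary.yaml` / `fis_fourclass.yaml` can be
edited freely):

* inputs: `low` = trapezoid (0, 0, 0.2, 0.55), `high` = trapezoid
  (0.45, 0.8, 1, 1). The supports deliberately overlap around the decision
  boundary: if `low` ended and `high` began exactly at 0.5, a score of
  exactly 0.5 would have zero membership in both sets, every rule involving
  that input would fail, and the output would fall back to the neutral
  value — a non-monotone glitch in an otherwise monotone response. With the
  overlap, the FIS output is non-decreasing in every input (verified on a
  $21^3$ grid) and permutation-invariant.
* outputs: four triangles of width 0.25 centred at 0.125, 0.375, 0.625,
  0.875, aligned with the uniform bins.
* rule base: symmetric, keyed on the number of `high` inputs — 0 high →
  lowest output set, 1 → low-mid, 2 → high-mid, 3 → highest. With crisp 0/1
  inputs exactly one rule fires and the centroid lands on the corresponding
  set centre, so the thresholded decision reproduces majority voting and
  the binned decision reproduces the group scheme. These defaults are the
  package's own declared sets, not a reconstruction of any particular
  deployed system.

The FIS output doubles as a confidence measure, $2\,|y - 0.5|$: frames
classified as definitely correct (or definitely not) score 1, boundary
frames score 0. Per-group histograms of the outputs
(`outputHistogram()`) show how confidence distributes over the consensus
groups.

# Classifiers

The package ships its own compact CNN engine (plain R, im2col matrix
multiplication, SGD with momentum on the categorical cross-entropy), with
three backbones:

* `vgg16` — the standard 13-conv-layer stack; by default the first 10
  convolution layers (definition order) are frozen.
* `densenet201` — dense connectivity with blocks (6, 12, 48, 32), growth
  32, bottleneck 1×1 convolutions and halving transitions: 200 convolution
  layers, the first 140 frozen by default.
* `tiny_test` — an 8× average-pool front end followed by two conv–bn–relu
  blocks (8 and 16 channels), global average pooling and a dense head;
  trainable from scratch at desk scale.

Shared hyperparameters follow the transfer-learning regime: SGD momentum
0.9, categorical cross-entropy, batch size 64, learning rate $10^{-4}$, 50
epochs for the two large backbones (50 rather than 100 because longer
training only inflates validation loss on this kind of data). Convolution
layers are counted in definition order for freezing, and frozen parameters
are verified to be bit-identical across training. Classification heads are
global-average-pool + dense, sized to 2 or 4 classes; class order is fixed
as (`no_ok`, `ok`) everywhere. Inputs are scaled to [0, 1] and, for the two
ImageNet-style backbones, standardized per channel with the usual ImageNet
statistics; no augmentation is applied.

`tiny_test` uses backbone-specific desk-scale defaults — learning rate 0.1,
batch size 16, 8 epochs — because a three-layer network trained from
scratch on a few hundred frames needs a far larger step size than a
pretrained backbone being fine-tuned, and smaller batches give enough
gradient steps per epoch at these sample sizes. Batch-normalization
inference statistics are re-estimated with one deterministic pass over the
training set after the final epoch (pooled first and second moments),
because running averages accumulated while the weights are still moving
are systematically stale on short schedules. Undersized remainder batches
(fewer than half the batch size) are dropped from the update loop unless
they are the only batch: the batch statistics of a handful of frames can
be near-degenerate, and a single such step is enough to throw a converged
model off. Training is deterministic given the seed: weight initialization,
shuffling and the statistics pass all flow from it.

Since no pretrained weights ship with the package, `vgg16` and
`densenet201` initialize randomly (He initialization) unless a checkpoint
is restored with `loadModel()`; their role in desk-scale runs is to express
and verify the freeze configuration, not to reach clinical accuracy.

# Evaluation harness

All experiments run under external 5-fold cross-validation: frames are
shuffled and dealt into five folds (sizes within one frame of each other);
within each fold's complement the frames are split 4:1 into training and
validation (the validation part is used for epoch logging only). Every
frame is predicted exactly once, by the models of the fold holding it in
the test set. Splitting is at frame level by default; a patient-level
grouping is easy to impose by filtering on `frameInfo()`, and frame-level
splitting is kept as the default because it matches the reference protocol
— note it is optimistic when consecutive frames of one sweep are
near-duplicates.

Metrics: accuracy, precision, recall, f1 from the confusion matrix
(rows = reference). Binary metrics report the `ok` class — the class the
selection step exists to find; multi-class metrics are macro-averaged.
Agreement between an algorithm and the experts is the same unweighted
kappa used for the annotators. The ten numbered evaluations map to
(path, reference-rule) pairs via `evaluationPlan()`: evaluation 1 is the
reliable-frames-only check of the path-1 model, 2/3/5/6 score paths 1–4
against majority labels, 7–10 score paths 5–8 against consensus groups,
and 4 scores per-expert models against their own expert's labels.

# Synthetic data generator

The generator emulates the *label and intensity structure* of an annotated
HFUS cohort, not the physics. A correct frame is a bright entry-echo band
(Gaussian profile, centre row 34 of 224) over depth-attenuated tissue with
multiplicative gamma speckle (shape 4) — the standard statistical stand-in
for fully developed speckle. The failure classes: `no_contact` (uniform
low-intensity noise, no band), `low_contrast` (dynamic range compressed by
$1 + 6(1-q)$, i.e. at least 4× for clearly bad frames), `geometry_artifact`
(band tilted by 22–52°, sometimes broken), `shadow` (dark vertical wedge
widening with depth). Severity ties to a latent quality score $q \in [0,1]$;
`correct` frames have $q \ge 0.7$, `no_contact` $q \le 0.1$.

Annotators flip the nominal label ($q \ge 0.5 \Rightarrow$ `ok`) with
probability $f_i \cdot b(q)$ where
$b(q) = \max\{0, 1 - ((q - 0.5)/0.35)^2\}$ peaks at the boundary and
vanishes for clear frames — so only ambiguous frames are contested, which
is what the real discordance pattern looks like. Experts 1 and 2 share a
flip rate (same person) with independent randomness. For two annotators
flipping a shared balanced label independently with constant probabilities
$p_1, p_2$, the expected kappa is $(1 - 2p_1)(1 - 2p_2)$; the test suite
verifies this parameter recovery by simulation at $n = 10{,}000$.

Default group proportions are taken from the published cohort's group sizes
(0.482 / 0.072 / 0.076 / 0.370, i.e. ~14.8% discordant frames, matching
the reported ~15%). To honour both the proportions and the flip mechanism,
`generateDataset()` draws each frame's *intended* group from the
proportions, synthesizes a frame whose class and quality are consistent
with it (discordant groups get mid-range qualities), and then
rejection-samples the annotator mechanism conditional on realizing the
intended group (cap 200 draws). When the mechanism cannot realize the group
— zero flip rates with a discordant group drawn — the unanimous nominal
label is kept, which makes "zero flip rates ⇒ zero discordance" exact.
Identical seeds give byte-identical datasets.

What passing tests on this generator do **not** show: robustness to real
speckle statistics, probe-pressure variation, anatomical variability
between facial sites, or annotator biases that are *not* boundary-local.
The constructed classes are deliberately separable, so the end-to-end
accuracy checks validate the pipeline's plumbing and the fusion logic, not
clinical-grade classification performance.

# Numerical choices and problem sizes

* Defuzzification grid: 1001 points (agrees with a $10^5$-point oracle to
  within $10^{-3}$); empty aggregate → 0.5.
* Binary decision threshold 0.5 with the tie assigned upward; 0.25 / 0.75
  act as confidence bounds, not decision thresholds.
* Label tokens accepted in annotation tables: `ok`, `no ok`, `no_ok`, `1`,
  `0`, case- and whitespace-insensitive; anything else is an error naming
  the offending cell.
* Resizing: bilinear, to 224 × 224 × 3; grayscale inputs are replicated to
  three channels, alpha channels dropped.
* The packaged study runs at $n = 600$ frames, `tiny_test`, 5 folds — a
  deliberate desk scale chosen so the whole pipeline (35 model trainings)
  completes in minutes on one CPU while still exercising every stage at
  meaningful sample sizes.

# Known limitations

* The two large backbones start from random weights here; reproducing
  clinical-scale accuracies requires ImageNet-pretrained weights and the
  full 17,425-frame cohort, neither of which ships with the package.
* Frame-level cross-validation can leak near-duplicate frames of one sweep
  across folds; use patient-level grouping for honest clinical estimates.
* The agreement analysis covers binary labels only (no weighted kappa, no
  more than two rating categories).
* The FIS defaults are declared, sensible sets — not a reconstruction of
  any specific deployed rule base; conclusions about FIS-vs-vote behaviour
  transfer only insofar as the rule base stays symmetric and monotone.
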