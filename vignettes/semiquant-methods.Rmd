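---
title: "Semi-quantitative T1 diagnosis of neonatal ABE: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-quantitative T1 diagnosis of neonatal ABE: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abeT1)
```

## The clinical problem and the score

Acute bilirubin encephalopathy (ABE) in neonates with hyperbilirubinemia
(HB) produces T1 hyperintensity in the deep-brain nuclei, most prominently
the globus pallidus (GP) and subthalamic nucleus (STN). Visual reading of
this hyperintensity is unreliable: normal myelination produces similar
signal, and inter-rater agreement is only moderate. The semi-quantitative
alternative implemented here replaces the visual impression with two ratios
measured on a single axial T1-weighted slice per subject — the slice
covering the largest cross-section of both nuclei:

$$\mathrm{GP_{norm}} = \bar{I}_{GP} / \bar{I}_{WM}, \qquad
  \mathrm{STN_{norm}} = \bar{I}_{STN} / \bar{I}_{WM},$$

where each $\bar{I}$ is the arithmetic mean intensity over the respective
region of interest and WM is an anterior subcortical white-matter reference
region. Dividing by the WM mean removes the arbitrary scanner intensity
scale; the ratios are exactly invariant under any positive rescaling of the
image (`normalized_intensities()` and a property test assert this).
Bilateral structures are pooled into one mean per region: the study design
reports a single score per patient and does not distinguish laterality.

A subject is called ABE when the score exceeds a cutoff chosen by the
Youden index $J = \text{sensitivity} + \text{specificity} - 1$, maximized
over the empirical ROC curve. `semiquant()` packages this estimator in the
usual modelling idiom: a formula/data fitting function returning an object
with `print`, `summary`, `coef`, `predict`, `plot`, and `simulate` methods.

## ROC construction, AUC and the cutoff

`roc_curve()` places operating points at every threshold that can change
the confusion matrix: the midpoints of adjacent distinct sorted scores,
plus one sentinel below the minimum and one above the maximum, so the
(0,0) and (1,1) corners are always present. The decision rule is
score $\ge$ threshold $\Rightarrow$ positive, because hyperintensity means
a higher score indicates disease; a score exactly at the cutoff is
positive. Reporting cutoffs as midpoints matches the reference analysis,
whose published GP cutoff of 1.3621 falls between achievable score values.

`auc()` integrates the curve with the trapezoid rule. Two independent
oracles guard it: `auc_rank()`, a brute force over all positive–negative
pairs (1 for a win, 0.5 for a tie), which must agree to within 1e-12 on
every instance, and `binormal_auc()`, the closed form
$\Phi\!\big((\mu_+-\mu_-)/\sqrt{\sigma_+^2+\sigma_-^2}\big)$ for normal
scores, which Monte Carlo means must approach. Youden ties are broken
toward the smallest threshold, favoring sensitivity; the tie convention of
the original software is unknowable, and this choice is asserted
explicitly in the tests so it cannot drift silently.

## Classification metrics and their display

`classification_metrics()` keeps full-precision fractions and formats a
display copy the way clinical tables print them: sensitivity and
specificity at one-decimal precision in percent padded to two decimals
(32/47 = 68.085% prints as "68.10%"), precision, F1, accuracy, and AUC at
two decimals. The two conventions coexist in the reference table and only
this per-metric rule reproduces the published row
68.10/78.10/82.05/74.42/72.15 from the matrix (tp, fp, fn, tn) =
(32, 7, 15, 25). Metrics with a zero denominator are flagged undefined
(`NA` plus a name in `undefined`), never silently zero.

Inter-rater agreement uses the standard Fleiss formulation
(`fleiss_kappa()`); accuracies of two methods are compared with a 2×2
Pearson chi-squared without continuity correction
(`compare_accuracy_chi2()`), which reproduces p = 0.014 for 57/79 vs 42/79
correct. Cohort covariates are compared with Welch's t from summary
statistics (`welch_t()`; a pooled option exists because the source's
t-test flavor is unstated) and the sex distribution with the same 2×2
chi-squared. `adjusted_group_test()` fits a least-squares model
`feature ~ group + covariates` and reports the partial F for the group
term — with no covariates this reduces exactly to the squared pooled t.

## The phantom cohort generator

No public data accompany the clinical study, so the package generates
synthetic cohorts whose statistical structure matches the published
design. The defaults of `phantom_config()` *are* the study conditions:
47 ABE and 32 non-ABE subjects; true subject-level ratios
GP 1.39 ± 0.06 vs 1.33 ± 0.06 and STN 1.47 ± 0.09 vs 1.42 ± 0.07
(the published dispersions are treated as SDs, consistent with the
sample sizes and t-test usage); covariate means/SDs and the male
proportion from the published cohort table; 18 axial slices per stack.
Postmenstrual age is emitted as gestational age plus chronological age.
Covariates are clamped to physiologic ranges (age to 1–18 days, the
study's inclusion window) to avoid nonsensical normal draws; BIND scores
are sampled metadata only (ABE cases have BIND ≥ 1 by definition).

The renderer draws an elliptical brain of WM-level tissue on every slice;
the central three slices carry an anterior WM reference ellipse (mask
code 1) and bilateral GP (2) and STN (3) ellipses, largest on the middle
slice so slice selection is deterministic. Regional clean intensities are
`wm_mean` × the subject's true ratio; voxel noise is independent
zero-mean Gaussian with SD = `noise_cv` × the local clean intensity
(default 0.02, chosen so the measurement error of an extracted ratio,
roughly noise_cv/√(region pixels) ≈ 0.002, is far below the
between-subject SD of 0.06), clipped at zero. Biological variation
therefore lives in the cohort sampler and measurement noise in the
renderer, which is what makes parameter-recovery experiments meaningful:
at 500 subjects per group the extracted group means recover the four
configured means within ±0.01.

What the phantom does **not** emulate: real neuroanatomy, partial-volume
effects, spatially varying hyperintensity within a nucleus, coil shading,
or 3-D acquisition physics. Passing recovery tests therefore demonstrates
that the measurement pipeline is unbiased for images satisfying the
uniform-regional-mean assumption — not that the scores behave this way on
real scans.

Datasets round-trip to disk as per-subject NIfTI image and mask volumes
plus a CSV cohort table and a JSON manifest recording the seed; replaying
the manifest seed regenerates a byte-identical cohort table.

## The desk-scale network protocol

The deep-learning component mirrors the reference training protocol at
sizes a single CPU handles in seconds to minutes: min–max normalization
to [0, 1], resizing and 3-channel replication (224 × 224 by default,
smaller in the experiments); augmentation by rotation in [−30°, 30°],
vertical flip with probability 0.5, zoom in [0.9, 1.1], and translation
in [−30, 30] px, applied in that order with reflection padding (the order
and padding are fixed here; the reference leaves them unstated);
a stratified 80/20 split with fivefold cross-validation inside the
training set; and SGD with momentum, learning rate 3e-4, minibatch 10,
6 epochs as the configuration defaults. Splitting is by subject by
default — a slice-level split lets slices of one patient straddle the
train/test boundary, and the slice-level mode exists only to mirror the
reference design.

The backbone is a compact residual network built from scratch: a 3×3
stem, two-convolution residual blocks obeying y = F(x) + x (asserted
numerically: zeroing the second convolution makes every identity block an
exact no-op), stride-2 downsampling with filter doubling and zero-padded
identity shortcuts, then global average pooling and a softmax classifier.
An 18-layer pretrained network is deliberately out of reach here: there
are no pretrained weights in this setting, and the reference network's
numeric results depend on unavailable patient data.

Training a network of this size from scratch on phantom slices required
three design choices that a pretrained pipeline never faces, each adopted
after the alternatives failed measurably:

* **Feature standardization at the head.** Phantom classes differ only
  over the ~2% of pixels inside the GP, so after global average pooling
  the between-class signal is a tiny fraction of the feature scale and
  plain gradient descent on the classifier stalls. The pooled feature
  vector is therefore standardized per channel (`calibrate_head()` at
  initialization, exponentially tracked during training, constant inside
  each backward step — so inference and training see the same map and
  nothing can leak through minibatch statistics). In-network
  alternatives behave worse here: per-image instance normalization makes
  the image's own background level class-informative and delocalizes the
  evidence, while true minibatch normalization lets a 10-image batch
  solve the task through batch composition and collapses at inference.
* **Discriminative learning rates.** The standardization amplifies
  gradients flowing into the convolutions by the inverse feature scale.
  `conv_lr_scale` sets the body's learning rate relative to the head;
  the bundled experiments freeze the body (`conv_lr_scale = 0`),
  training the classifier on the frozen random residual features, which
  is stable at every seed tried and reaches the accuracy the experiments
  need. Full-body training at the protocol settings remains the default
  configuration.
* **A zero-initialized classifier.** Every fully-connected weight is then
  learned evidence, which matters for interpretation: with random
  initialization, channels whose pooled feature barely varies across
  images acquire enormous standardized weights that are pure
  initialization noise.

Class activation maps follow the standard definition — the final
convolutional maps weighted by the predicted class's classifier weights,
upsampled and min–max scaled; the head's standardization is a fixed
affine map whose scales are absorbed into the weights. For a compact
from-scratch backbone the raw map is dominated by class-independent
spatial structure (edges, the anchor nucleus) that a deep pretrained
network's sparse features do not carry; `class_activation_map()`
therefore accepts an optional `baseline` (the training-cohort mean
feature map, `feature_map_baseline()`) whose subtraction localizes the
image's own evidence. `cam_localization_experiment()` uses it, together
with full-resolution 128 × 128 slices and a single-stage stride-1
backbone (receptive field ≈ 7 px, feature maps at image resolution) so
the ~10-pixel GP is resolvable at all, and scores the slice with the
largest GP cross-section per subject — the same slice a radiologist
would score. The experiment's phantom fixes the STN ratio at the global
intensity maximum in *both* groups so that per-slice min–max
preprocessing leaves the two classes differing only inside the GP; the
localization rate is computed over correctly classified ABE slices,
because the negative class's evidence is the *absence* of a local
pattern, which convolutional features cannot pin to a location.

## Numerical conventions and degenerate inputs

Empty ROI regions, single-class label vectors, constant images, zero WM
reference means, rank-deficient covariate designs, and all-one-category
rating matrices raise typed errors or explicit undefined flags rather
than returning sentinels. Slice indices are 0-based; mask codes are fixed
at {0 background, 1 WM, 2 GP, 3 STN}; a slice carrying the nuclei must
give each labeled region at least 20 pixels or rendering fails. All
randomness flows through R's session RNG, so a single `set.seed()` (or
the seed fields of the config objects) makes cohorts, splits,
augmentation, initialization, and training bit-reproducible.

## Problem sizes used by the tests and acceptance script

Monte Carlo ROC experiments use 10,000 replicate cohorts of 47 + 32
scores; parameter recovery renders 500 subjects per group at the default
18-slice, 128 × 128 geometry; the network experiments use 30 + 30
subjects at 128 × 128 (localization) and smaller 32 × 32 settings for the
chance-level and protocol checks. These sizes give Monte Carlo standard
errors an order of magnitude below the tolerances they are checked
against while keeping any single experiment under a few minutes on one
CPU.

## Known limitations

The phantom's geometric simplicity means recovery results bound
measurement bias only under the generator's assumptions. The published
Fleiss' kappa (0.5082) is not reproducible because per-rater ratings were
never published, and the reference network's performance row depends on
the unavailable clinical images; neither is asserted anywhere. The
desk-scale network experiments characterize the implemented protocol on
phantoms — they are not evidence about diagnostic performance of deep
networks on real neonatal MRI.
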