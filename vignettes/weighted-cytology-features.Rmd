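---
title: "Weighted deep features for seven-class cervical cytology: methods and design"
author: "cytoweight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted deep features for seven-class cervical cytology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The pipeline and its assumptions

`cytoweight` classifies single cervical cells into seven categories —
normal superficial squamous, normal intermediate squamous, normal
columnar, and mild / moderate / severe dysplasia plus carcinoma in situ —
from one of three views of each cell: the whole cell, the cytoplasm with
the nucleus excluded, or the nucleus alone. The views are realized by
masking, so the package assumes a binary nucleus mask is available per
image for the masked scenarios; it deliberately does **not** segment
nuclei (masks are inputs).

The modelling chain is: balance classes by geometric augmentation →
extract a fixed block of 7 features per extractor → concatenate blocks →
rank and select features by PCA loading magnitude → learn a multiplicative
weight in [0, 1] per selected feature by maximizing cross-validated
classifier accuracy → classify and report confusion-matrix metrics. The
weighting step is the scientific core: instead of a binary keep/drop
decision per feature, each feature receives a continuous relevance
multiplier, fitted by a population metaheuristic against the classifier
itself (a wrapper objective).

Key assumption of the wrapper objective: the cross-validated accuracy
surface over the weight hypercube is cheap enough to evaluate thousands of
times and informative enough that down-weighting noisy features raises it.
Both optimizers treat the objective as a black box; neither needs
gradients.

# Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| rotation range | [−20, 20] | degrees | published augmentation protocol |
| scale range | [0.1, 1] | factor | published protocol (shrink only) |
| translation range | [−1, 1] | pixels | published protocol; the unit is configurable because published ranges often omit it |
| augmentation fill | constant 235 | intensity | the bright slide background; filling with background avoids inventing tissue |
| target per class | 200 | images | the published balanced design (7 × 200 = 1400) |
| features per extractor | 7 (fixed) | — | one per class: the contract of a 7-way adapted head |
| selection k | 10 | features | the published 21 → 10 reduction |
| population / iterations | 30 / 100 | — | standard reference budgets for ALO and PSO; no budgets are published for the pipeline itself |
| PSO inertia | 0.9 → 0.4 linear; c1 = c2 = 2; clamp 0.2 × range | — | canonical PSO settings |
| ALO shrink schedule | w = 2,3,4,5,6 above iteration fractions 0.1, 0.5, 0.75, 0.9, 0.95 | — | the standard boundary-shrink schedule of the original ALO |
| CV folds | 5 | — | the convention of comparable published evaluations; any k ≥ 2 with every class ≥ k works |
| SVM | poly degree 3, C = 1, gamma 1/d | — | reference defaults; none are published for the pipeline |
| random forest | 100 trees, √d per split | — | reference defaults |

# The synthetic data generators

**Images.** Each image is a single-channel 8-bit raster: bright
background (235), a lighter cytoplasm ellipse (~180) and one darker
nucleus ellipse, plus Gaussian noise (SD 8) clipped to [0, 255]. Nucleus
area fraction and darkness are monotone in dysplasia grade (defaults
0.04–0.34 of image area and 35–105 intensity units below cytoplasm, from
normal superficial to carcinoma in situ), emulating the enlarged, darker
nuclei of higher grades. Per-class counts default to the Herlev
distribution (74/70/98/182/146/197/150). One master seed spawns
independent per-class substreams, so adding a class never shifts another
class's pixels. What the generator does **not** emulate: staining
texture, chromatin granularity, overlapping cells, debris, uneven
illumination, colour. Tests passing on these images therefore demonstrate
pipeline correctness and statistical behaviour, not clinical performance.

**Feature tables.** A planted-structure generator emits balanced tables
with `nInformative` class-informative and `nNoise` class-independent
standard-normal columns. Informative column 1 carries a centred ordinal
severity ramp (adjacent classes one separation unit apart — the analogue
of a feature tracking dysplasia grade); further informative columns carry
the binary code bits of the class index, scaled by the separation. This
makes the seven class means distinct and well separated for three or more
informative columns, while noise columns bound what an optimizer should
suppress. An earlier all-binary design was replaced once during
development because its minimum inter-class distance equalled the nominal
separation, leaving essentially no margin for the "linearly separable at
separation 4" property the generator is specified to provide.

# Numerical and design choices

**PCA scaling.** `fitPca()` centres columns but does not standardize by
default. Loading-magnitude importance weighted by explained variance
treats a variable's variance share as part of its importance; z-scoring
first equalizes all variances, which (i) destroys the intended behaviour
on variables of genuinely different variance, (ii) inflates
negligible-variance noise columns to unit variance, and (iii) empirically
inverts the informative/noise ranking on the synthetic tables (diffuse
noise loadings accumulate more weighted absolute-loading mass than
concentrated signal loadings). `scale. = TRUE` remains available for
feature sets on incommensurate scales. Ties in the importance ranking are
broken by the lower column index — deterministic and documented.

**Geometric transforms.** Rotation, scaling and translation use one
backward-mapping affine resampler about the image centre: bilinear for
pixels (exact at integer sample coordinates, so identity transforms are
bit-exact), nearest-neighbour for masks (masks stay binary), constant or
replicate fill. The output canvas always keeps the input size; the mask
undergoes the identical transform. Augmentation applies rotation, then
scale, then translation, each drawn uniformly from its range. Balancing
happens before fold splitting, matching the published order of operations;
this means augmented copies of one original can appear on both sides of a
CV split, which inflates absolute accuracies — a property of the emulated
protocol, not of this implementation. The
`pipelineConfig(augmentWithinFolds = TRUE)` switch removes that leakage by
grouping fold assignment on source cells (every augmented copy inherits
its original's fold), which is equivalent to augmenting within training
folds for fold-independent augmentation draws. The fitness comparison
that matters (weighted vs. all-ones baseline) always uses identical folds
either way.

**Frozen-fold fitness.** The stratified fold assignment of the weighting
objective is drawn once per optimization and frozen, and any
classifier-internal randomness is re-seeded identically per evaluation, so
the objective is a pure function of the weight vector. Without this, the
optimizers chase objective noise. Per-fold standardization is fitted on
the training part only; weights multiply the standardized columns.

**All-ones injection.** Both optimizers accept injected initial
candidates, and the pipeline injects the all-ones weight vector. With
elitist bookkeeping this guarantees the reported weighted fitness is ≥ the
unweighted baseline on the same folds — a provable property rather than an
empirical hope.

**ALO details.** Random walks are cumulative ±1 step sums of length
`maxIterations`, min–max rescaled into the current interval; a degenerate
interval yields a constant walk. The shrink ratio is `I = 10^w · t/T`
with the exponent schedule above. Roulette selection min-shifts fitness
values to be nonnegative and falls back to uniform selection when all are
equal. An ant replaces its ant lion only on strict improvement; positions
are clipped to [0, 1]^d. Budget accounting: at most
`population × (iterations + 1)` objective evaluations.

**Degenerate inputs.** Empty classes reject balancing (nothing to
augment); classes smaller than k reject stratified CV; zero-variance
columns are left unscaled rather than dividing by zero; a class row with
no samples reports NA sensitivity rather than 0; all-zero weight vectors
legitimately evaluate (the classifier collapses to majority behaviour,
~1/7 on balanced data).

**Extractor plugins.** The mock extractors compute 7 deterministic image
statistics (mean, SD, dark-pixel fraction, darkness-weighted centroid
offset and second moments, 10–90% spread) after resizing to each
extractor's canonical input (227² / 256² / 224² — the mobile variant for
the third backbone, chosen for desk-scale feasibility). A real CNN
backbone can be supplied via `extractorSpec(fun = ...)` under the same
7-feature contract; no weights are shipped or downloaded, and the test
path never requires one.

# Problem sizes used in the tests and acceptance script

Chosen as the package's own balance between statistical resolution and
desk-scale runtimes: synthetic images at 24–64 px; the full 917-image
class distribution for the balancing checks; feature tables with 30
samples per class (n = 210) for optimizer studies; recovery studies over
10 seeds with population 15 × 40 iterations and 3-fold SVM fitness;
optimizer oracle at the default 30 × 100 budget on a concave quadratic
validated against an exhaustive 11⁵ grid; end-to-end pipeline runs at 12
images per class with small optimizer budgets.

# Known limitations

- Headline accuracies from real Pap smear data with pretrained CNN
  features are not reproducible here: the synthetic renderer and mock
  statistics preserve the pipeline's statistical structure, not its
  absolute performance.
- Augment-then-split leakage (see above) is faithful to the emulated
  protocol; a leakage-free variant would augment within training folds
  only.
- The wrapper objective is piecewise constant (accuracy on finite
  samples); optimizers can wander across plateaus, and learned weights
  are identified only up to fitness ties.
- Nucleus segmentation is out of scope; masked scenarios need masks.
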