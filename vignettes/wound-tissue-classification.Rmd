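---
title: "Methods: wound-bed segmentation and tissue classification"
author: "woundtissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wound-bed segmentation and tissue classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundtissue)
```

# The problem

Chronic wounds — wounds that fail to heal through the orderly reparative
process for six weeks or more — are assessed clinically by the balance of
three tissue types in the wound bed: red **granulation** tissue (new
connective tissue and microvessels, a sign of healing), yellow fibrinous
**slough**, and black **necrotic** tissue (dead tissue from inadequate
blood supply). Visual estimation of these proportions on a red–yellow–black
scale is subjective and expert-intensive. This package implements an
automated alternative that works from an ordinary RGB photograph: segment
the wound bed, describe each tissue region quantitatively, and classify
regions into the three tissue classes with statistical learners.

# Pipeline and assumptions

## Preprocessing

Rapid clinical photography produces salt-and-pepper impulses. Each RGB
channel is median-filtered independently with a square window
(`medianFilterRGB()`, default 5 × 5 pixels). The median is computed
exactly; image borders are handled by **edge replication**, chosen so
that no artificial dark frame is introduced — a dark border would bias
the saturation statistics that the segmentation relies on. A constant
image passes through unchanged and the output range never leaves the
input range, per channel.

## Saturation-channel segmentation

The RGB image is converted to the geometric HSI model (`toHSI()`):
intensity $I = (R+G+B)/3$, saturation $S = 1 - 3\min(R,G,B)/(R+G+B)$
(with $S = 0$ for black pixels), and hue from the arccos formulation.
Saturation measures how far a color lies from gray. Skin is close to
achromatic while a vascularized or fibrinous wound bed is strongly
colored, so the wound boundary has its best contrast in the $S$ plane;
segmentation therefore runs on $S$ scaled to $[0, 255]$ (`sChannel()`).

The threshold is chosen by **fuzzy-divergence minimization**
(`selectThreshold()`). For a candidate gray level $t$, pixels split into
an object region ($f \ge t$) and a background; each pixel receives a
Gaussian membership expressing closeness to its own region's mean:

$$\mu(f) = \exp\!\left(-\frac{(f - m_{\mathrm{region}})^2}{2\sigma^2}\right),
\qquad \sigma = \tfrac{1}{2}(\max f - \min f),\ \sigma \ge 1 .$$

The exponential fuzzy divergence between this membership image $A$ and
the ideally segmented image $B$ (membership 1 everywhere) is

$$D(A, B) = \sum_{ij} \Big[ 2 - (1 - \mu_A + \mu_B)\, e^{\mu_A - \mu_B}
 - (1 - \mu_B + \mu_A)\, e^{\mu_B - \mu_A} \Big],$$

which is symmetric, non-negative, and zero only for identical maps. The
scan over all 255 candidate thresholds is exhaustive — gray-level
histograms only speed up the arithmetic, and the test suite checks the
result against a literal per-pixel re-scan. Ties are broken toward the
smallest minimizing threshold, for determinism. The object is the
high-saturation side, i.e. the wound.

Design choices worth flagging:

* **The reference image.** With a Gaussian membership alone the
  divergence needs a second image to compare against; we use the
  all-ones ("perfectly segmented") reference, so the optimizer rewards
  thresholds whose two regions are internally tight. This is the
  standard construction for this family of divergence thresholders.
* **The spread $\sigma$.** Half the dynamic range, floored at 1. This is
  parameter-free and scale-aware; it is deliberately wide so that
  memberships stay informative across the whole histogram rather than
  saturating near the region means.

The raw mask is then refined (`refineMask()`): morphological closing
then opening with a disk structuring element, hole filling, and
retention of the largest 8-connected component, yielding a single
compact wound bed. The disk radius scales with image size as
$\max(1, \mathrm{round}(3 \cdot \min(H, W)/512))$ — radius 3 on a
~0.25-megapixel frame, radius 1 on the 128 × 128 synthetic images used
throughout the tests.

## The 675-entry descriptor

Each tissue region is described on **45 color channels**: the three
components of 15 color spaces (RGB, HSI, XYZ, Lab, Luv, LCH, HSV, HSL,
YUV, YIQ, CAT02 LMS, YCbCr, full-range JPEG YCbCr, YDbDr, YPbPr), in the
fixed order of `channelManifest()`. The standards adopted where a choice
existed: sRGB primaries with D65 white point for the colorimetric spaces
(consumer-camera default); ITU-R BT.601 matrices on gamma-encoded values
for the video spaces; the full-range JFIF variant for JPEG YCbCr. Each
channel keeps its native numeric range — the moments are
scale-covariant and the classifiers standardize features, so per-channel
rescaling would add nothing.

Per channel, 15 features (5 color + 10 texture), for 675 in total:

* **Color moments** (`colorMoments()`): mean, standard deviation,
  variance, skewness, kurtosis — population ($1/N$) forms. A
  zero-variance region gets skewness = kurtosis = 0 rather than NaN so
  learners never see non-finite inputs.
* **Shannon entropy** (`shannonEntropy()`), in bits, over 256 equal bins
  spanning the channel's declared range.
* **Local contrast** (`localContrast()`) about the mean, median and
  mode: $LC = (T - A)/(T + A)$ where $T$ and $A$ average the values at
  or above, respectively below, the central measure; 0 when a side is
  empty. The mode only exists on a quantized scale, so the mode-centered
  contrast is computed wholly on the 256-bin values (smallest modal bin
  on ties); mean- and median-centered contrasts use raw values.
* **Rotation-invariant local binary patterns and local variance**
  (`lbpVarFeatures()`) at radii $R = 1, 2, 3$ with $P = 8R$ neighbors
  sampled on the circle by bilinear interpolation (neighbor $p$ at angle
  $2\pi p/P$ from the positive x-axis). The LBP code thresholds
  neighbors against the center ($s(x) = 1$ iff $x \ge 0$) and packs bits
  as $\sum s_p 2^p$; rotation invariance takes the minimum over all $P$
  circular bit rotations. The companion contrast measure is the
  neighborhood variance $VAR = \frac{1}{P}\sum_p (g_p - \bar g)^2$. Both
  are averaged over all region pixels whose **entire neighborhood lies
  inside the region mask** — no padding, so background never
  contaminates tissue texture. Texture operators run on the quantized
  (256-bin) channel for comparison stability; if no pixel has full
  support the features are 0 with a warning.

Whether texture should run on raw or quantized values is not dictated by
the method itself; quantization was chosen because LBP's $\ge$
comparisons are brittle under sub-resolution float noise, and it is the
documented, tested convention here.

## Feature selection

`selectFeaturesF()` ranks columns by the classic one-way ANOVA F across
the three classes and retains features with $F$ above a cutoff
(default 21, at which retention implies significance far beyond
$p < 0.001$ for these designs). Conventions for degenerate columns: zero
within-class and nonzero between-class variance gives $F = +\infty$
(a perfectly separating feature, always retained); a globally constant
column gives $F = 0$. No multiple-testing correction is applied — the
cutoff is an operating point, not an inference.

## Classifiers

Both learners consume z-scored retained features; the standardization
parameters are learned on training data and baked into the model, so
queries arrive on the raw scale.

* **Gaussian naive Bayes** (`fitBayes()`): priors are class frequencies;
  each feature gets per-class normal marginals by maximum likelihood
  ($1/N$ variance, floored at $10^{-9}$). Posteriors are computed in the
  log domain and normalized; prediction is the maximum posterior with
  ties broken in the fixed class order granulation < slough < necrotic.
  The normal marginal family is a choice (the features are continuous);
  it is the standard one.
* **Kernel SVM** (`fitSVM()`): soft-margin dual SVM with kernels
  $x \cdot y$, $(\gamma x \cdot y + 1)^d$ for $d = 2, 3$, and
  $\exp(-\gamma \lVert x-y \rVert^2)$. Defaults: $C = 1$, $\mathrm{coef}_0 = 1$,
  $\gamma = 1/(d_{\mathrm{features}} \cdot \mathrm{var}(X))$ on the
  standardized training matrix. Multiclass handling is one-vs-one
  voting. The dual problems are solved by libsvm (via e1071), but the
  support vectors, dual coefficients and intercepts are extracted into
  the model object: prediction is computed in-package from the kernel
  formulas, serializes to plain JSON, and is verified in the tests both
  against the backend's own predictions and against an independent
  quadratic-programming solve of the dual on a small problem.

## Evaluation

`evaluationReport()` assembles the 3 × 3 confusion matrix (rows = true),
tissue-wise accuracies (diagonal over row total, percent), a **macro**
overall accuracy (mean of tissue-wise values) and a **micro** overall
accuracy (pooled trace over total), and Cohen's chance-corrected kappa
$\kappa = (p_o - p_e)/(1 - p_e)$. Both overall definitions are reported
because published "overall accuracy" figures in this literature usually
track the macro mean (to within rounding) but not exactly; the macro
value is the headline figure here. Percentages print at 2 decimals with
round-half-even.

# The synthetic wound generator

Clinical wound photographs cannot ship with a package, so every stage is
exercised on synthetic images (`woundSpec()`, `generateWound()`,
`makeBenchmark()`). A generated image is a flat skin-toned background
(default RGB (225, 190, 160)) with an elliptical wound partitioned into
**contiguous angular sectors** of granulation (≈ (180, 40, 50)), slough
(≈ (200, 180, 80)) and necrotic (≈ (30, 25, 25)) tissue. Sector
boundaries are placed by pixel-count quantiles of the polar angle, so
the realized tissue fractions match the requested ones to within
rounding — fraction targets are exact by construction, which is why
sectors were preferred over random blobs. Inside the wound, per-pixel
Gaussian color jitter (SD 8 gray levels) and a sinusoidal texture
(amplitude 10, wavelength 8 px) make the texture features non-trivial;
salt-and-pepper impulses (default 2% of pixels) are applied image-wide.
Generation is bit-identical under a fixed seed.

The single-image default uses tissue proportions 64.3 / 16.6 / 19.1
percent — a granulation-dominant wound of the kind used as a worked
example in this literature. The 10-image benchmark suite randomizes
geometry and draws fractions with granulation in $U(0.45, 0.60)$ and
necrotic in $U(0.05, 0.12)$, reflecting clinical corpora in which
necrotic tissue is the minority class (roughly one region in eight).

**What the generator does not emulate:** specular highlights, hair,
rulers and markers, shading gradients, camera noise correlated across
channels, irregular (non-elliptical) wound outlines, and multi-wound
frames. Passing the synthetic benchmark therefore demonstrates that the
pipeline's machinery is correct and internally consistent — not that
clinical accuracy on real photographs would match it. The synthetic
tissue colors are well separated; real slough/granulation boundaries are
far more ambiguous.

## A structural limitation worth knowing

Saturation thresholding segments *chromatic* tissue. Necrotic tissue is
nearly achromatic (black), with saturation below even that of skin, so
the raw mask systematically excludes necrotic sectors; hole filling
recovers them only where they are enclosed by chromatic wound tissue.
On a wound with necrotic fraction $f$ touching the wound outline, the
achievable Dice overlap against the full wound bed is capped near
$2(1-f)/(2-f)$ (≈ 0.89 at $f = 0.19$). This is a property of the
method, not of the implementation; it is why the benchmark's necrotic
fractions sit at clinically typical minority levels, and why the
19%-necrotic default image scores Dice ≈ 0.89 while the benchmark suite
scores ≈ 0.94–0.97.

# Numerical choices and degenerate inputs

* Threshold search: exhaustive over $t \in [1, 255]$; smallest-$t$
  tie-break; constant channels are rejected as degenerate (there is no
  threshold to find) with an error.
* Median filter: exact medians; 8-bit values are representable exactly
  in the 16-bit working precision of the filter backend.
* VAR maps use the $E[x^2] - E[x]^2$ accumulator; values below
  $10^{-9}$ gray² (float residue on constant patches) are zapped to 0 so
  flat regions report exact zeros.
* Empty mask after refinement, empty regions, non-finite features and
  queries, single-class training tables, and unknown labels all raise
  immediate errors naming the problem; the pipeline wrapper adds the
  failing stage name.
* All randomness (generator, splits) flows from explicit seeds; repeat
  runs are bit-identical.

# Problem sizes

The shipped tests and the acceptance script run the full pipeline on a
10-image 128 × 128 benchmark (30 labeled regions, 675 features each), a
scale at which the complete suite executes in a few minutes on one CPU
while still exercising every stage end to end. The feature bank's cost
is dominated by the 45 × 3 LBP/VAR maps; channels and texture maps are
computed once per image and shared across that image's regions.

# Reproducing the evaluation numbers

`scripts/acceptance.R` (repository root) recomputes, from scratch at run
time: the tissue-wise accuracies and kappa that the evaluation module
derives from the worked-example confusion matrices shipped in
`inst/extdata/` (five classifiers over a 767-region corpus), the
structural counts (45 channels, 675 features), and the synthetic
benchmark's segmentation Dice and held-out classification accuracies.
See the README for usage.
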