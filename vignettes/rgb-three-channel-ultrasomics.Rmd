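---
title: "RGB three-channel ultrasomics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{RGB three-channel ultrasomics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgbomics)
```

## The problem

Shear-wave elastography (SWE) displays tissue stiffness (kPa) as a color
overlay, conventionally dark blue for soft tissue through green to red for
stiff tissue. Radiomics pipelines are built for grayscale input, so a color
SWE frame must be reduced to one or more grayscale images before feature
extraction. Two reductions are compared throughout this package:

* **Direct conversion** — the perceptual luminance weighting
  $g = 0.2126\,R + 0.7152\,G + 0.0722\,B$, one grayscale image per frame.
* **RGB three-channel decomposition** — the three single-channel images
  $R$, $G$, $B$ taken verbatim, three grayscale images per frame.

Direct conversion is lossy in a specific, structured way: it is a rank-one
projection of the three-dimensional color space. Any two colors that differ
only within the projection's null space — *metamers* under this weighting,
such as $(50, 0, 0)$ and $(0, 0, 147)$, whose luminances differ by less than
0.02 gray levels — become indistinguishable. On an SWE overlay the R, G and
B channels are deterministic functions of stiffness, so this is not merely a
theoretical concern: stiffness differences that the palette encodes as
different hues of similar luminance are erased. Channel decomposition is
lossless by construction (`recombine(split_channels(x))` is the identity on
every 8-bit RGB image), at the cost of tripling the feature count.

## Pipeline and assumptions

The experiment implemented by `run_comparison()` is strictly paired: one
cohort of images, one ROI mask per lesion, one train/validation split, and
identical derived seeds in both arms, so the conversion method is the only
varying factor. Per arm:

1. **ROI extraction.** The lesion contour is rasterized by the pixel-center
   even-odd rule (`polygon_to_mask()`), and the *same* mask indexes every
   derived image (`propagate()` with fixed row-major ordering). Feature
   differences between channels are therefore attributable to intensities
   only. The package assumes a single pre-registered image pane; it does not
   model the B-mode/SWE dual-pane registration of clinical exports, and it
   does not attempt to strip a grayscale B-mode underlay from the color box.
2. **Feature extraction.** A configurable bank of 19 first-order, 10 GLCM
   and 5 GLRLM features over derivative images (original,
   Laplacian-of-Gaussian, stationary Haar wavelet subbands). The direct arm
   extracts the bank once (`gray_` prefix); the RGB arm three times (`R_`,
   `G_`, `B_`). Shape descriptors are channel-independent, so they are
   emitted once (under the `gray` prefix) and excluded from the 3×
   multiplicity law; duplicating them per channel would only manufacture
   collinear columns.
3. **Split and rebalancing.** Stratified 1:1 split; SMOTE oversampling of
   the training minority class to parity. The pipeline order is
   split → standardize (training parameters) → SMOTE → LASSO → classifier:
   oversampling strictly inside the training cohort prevents synthetic
   samples from leaking information into validation, and running LASSO on
   the balanced table keeps the selection criterion from being dominated by
   the majority class.
4. **Selection and scoring.** Logistic LASSO with 5-fold cross-validated
   deviance and the 1-SE rule; then one of four classifiers on the selected
   columns. SVM and AdaBoost margins are mapped to probabilities by a Platt
   sigmoid fitted on out-of-fold training margins so that all four model
   kinds emit comparable risk scores in $[0, 1]$. Each model's operating
   cutoff is the Youden maximizer on its training scores.
5. **Evaluation.** AUC with DeLong variance and the paired DeLong test,
   confusion metrics at the training-chosen cutoff with exact
   Clopper–Pearson intervals, two-category NRI with each model at its own
   cutoff, Brier score, equal-width calibration bins, and decision curves
   $NB(p_t) = TP/n - FP/n \cdot p_t/(1-p_t)$.

## The synthetic generator

`generate_cohort()` emulates the study conditions that matter for testing
the pipeline, not ultrasound physics. Defaults, with rationale:

| parameter | default | why |
|---|---|---|
| image size | 128 × 128 px | typical size of an exported SWE color box |
| colormap range | 0–100 kPa | common liver display range; soft-to-stiff palette |
| background stiffness | 10 ± 2 kPa | healthy-liver shear moduli |
| benign lesion mean | 25 kPa | benign lesions moderately stiffer than background |
| malignant lesion mean | 70 kPa | malignancy markedly stiffer; clearly inside the display range |
| per-lesion mean SD | 6 kPa | between-lesion heterogeneity |
| within-lesion pixel SD | 5 kPa | intra-lesion texture |
| noise correlation length | 3 px | smooth, seed-reproducible background texture |
| lesion semi-axes | 10–25 px | lesions occupy a realistic fraction of the frame |

Background texture is Gaussian-smoothed white noise normalized by the kernel
$\ell_2$ norm so the stated marginal SD is exact; lesion pixels are i.i.d.
normal so that standard-error arguments apply exactly in tests. The
colormap is three control points with linear interpolation — the simplest
mapping consistent with the soft→blue, mid→green, stiff→red ordering —
quantized to 8 bits by round-half-up.

**Metameric mode** is the adversarial configuration: lesion pixels of the
two classes are painted with colors on a common luminance isoline
($0.2126R + 0.0722B$ constant at shared $G$), with the green channel and an
achromatic per-pixel noise term identically distributed in both classes.
The default pair, benign $(85, G, 30)$ versus malignant $(20, G, 221)$, was
chosen on the isoline but away from the 0/255 boundaries so that additive
noise cannot clip asymmetrically between classes — clipping would leak
class information back into the luminance image through higher moments,
weakening the construction. The luminance gap between the class colors is
0.029 gray levels against a per-lesion luminance SD of ≈ 4 gray levels, so
the direct arm faces (almost exactly) a null problem while the R channel
carries a 65-level mean shift.

What the generator does **not** emulate: speckle, the grayscale B-mode
underlay, vendor-specific palettes (the real colormaps are unpublished, so
absolute synthetic feature values are not comparable to clinical ones),
acquisition variability, multi-lesion frames. Consequently a passing
metameric test demonstrates that the pipeline *recovers channel-coded
signal that luminance conversion destroys*; it does not certify clinical
effect sizes.

## The full-size bank preset

The motivating literature reports 5,936 features per converted image
(17,808 for three channels) without publishing the feature identities.
`paper_bank()` therefore matches the *count*, not the composition: 29
derivative images (original, LoG at σ = 1–4 px, six stationary-Haar levels
× 4 subbands) × 6 gray-level bin settings (8, 16, 24, 32, 48, 64) × 34
features, plus distance-2 GLCM on the original image at the two finest bin
settings. Recomputing the family grid per bin setting follows the
intensity-histogram convention in which discretization is part of the
feature definition; it also means many first-order columns are duplicates
across bin settings, which is harmless downstream because exact duplicate
columns are dropped (lowest index kept) before selection. The default bank
(`feature_bank()`) is the compact version: original + LoG(σ=2) + one
wavelet level, 32 bins, 204 features per image.

## Numerical choices

* **Luminance precision.** `to_gray_direct()` keeps full real precision (no
  8-bit re-quantization) for feature extraction; the formula is evaluated in
  the rearranged form $B + 0.2126(R-B) + 0.7152(G-B)$, which is algebraically
  identical and makes achromatic pixels map to their own value *exactly* in
  floating point — the property that guarantees the achromatic negative
  control is bitwise null. A separate export path rounds half-up for PNG.
* **Discretization.** Equal-width binning over the ROI's own `[min, max]`;
  a constant ROI maps to bin 1. 32 bins by default (common radiomics
  practice).
* **GLCM/GLRLM conventions.** Four symmetric offsets at distance 1,
  statistics computed per offset and averaged; GLCM correlation of a
  zero-variance matrix is defined as 1; a single-pixel ROI is an error
  rather than a silent NaN. Run collection breaks runs at mask gaps.
* **Cutoff tie-breaking.** The Youden search uses the integer-exact
  numerator $TP \cdot n_0 - FP \cdot n_1$, so ties are detected exactly and
  broken toward the lower cutoff; degenerate single-valued scores fall back
  to 0.5 with a warning.
* **LASSO fallbacks.** If the 1-SE model is intercept-only the selection
  falls back to `lambda.min`, then to the first feature entering the path —
  necessary because on signal-free arms (the metameric direct arm) the CV
  curve is flat, and downstream classifiers need at least one predictor.
  A selection forced this way carries no information, and the affected arm
  duly scores at chance.
* **Duplicate columns.** Exact duplicates are dropped before fitting,
  keeping the lowest-index copy. Besides removing degenerate collinearity,
  this is what collapses the RGB arm onto the direct arm for achromatic
  input, making the negative control exact rather than approximate.
* **Confidence intervals.** Confusion-metric CIs are exact Clopper–Pearson
  rather than Wald; normal-approximation intervals on proportions near 1 at
  n = 65 can exceed 1, which exact intervals cannot.
* **NRI variant.** Two-category NRI (predicted benign/malignant at each
  model's own operating cutoff), matching the events/non-events
  decomposition convention; the z statistic uses the standard asymptotic
  (binomial-difference) variance. A continuous-NRI variant was considered
  and set aside: with only two decision categories in play, the categorical
  version is the statistic that answers the clinical question.
* **Seeds.** Every stage seed is derived from the master seed by a fixed
  affine map modulo $2^{31}-1$; the run manifest records all of them, and
  two runs with the same manifest agree exactly.

## Problem sizes

The test suite and the acceptance script use cohorts of 130 lesions
(40 benign / 90 malignant) at 128 × 128 px for the headline two-arm
comparison, 48–64 px images for module-level checks, and brute-force oracle
comparisons on ≤ 16 × 16 images where exhaustive enumeration is feasible.
These sizes were chosen so that every stochastic assertion is backed by an
explicit standard-error argument at fixed seeds while the whole suite runs
in about a minute.

## Known limitations

* Single-pane, pre-registered images only; no DICOM ingestion.
* The feature bank matches the published per-image *count*; feature
  identities of the original 5,936-feature bank are unavailable.
* Classifier hyperparameters are sensible fixed defaults (500 trees, RBF
  SVM with γ = 1/p and C = 1, 100 stumps, unpenalized LR) — no tuning, by
  design, since the comparison is between conversion methods, not between
  classifiers.
* Clinical endpoint values (validation AUCs, NRI, Brier of real liver
  cohorts) are out of reach of synthetic data; only the direction and
  mechanism of the RGB advantage are validated here.
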