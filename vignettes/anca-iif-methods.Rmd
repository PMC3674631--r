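---
title: "Automated ANCA IIF interpretation: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated ANCA IIF interpretation: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancaiif)
```

## The problem

Indirect immunofluorescence (IIF) on fixed human neutrophils is the
front-line screen for antineutrophil cytoplasmic antibodies (ANCA) in the
ANCA-associated vasculitides. A reader grades the FITC fluorescence
intensity of each serum on an ordinal scale from negative (`-`) through
borderline (`+/-`) to very strong positive (`++++`), and classifies the
staining geometry: diffuse granular **cytoplasmic** fluorescence (C-ANCA,
typically anti-PR3), **nuclear/perinuclear** rim fluorescence (P-ANCA,
typically anti-MPO), patterns fitting neither (**atypical**), or
**negative**. Visual reading is subjective; `ancaiif` implements an
automated two-step reading:

1. **DAPI step** — the nuclear counterstain drives autofocus scoring,
   tile-based scene quality control, and segmentation of individual
   neutrophils.
2. **FITC step** — the antibody channel is quantified per accepted cell,
   the sample is graded on the six-level scale, and the pattern is called
   under a fixation profile.

The fixation profile matters because MPO relocates to the nuclear
periphery on ethanol-fixed neutrophils (ethN) but is immobilized by
formalin (formN): a serum that is P-ANCA on ethN appears cytoplasmic on
formN, and only three classes (cytoplasmic, atypical, negative) exist on
formN. The package encodes this in the *specimen*, not the classifier: the
synthetic generator renders a nuclear-type request under formN as
cytoplasmic, because antigen mobility is a property of the slide.

## Synthetic imaging model

No public image set exists for this assay, so the package ships a
deterministic generator whose defaults define the study conditions used by
every test.

**Geometry.** A neutrophil nucleus is a union of 2–4 overlapping ellipses
(default 3 lobes) on a ring of radius 7.5 px with semi-axes 9.5 × 7 px,
giving a cell radius near 22 px — a 40× objective scale at the default
1024 × 1024 (tests use 512 × 512) field. Bilobed nuclei use a reduced ring
(0.65×): with two opposed lobes at full spacing the waist between them is
deep enough for the watershed's h-criterion to cut the nucleus in half,
which is a segmentation artifact, not a biology we want to emulate.
Around each nucleus the generator defines the same zones the classifier
measures: a perinuclear **rim** (distance 0–3 px from the nucleus
boundary) and a **cytoplasm** band (3–12 px).

**Staining.** Mean cell FITC is `intensity_au × gain` with a default gain
of 100 grey-levels per AU, so 100 AU ≈ 10000 grey on the 16-bit scale.
This calibration keeps the strongest grade (~180 AU) far from saturation
while holding per-pixel signal well above the read noise (sigma = 1% of
the dynamic range, ~655 grey); a gain near unity would bury every
descriptor the classifier depends on in noise. Patterns are rendered as:
cytoplasmic — granular (gamma speckle) signal in the cytoplasm band with a
dim rim (0.35×); nuclear — nucleus + rim at full intensity with faint
(0.08×) cytoplasm; atypical — flat signal over the whole cell; negative —
background (2% of range) only. Each cell's template is rescaled so its
noiseless mean equals the requested AU exactly, which is what makes AU
recovery testable. Optical blur is a truncated Gaussian (default sigma
1 px) applied over the content rectangles (the rest of the scene is
constant background, which Gaussian filtering leaves unchanged); noise is
Poisson shot noise taken in its Gaussian regime (all rendered values are
≫ 100, where Normal(m, √m) is indistinguishable from Poisson) plus
Gaussian read noise. Sub-seeds for placement, speckle, and the two
channels split from the master seed in a fixed order, so equal seeds give
byte-identical TIFFs.

**Aggregates and artifacts.** Fused cell clumps — the objects the
convexity filter exists for — are bent chains of five nuclei (28 px
steps, 0.7 rad bend) joined by confluent chromatin bridges (radius 13 px).
The bridges keep the clump's distance map free of deep saddles, so the
lobe-preserving watershed keeps it a single object, while the bent outline
drives solidity to ~0.70, safely below the 0.80 gate. Bright artifacts
are saturated blocks painted into both channels. What the generator does
**not** emulate: real point-spread optics, chromatic shift, uneven
illumination, autofluorescent debris with structured texture, or the
morphological variety of real granulocytes — so green tests demonstrate
the pipeline's internal consistency at realistic signal levels, not
clinical performance on real slides.

## DAPI step: focus, QC, segmentation

**Autofocus.** Sharpness is the grey-level co-occurrence (GLCM) contrast
`sum p(i,j) (i-j)^2` at Q = 64 levels, offsets (0,1) and (1,0) averaged
symmetrically. Quantization uses a *fixed bin width* (dynamic range / Q)
anchored at the observed minimum: this makes the score invariant to adding
a constant and keeps the camera noise floor at a constant contrast
contribution. Min–max quantization, the obvious alternative, re-scales the
noise floor as defocus compresses the dynamic range, and the focus curve
turns back up at strong blur — the wrong shape for an autofocus
criterion. Tile QC, by contrast, quantizes each tile over its own observed
range, because there the statistics are compared within a tile, not along
a focus series.

**Tile QC.** The image is cut into 128 px tiles; a tile is flagged when
more than 1% of its pixels are saturated or its GLCM homogeneity falls
below 0.05; a field passes while at most 25% of tiles are flagged. These
thresholds are package defaults chosen to catch the planted saturated
artifacts while never flagging clean synthetic fields; they are
configuration, not measured constants.

**Segmentation.** Otsu's threshold on a sigma = 1 px Gaussian-smoothed
DAPI channel (a blank-scene guard requires the threshold to clear the
median by five MADs, so noise-only fields yield empty masks), hole
filling, and a minimum area of 120 px. Touching nuclei are split by a
watershed on the Euclidean distance transform with depth criterion
h = 2 px: a peak must rise at least 2 px above its contact point to count
as a separate object, which preserves nuclear lobes (shallow saddles)
while splitting genuinely touching nuclei. Objects are then filtered:
solidity (area / convex-hull lattice area) below 0.80, area outside
120–4000 px, or touching the border. The solidity gate is calibrated
against the generator: single lobed nuclei measure ≈ 0.90–0.95, fused
clumps ≈ 0.70. Surviving nuclei get rim (0–3 px) and cytoplasm (3–12 px)
distance bands, with contested pixels assigned to the nearest nucleus by
seeded region growing.

## FITC step: descriptors, grading, classification

Background (median FITC over non-cell pixels) is subtracted and floored at
zero. Per cell the package computes regional means and totals per zone,
the topological ratios rho = rim/cytoplasm, nu = nucleus/cell and the
cytoplasm dominance cytoplasm/cell (all epsilon-guarded at 1e-6 of the
dynamic range), and GLCM texture over the cytoplasm zone quantized over a
brightness-normalized range (0 to twice the cell mean). Cells with any
zone under 10 px are dropped as unreliable.

The sample intensity is the **median** background-corrected cell mean
divided by the gain — robust to residual artifacts; a sum-based aggregate
is available behind `method = "sum"` for users who prefer total
fluorescence. Grades are half-open bins with the boundary belonging to the
higher grade; the default edges are (20, 40, 80, 120, 160) AU on ethN and
(15, 30, 70, 110, 150) AU on formN, anchoring the positivity edge at the
functional assay sensitivity of 40/30 AU. Edges above the anchored cutoff
are declared defaults: the instrument's internal ranges are unpublished,
so only the positivity edge carries external meaning.

Cell classification applies ordered rules: below the cutoff → negative;
(ethN only) rho ≥ tau_p = 1.5 → nuclear; dominance ≥ tau_c = 1.3 with
texture contrast ≥ tau_t = 0.5 → cytoplasmic; otherwise atypical. On the
generator the classes sit far from these boundaries (nuclear rho ≈ 7–8,
cytoplasmic rho ≈ 0.4–0.5 and dominance ≈ 1.4–1.6, atypical ≈ 1.0), so the
thresholds are not fine-tuned constants but separators of well-spaced
distributions. A sample pools cells across QC-passed fields; fewer than 20
reliable cells is a QC failure (`insufficient_cells`), the pattern is the
modal positive-cell pattern with ties resolved to atypical (the
conservative call that routes a slide to manual review), and a sample
graded `-` or `+/-` is always reported negative.

`fit_thresholds()` re-derives the positivity cutoff from a labelled
cohort as the midpoint of the gap between the highest negative and lowest
positive sample AU (or the misclassification-minimizing cut when they
overlap, ties to the midpoint), and re-fits tau_p / tau_c from cell-level
distributions the same way when both classes are present. Fitting is
deterministic given its input.

## Agreement statistics

The validation layer is self-contained: weighted Cohen's kappa (identity,
linear, quadratic weights `w_ij = 1 - (|i-j|/(k-1))^q`) with the
Fleiss–Cohen large-sample standard error; exact McNemar on the discordant
counts of a paired 2 × 2 table (`p = min(1, 2 P(X ≤ min(b,c)))`,
X ~ Binomial(b+c, ½), with the b + c = 0 convention p = 1); Fisher's exact
test (delegated to `stats::fisher.test`, cross-checked in the tests
against full hypergeometric enumeration); inter-assay CV (100·sd/mean per
sample, undefined and flagged at mean 0); and functional assay sensitivity
(lowest AU level with CV below 20%). Quadratic weights are the default
kappa because ordinal grade disagreements two steps apart are genuinely
worse than one step; the weighting is always reported, never silent.
Kappa confidence intervals use the asymptotic SE and are reported for
orientation; different statistical packages produce slightly different
intervals, so downstream comparisons should rely on the kappa itself.

The package ships transcribed six-level grade and pattern agreement tables
of a published 342-sample visual-vs-automated comparison as CSV fixtures
(`anca_reference_table()`). On these tables quadratic weighting reproduces
the published kappas on three of four blocks to three decimals; the
formalin pattern block does not match any standard weighting (identity
0.827, linear 0.850, quadratic 0.861 against a printed 0.847) and is
shipped as a transcription with that discrepancy documented here rather
than force-fit.

## Numerical choices and degenerate inputs

* Constant images: GLCM statistics return contrast 0 / homogeneity 1;
  focus score 0; `threshold_nuclei` returns an empty mask.
* The rim band is the pixel-exact dilation difference
  `dilate(nucleus, r) \ nucleus` on the lattice; against the continuous
  annulus this band runs ≈ 6% narrow at a radius of 10 px (half-pixel
  boundary quantization), which is why tests compare it exactly to an
  independent dilation and only loosely (7.5%) to the analytic area.
* `select_focus` breaks ties toward the lowest index; `grade_intensity`
  puts boundary values into the higher grade; the modal-pattern tie goes
  to atypical.
* Ratios guard their denominators with epsilon = 1e-6 of the dynamic
  range, so a zero FITC channel yields rho = 0, not NaN.
* All randomness (placement, geometry, speckle, noise, cohort design)
  derives from integer seeds below 2^31; equal seeds reproduce results
  bit-exactly, including written TIFFs.

## Problem sizes used in the shipped tests

The test suite exercises the full pipeline at 512 × 512 px fields, five
fields per sample, 4–7 cells per field: a 170-sample training-set analog
(70 positive / 100 negative) for threshold fitting, a held-out 200-sample
test cohort for pattern accuracy, 100 single fields for segmentation
accuracy, and 20-seed blur series for the focus criterion. These sizes
keep a full run in the tens of minutes on one CPU while leaving every
pipeline stage (QC, segmentation, zones, descriptors, grading,
aggregation, statistics) on its default parameters.

## Known limitations

* The descriptor set and decision rules are a faithful re-design of a
  proprietary instrument's unpublished logic, not a decompilation;
  agreement with the published tables is exercised only where the paper
  trail (the tables themselves) allows.
* Synthetic cells are geometrically idealized; the reported accuracies
  bound what the *algorithmic* pipeline does under its own assumptions and
  say nothing about antigen specificity (PR3 vs MPO requires ELISA) or
  titer endpoints.
* The AU scale is instrument-arbitrary; the generator defines the
  calibration (100 grey-levels per AU) so that grading is testable, and
  real deployments would re-derive gain from calibrator sera.
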