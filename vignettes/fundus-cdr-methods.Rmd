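---
title: "Methods: automatic cup-to-disc ratio screening and the multi-grader evaluation protocol"
author: "fundusCDR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic cup-to-disc ratio screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusCDR)
```

## The clinical problem

Glaucomatous damage erodes the neuroretinal rim of the optic disc, enlarging
the central cup. The horizontal and vertical cup-to-disc ratios (HCDR, VCDR)
— the cup's extent divided by the disc's along each axis — are the standard
structural screening parameters read off colour fundus photographs.
`fundusCDR` implements an automatic pipeline that segments the disc and cup
and computes both ratios, together with the statistical protocol used to
score such an algorithm against a panel of six manual graders, and a
synthetic phantom generator that makes every stage testable without clinical
images.

## Pipeline overview

For one image the stages are:

1. **Vessel extraction** (`extract_vessels`): black top-hat (morphological
   closing minus image, disk structuring element) of the denoised green
   channel. The response is divided by the local closing so that vessels
   crossing the bright disc and vessels over the darker periphery score the
   same relative darkness; Otsu's rule on that normalized response gives the
   vessel mask. Polarity is black because vessels are darker than retina.
   The structuring-element radius defaults to 7 px at width 512 and scales
   with image width, tracking the resolution dependence of vessel calibre.
2. **Inpainting** (`inpaint`): vessels are erased by iterated diffusion with
   a normalized 3×3 kernel (cross weights 0.1875, diagonal 0.0625, zero
   centre); masked pixels are repeatedly replaced by the kernel average while
   unmasked pixels are pinned. The fixed point is the discrete harmonic fill
   of each hole, so inpainted values obey the maximum principle. Iteration
   stops when the largest per-pass change drops below 0.1 gray level
   (cap 100 passes in the pipeline). Vessels otherwise imprint spurious
   edges on the level-set edge map and a dark mode on the thresholding
   histogram.
3. **Disc localization** (`localize_disc`): multilevel thresholding (k = 2)
   of the inpainted green channel; the largest connected component of the
   brightest class is the optic nerve head. A square window of side
   0.25 × image width is centred on its centroid. Localization *fails* (a
   state, not an error) when the brightest component is smaller than
   5×10⁻⁴ of the image area — e.g. on a featureless frame.
4. **Disc segmentation** (`level_set_evolve`, `segment_disc`): an edge-based
   distance-regularized level set with edge indicator
   $g = 1/(1+|\nabla (G_\sigma * I)|^2)$, curvature regularization and an
   outward balloon force, initialized from a circle at 70% of the ROI
   half-side. Defaults: time step 1, 400 iterations, regularization weight
   0.2 (stability needs μ·Δt < ¼), edge weight 5, balloon −1.8, smoothing
   σ = 2 px, stopping when fewer than 10⁻³ of pixels change sign between
   checks. High-quality images take this single pass. Low-quality images
   re-centre the window on the first contour (a second localization), split
   it vertically into left/right halves — disc asymmetries are predominantly
   nasal/temporal — evolve a level set per half initialized from the first
   contour's restriction, and keep the largest component of the union.
5. **Cup segmentation** (`segment_cup`): a four-loop thresholding cascade
   with k = 3, 2, 4, 3 thresholds and image enhancement (linear contrast
   stretch between the 1st and 99th percentiles) on in loops 1–2, off in
   loops 3–4. Each loop takes the brightest threshold class, drops
   components under 50 px, restores vessel pixels near the candidate inside
   the disc to bridge the gaps left by inpainting, closes with a 5-px disk,
   clips to the disc, opens with the same radius to shave vessel-width
   protrusions, and approximates the boundary by a circular Hough transform
   (radii 0.15–0.6 of the disc-equivalent radius, centres constrained to the
   disc interior). The fitted cup is accepted when its area exceeds the
   minimum-cup floor **and** it does not touch the disc boundary
   (8-adjacency to any non-disc pixel); otherwise the next loop runs. The
   floor is 3000 px in the 2376-wide frame where it was calibrated and is
   scaled by (width/2376)² elsewhere; an unscaled mode reproduces the
   literal constant. Whether the floor applies before or after the Hough fit
   is unstated in the source protocol; it is applied to the fitted cup by
   default and is switchable (`area_test_after_hough`).
6. **Metrics** (`hcdr`, `vcdr`, `region_params_from_masks`): extents are the
   furthest two true pixels along an axis (inclusive, max − min + 1); the
   ratios divide cup extent by disc extent and are deliberately not clipped
   at 1 — a cup wider than its disc is a segmentation failure that the
   evaluation stage must see.

## The Type-II fuzzy-entropy thresholding objective

The multilevel thresholds are chosen by maximizing an interval Type-II
fuzzy entropy searched with Differential Evolution. The source protocol
names the scheme but not its formula, so the objective is fixed here, is
isolated behind `t2_fuzzy_entropy`, and exact numeric agreement with any
particular earlier implementation is not claimed:

* each of the k+1 classes carries a triangular primary membership peaking at
  the class centre and vanishing at the class boundaries;
* widening/narrowing the triangle by the footprint-of-uncertainty width
  (default 10 gray levels) gives upper and lower memberships; their average
  is the interval membership, normalized across classes at each gray level;
* the class's entropy is the Shannon entropy −Σ q log q of the
  membership-weighted histogram masses normalized within the class, and the
  score is the sum over classes. A class with no mass makes the threshold
  set infeasible (−∞), so every class must be occupied.

This is the Kapur-style maximum-entropy partition generalized to fuzzy
memberships. The alternative reading — entropy of the class-mass vector
itself — degenerates to equal-mass quantile splitting, which ignores
histogram structure entirely and was rejected. With zero footprint width the
interval collapses and the score equals the Type-I fuzzy entropy of the same
memberships.

The optimizer is DE/rand/1/bin over k-dimensional real vectors in [1, 254]
(population 30, 100 generations, F = 0.5, CR = 0.9), sorted and rounded at
evaluation, with duplicate levels infeasible. Every `de_params` requires an
explicit seed; identical seeds give identical thresholds. An
exhaustive-search oracle (`exhaustive_thresholds`) verifies DE optimality
for k ≤ 3 in the test suite.

## The multi-grader evaluation protocol

Six ophthalmologists mark each image; the automatic system is scored as a
seventh marking. Per image and parameter (disc area, disc centroid, cup
area, cup centroid, HCDR, VCDR) the spread across graders is the unbiased
(n−1) sample SD — the convention that reproduces the protocol's printed
worked examples; centroids combine the per-coordinate SDs in quadrature.
The outlier threshold per parameter is the mean per-image SD
(`sd_thresholds`); the CDR thresholds are the fixed constant 0.075.
Published calibration constants for specific camera profiles (cup area
3000 px; disc area 8000 px and centroid 10 px at high resolution) are
exposed by `protocol_thresholds`.

Which grader "causes" a super-threshold SD is not algorithmically defined in
the source; `detect_outliers` adopts iterative leave-one-out: while the
spread exceeds the threshold and more than three values remain, remove the
value whose removal most reduces the spread (ties: larger deviation from the
mean, then lower grader id). An image is **eliminated** when any parameter
collects ≥ 3 flags, or ≥ 4 flags total include two on one parameter; exactly
three flags on three distinct parameters keep the image. Non-localized
images are excluded from testing. An entity is *accurate* on a tested image
iff none of its markings is flagged on any analysis parameter; the HCDR
analysis uses five parameters (both disc, both cup, HCDR), the VCDR analysis
swaps the ratio, and the final analysis uses all six.

Accuracy percentages are **truncated** to one decimal, not rounded: the
published tables print 82/127 as 64.5, 148/194 as 76.2 and 149/169 as 88.1,
which half-up rounding would contradict. Pairwise agreement counts images on
which both entities are tested and unflagged under their own evaluations;
the matrix is symmetric with the total image count on the diagonal. The
per-grader "images removed" columns of the source tables imply a
grader-dependent elimination the source never defines; this package computes
one elimination set per entity evaluation and does not claim to reproduce
those per-column counts.

## The synthetic phantom and grader generator

`generate_phantom` builds the geometry the pipeline assumes: a bright
elliptical disc containing a brighter concentric elliptical cup (cup axes =
CDR × disc axes, so target ratios are exact up to rasterization), dark
vessel random walks seeded at the disc centre (darkness = background − 40;
only their role as dark occluders matters), a radial vignette, Gaussian blur
then Gaussian noise. Canvas profiles mimic the three camera frame sizes
(2240×1488, 2376×1584, 2743×1936) plus a fast 512×512 test profile. Default
brightness levels (background 70, disc 150, cup 225) give the ordering and
contrast of a mid-quality fundus photograph; the standard test suite uses
noise SD 8 and per-phantom CDRs drawn uniformly from 0.35–0.7, the range
spanning normal to clearly glaucomatous cupping.

`simulate_markings` perturbs ground truth per grader: areas get
multiplicative log-normal jitter (keeping them positive, with spread
proportional to size, matching the scale dependence of manual marking
variability), centroids and CDRs additive Gaussian jitter (defaults: CV
0.05, 2 px, 0.03). With probability `outlier_rate` per (image, grader,
parameter) a record becomes a gross error: random sign, magnitude at least
one base-jitter SD before multiplication by `outlier_scale`. A gross
mis-marking is *displaced*, not merely noisier — under pure scaled-Gaussian
outliers nearly a third of "outliers" would be numerically indistinguishable
from normal jitter and no detector could reach high sensitivity. Injected
outliers are returned in a ledger, the recovery target for the detection
tests.

What the phantoms do **not** emulate: peripapillary atrophy, pallor
gradients inside the cup, vessel kinks at the cup margin, non-elliptical
disc shapes, illumination artefacts and compression noise. Passing the
phantom suite therefore demonstrates the pipeline's internal consistency and
its behaviour under the stated geometry/noise model, not clinical-grade
performance on real photographs.

## Numerical choices and degenerate inputs

* Coordinates are 0-based (row, col); ROI windows are half-open; a pixel
  equal to a threshold joins the upper class — all fixed so results are
  bit-reproducible.
* 16-bit rasters are rescaled to 8 bits by integer division of the full
  range; 8-bit round-trips are lossless.
* The level set runs 400 iterations by default with a sign-change stopping
  rule; zero iterations return the initialization (identity), and a vanished
  contour returns an empty mask flagged as failure rather than an error.
* `detect_outliers` never shrinks the panel below three values.
* Problem sizes used by the test and acceptance suites — 20 phantoms at
  512×512 for segmentation recovery, 500 simulated images for detection
  sensitivity, exhaustive threshold search on 32-level grids for k ≤ 3 —
  were chosen to exercise every stage at full fidelity while keeping a
  complete run in the low minutes on one core.
* Sensitivity experiments calibrate thresholds on an outlier-free table with
  identical jitter before injecting gross errors: calibrating on the
  contaminated table lets heavy-tailed area outliers inflate the mean-SD
  threshold and mask opposite-signed errors, which measures the
  contamination of the judge rather than the detector.

## Known limitations

* The Hough approximation is a circle; strongly elliptical cups bias one of
  the two ratios (visible as larger VCDR errors on elongated phantom cups).
* The double level-set path is exercised on synthetically degraded phantoms
  only; its split axis (vertical) is a design choice the source states only
  as "split into two".
* The vessel-kink cue for the cup margin and the second-stage centroid
  correction mentioned in the source literature are not specified there and
  are out of scope here.
* Headline accuracies of the original study depend on its clinical dataset
  and six human graders and are not reproducible from scratch; this package
  reproduces the in-protocol arithmetic (worked SD examples, percentage
  arithmetic, elimination rules) and validates the pipeline on phantoms.
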