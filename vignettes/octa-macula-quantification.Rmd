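---
title: "Quantifying macular microvasculature in en-face OCTA: methods and design"
author: "octamacula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying macular microvasculature in en-face OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The measurement problem

En-face OCTA angiograms map blood flow in the superficial and deep
capillary plexus (SCP, DCP) of the macula. Commercial instruments report
vessel densities, but in eyes with poor fixation and heavy artifact — the
very eyes in which capillary loss matters clinically — built-in software
can misread noise inside avascular zones as flow signal. This package
implements an explicit, reproducible measurement chain for 3×3 mm macular
scans: enhancement, binarization, skeletonization, regional density
measurement, foveal avascular zone (FAZ) extraction, burnout
classification, and paired-eye cohort statistics, validated end-to-end on
synthetic angiograms with exact ground truth.

All pixel geometry assumes the instrument's export format: a 365×365 px
8-bit image with a 1-px border, cropped to 364×364 px, covering 3 mm, i.e.
about 8.24 µm/px. Vessels are bright on a dark background.

# The enhancement chain

`runPreprocess()` applies, in order, clipping to [0, 1] between stages:

1. **Grayscale + crop** (`grayscaleAndCrop`). RGB exports collapse by
   luminance (0.299, 0.587, 0.114); the border row and column are removed.
   Any other input size is an error — geometry is a contract, not a hint.
2. **Homomorphic filter** (`homomorphicFilter`). The image is taken to
   `log1p`, filtered in the Fourier domain with a Gaussian high-boost
   transfer (cutoff 10 cycles/image, low-frequency gain 0.5, high-frequency
   gain 1.5), and exponentiated back. We deliberately log the unit-scaled
   intensities (the `log(1 + im2double(x))` convention of double-precision
   MATLAB-style pipelines): on [0, 1] the transform is gently nonlinear, so
   the stage acts as a high-boost with mild multiplicative correction. The
   aggressive alternative — logging the 8-bit scale so shading becomes
   strictly additive — amplifies background noise relative to vessels and,
   in our phantom study, roughly tripled the density-recovery error, so we
   rejected it. The filter is exactly linear in its log domain: applying it
   twice equals one application with the squared transfer (exposed via the
   `passes` argument, which the tests exercise).
3. **Normalization** (`normalizeImage`): min→0, max→1; a constant image
   maps to zeros rather than dividing by zero.
4. **FAZ background subtraction** (`subtractFazBackground`). The mean
   intensity over a sample region inside the FAZ estimates the avascular
   noise floor and is subtracted globally (clipped at zero). The original
   procedure selected this region manually; for reproducibility we default
   to a central disc of radius 15 px (the scans are fovea-centered) and
   accept an explicit mask instead. Subtraction is applied after
   normalization and is not followed by renormalization, so the stage is a
   pure clipped shift.
5. **Top-hat/bottom-hat** (`tophatBottomhatEnhance`):
   `enhanced = clip(image + tophat − bottomhat)` with a disc structuring
   element of radius 4 px — the canonical contrast-enhancement composition
   of the two morphological residues.
6. **Bilateral filter** (`bilateralDenoise`): spatial sd 3 px, range sd 0.1
   (normalized intensity), window radius 2 spatial sd. Flat-region noise is
   averaged; step edges far above the range sd survive essentially intact.
7. **Vesselness** (`jermanVesselness`). For each scale the Gaussian-smoothed
   Hessian eigenvalues are computed with scale normalization (×s²). With x
   the negated larger-magnitude eigenvalue (positive on bright ridges) and
   ρ its τ-regularized version (ρ = x above τ·max(x), else τ·max(x)), the
   response is 0 for x ≤ 0, 1 for x ≥ ρ/2, and x²(ρ−x)(3/(x+ρ))³ between;
   the map is the maximum over scales, bounded in [0, 1].

**Scale set and τ.** We default to scales {0.8, 1.6} px with τ = 0.9.
Capillaries in these scans are 1–5 px wide; on phantoms, adding a 3-px
scale dilates the response around thin capillaries and biases vessel area
density upward by about +0.10, while {0.8, 1.6} with τ = 0.9 recovers
ground-truth densities with mean absolute error ≈ 0.03 and overlap (Dice)
≈ 0.8. Both knobs are exposed in `preprocessConfig()`.

Two properties of the τ-regularized response are worth knowing. The
response saturates to exactly 1 in a plateau around strong ridges, so "the
argmax of a cross-section" is only defined up to that plateau (the tests
assert that the centerline attains the maximum). And the 2-D form uses only
the larger-magnitude eigenvalue, so an isotropic blob of equal peak
intensity saturates exactly like a ridge; ridge selectivity shows in the
integrated response (a ridge excites many more pixels), not the pointwise
peak.

# Binarization, skeletonization, densities

**Otsu** (`binarizeOtsu`) maximizes the between-class variance over a
256-bin histogram of [0, 1]; the background class is bins 0..t and vessels
are the pixels in higher bins. The implementation is a vectorized cumulative
form; the test suite checks it bin-for-bin against an exhaustive 255-way
search. A constant map yields all-background with a warning.

**Skeletonization** (`skeletonizeMap`) is Guo–Hall two-subiteration
thinning. Each subiteration is applied in two checkerboard subfields with
the deletion conditions recomputed in between, so two 8-adjacent pixels are
never deleted on the same evaluation and the connectivity-number guard
(C = 1) genuinely preserves each component's topology — the purely parallel
form can split a component in rare configurations. Terminal spurs shorter
than 3 px hanging off junctions are pruned by default (`pruneSpurLen = 0`
disables); open line ends that never reach a junction are left alone, so a
plain bar keeps its full centerline. Skeleton length counts pixels (a
diagonal step counts 1, not √2).

**Regions** (`makeRegionMasks`) rasterize the ETDRS-style geometry: the
1-mm-diameter foveal disc and the 1–3 mm parafoveal annulus, at
`scanWidthMm / sidePx` mm per pixel, centered by default on the image
center (fovea-centered acquisition; the FAZ centroid may be passed
instead). VAD and VSD are plain pixel-count ratios; Otsu is computed once
globally, not per region.

# FAZ extraction

`extractFaz()` works on the raw image, not the vesselness map:

1. **Variable threshold** (`binarizeVariableThreshold`): mean-based
   adaptive thresholding, window 25 px, offset 0.10 above the local mean.
   The offset tracks the local background so only clear vessel margins are
   marked. Isolated speckle inside avascular zones that still crosses the
   threshold is exactly what the next step removes: after hole removal,
   under 1% of the FAZ interior remains foreground even with strong FAZ
   speckle (σ = 0.1). Offsets high enough to exclude that speckle at the
   thresholding stage alone (≥ 0.15) destroy rim detection for small FAZs,
   so the division of labor is deliberate.
2. **Hole removal** (`removeSmallSpecks`): 8-connected foreground
   components of ≤ 20 px (≈ 1.4×10³ µm²) are deleted.
3. **Morphological linking** (`morphologicalOpenLink`): closings with a
   5×5 square and 9×1 / 1×9 rectangles bridge inter-capillary gaps at the
   FAZ rim so the avascular background becomes one enclosed region.
   (Equivalently: an opening of the background, which preserves the
   boundary of regions larger than the element — so the FAZ area is not
   systematically eroded, and no compensating dilation is applied.)
4. **Candidate selection**: avascular candidates are the 8-connected
   background components. Among those whose centroid lies within 0.75 mm of
   the image center, that do not touch the image border, and that are at
   least 0.05 mm² (smaller central gaps are ordinary inter-capillary
   spaces), the largest is the FAZ. "Largest near the center" is ambiguous
   between two orderings; we pick largest-among-central and expose the cap.
   The border and minimum-area rules matter in practice: without them,
   large peripheral background regions whose centroids happen to fall near
   the center outrank a correctly segmented small FAZ. If no candidate
   qualifies the function throws "FAZ not found" — the expected outcome for
   burnout eyes whose avascular area merges with the background.

Areas are reported in mm² (pixel count × pixel area).

# Burnout classification and cohort statistics

`classifyBurnout()` closes the vessel map with a 5×5 square (so normal
inter-capillary spacing does not count as nonperfusion) and measures the
nonperfused area inside the 3-mm disc (7.07 mm²); the eye is flagged above
6.0 mm². The literature's "more than 9 mm²" ischemia figure exceeds the
whole 3×3 mm scan's central disc, so it cannot be meant literally within
this field; 6.0 mm² (85% of the disc) operationalizes "capillary detail
undetectable" and is config-exposed. On phantoms the nonperfused area rises
monotonically with programmed attenuation and crosses the threshold
around 80% vessel loss.

**Treated-vs-fellow comparisons** (`compareGroups`) use a patient-clustered
bootstrap: patients — not eyes — are resampled with replacement, preserving
the inter-eye correlation of the paired design; the 95% CI is the
percentile interval and the two-sided p-value is the smoothed tail
proportion. This replaces generalized estimating equations deliberately:
the bootstrap respects the clustering with no distributional assumptions
and is fully reproducible from one seed. Rows with missing metric values
(eyes whose FAZ was not found) are dropped before resampling. No
multiple-testing correction is applied.

**Spearman** (`spearmanCorr`) uses average ranks; for n < 30 the two-sided
p-value comes from ≥ 10⁴ random permutations (with the +1 smoothing), above
that from the asymptotic t approximation. **ROC** (`rocAuc`) computes AUC
as the Mann–Whitney statistic from average ranks (ties count ½), which the
tests verify against brute-force pair counting; the full
sensitivity/specificity grid over unique thresholds is returned.

# The synthetic angiogram generator

`generatePhantom()` builds the scene the pipeline assumes:

- a perturbed-elliptical FAZ (random orientation, eccentricity 0.78–1,
  low-order boundary ripple), rasterized and renormalized so the mask area
  hits the requested mm² to well within 5%;
- a capillary ring hugging the FAZ rim, the geometry the FAZ extractor
  relies on;
- vessel trees grown as angle random walks pulled toward wandering
  waypoints, branching with tapered widths, entering from the image edge
  and later sprouting from the existing network; growth stops at the FAZ
  rim and is *self-avoiding* — a path that runs more than a few steps along
  existing vessel mass terminates. Self-avoidance is what keeps high-density
  networks mesh-like; without it the generator produces solid merged clumps
  whose flat interiors no ridge filter should (or does) mark as vessels,
  which real capillary beds never form. Trees are added until the
  pixel-counted density inside the 3-mm disc reaches `targetVad`
  (unreachable targets raise an error);
- rendering at OCTA-like contrast (background 0.18, vessels 0.45–0.85),
  blurred lightly, with a multiplicative low-frequency illumination
  gradient (default amplitude 0.15), and a noise model scaled by
  `noiseSigma`: low-frequency background haze, multiplicative speckle, and
  an additive floor, plus optional extra Gaussian noise inside the FAZ
  (`fazNoiseLevel`) emulating the false-flow speckle that motivates the FAZ
  pipeline. Intensities are clipped and quantized to 8 bits.

Ground truth (`PhantomTruth`) is computed from the final masks by exact
pixel counting — the generator reports what it drew, not what was
requested — and the truth skeleton uses the package's own thinning.
`applyBurnout()` removes random focal dropout patches until the surviving
area matches (1 − attenuation), dims survivors, fills a dilated
neighborhood of the dropout (so no blur halos of removed vessels remain),
and recomputes the truth.

`generateCohort()` draws per-patient baseline densities from the
control-arm means/SDs of a brachytherapy maculopathy cohort (SCP foveal VAD
29.4 ± 3.8%, DCP parafoveal 36.6 ± 3.5%, and so on), shares them between
the two eyes (inducing inter-eye correlation), and programs treated-eye
deficits — 7 percentage points at SCP, 12 at DCP by default, matching the
published treated–fellow differences — linked to a drawn foveal dose
(default 30 ± 30 Gy, 0.05 pp/Gy slope), a 4× FAZ enlargement, and a
burnout fraction of 9/31 of treated eyes with 80–95% attenuation. Rendering
the actual images is optional (`render = TRUE`); the ground-truth table
alone drives the statistical validation.

**What the phantoms do not emulate.** No projection artifacts, no motion or
decentration artifacts, no 3-D structure, no physically modelled speckle
statistics. Vessel strokes are uniformly bright along their length and
geometrically exact. One honest consequence: on these phantoms a plain
global Otsu threshold on the *raw* image is already near-optimal (Dice
0.78–0.83 against truth), slightly better than the full enhancement chain
(0.74–0.81), across every noise regime we tested — so the phantom study
validates the chain's correctness and calibration, but does not demonstrate
an enhancement benefit over naive thresholding. Demonstrating that benefit
would require degradations (structured artifacts, heterogeneous vessel
signal) that this generator intentionally does not model.

# Numerical choices and degenerate inputs

- Constant images: zero vesselness; Otsu warns and returns all background;
  normalization returns zeros.
- `binarizeOtsu` records both the threshold (upper edge of the background
  bin) and the 0-based bin index.
- Empty regions are errors in `vad`/`vsd`; mismatched geometries are
  errors everywhere.
- Determinism: every stochastic routine takes a seed and restores the
  caller's RNG state; the end-to-end runner fans one global seed out to
  per-stage child seeds by fixed offsets.
- 90° rotations commute with the full chain to machine precision (the
  transfer function, brushes and windows are all symmetric), and densities
  on rotated binary maps are exactly invariant.

# Problem sizes in the tests and acceptance study

The validation study uses 20 full-size (364 px) phantoms spanning target
VAD 0.1–0.4 and FAZ 0.15–0.6 mm² for density recovery (varying both is
what identifies the foveal measurement — with a fixed FAZ the foveal truths
cluster and rank agreement is dominated by ties), 20 phantoms spanning FAZ
0.1–1.0 mm² at noise σ = 0.05 for area recovery, 50 small (121 px, 1 mm)
phantoms for the skeleton-thickness contract, and 200 null cohorts of 30
patients (1000 bootstrap replicates each) for type-I calibration, plus one
50-patient cohort for effect recovery. These sizes keep the whole study at
a few CPU-minutes while leaving the acceptance margins wide.

# Known limitations

- The Otsu-on-vesselness step recovers density with MAE ≈ 0.03; individual
  regions of a single eye can be off by up to ~0.07 at high density.
- FAZ extraction assumes a fovea-centered scan and a capillary ring; heavy
  decentration or a ring broken over long arcs defeats the morphological
  linking.
- The burnout threshold is an operational definition inside the 3-mm disc,
  not a clinical grading.
- Cohort tables model densities directly; when phantoms are rendered for a
  cohort, an enlarged FAZ legitimately depresses the *measured* foveal
  density below the table's programmed value — the table is the statistical
  scene description, the `PhantomTruth` masks are the imaging ground truth.
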