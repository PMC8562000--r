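# octamacula

Quantification of the macular microvasculature in en-face OCTA angiograms.

Optical coherence tomography angiography (OCTA) produces en-face maps of
retinal blood flow in the superficial and deep capillary plexus (SCP, DCP).
In diseases that destroy the macular capillary bed — radiation maculopathy
after ocular plaque brachytherapy is the motivating case — the clinically
relevant biomarkers are:

- **VAD** (vessel area density): the fraction of a region's area covered by
  binarized vessels,
- **VSD** (vessel skeleton density): the fraction covered by one-pixel-wide
  vessel centerlines, which de-emphasizes large-vessel caliber,
- the **FAZ** (foveal avascular zone) area in mm², and
- the **burnout** pattern: end-stage attenuation with undetectable capillary
  detail.

`octamacula` implements the full measurement chain for 3×3 mm macular scans
(365×365 px exports), plus the statistics layer for paired-eye cohorts, and
a synthetic angiogram generator with exact ground truth so that every stage
is testable without patient data.

## Pipeline

1. **Preprocessing** (`runPreprocess`): grayscale conversion and crop of the
   1-px border to 364×364; homomorphic illumination correction; min–max
   normalization; subtraction of the mean intensity of a FAZ sample region
   (the avascular noise floor); top-hat/bottom-hat contrast enhancement with
   a 4-px disc; bilateral denoising; multiscale Hessian vesselness with the
   τ-regularized response, bounded in [0, 1].
2. **Vessel metrics** (`binarizeOtsu`, `skeletonizeMap`, `quantifyEye`):
   Otsu binarization (256-bin between-class variance), topology-preserving
   iterative thinning, and VAD/VSD inside the 1-mm foveal disc and the
   1–3 mm parafoveal annulus centered on the fovea.
3. **FAZ extraction** (`extractFaz`): adaptive (variable) thresholding of
   the raw image, removal of small speckle components, morphological
   linking of the capillary ring with square/rectangular elements, then
   selection of the largest central avascular component; area in mm².
4. **Cohort statistics** (`compareGroups`, `spearmanCorr`, `rocAuc`,
   `classifyBurnout`, `runCohortAnalysis`): treated-vs-fellow comparisons by
   patient-clustered bootstrap (eyes within a patient are correlated),
   Spearman rank correlations, ROC/AUC for burnout prediction, and burnout
   classification from the nonperfused area inside the 3-mm disc.
5. **Synthetic data** (`generatePhantom`, `applyBurnout`, `generateCohort`):
   branching vascular phantoms converging on an avascular foveal zone with
   exact vessel/FAZ masks, plus paired-eye cohorts with programmable
   density deficits, FAZ enlargement, dose links and burnout fractions.

`runEndToEnd` chains all five stages into one seeded, reproducible run that
writes CSV tables and a config snapshot.

## Worked example

```r
library(octamacula)

params <- phantomParams(targetVad = 0.32, fazAreaMm2 = 0.30,
                        noiseSigma = 0.05, fazNoiseLevel = 0.05, rngSeed = 7)
ph <- generatePhantom(params, plexus = "SCP", eyeId = "demo")
ph$truth
#> PhantomTruth: FAZ 0.300 mm^2; VAD fov/para 0.244/0.352; VSD fov/para 0.134/0.195

vmap <- runPreprocess(ph$angiogram)
quantifyEye(vmap, vmap, scanWidthMm = 3, eyeId = "demo")
#>   eyeId plexus     region   vad    vsd otsuThreshold
#> 1  demo    SCP     foveal 0.239 0.0997         0.453
#> 2  demo    SCP parafoveal 0.327 0.1352         0.453
#> ...

extractFaz(ph$angiogram)
#> FAZResult: 0.3074 mm^2 (4526 px), centroid (182.6, 182.5)

burn <- classifyBurnout(binarizeOtsu(vmap))
attr(burn, "nonperfusedMm2")
#> [1] 3.07
```

The phantom was asked for a vessel area density of 0.32 inside the 3-mm
disc and a 0.30-mm² FAZ; the measurement chain recovers foveal/parafoveal
VAD within a few hundredths of the pixel-counted truth and the FAZ area
within ~2%. The nonperfused area (3.07 mm² of the 7.07-mm² disc) is far
below the 6-mm² burnout threshold, so the eye is not flagged.

Densities are stored as fractions; multiply by 100 for the conventional
percent scale.

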