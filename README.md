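# MyelinPET

Quantification of white-matter myelin integrity from dynamic
amyloid-ligand PET (e.g. [18F]florbetapir), for imaging scientists studying
demyelinating disease. Amyloid-targeting stilbene tracers also bind myelin
basic protein, so their white-matter uptake falls where myelin is damaged;
this package turns a 90-minute dynamic acquisition plus MR-derived masks
into voxelwise myelin maps and lesion-centred statistics, with a digital
phantom providing ground truth for every stage.

## What it computes

* **SVCA reference region** — each frame is z-scored over the brain; every
  grey-matter voxel's normalized TAC is regressed (non-negative least
  squares) on three kinetic classes (grey matter, blood pool — the 30
  hottest voxels over the first 60 s — and white matter); voxels with
  class-1 weight ratio > 0.9 form the reference region.
* **Logan reference DVR** — per voxel, the slope of
  ∫C_t/C_t versus ∫C_ref/C_t over frames beyond t\* (default 30 min) is the
  distribution volume ratio, DVR = 1 + BP_nd.
* **SUV / SUVR** — SUV = C/(ID/BW) on the 70–90 min window average; SUVR
  normalizes by a reference mask's mean.
* **Lesion geometry** — NAWM (WM minus T1∪T2 lesions), in-plane 2D (or 3D)
  perilesional rings at 0–4 and 4–8 mm via an exact Euclidean distance
  transform, equal-depth intralesional layers, a 4.3 mm
  equivalent-diameter lesion filter, and the impaired-white-matter mask
  below the cutoff mean − 1.96·SD of reference WM DVR.
* **CBF** — single-delay pCASL quantified by the consensus one-compartment
  equation (ml/100 g/min).
* **ROC / DeLong** — trapezoid AUC (= Mann–Whitney concordance) for DVR and
  SUV classifying NAWM vs lesion voxels, compared with the DeLong
  correlated-AUC test.
* **Digital phantom** — simplified-reference-tissue-model kinetics over an
  analytic plasma input with known per-voxel DVR, planted blood voxels,
  ASL triplets encoding a known CBF map, and DVR-coupled DTI-like maps.

## Worked example

```r
library(MyelinPET)
parseFrameScheme("8x15,3x60,5x120,5x300,5x600")
#> FrameScheme: 26 frames, 90.0 min total (8x15,3x60,5x120,5x300,5x600)

res <- runPipeline(defaultPipelineConfig(seed = 3L), "pipeline_out")
res$dvr
#> ParametricMap [DVR, unitless]: 24x24x24 voxels, range 0.949..1.51 (8208 invalid)
str(roiMean(res$dvr, res$nawm))        # normal-appearing white matter
#> List of 3
#>  $ mean: num 1.44
#>  $ sd  : num 0.0183
#>  $ n   : int 1372
str(roiMean(res$dvr, res$lesions > 0)) # T2-type lesions
#> List of 3
#>  $ mean: num 1.27
#>  $ sd  : num 0.0225
#>  $ n   : int 100
res$impaired$cutoff
#> [1] 1.402195
res$roc$dvr
#> RocResult: AUC = 1.0000 (n_pos = 100, n_neg = 1372, DeLong SE = 0.0000)
roiMean(res$cbf, res$phantom$masks$wm)$mean
#> [1] 33.48279
```

The phantom plants white matter at DVR 1.44 and lesions near 1.28, so NAWM
recovers 1.44 ± 0.018 and the lesions 1.27 ± 0.023 under the default
noise level; the invalid voxels of the DVR map are the out-of-brain
background, excluded from fitting. DVR separates lesion from NAWM voxels
perfectly here (AUC 1.0) because the phantom's only within-class
variability is frame noise. The white-matter CBF of the ASL stage recovers
the planted 33.73 ml/100 g/min up to noise. `pipeline_out/` holds every
intermediate (NIfTI volumes with JSON provenance sidecars, a layer
catalogue and a tidy per-ROI table).

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/petmyelin.R", package="MyelinPET"))')" run --out out/ --seed 1
```

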