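---
title: "Quantifying white-matter myelin with dynamic amyloid-ligand PET"
author: "MyelinPET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying white-matter myelin with dynamic amyloid-ligand PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MyelinPET)
```

## The measurement problem

Stilbene amyloid tracers such as florbetapir bind the ordered secondary
structure of myelin basic protein, so their uptake in white matter drops
where myelin is disrupted. In demyelinating disease (multiple sclerosis
being the canonical case) this yields an in-vivo, myelin-specific signal
that conventional MRI lacks. Turning a 90-minute dynamic PET acquisition
into a quantitative myelin map requires a chain of steps — reference-region
extraction, graphical kinetic modelling, static-uptake normalization,
lesion-centred morphometry, perfusion mapping, and discrimination
statistics — and each step has parameters whose values matter. This
vignette documents the model behind each stage, the defaults, and the
numerical choices, and states precisely what the synthetic phantom used by
the test suite does and does not demonstrate.

## Dynamic frames and decay

A `FrameScheme` holds contiguous frame start times and durations; the
compact text `"8x15,3x60,5x120,5x300,5x600"` (the default acquisition)
expands to 26 frames covering 90 minutes. All kinetic computation uses
frame midpoints in minutes. Decay correction multiplies frame $f$ by
$e^{\lambda t_f}$ with $\lambda = \ln 2 / T_{1/2}$, $T_{1/2} = 109.77$ min
for F-18, referenced to injection time; the `DynamicImage` carries an
idempotence flag so correction cannot be applied twice. The late static
image for SUV is the duration-weighted mean of frames whose **midpoints**
fall in the half-open window $[t_0, t_1)$ — the midpoint rule avoids
double-counting boundary frames when windows abut; on the default scheme
the 70–90 min window selects exactly the last two 600 s frames (midpoints
75 and 85 min).

## Supervised cluster analysis (SVCA)

Every frame is z-scored over the brain mask (mean 0, SD 1 per frame), which
removes global scale and isolates kinetic *shape*. Three class curves are
built from control scans:

* class 1, grey matter: grand mean of normalized TACs over the GM mask;
* class 2, blood pool: per control scan, the mean normalized TAC of the 30
  voxels with the highest raw activity summed over the frames wholly inside
  the first 60 s, then averaged across controls;
* class 3, white matter: grand mean over the WM mask.

Each grey-matter voxel's normalized TAC is then modelled as a non-negative
linear combination of the three classes. Non-negative least squares is used
because it makes the class-1 weight ratio $w_1 / \sum_k w_k$ well defined
in $[0,1]$ (an ordinary-least-squares mode is available for comparison).
With only three regressors the NNLS optimum is found exactly by
enumerating the seven possible supports and keeping the feasible solution
with minimal residual; supports with an ill-conditioned Gram matrix
(collinear classes, which arise in noiseless two-tissue data) are skipped.
Voxels with ratio above 0.9 form the reference region, and the reference
TAC is the mean of their **raw** (non-normalized) curves, restoring
physical units. Design points decided here: blood-voxel selection happens
per control scan before averaging (pooled selection would weight controls
unequally); rank-30 ties are broken by lexicographic voxel index so the
selection is deterministic; "first 60 s" means frames with
start + duration ≤ 60 s; a voxel with all-zero weights gets ratio 0 and is
excluded; an empty reference region is an error, not an empty result.

## Logan graphical reference analysis

For each voxel, with $C_t$ the voxel TAC and $C_{ref}$ the reference TAC,
the late-time relation

$$\frac{\int_0^t C_t\,d\tau}{C_t(t)} =
  DVR \cdot \frac{\int_0^t C_{ref}\,d\tau}{C_t(t)} + b$$

is fitted by unweighted ordinary least squares over frames with midpoints
$\ge t^*$; the slope is the distribution volume ratio, $DVR = 1 + BP_{nd}$
under reference-tissue assumptions. Integrals use the trapezoidal rule on
$(0, t_{mid})$ anchored at $C(0)=0$ — closed-form testable and standard in
graphical analysis. Defaults and their reasons:

* $t^* = 30$ min, configurable. The phantom's kinetic defaults
  ($k_2' = 0.25\,/$min; see below) place the onset of linearity well before
  30 min, and estimates at $t^* = 30$ and $40$ min agree to $<0.005$ on
  noiseless data (a property test).
* the $C_{ref}/k_2'$ intercept-correction term is omitted by default and
  available as an argument; provenance records both $t^*$ and $k_2'$.
* voxels whose activity is not strictly positive over the fit window cannot
  be transformed; they are flagged NA and counted, never silently fitted.

Logan slopes are biased **low** under frame noise (the shared noisy
denominator correlates ordinate and abscissa); the suite verifies the
median estimate under multiplicative noise never exceeds the noiseless
value (500-voxel simulation) and the same holds through the phantom's
variance model at noise scale 0.3.

## SUV and SUVR

$SUV = C/(ID/BW)$ with $C$ in kBq/ml, injected dose in MBq and body weight
in kg, assuming 1 g/ml tissue density (the kBq/MBq and kg/g factors of
1000 cancel, so this equals the conventional dimensionless SUV). SUVR
divides by the mean SUV in a reference mask; because a reference region is
only valid if its uptake is comparable across groups, `suvrMap()` writes a
caveat into its provenance rather than deciding that question itself.

## Lesion geometry

All distances are exact Euclidean distances between voxel centers with
physical spacing, computed by a separable lower-envelope distance
transform and verified voxel-for-voxel against a brute-force all-pairs
oracle in the tests (grids up to $22 \times 20 \times 14$).

* **NAWM** = white matter minus the union of T1 and T2 lesion masks.
* **Perilesional rings**: distance from each lesion (to its nearest lesion
  voxel), binned 0–4 mm and 4–8 mm, computed per axial slice by default
  ("in-plane 2D", matching how such ROIs are drawn; a 3D mode is flagged in
  provenance). Rings are clipped to white matter, exclude every lesion's
  voxels, and a voxel claimed by two lesions' rings is conservatively
  dropped from both — the strictest reading of excluding ambiguous
  perilesional tissue.
* **Intralesional layers**: depth = distance to the nearest voxel outside
  the lesion, split into bands of equal depth range (outer = shallow,
  inner = deep; the bands partition the lesion exactly). The layer count is
  a parameter defaulting to 2; a three-layer split of the same lesions is a
  single argument away. A lesion with uniform depth (e.g. a single voxel)
  goes entirely to the outer layer with a warning.
* **Size filter**: lesions whose equivalent-sphere diameter
  $(6V/\pi)^{1/3}$ is below the PET resolution (4.3 mm default) are
  dropped; the criterion is a deliberate choice since several size metrics
  would be defensible, and the filter is idempotent.
* **Impaired white matter**: cutoff $= \bar{x}_{ref} - 1.96\,s_{ref}$ of
  reference white-matter DVR; WM voxels below it are "impaired", the rest
  "unaffected" (an exact partition). The 1.96 multiplier is applied as
  printed in the field's usage; under normality it marks the 2.5th
  percentile, and no percentile interpretation is used computationally.

## Perfusion

CBF comes from single-delay pCASL via the consensus one-compartment
equation

$$CBF = \frac{6000\,\lambda\,\Delta M\,e^{PLD/T_{1b}}}
  {2\,\alpha\,T_{1b}\,M_0\,(1 - e^{-\tau/T_{1b}})}
  \;\;\mathrm{ml/100\,g/min},$$

with $\Delta M$ the mean of pairwise control−label differences (pairwise
first, to allow per-pair QC; identical in expectation to
average-then-subtract). Defaults: $\lambda = 0.9$ ml/g, $T_{1b} = 1.65$ s,
$\alpha = 0.85$, $\tau = 1.5$ s, $PLD = 1.8$ s — the consensus 3 T model
constants and the acquisition timing of the emulated protocol; all are
arguments and all are recorded in provenance. Non-positive $M_0$ voxels
are masked with a count.

## Discrimination statistics

`rocAuc()` sweeps all thresholds and integrates the empirical curve by the
trapezoidal rule; with half-credit for ties this equals the Mann–Whitney
concordance probability exactly (a property test checks the identity
against exhaustive pair counting and `wilcox.test`). Because demyelination
*lowers* uptake, the lesion-positive orientation is "low" by default in
the pipeline and always recorded. `compareAuc()` implements the DeLong
placement-value test for two AUCs measured on the same voxels; its
z-statistic and p-value match an independent reference implementation to
$10^{-9}$ and its type-I error is calibrated against 500 null simulations
in the suite. Voxel-level ROC is the default unit of analysis; lesion-level
summaries can be fed in equally well since the functions take plain score
vectors.

## The digital phantom

`phantomSpec()`/`buildPhantom()` generate a pre-aligned synthetic dataset
with known truth: a spherical brain (GM shell, WM core), spherical WM
lesions, 30 early-peaking blood-pool voxels planted in GM, an ASL triplet
that encodes a known CBF map through the inverse of the consensus
equation, and FA/MD/AD/RD-like maps linear in true DVR. Kinetics follow
the simplified reference-tissue model: the reference (GM) curve is the
closed-form one-tissue response to a tri-exponential plasma input, and
each target tissue is

$$C_t = R_1 C_{ref} + (k_2 - R_1 k_{2a})\,
  C_{ref} \otimes e^{-k_{2a} t}, \qquad k_{2a} = k_2/(1+BP_{nd}),$$

evaluated on a 1 s internal grid with trapezoidal frame averaging, so
ground-truth DVR $= 1 + BP_{nd}$ is known per voxel. Default study
conditions: white matter $R_1 = 0.85$, $BP_{nd} = 0.44$ (DVR 1.44, the
healthy-control white-matter value), T2-type lesions near DVR 1.28 and a
T1-type lesion at 1.23, WM CBF 33.73 ml/100 g/min, injected dose 300 MBq,
body weight 75 kg. The reference efflux default $k_2' = 0.25\,/$min is
chosen so that the slowest simulated tissue ($BP_{nd} = 1$,
$k_{2a} \approx 0.11\,/$min) reaches Logan linearity well before
$t^* = 30$ min, keeping the noiseless recovery error below 0.02 across
$BP_{nd} \in [0, 1]$ — with slower kinetics the residual transient, not
frame discretization, would dominate the recovery error.

Further generator choices: spheres are voxelized by a center-inside test
(no fractional partial-volume mixing) so truth stays piecewise constant
and mask tests are unambiguous; frame noise is zero-mean Gaussian with SD
proportional to $\sqrt{C/\Delta t}$ times `noiseScale` (the first-order
PET frame-noise approximation) added to the *measured*, decay-uncorrected
signal; a single seed drawn once at build time makes outputs bit-identical
for identical specifications. Lesions may carry a radial binding profile
whose shells can extend beyond the lesion radius: such a rim keeps the WM
label but carries its own reduced DVR, which is how graded perilesional
demyelination is planted (the end-to-end demo uses a lesion ~11% below WM
with rim shells at DVR 1.34 and 1.40 to reproduce the centripetal
NAWM > perilesional > intralesional gradient). Blood-pool voxels carry NA
in the truth DVR map — a vessel has no tissue binding potential.

What the phantom does **not** emulate: scanner resolution/PSF, attenuation
and scatter, head motion, realistic anatomy, registration error (all
images are generated aligned, so the registration steps a real study needs
are out of scope here), and count-statistics beyond the Gaussian
approximation. Passing tests therefore demonstrate correctness of the
estimators on data satisfying their model assumptions — parameter
recovery, exactness of geometry, calibration of tests — not robustness to
the artefacts of real scanners.

## Problem sizes and runtime envelope

The suite runs on $16^3$–$24^3$ grids (a few thousand brain voxels), which
keeps every stage exact-testable: brute-force distance oracles are
feasible, NNLS supports are enumerable, and 500-replicate calibration
loops finish in seconds. These sizes are the package's chosen test
conditions; the implementation itself is resolution-agnostic and purely
array-based.

## Worked example

```{r example, eval = FALSE}
res <- runPipeline(defaultPipelineConfig(seed = 3L), "pipeline_out")
res$roc$dvr            # ROC of DVR for NAWM-vs-lesion voxels
head(res$roiTable)     # tidy per-ROI export for external modelling
```

## Known limitations

Beyond the phantom's scope above: the Logan fit is unweighted OLS
(perpendicular-distance and likelihood variants are out of scope); SRTM
nonlinear fitting is not implemented (the phantom simulates it, the
estimator is graphical); mixed-effect and hierarchical regressions on the
exported ROI tables are deliberately left to dedicated statistical
software; and lesion detection/segmentation is assumed done — masks are
inputs, not outputs.
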