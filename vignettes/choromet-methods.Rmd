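---
title: "Methods: choroidal morphometry and stress-session analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: choroidal morphometry and stress-session analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Acute mental stress engages the autonomic nervous system, and the choroid —
the densely vascularised layer between the retinal pigment epithelium (RPE)
and the sclera — is one of the most autonomically responsive tissues in the
eye. Detecting a stress-induced change in choroidal thickness (CT) of a few
micrometres from swept-source OCT (SS-OCT) volumes requires a pipeline in
which every stage is quantitatively trustworthy: image enhancement, rigid
inter-session registration, layer segmentation, magnification-corrected
morphometry, heart-rate-variability (HRV) windowing, and a statistical
battery for paired sessions. `choromet` implements that pipeline and, since
no raw study data are distributable, a ground-truthed synthetic generator
that reproduces the statistical structure the analysis assumes, so that
every stage can be validated end to end.

## The synthetic eye and what it does (and does not) emulate

`generate_eye()` builds three boundary surfaces on a B-scan x A-scan grid:

* the **mid-RPE** lies on a sphere cap (default radius 20 mm, in the range
  of posterior-pole best-fit radii in adults) whose apex — the deepest
  point — sits at the fovea;
* the **ILM** sits above it by a retinal thickness field (default 345 um
  mean) with a Gaussian foveal pit (depth 123 um, radius 0.75 mm). These
  values were chosen so the fovea-centred 1 mm and 3 mm mean retinal
  thicknesses are about 246 and 315 um, typical of healthy adults;
* the **choroid–scleral interface (CSI)** sits below the mid-RPE by a
  choroidal thickness field (default 283 um mean with a -5 um/mm
  nasal-temporal slope).

A smooth random axial undulation (4 um) distinguishes eyes at different
seeds without disturbing thickness fields (it shifts all three surfaces
together). All physical coordinates use the Bennett-scaled transverse
pitch of the configured axial length, so generator truth and morphometry
operate in the same physical frame.

`render_volume()` assigns band reflectivities (vitreous 0.04, retina 0.38,
RPE 0.95, choroid 0.30, sclera 0.14 — the choroid is darker than the
retina, as its vascular lumens are in real OCT), multiplies the choroid by
a smooth 3D vascular texture field (multiplicative SD 0.15, correlation a
few voxels in all three axes; vessels are 3D structures, so the texture is
coherent across B-scans), attenuates with depth (`exp(-0.5 z_mm)`), applies
unit-mean gamma speckle (shape 4, i.e. 50% multiplicative SD), adds a
0.02 background floor and clips to [0, 1].

The default grid is 64 x 64 x 256 voxels over the full-protocol extents of
12 x 12 x 4.5 mm, so the whole suite runs on one CPU in minutes; the full
512 x 512 x 1920 acquisition grid is configuration only. What the phantom
does **not** emulate: vessel-level anatomy (the texture is a stationary
random field), intra-scan motion (the modelled device tracks the eye), or
signal-strength variation. Passing tests therefore demonstrate correctness
of the algorithms under known geometry and realistic noise, not performance
on pathological eyes or low-quality scans.

The stress effect (`apply_stress_effect()`) displaces the CSI posteriorly
by a configurable thickening (cohort draws: N(3.326, 6.143) um per subject,
the scale of the published 3 mm choroidal change), then moves the whole
geometry rigidly (translation SD 0.5 voxel, depth-axis rotation SD 0.3 deg,
the residual motion scale of tracker-assisted acquisition).

RR-interval series are first-order autoregressive Gaussian sequences; the
AR coefficient 0.4 keeps RMSSD below the marginal SD as in real recordings,
and per-condition means reproduce the published baseline/stress heart rates
(77.0 to 86.7 bpm) and RMSSD (36.9 to 25.5 ms); a subject's RMSSD target is
converted to the marginal SD via `sd = rmssd / sqrt(2 (1 - ar))`.

## Enhancement

Denoising is classic Perona–Malik anisotropic diffusion (4-neighbour,
conduction `exp(-(g/kappa)^2)`, reflective borders). `lambda = 0.2`
respects the explicit-scheme stability bound (<= 0.25) and the symmetric
edge fluxes make the scheme conservative, so the image mean is preserved to
rounding error. `kappa = 0.07` places the conduction scale *below* the
smallest anatomical contrast in the rendered scene (the attenuated
vitreous-retina step, about 0.09), which roughly halves the boundary
distortion relative to `kappa = 0.1` while still flattening speckle; 20
iterations is the point of diminishing returns for segmentation quality.
Even so, nonlinear diffusion rounds high-curvature anatomy: at the default
settings the foveal pit's ILM is displaced by up to ~2.5 px on a clean
image. This is a known cost of diffusion denoising and is the main reason
the per-A-scan noise-free accuracy of the segmenter is a few pixels at its
worst rather than sub-pixel everywhere.

Attenuation compensation is the standard column-wise energy normalisation:
the compensated value at depth z is `I^n / (2 * suffix-sum of I^n)` with
contrast exponent `n = 2` and a final `1/n` root to restore the intensity
scale (both the exponent and the root are selectable, since the exact
variant used on the study device is not documented). By construction the
deepest non-zero sample of every column maps to 0.5 before the root; the
practical consequence is a *blow-up band* at the bottom of every compensated
image where the remaining energy in the denominator vanishes. Downstream
stages treat the deepest 300 um as unusable (`bottom_guard_um`).

## Segmentation

The boundary search is classical dynamic programming (minimum-cost path
across A-scans with a per-step vertical penalty), replacing the study's
trained network behind the same output contract: per-(B-scan, A-scan)
depths of ILM, mid-RPE and CSI plus a validity mask, with external
segmentations accepted through the same TSV format.

Design points that mattered:

* **Flattening.** At the reduced grid the posterior curvature reaches
  ~4 px per A-scan, so no small step bound can both follow the anatomy and
  regularise against texture. A coarse bright-band pass (center-surround
  score, step limit 5, penalty 0.02 on unit-normalised costs) finds the RPE
  complex; the slice is flattened along it; the definitive searches run in
  the flattened frame where the anatomy is near-horizontal and the default
  step limit 2 / penalty 0.5 act at full strength. Flattened slices are
  mirror-padded by 8 columns so the path has context at scan edges.
* **Mid-RPE** is the peak of a center-surround (bright-band) score: the
  monotone compensation blow-up scores ~0 under a band-pass operator, while
  the RPE band scores strongly.
* **ILM** is the strongest dark-to-bright axial gradient above the RPE
  complex, refined by a half-maximum crossing whose deep reference window
  shrinks with local retinal thickness so it never reaches into the RPE at
  the pit.
* **CSI** is the strongest sustained bright-to-dark drop on the *squared*
  smoothed intensity. The domain matters: gradients of the log image are
  1/I-weighted and bias the edge towards the dark side, gradients of the
  plain image inherit the compensation's depth-amplification tilt; the
  squared domain empirically cancels the tilt bias to ~0.2 px.
* **Two orthogonal passes.** Path estimates weaken near slice borders, so
  the volume operation also segments the orthogonal (fixed-A-scan) slices
  and averages the two passes with weights favouring each pass's in-slice
  interior. Surfaces are then median-filtered across B-scans and lightly
  mean-smoothed (the anatomy is smooth at the 0.2 mm pitch).

On ten seeded default-noise volumes this yields mean Dice ~0.97 (retina)
and ~0.95 (choroid) against generator truth — the same bar the study's
network reports on real data, met here on synthetic data only — and a 3 mm
choroidal thickness error of a few micrometres.

## Registration

Inter-session alignment is rigid 3D registration (6 parameters, physical
millimetre coordinates, centre at the volume centroid) minimising the
mean-squared intensity difference, sampled on an interior-margin grid (so
border voxels entering/leaving the field cannot make the metric
discontinuous) over a 2-level pyramid. Three numerical details are worth
recording:

* the trilinear MSE is only piecewise smooth; finite-difference
  quasi-Newton methods stall on it, so each level runs a derivative-free
  Nelder–Mead simplex (with a restart against premature contraction);
* both volumes are 3-box blurred before the fine level: the resampled
  moving volume carries interpolation smoothing the fixed volume lacks,
  which otherwise displaces the weakly-determined depth-axis rotation
  optimum by ~0.5 deg;
* a final *symmetric half-transform* refinement re-optimises a metric that
  samples both volumes midway (each interpolated at half the offset), so
  the interpolation smoothing cancels between the arms. This removes the
  residual depth-axis rotation bias, which is worst near half-voxel
  translations.

With the refinement, twenty random small transforms (the cohort's motion
scale) are recovered within 0.25 px translation and 0.2 deg rotation. The
subject pipeline disables the refinement (`refine_interp = FALSE`): ROI
thickness is insensitive to sub-degree depth-axis rotation and the cohort
budget is better spent elsewhere.

Two further pipeline choices protect the between-session thickness
difference, the study's primary endpoint:

* the transform is estimated on enhanced intensities (robust metric) but
  applied to the *raw* stress volume, and enhancement runs again on the
  resampled grid, so both conditions pass through an identical processing
  chain;
* by default (`snap_to_grid = TRUE`) the applied translation is rounded to
  whole voxels and the sub-degree rotation dropped. Integer-shift
  resampling is an exact copy — no interpolation smoothing — whereas
  sub-voxel resampling smooths one arm only, which empirically inflated the
  per-subject ΔCT noise from ~3 to ~7 um and pushed spurious retinal and
  curvature "effects" into significance. The cost is at most half a voxel
  and a fraction of a degree of residual misalignment, which shifts both
  boundaries of a layer together and is negligible for fovea-centred
  ROI means.

## Morphometry

The transverse scale is corrected per eye with Bennett's formula
(`ratio = 3.382 * 0.013062 * (axial_length - 1.82)`; the device camera
factor times the eye-specific factor); the axial scale is unaffected. The
fovea is the deepest valid ILM point within the central half of the grid
(ties broken towards the grid centre). ROI thicknesses average the axial
boundary separation over all A-scans whose Bennett-scaled en-face distance
from the fovea is strictly below half the diameter (1 mm and 3 mm). The
four directional radii sample the mid-RPE along en-face lines through the
fovea at 0/45/90/135 deg (0 deg = B-scan direction, counterclockwise
positive), keep points by horizontal distance (< 6 mm at 45/135 deg,
< 5 mm at 90 deg, and < 5 mm temporal / < 3 mm nasal at 0 deg, resolved by
the declared eye orientation — temporal-to-nasal A-scan order for a left
eye), and fit a circle in the (arc-position, depth) plane in physical mm:
an algebraic Kåsa fit then one Gauss–Newton pass on the geometric
residuals. The inclusion windows are applied in Bennett-scaled physical
millimetres (all other endpoints are physical too), and oblique lines
sample the surface bilinearly at 1-nominal-pixel steps.

## HRV

Each acquisition-end event takes the beats whose interval *end* lies within
the preceding 20 s (end-anchored; the boundary beat counts iff its end-time
qualifies). Mean HR uses the time-weighted convention
`60000 * n / sum(RR)`, not the mean of instantaneous rates, which is
unstable in short windows. RMSSD is the root mean square of the n - 1
successive differences. No ectopic-beat filtering is applied by default,
matching a study population with no reported arrhythmia.

## Statistics

Paired comparisons are gated by Shapiro–Wilk on the differences at
alpha = 0.05 (a paired t-test when normality is not rejected, otherwise a
Wilcoxon signed-rank test with zero differences excluded, exact null for up
to 25 non-zero pairs and the normal approximation beyond). Correlations are
Pearson iff both variables pass the same gate, otherwise Spearman.
Bland–Altman repeatability uses differences scan2 - scan1 and limits
mean ± 1.96 SD (sample SD). No multiple-testing correction is applied
(eight endpoints, each at 0.05), matching the study design; reports flag
this. Simulation checks confirm the gate preserves the nominal level for
both Gaussian and heavy-tailed nulls at n = 33 and gives > 75% power at
the published 3 mm choroidal effect scale.

One published inconsistency is deliberately not reproduced: the printed
1 mm choroidal limits of agreement are not consistent with their printed
mean under any sign convention, and the 1 mm retinal limits differ from the
1.96-SD reconstruction in the third decimal (rounding of unprinted digits).
The bundled reference tables flag these rows (`loa_consistent = FALSE`) and
the consistency checks use only the reconstructible rows.

## Problem sizes and reproducibility

The validation suite uses the reduced 64 x 64 x 256 geometry throughout:
ten seeded volumes for the Dice floor and thickness recovery, twenty seeded
transforms for registration, one full 33-subject imaging cohort for effect
recovery (per-subject ΔCT drawn from N(3.326, 6.143) um), 2000/500
replicates for test level/power and 200 replicate stress sessions for the
HRV pattern. Every generator is a pure function of (configuration, seed),
so any run — including the whole cohort report — is bit-reproducible.
`scripts/acceptance.R --seed <s> --out <path>` re-derives every quantity
from scratch under a caller-chosen seed.

## Known limitations

* The classical segmenter replaces the study's trained network only on the
  synthetic phantom's contrast model; real scans with pathology or shadowing
  need the TSV drop-in path for external segmentations.
* Perona–Malik denoising rounds the foveal pit (~2.5 px at defaults),
  biasing single-scan foveal retinal thickness slightly low; choroidal
  endpoints are unaffected (the bias cancels in the RPE/CSI difference and
  between sessions).
* The depth-axis rotation of a freshly rendered, nearly axisymmetric scene
  is close to unobservable by any intensity metric; registration accuracy
  claims for that component hold for resampled volumes (coherent texture),
  which is also the relevant regime for same-eye session alignment.
* Directional radii are fitted in the (arc-position, depth) plane of each
  sampled line, not in a re-projected oblique plane; for surfaces as smooth
  as the posterior pole the difference is far below the reported precision.
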