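---
title: "Z-score activity mapping for manganese-enhanced MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Z-score activity mapping for manganese-enhanced MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memriz)
```

## The measurement and its normalization problem

Manganese-enhanced MRI (MEMRI) uses systemically administered Mn^2+^ as an
activity-dependent contrast agent: Mn^2+^ enters active neurons through
voltage-gated calcium channels, accumulates intracellularly, and shortens the
local T~1~ relaxation time, so regions with higher basal activity appear
brighter on T~1~-weighted images. The raw signal, however, carries large
scan-to-scan variability — coil loading, receiver gain, animal-to-animal
uptake differences — that must be removed before any between-group
comparison of intensities is meaningful.

`memriz` implements a whole-brain Z-score normalization for this purpose.
With $x_i$ the intensity of in-brain voxel $i$, and $\bar{x}$, $\sigma$ the
mean and standard deviation of intensity over all in-brain voxels,

$$Z_i = \frac{x_i - \bar{x}}{\sigma}.$$

Every brain is thereby mapped onto a common dimensionless scale with mean 0
and variance 1, and a fixed threshold $Z_t = 1$ — one standard deviation
above the whole-brain mean — selects comparably "enhanced" voxels in every
subject. Two readouts summarize each atlas region of interest (ROI): the
**mean suprathreshold Z** (mean signal over voxels with $Z \ge Z_t$) and the
**active volume** (mm^3^ of suprathreshold voxels). Groups are compared per
ROI with a homoscedastic unpaired two-tailed t-test,
$\mathrm{df} = n_1 + n_2 - 2$, at $\alpha = 0.05$ (inclusive), with no
multiplicity correction by default (raw per-ROI p values are reported;
Holm adjustment is available and flagged in the output when used).

Two deliberate conventions are worth stating explicitly:

* $\sigma$ is the **standard deviation**, not the variance. Only the SD
  yields unit-variance maps for which "$Z \ge 1$" means one standard
  deviation above the mean.
* $\sigma$ is the **population** (1/N) SD over the brain mask. At the
  $10^5$–$10^6$ voxels of a brain mask the sample/population distinction is
  far below float tolerance, but one convention must be fixed for exact
  tests; group *descriptive* SDs in the t-test use the usual $n-1$ form —
  the two contexts are kept deliberately separate.

The un-thresholded map is retained alongside the thresholded one: histogram
censuses and suprathreshold-fraction summaries are computed on the full
distribution, and thresholding an already-thresholded map is an error rather
than a silent no-op, so the distinction cannot be lost by accident.

## Pipeline stages

Processing follows the classical MEMRI chain, each stage re-entrant from its
on-disk artifacts (NIfTI-1 volumes and CSV tables with JSON provenance
sidecars):

1. **Brain masking** — non-brain voxels are set exactly to 0. Masks are
   normally supplied externally; `auto_brain_mask()` (Otsu threshold,
   largest 6-connected component, morphological closing) is a fallback for
   phantoms.
2. **Denoising** — a non-linear filter that does not alter the grid. The
   default is a 3D median filter of radius 1 voxel; Perona–Malik
   anisotropic diffusion is available. The median default is a concrete,
   documented choice of non-linear filter, not a claim of equivalence to
   any particular published filter.
3. **Affine atlas registration** — a 12-parameter (translation, rotation,
   scale, shear) world-coordinate transform from atlas to subject space,
   estimated by maximizing normalized mutual information (NMI),
   $\,(H(A)+H(B))/H(A,B)$, over the subject's brain voxels. NMI is the
   default because the Mn^2+^ enhancement makes atlas-template and subject
   intensities differently distributed; correlation ratio and normalized
   MSE are available. Atlas labels are then propagated with
   nearest-neighbour interpolation only (no new label ids can appear), and
   scripted voxel-level label edits (`adjust_labels()`) stand in for the
   manual touch-up step of interactive workflows, with a retained edit log.
4. **Z-map, ROI and sub-region statistics, group tests** — as above, plus
   hippocampal sub-region readouts: CA1 and DG relative intensity
   (ROI mean ÷ whole-brain mean), their ratio (the brain mean cancels),
   dorsoventral hippocampal thickness, and segmented volumes.

### Registration internals

The optimization is the pipeline's only numerically delicate step, and its
design is dictated by two measured failure modes. First, a 12-dimensional
Nelder–Mead simplex started cold converges poorly; the optimizer therefore
works on the *matrix entries* (translation + the nine linear-part entries,
about the fixed image's intensity centroid — a non-redundant, smooth
parameterization) and descends block-cyclically: 3-parameter simplices over
translation, rotation-like, scale-like and shear-like blocks in turn,
finished by a full 12-parameter polish. Second, the similarity surface is
multi-modal in rotation, and the coarsest pyramid level can *misrank*
basins: a wrong basin can genuinely score above the true one at 4×
downsampling. The global stage therefore uses the coarse level only to
rank a 5°-spaced grid of rotation triples (with angular diversity
enforced), refines the leading candidates — plus the identity and seeded
random restarts (default 3) — at the *mid* (2×) level, carries the two best
into the full-resolution level, and polishes the winner. The best final
metric wins; ties break to the first candidate. Typical recovery on
simulated subjects at default misalignment bounds is hippocampus Dice
≈ 0.95 (median ≈ 0.97, minimum ≈ 0.89 over 20 phantoms at the 64^3^ test
grid).

### Hippocampal thickness

Thickness is measured on label volumes: at the coronal slice nearest a
stereotaxic anterior–posterior coordinate (default Bregma −2 mm; the
phantom's affine anchors a nominal bregma at the world origin so this is
well-defined), in the voxel column 1.5 mm lateral of the midsagittal plane
on each hemisphere, the contiguous run of hippocampus-labeled voxels
containing the dorsal-most hippocampal voxel is counted and multiplied by
the dorsoventral spacing. "1.5 mm from center" is interpreted as lateral
world-distance from the midline; both hemispheres are measured and
averaged, and a column that misses the hippocampus is a missing value, not
zero. ROI volumes are measured in subject space (volumes are properties of
the subject), with the transform direction atlas→subject stored explicitly.

## The phantom cohort generator

No real scans ship with the package, so every claim about the pipeline is
established on simulated cohorts with known ground truth. The generator is
first-class, tested code, and its defaults *are* the study conditions for
the package's validation experiments.

`build_atlas_phantom()` constructs a deterministic nested-ellipsoid brain
with the 12 standard atlas ROIs (neocortex, striatum, globus pallidus,
olfactory bulb, hypothalamus, septum/basal forebrain, midbrain, brainstem,
thalamus, hippocampus, amygdala, cerebellum), a dorsal hippocampal slab of
known thickness containing a CA1 sheet (dorsal third) and DG sheet (ventral
third), and interior ventricles. Base tissue intensities are distinct per
ROI (range 0.85–1.20, CSF-dark ventricles at 0.3), mimicking the regional
T~1~ contrast of a real template — a flat template makes the registration
problem ill-posed, since an intensity metric then has almost nothing to
lock onto. The default grid is 128×128×64 at 0.2×0.156×0.3 mm, echoing a
typical T~1~-weighted mouse acquisition; validation experiments use 48^3^
and 64^3^ grids (stated with each experiment below) to keep a full
simulation study at desk scale. The geometry seed jitters ROI centers and
sizes by ±2%.

`simulate_subject()` applies, in order:

1. **Atrophy** — iterative 6-connected morphological erosion of an ROI
   toward its centroid until a target volume fraction is met (the final
   partial shell removes the voxels farthest from the centroid, ties by
   index order, for bit-determinism). Eroded hippocampal voxels are
   reassigned to the ventricles — mimicking ventricle widening — and other
   ROIs donate to background. Mesh-free erosion was chosen as the simplest
   scheme with a controllable volume target.
2. **Enhancement** — a multiplicative uptake factor per ROI; subfield
   entries override their parent's factor.
3. **Biological variability** — two log-normal factors: `uptake_cv`
   (default 0.075), one draw per ROI per subject, the between-animal
   variability of systemic Mn^2+^ uptake; and `texture_cv` (default 0.12),
   one draw per voxel, giving tissue a continuous intensity distribution
   rather than flat plateaus. Both are unit-median. Without them a phantom
   cohort has essentially zero within-group variance and whole ROIs cross
   the threshold together, so every t-test saturates — the opposite of the
   statistical structure a two-group comparison assumes.
4. **Bias field** — a multiplicative second-order polynomial shading field,
   centered to mean 1 over the brain, amplitude default 5% — mimics coil
   shading without dominating the z-scores.
5. **Misalignment** — a per-subject affine (atlas→subject) resampling,
   default bounds ±1 mm translation, ±10° rotation, ±10% scale and shear —
   small enough for the registration stage to recover.
6. **Noise** — Rician by default (magnitude MR data; two Gaussian channels
   in quadrature), `noise_sigma` default 0.05 (≈5% of mean tissue
   intensity). Gaussian noise is available for analytically clean tests;
   with Gaussian noise and all other effects off, the residual SD recovers
   `noise_sigma` within 2%.

Identical (spec, seed) pairs reproduce bit-identical volumes; a cohort's
per-subject seeds derive deterministically from one master seed.

### Default effect sizes and their calibration

The cohort defaults describe a tauopathy-like mutant: a hippocampus +
amygdala uptake deficit, a CA1-up/DG-down subfield shift, 30% hippocampal
volume loss donated to the ventricles, and mild (10%) cortical atrophy.
Control uptake is high in hippocampal subfields, hypothalamus, amygdala,
septum/basal forebrain, olfactory bulb and cerebellum — the canonical
systemic-Mn^2+^ pattern.

Two numbers deserve justification rather than assertion:

* **`uptake_cv = 0.075`.** Published two-sample t statistics at $n = 5+5$
  for contrasts of this kind correspond to standardized effects
  ($d = t\sqrt{2/n}$) of roughly 2–3. With a ~20–30% uptake deficit, a
  between-animal CV of 7–9% reproduces exactly that effect-size scale;
  0.075 is the midpoint. Larger CVs would make a 5+5 study underpowered
  for every contrast; smaller CVs make every contrast trivially
  significant, including renormalization spillover onto unaffected ROIs.
* **`deficit = 0.30`** (the default group effect in
  `deficit_subject_spec()`). Chosen by an explicit power analysis over a
  (deficit × CV) grid: at 0.30/0.075 a 5+5 cohort detects the hippocampus
  and amygdala active-volume deficits while cerebellum (equal uptake in
  both groups) stays near the nominal false-positive rate. This is the
  simulation-design step any power-conscious study would run before
  collecting data.

One consequence of whole-brain z-normalization is worth knowing: the
normalizers $\bar{x}, \sigma$ are computed over the brain, so a genuine
deficit in one region slightly *raises* every other region's Z values
(compositional spillover). In these simulations the spillover is roughly a
tenth of the direct effect; it is the reason the "unaffected ROI stays
unflagged" check is part of the validation rather than being assumed.

## Validation experiments and problem sizes

The test suite and `scripts/acceptance.R` re-derive the following, from
scratch, at these sizes:

* **Printed-statistic worked examples** — two-tailed Student-t p values via
  the regularized incomplete beta function, checked against `pt()`,
  adaptive numerical integration of the t density, and published reference
  statistics for this study design (e.g. $t_8 = 3.407 \to p = 0.009$).
* **Conservation laws** — in-mask mean $0 \pm 10^{-6}$ and SD
  $1 \pm 10^{-6}$ for every phantom z-map; suprathreshold counts monotone
  in the threshold; affine intensity invariance.
* **Gaussian calibration** — on $10^6$ i.i.d. standard-normal voxels,
  the suprathreshold fraction at $Z_t = 1$ equals the normal survival
  value 0.1587 within ±0.002. Real brains are far from Gaussian — reported
  MEMRI histograms put <5% of voxels above $Z = 1$ — so this is a
  calibration of the
  machinery, not a model of real intensity histograms, and the phantom
  makes no attempt to match the real distribution's heavy central mass.
* **Oracle equivalence** — every ROI metric agrees exactly with per-voxel
  brute-force loops on 100 random 16^3^ instances.
* **Registration recovery** — 20 phantom subjects at 64^3^ with
  misalignments drawn within default bounds: post-warp hippocampus Dice
  median ≥ 0.90, minimum ≥ 0.80.
* **Effect detection** — 50 cohorts (5+5) at 48^3^ with the default
  deficit: hippocampus and amygdala flagged on active volume and
  cerebellum not, in ≥ 90% of replicates. 500 null cohorts give a pooled
  per-ROI type-I error within [0.03, 0.07] on mean suprathreshold Z.
  (Active volumes of small ROIs are discrete at reduced grids, which makes
  the t-test conservative for them — a property of that readout, visible
  in the per-ROI rates, not a defect of the test.)
* **Atrophy recovery** — a 5+5 cohort with hippocampal atrophy factor 0.70
  yields a mutant:control volume ratio in [65%, 75%]. Volumes are
  brain-mask-normalized per subject before the ratio, because the
  phantom's ±10% random scale misalignment is a nuisance a raw-mm^3^ ratio
  would absorb; normalization cancels it exactly while preserving the
  atrophy signal.

## Degenerate inputs, tie-breaks, tolerances

* Constant in-mask images cannot be z-normalized (error, not NaN).
* Double thresholding errors; the un-thresholded map must be kept.
* An ROI with no suprathreshold voxels has active volume 0 and mean
  suprathreshold Z recorded as missing (recording 0 would bias group means
  toward the threshold); group tests drop missing entries pairwise and
  report usable counts, and an ROI with fewer than two usable values per
  group yields an untestable row rather than an error mid-cohort.
* A pooled variance of 0 with equal means gives $t = 0, p = 1$; with
  unequal means it is reported as the $p \to 0$ limit with a degeneracy
  flag.
* Significance at $p = \alpha$ exactly is inclusive ($p \le \alpha$).
* Overlapping scripted label edits: the later edit wins; the full log is
  retained.
* Grid mismatches (shape, spacing, affine) error at module boundaries;
  nothing is silently broadcast or resampled.

## Known limitations

The phantom is a geometric idealization: ellipsoidal structures, white
log-normal texture, polynomial bias, affine-only misalignment. It does not
model MR sequence physics (TR/TE/flip angle), Mn^2+^ pharmacokinetics,
nonlinear anatomical variability, or the heavy-tailed intensity
distributions of real scans — passing tests demonstrate the pipeline's
correctness and statistical calibration under these controlled conditions,
not performance on real data. Registration is affine only (by design; the
method it follows used a 12-parameter registration), so residual nonlinear
anatomy ends up in the ROI statistics. Thickness is measured on label
columns, which quantizes at the dorsoventral voxel pitch.
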