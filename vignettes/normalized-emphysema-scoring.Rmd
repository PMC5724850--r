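---
title: "Reconstruction-robust emphysema scoring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction-robust emphysema scoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The density-mask emphysema score — the percentage of lung voxels below
−950 HU — is the standard computed biomarker of emphysema on chest CT.
It is also notoriously dependent on how the scan was reconstructed:
sharp kernels add high-frequency noise that pushes parenchymal voxels
below the threshold and inflates the score, while soft kernels and thick
slices average emphysematous clusters into their surroundings and
deflate it. In a single-protocol study this hardly matters; in a
multi-scanner screening cohort the reconstruction signature can swamp
the biological signal, to the point that the score's association with
mortality disappears.

`normES` implements a harmonized score and the machinery to evaluate it
against censored mortality outcomes:

1. **Resampling** — every scan is reduced to a common slice thickness
   (3 mm) by overlap-weighted slab averaging along z.
2. **Kernel normalization** — the image is split into frequency bands
   (differences of Gaussians at physical scales), and each band is
   rescaled so that its in-lung energy (standard deviation) matches a
   reference kernel's profile.
3. **Bullae filtering** — per axial slice, 8-connected clusters of
   sub-threshold voxels smaller than 5 mm² are discarded as noise.
4. **Scoring** — the percentage of lung voxels strictly below −950 HU
   among the survivors (`normES`), versus the same percentage on the
   untouched scan (`origES`).

The evaluation side mirrors a screening-cohort marker study: weighted
Kaplan-Meier curves by severity category, pairwise log-rank tests with
a Bonferroni threshold (p < 0.0167 for three groups), time-dependent
cumulative/dynamic ROC AUC under inverse-probability-of-censoring
weighting, bootstrap confidence intervals for AUC differences, and the
continuous net reclassification improvement (NRI) for censored data.

## The harmonization model

Let $I$ be the resampled scan and $G_\sigma$ a Gaussian smoothing at
physical scale $\sigma$ mm (separable, respecting anisotropic voxel
spacing). With scales $\sigma_i = \sigma_0 \gamma^{i-1}$,
$i = 1 \dots N$:

$$b_1 = I - G_{\sigma_1}(I), \qquad
  b_i = G_{\sigma_{i-1}}(I) - G_{\sigma_i}(I), \qquad
  L = G_{\sigma_N}(I),$$

so that $I = L + \sum_i b_i$ exactly (telescoping). The normalized image
is

$$\hat I = L + \sum_i s_i\, b_i, \qquad
  s_i = \mathrm{clamp}\!\left(\frac{E^{\mathrm{ref}}_i}{E_i},\;
  [1/c,\, c]\right),$$

where $E_i$ is the population standard deviation of $b_i$ over the lung
mask, $E^{\mathrm{ref}}_i$ the reference profile (per-band median over
one or more reference-kernel scans), and $c$ the gain clamp. A sharp,
noisy scan has inflated fine-band energies, so its fine bands are
attenuated; a smoothed scan has depleted ones, so they are amplified —
both are pulled toward the common reference appearance before the
density mask is applied.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `density_threshold` | −950 HU | density-mask cutoff, strictly below |
| `min_cluster_area` | 5 mm² | smallest surviving per-slice cluster |
| `target_slice_thickness` | 3 mm | z-resampling target |
| `n_bands` | 6 | number of DoG bands |
| `sigma0`, `sigma_growth` | 1 mm, 2 | band scales 1, 2, 4, 8, 16, 32 mm |
| `scale_clamp` | 4 | band gains bounded in [1/4, 4] |

The band schedule and clamp are this package's own defaults: six doubling
scales bracket everything from reconstruction noise (≈1 mm) to lobar
attenuation gradients (≈32 mm), and the clamp keeps a pathological energy
ratio (for example a band that is pure noise on one kernel and nearly
empty on another) from amplifying artifacts. They are configuration
fields, not constants, so a site with its own calibration data can refit
them.

### Numerical choices

* Gaussian filtering uses discrete kernels truncated at $3\sigma$ and
  renormalized, applied as banded row-stochastic matrices with
  replicated boundaries. A constant image is therefore reproduced
  exactly, and band reconstruction holds to floating-point rounding
  (the acceptance suite bounds it at $10^{-4}$ HU).
* Resampling treats the volume as piecewise-constant slabs and emits
  `round(extent / target)` output slabs; a trailing partial slab
  averages only what it covers. Masks resample with the same weights and
  re-binarize at 0.5. When input and target thickness coincide the
  operation is the identity, bit for bit.
* The density mask uses a strict inequality (a voxel at exactly
  −950 HU does not count), and the bullae filter keeps clusters at
  exactly 5 mm² (only strictly smaller ones are discarded).
* Cluster connectivity is 8-connected in 2-D, per axial slice; the area
  unit is mm², so the pixel count threshold adapts to in-plane spacing.
* Band energies are measured inside the lung mask only, but the gain is
  applied to the whole band grid — normalizing only in-lung voxels
  would create a seam at the lung boundary.
* Normalization gains treat a measured band energy below $10^{-8}$ HU as
  zero (gain 1 with a warning) to avoid dividing by floating-point
  residue on degenerate images.
* The normalized image is clamped to the ingest HU range
  [−1100, 3200]; the threshold at −950 is interior to it, so clamping
  never moves a voxel across the density mask.

### Lung segmentation

The lung mask is produced by thresholding at −500 HU, removing
low-attenuation components that touch the in-plane border (exterior
air), dropping components below 50 ml, keeping the two largest
components, then closing with a 2 mm spherical element and slice-wise
hole filling. Airways are *not* removed; on real scans this inflates
the lung volume slightly and dilutes the score by a roughly constant
factor, which cancels in the orig-versus-norm comparison. Users with
their own segmentations can supply a mask file instead.

## Survival evaluation

* **Weights.** The case-control design (all deaths retained, a fraction
  $f$ of survivors sampled) is handled deterministically by giving each
  sampled survivor weight $1/f$; weighted Kaplan-Meier, log-rank, Cox
  and AUC estimators then target the full-cohort quantities. With
  integer weights the weighted KM equals the KM of the correspondingly
  replicated cohort exactly, which the tests assert.
* **Time-dependent AUC.** Cumulative/dynamic definition: cases have an
  observed event by the horizon $t$, controls are still under follow-up
  beyond $t$. Censoring is corrected with IPCW weights $1/\hat G(T_i^-)$
  for cases and $1/\hat G(t)$ for controls, $\hat G$ being the censoring
  KM. Marker ties count one half. The implementation is an
  $O(n \log n)$ weighted concordance; an $O(n^2)$ enumeration oracle
  checks it exactly in the uncensored case.
* **Continuous NRI.** Risks are mapped through univariate
  proportional-hazards fits (Breslow ties, weighted partial likelihood
  via `survival::coxph`); the up/down reclassification probabilities
  under censoring come from weighted KM curves inside the up and down
  groups with Bayes' rule. Identical markers give NRI = 0 and swapping
  the markers negates it exactly.
* **Bootstrap.** Percentile intervals from resampling stratified by
  event status, preserving the case-control composition; all three
  statistics (two AUCs and the NRI) share each replicate. Everything is
  seeded and bit-reproducible.
* **Cause-specific analyses** censor other-cause deaths at their death
  time. How the original analysis treated competing risks is not
  derivable from its description; the cause-specific convention is the
  standard one for KM/ROC comparisons and is applied uniformly to both
  markers, so the comparison itself is unaffected.
* **Category cuts** are 60th/80th percentile values (linear-interpolation
  quantiles; weighted quantiles when sampling weights are present). A
  score exactly at the 60th percentile is "medium", exactly at the 80th
  is still "medium".

## What the synthetic data emulates — and what it does not

`generate_phantom()` builds a body cylinder with two ellipsoidal lungs,
correlated Gaussian parenchymal texture (2 mm correlation scale,
40 HU), and non-overlapping −985 HU spheres as emphysema with exact
ground truth. `simulate_kernel()` renders soft (1.5 mm blur, 2 mm
slices), medium (0.7 mm blur, 5 HU noise) and sharp (unsharp boost,
25 HU noise) versions of the same anatomy. The texture correlation
matters: uncorrelated voxel noise would be statistically
indistinguishable from scanner noise, and the normalization would then
treat anatomy as noise; real parenchyma has vascular structure at
millimetre scales, which is what keeps mid-band energies
anatomy-dominated on real scans.

The phantom study measures, per kernel, an affine calibration of each
score against truth (intercept, gain, residual sd). The conventional
score's calibration is strongly kernel-dependent — sharp noise adds a
large intercept, soft blur shrinks the gain — while the normalized
score's is nearly kernel-independent. `simulate_cohort()` then draws a
case-control survival cohort (gamma-tailed true emphysema burden with a
point mass at zero, exponential event times with log hazard linear in
the true burden, administrative plus uniform early censoring) whose
observed markers come from that measured affine error model. This
couples the cohort's marker corruption to the imaging pipeline at a
subject count no phantom-rendering loop could reach. The affine form is
itself a measurement: a purely additive error model mis-attributes the
partial-volume gain loss to noise and understates the harmonization
advantage.

What passing tests therefore show: the pipeline's internal contracts
(conservation, identity, monotonicity, oracle agreement) hold exactly;
and *given* kernel corruption of the measured form, the harmonized
score is the more faithful and more prognostic marker. What they cannot
show: performance on real anatomy (airways, vessels, fissures, gravity
gradients), real reconstruction physics (structured noise, beam
hardening), or real mortality processes. The phantom world is a
controlled analogue, not a validation cohort.

## Problem sizes and demo conditions

The packaged demonstration study uses 20 phantoms (60×84×84 voxels at
1×1.5×1.5 mm) under 3 kernels, a simulated cohort of 2000 subjects
with half the survivors sampled (weight 2), 7 yearly horizons at
365.25 days, and 500 bootstrap replicates; the unit-test suite uses
smaller miniatures of the same objects. These sizes make the entire
analysis reproducible on a single CPU in minutes while keeping every
estimator in its asymptotically sensible regime.

One consequence of the scaled-down cohort is worth stating plainly: an
all-cause AUC difference of the size reported in large screening
cohorts (≈0.02) is below the resolution of a 2000-subject study — its
bootstrap CI straddles zero in a substantial fraction of seeds, exactly
as a power calculation predicts. The lung-cancer-specific difference
(≈0.06–0.08 here) is large enough to clear zero, and that is the
endpoint the acceptance checks pin down quantitatively; the all-cause
difference is asserted directionally.

## Known limitations

* No airway or vessel removal in segmentation; no lobe separation.
* Kernel simulation is blur/unsharp-plus-noise, not projection-domain
  CT reconstruction; iterative-reconstruction appearance is out of
  scope.
* DICOM support is deliberately minimal: one series per directory,
  uncompressed little-endian, axial sorting only; no gantry-tilt or
  oblique correction, no DICOM writing.
* The NRI risk mapping is univariate by construction; this package does
  not build multivariable prognostic models.
* Band-schedule defaults are package choices made configurable; sites
  with calibration scans should derive their own reference profile with
  `compute_reference_profile()`.
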