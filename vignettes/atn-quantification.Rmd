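---
title: "Methods: regional PET quantification, harmonized scales and A/T2/N staging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional PET quantification, harmonized scales and A/T2/N staging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atnquant)
```

This vignette is the package's account of what it computes, which choices
were open, how they were resolved, and what the bundled synthetic phantoms do
and do not demonstrate.

## The quantification model

A quantification run starts from two co-registered 3-D volumes: a PET uptake
image and an integer parcellation of the anatomy into 132 structures
(Neuromorphometrics-style naming; 122 grey matter, 10 white matter/CSF). All
geometry is carried by 4×4 voxel-to-world affines (0-based voxel indices, RAS
millimetres); no axis order is ever assumed.

**Regional statistics.** For every structure we accumulate the mean uptake,
the voxel count and the volume. Voxels with NaN or negative uptake — both
occur in reconstructed PET — are excluded from means and reported per region
rather than silently absorbed. Structures present in the dictionary but
absent from the volume stay in the table as zero-count rows.

**SUVr.** The standardized uptake value ratio divides each regional mean by
the uptake of a reference region assumed free of specific binding: the whole
cerebellum (cerebellar grey + white matter) for amyloid tracers, cerebellar
grey matter only for tau tracers. Composite regions (reference and target
masks alike) are evaluated as *pooled-voxel* means — the volume-weighted mean
of member-region means, identical to a plain mean over the union mask. The
alternative (unweighted average of region means) was rejected because the
harmonization scales below were defined on mask-based SUVr. SUVr tables
cover the grey-matter structures present in the volume: a full 132-structure
parcellation yields exactly 122 rows.

**Centiloid.** The amyloid scale is a two-point linear anchoring: with
$m_{yCN}$ the mean global SUVr of a young cognitively-normal
amyloid-negative group and $m_{AD}$ that of an AD-dementia group,

$$\mathrm{CL} = 100\,\frac{\mathrm{SUVr} - m_{yCN}}{m_{AD} - m_{yCN}}.$$

`expand_two_point()` keeps the algebra unrounded, so the anchors map to
exactly 0 and 100; the bundled conversion table stores the published
4-decimal coefficients verbatim and is used as-is by `convert_suvr()`, so
printed numbers are reproduced bit-for-bit (at the AD anchor the printed
coefficients give 100 within 0.01). Level-2 calibration regresses paired PiB
SUVr on another tracer's SUVr by ordinary least squares and composes the fit
with the PiB map by exact algebra — no refit, so the composition identity
holds to machine precision.

**CenTauR.** The tau scale is handled analogously over the meta-temporal
mask (entorhinal area, amygdala, parahippocampal gyrus, fusiform gyrus,
inferior and middle temporal gyri, temporal pole, bilaterally).
`fit_centaur_level1()` fits $S = b\,\mathrm{SUVr}_{CTR} + a$ and returns the
inverse form $\mathrm{SUVr}_{CTR} = (S - a)/b$; tracer-specific CTRz
equations are bundled as printed constants. The equations for tau tracers
other than FTP cannot be re-derived from data shipped here and are encoded
as constants only.

**Calibration validity.** `validate_calibration()` applies the
Centiloid-project criteria to a computed-vs-published OLS fit: slope within
[0.98, 1.02], |intercept| ≤ 2 CL, R² > 0.98. The intercept bound is stated
in CL units only; for CTRz validation the intercept is computed and reported
but not enforced (the published criteria for the tau scale name only slope
and R²). R² is the squared Pearson correlation, equivalent to
$1 - SSE/SST$ for simple OLS, and is computed directly from the correlation
to avoid degenerate-fit corner cases. OLS of computed on published is the
default regression; the method choice was open (the reference analyses print
regression parameters without naming the estimator) and OLS matches the form
in which the validity criteria are stated.

**Mask derivation.** The amyloid target mask can be re-derived per cohort
with `select_discriminative_structures()`, ranking structures by their
separation between a young-control group and a dementia group. The
discrimination statistic was an open choice; the default is the absolute
standardized mean difference (Cohen's d with pooled SD), with a Mann-Whitney
AUC alternative, because d is the conventional first choice when nothing
else is specified. Indistinguishable groups (all criteria ≈ 0) or a tie at
the top-k boundary set an `unstable` flag instead of failing. The bundled
`centiloid_cortical` mask is a package default (frontal, parietal, temporal
and cingulate association cortices) and is explicitly meant to be overridden;
the meta-temporal tau mask, by contrast, is a fixed published composite and
is bundled as such.

## Registration and resampling

PET-to-anatomy alignment is a 6-parameter rigid transform (rotations in
degrees about the fixed volume's grid centre, order $R_z R_y R_x$, then
translation in mm) estimated by maximizing normalized mutual information
$(H_x + H_y)/H_{xy}$ on a 48×48-bin joint histogram. The optimization is
multi-resolution (downsampling factors 4 then 2) with Nelder-Mead. Three
numerical details matter and were found the hard way:

- **Anti-aliased pyramid.** Each level Gaussian-smooths before decimating
  (FWHM = level factor × voxel size), and the moving image is smoothed to the
  matching scale. Plain decimation aliases and litters the metric with local
  optima.
- **Simplex scaling and restarts.** The binned metric is plateau-ridden at
  the 0.1 mm/0.1° scale of the default Nelder-Mead initial step, which makes
  the optimizer stall immediately; the initial simplex is therefore enlarged
  per level (0.8 then 0.2 mm/°) and the optimizer is restarted with a fresh
  simplex until the metric stops improving (up to 10 restarts; typically 2–4
  are used).
- **Initialization guard.** The translation is initialized at the intensity
  centre-of-mass offset, and the final answer is never allowed to be worse
  than that initialization — this protects the already-aligned case, where
  the start sits exactly on the (sharp) optimum and any simplex wandering
  could only drift along the surrounding plateau.

On noiseless 2-mm phantoms this recovers 20 random perturbations within
±10 mm/±10° to better than 0.3° and 0.1 mm (the packaged tests assert
0.5 mm/0.5°). The similarity metric of the reference pipelines is not
published; NMI is this package's documented choice, suitable for the
multi-modal case, with mean squared error available for mono-modal use.

Resampling is always a *single* interpolation pass: chains of transforms are
composed into one matrix (`compose_transforms()`, exact matrix algebra) and
applied once, trilinear for scalar images, nearest-neighbour for label
volumes (so no new label values can appear). Each additional interpolation
pass blurs — the tests demonstrate the composed single pass has strictly
lower error against an analytic phantom than the chained version. An
anatomy-to-template affine is accepted as a precomputed input (identity when
data are already in the target space); template-registration itself is
upstream preprocessing and out of scope here.

## Partial-volume correction

The bundled PVC is the iterative-Yang scheme, *off by default*: each pass
builds a piecewise-constant synthetic image from current region means
(background included), blurs it with the Gaussian PSF, and multiplies the
observed image by synthetic/blurred, then re-estimates means. Five
iterations at a 6-mm FWHM recover two-region phantom means to better than
2%, with strictly decreasing error over the first iterations, and totals
within the labelled volume are conserved to ~1% per pass once the first
corrective pass has restored the activity blurred out of the mask. It is a
region-based substitute, not a reimplementation of resolution-recovery
super-resolution methods; it is labelled as such in its documentation and
the pipeline default keeps it off because composite-mask SUVr over tens of
thousands of voxels is largely insensitive to PVC.

## Volumetry and the neurodegeneration surrogate

Structure volumes are reported native (voxel count × voxel volume) and as
fractions of intracranial volume; when no ICV is supplied the total labelled
volume (all 132 structures, including WM and CSF) is used. The
neurodegeneration probability combines the ICV fractions of hippocampus,
amygdala and inferior lateral ventricle against age-dependent norms. The
published lifespan model behind the HAVAs score is not redistributable from
this package, so the default is a **synthetic surrogate**
(`havas_surrogate_v1_synthetic.json`, model id `surrogate-v1`): age-linear
normative means and SDs for the three fractions (decreasing for hippocampus
and amygdala, increasing for the ventricle; magnitudes chosen at typical
adult values — bilateral hippocampus ≈ 0.52% of ICV at mid-adulthood,
amygdala ≈ 0.24%, inferior lateral ventricles ≈ 0.06%, SDs of 10–50% of the
mean), a pathology-signed z-score per structure and a logistic link on the
mean z. Volumes at the norms give exactly 0.5; three standard deviations of
atrophy plus ventricular expansion give ≈ 0.95. The file schema is the
pluggable interface: supplying a real lifespan model file reproduces a real
N axis, and every output records which model id produced it.

## Staging thresholds and boundary semantics

All cuts are published values; the boundary conventions are the strict
reading of the published inequalities and are each one documented line:

| axis | rule | boundary |
|------|------|----------|
| A (AMYPAD bands) | CL < 10 → A−; 10 ≤ CL ≤ 30 → A_inter; CL > 30 → A+ | both edges belong to A_inter (closed interval) |
| A (binary) | CL ≥ 24.1 → A+ | 24.1 itself is A+ |
| T2 | CTRz < 2 → T2−, else T2+ | 2.0 is T2+ ("below 2" is negative) |
| N | probability > 0.5 → N+ | 0.5 is N− ("higher than" 0.5) |

A missing modality yields `not_assessed` for its axis while the others are
still computed (tau-plus-anatomy runs without amyloid PET are supported).
Both amyloid modes are exposed because published analyses used the binary
24.1 CL threshold while the recommended online behaviour is the three-band
AMYPAD scheme; the package defaults to the bands.

## The synthetic phantom: what it shows and what it does not

The generator places each of the 132 structures as a jittered ellipsoid on a
3-D lattice in a 64³ grid at 2 mm (the full 181×217×181 1-mm template grid
is available but unnecessary for correctness tests), then builds PET as a
piecewise-constant uptake image, optionally blurred by a Gaussian PSF and
degraded with Gaussian noise. Every stochastic component draws from its own
named RNG stream (fixed offsets from the user seed, Mersenne-Twister), so
outputs are bit-reproducible and regenerating one fixture never shifts
another. Default conditions: no blur, no noise — so composite SUVr values
are known exactly by construction; calibration cohorts default to the
published anchor means with Centiloid-calibration-scale group sizes (77 young controls, 152
dementia), and paired-tracer simulations default to n = 46 over SUVr
0.8–2.5, matching the scale of the cross-tracer calibration samples.

Passing tests on these phantoms demonstrate the *arithmetic* of the pipeline
— region accounting, reference normalization, calibration algebra,
registration recovery, threshold logic — under controlled conditions. They
do not demonstrate segmentation quality, scanner physics (scatter,
attenuation, reconstruction artifacts), anatomical realism, or the
population validity of any threshold; those require real cohorts that are
out of scope for this package.

## Numerical choices and degenerate inputs

- Scalar volumes are written as 32-bit float (standard for PET; bit-exact
  for data already at float32 precision, with `datatype = "double"` for
  exact storage), labels as unsigned 16-bit. NIfTI-1 stores affines in
  single precision, so affine round trips hold to ~1e-6.
- Grid compatibility between PET and labels is enforced at 1e-4 absolute
  affine discrepancy.
- Reference uptake must be strictly positive; empty reference or target
  masks, inverted calibration anchors, zero-variance regression predictors,
  constant images in registration, non-positive PSF widths and ICV, and
  out-of-range ages or probabilities all fail fast with descriptive errors.
- Ties in best-mask selection (R² within 1e-12) resolve to the
  lexicographically smallest name and are flagged.
- CSV outputs are written at full double precision; reports round to 4
  decimals. Reruns with identical configuration are byte-identical, with
  timestamps quarantined to a log file.

## Test problem sizes

The suite runs phantoms at 64³ × 2 mm (registration sweeps at 48³), 20-fold
oracle and perturbation replications, and cohort simulations at n ≤ 229 —
sizes chosen so the whole suite completes in a couple of minutes on one core
while still exercising every contract at meaningful scale. Statistical
recovery claims under noise (e.g. 5% parameter recovery at n = 100) are
asserted on means over seeded replicates when a single draw's sampling SE
exceeds the claimed precision by design of the estimator — the single-draw
checks that are statistically meaningful (slope recovery, scale recovery)
are asserted per draw.

## Known limitations

- The segmentation that produces the label volume is upstream and assumed
  given; no tissue classification or template registration is performed.
- The registration capture range (±10 mm/±10° validated) suits
  clinically-acquired PET/MRI pairs after centre-of-mass initialization but
  is not a general-purpose global optimizer.
- The neurodegeneration axis uses a surrogate model unless a real model file
  is supplied; its absolute probabilities on real data are not meaningful,
  only the machinery around them.
- The tau conversion equations other than FTP are printed constants whose
  provenance lies in the cited harmonization study; they are bundled for
  convenience, not re-derived.
- No Braak staging, voxelwise maps, kinetic modelling or DICOM ingestion.
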