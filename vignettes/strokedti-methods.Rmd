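---
title: "Methods: quantitative MRI for rodent stroke recovery"
author: "strokedti"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative MRI for rodent stroke recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`strokedti` implements the analysis layer of a longitudinal rodent
stroke study with cell-therapy arms: T2-based lesion and ventricular
volumetry, diffusion-tensor microstructure, deterministic tractography,
recovery-ROI relative metrics, mNSS behavioral scoring, and the group
statistics that tie them together. Because studies of this design
rarely deposit raw imaging data, the package ships a synthetic phantom
generator with planted ground truth, and every claim the test suite
makes is a claim about recovering that ground truth.

# The diffusion model

Water diffusion per voxel is modeled as a symmetric 3x3 tensor $D$
(mm^2/s). The acquisition follows the monoexponential Stejskal–Tanner
signal equation

$$S_i = S_0 \exp(-b_i\, g_i^\top D\, g_i),$$

with $b$ in s/mm^2 and $g_i$ unit gradient directions. Fitting is
log-linear ordinary least squares on
$[1, -b g_x^2, -b g_y^2, -b g_z^2, -2b g_x g_y, -2b g_x g_z, -2b g_y g_z]$,
the default behavior of the standard DTI toolchains this stage
replaces. Weighted or nonlinear fits are deliberately out of scope; the
log-linear fit is fully specified and reproducible. Two numerical
choices matter:

* **Signal floor.** Noise can push magnitude signal to ~0; signals are
  clipped at $10^{-6}\hat S_0$ (per-voxel mean b0) before the log, so
  the design never sees $-\infty$.
* **Design conditioning.** b-values are scaled by their maximum inside
  the design so all columns are O(1); the tensor coefficients are
  rescaled afterwards. This keeps the noiseless round trip at ~1e-14
  relative error rather than ~1e-9.

Eigenvalues are computed in closed form (the trigonometric solution for
symmetric 3x3 matrices, which preserves the trace exactly), and
eigenvectors by cross products of the best-conditioned row pair of
$(D - \lambda I)$; voxels with a repeated eigenvalue (isotropic tissue)
are flagged `degenerate` and given a fixed placeholder direction rather
than an arbitrary noise-driven one. Negative eigenvalues, which occur
under noise, are clamped to zero for the scalar maps but kept raw with
a `negative` flag. The maps are the standard indices: FA (normalized
eigenvalue dispersion, dimensionless, defined as 0 when all
eigenvalues vanish), AD $=\lambda_1$, RD $=(\lambda_2+\lambda_3)/2$,
MD $=\bar\lambda$.

# Tractography and fiber density

Tracking is deterministic streamline integration: fixed-step Euler
along the principal eigenvector, bidirectional from each seed, with the
two study-defined stopping rules — FA below 0.15 and turning angle
above 45 degrees — plus volume exit and a step cap. Design choices:

* **Interpolation.** Nearest-neighbour eigenvectors with trilinear FA.
  Averaging eigenvectors across voxels is sign-ambiguous; nearest
  neighbour avoids that while trilinear FA keeps stopping smooth.
* **Step size** defaults to half the smallest voxel dimension
  (0.078 mm at the study resolution); **min_length** defaults to two
  voxel widths, suppressing single-step stubs.
* **Seeding.** One seed per ROI voxel at the voxel centre. The
  seeding density is not critical because fiber density (FD) is
  normalized: FD = streamline count / seeding voxel count. Seeding is
  restricted to the analysis ROI on each side (the mirrored ROI seeds
  the contralateral side), which makes the rFD numerator and
  denominator structurally symmetric.

# Morphometry

The lesion rule is the classical intensity threshold: ipsilesional
voxels brighter than mean + 2 SD of contralateral normal tissue.
"Normal tissue" excludes CSF — ventricular hyperintensity would inflate
both moments — and the exclusion mask is an explicit argument, since
whether the original analyses excluded it is not documentable.
Segmentation runs in 3-D over the slab; ventricular volumetry applies
the same threshold machinery inside a ventricle prior restricted to a
contiguous slice window (8 slices by default, matching atlas-guided
manual practice). Volumes are normalized per animal to day 1, so the
day-1 entry is exactly 1 and later entries are shrinkage/expansion
factors.

The recovery ROI is the set difference (day-1 lesion) minus (final
lesion): tissue that was acutely damaged but no longer appears
lesioned. Its contralateral control is the exact voxel mirror across
the midsagittal plane; the grid is constrained to have the midplane on
a voxel boundary so mirroring is an index flip — count-preserving and
an involution, both asserted. Relative metrics divide the ipsilesional
ROI mean by the contralesional one (medians available). The ROI is
defined once on the final-timepoint grid and applied to all timepoints;
cross-session voxel correspondence is a documented usage requirement,
not something the package resolves (no registration is performed).

# Behavioral scoring

The mNSS scorer consumes pre-judged item values: three tail-raise
binaries (0–3), four sensory ordinals of 0–3 (0–12), and one beam
category (0–6). The published scale describes the total as 0–18 while
its subtotals sum to 21; the scorer returns the arithmetic subscale sum
and warns above 18 instead of silently rescaling — preserving the
printed rubric and surfacing the inconsistency. Exclusion filtering
removes animals flagged `died_24h`, `no_deficit`, or `SAH` and reports
per-group, per-reason counts; it is idempotent.

# Statistics

Outcomes are scores and ratios, so the longitudinal model is a Gaussian
identity-link GEE with subjects as clusters, fitted by iteratively
reweighted estimating equations; the working correlation defaults to
exchangeable (independence available), neither being documentable from
the study description. The treatment-by-time test is a joint Wald test
on the full interaction block.

The covariance needed a genuine decision. With ~18 clusters the plain
sandwich is badly anti-conservative: under the package's own null
simulation (3 arms x 6 subjects, 3 timepoints, exchangeable rho = 0.5,
1000 replicates) the chi-square Wald on the plain sandwich rejected at
0.22 instead of 0.05. The default is therefore the Mancl–DeRouen
bias-corrected sandwich (leverage-adjusted cluster residuals) with an
F(q, K − p) reference, which rejected at 0.040 in the same simulation —
the standard small-sample GEE practice. The asymptotic chi-square and
the uncorrected sandwich remain available as arguments.

Per-timepoint comparisons are one-way ANOVA with Tukey HSD, run only
when the GEE interaction p falls under the configurable gate (0.05).
These use base R's `aov`/`TukeyHSD`; the studentized-range distribution
comes from R's own `ptukey` rather than a re-derivation, since that is
the reference implementation. A zero within-group-variance degenerate
case is flagged with a warning and p reported as 0. Pearson
correlations (morphology vs microstructure at the final timepoint) use
the t transform with n − 2 df. No correction is applied across
outcomes, matching the sequential-gate design.

# The phantom: what it emulates, and what it does not

The generator reproduces the study's *structure*, not its anatomy:

* acquisition geometry: 0.156 x 0.156 x 0.75 mm voxels, 30 diffusion
  directions (deterministic Fibonacci-sphere spread) at b = 1000
  s/mm^2 plus one b0;
* an ellipsoidal two-hemisphere brain with an exact mirror plane, one
  straight left–right white-matter cylinder per hemisphere, mirrored
  ellipsoidal ventricles that enlarge over time, and a spherical
  ipsilesional lesion whose radius is non-increasing over day 1 →
  week 2 → week 5 (infarcts are largest acutely);
* Rician magnitude noise, $\sqrt{(S+n_1)^2+n_2^2}$ with
  $n \sim N(0,\sigma^2)$ and $\sigma$ = (white-matter b0)/SNR,
  default SNR 30; `Inf` disables noise for exactness tests;
* three treatment arms with planted final-severity ordering
  SS-hMSCs < FBS-hMSCs < PBS-only in both lesion size and mNSS, equal
  acute severity, and samplable exclusion flags.

Tissue diffusivities and T2 intensities are not documented by studies
of this kind, so defaults are literature-typical (gray 0.8e-3 mm^2/s
isotropic; white 1.7/0.2/0.2e-3; CSF 3.0e-3; lesion = gray x a
per-timepoint factor, T2-hyperintense at 130 vs gray 100 +/- 5) and are
config-exposed rather than claims about any particular animal. Simple
shapes were chosen deliberately: spheres, ellipsoids and cylinders have
closed-form volumes, so volumetric recovery is testable analytically.

The phantom does **not** model partial-volume mixing, motion or eddy
artifacts, pulse-sequence physics beyond the monoexponential decay,
crossing fibers, or anatomically realistic geometry. Passing tests
therefore demonstrate that the *analysis* is correct and calibrated,
not that it is robust to real-data artifacts; skull stripping and
motion/eddy correction are assumed done upstream for real data.

# Problem sizes and determinism

The default grid is 64 x 64 x 16 so a full-pipeline cohort run stays
fast on one CPU; unit tests mostly use 32 x 32 x 8 with lesion radii
scaled by `lesion_scale = 0.42` so lesions fit the smaller hemisphere.
Monte-Carlo checks use fixed seeds throughout: the type-I-error
simulation uses 1000 replicates, the direction-of-effect recovery 200
seeded cohorts, and the intact-cohort rFA check n = 6 phantoms at
SNR 30 (the scale at which normal-animal relative indices are reported
as 1.00 +/- 0.03). Every stochastic stage takes an explicit integer
seed, and identical seeds give bit-identical volumes, cohorts and
pipeline outputs.

# Known limitations

* Single-tensor model only; crossing-fiber voxels are acknowledged as
  inconsistent for tensor modeling and no ODF-based alternative is
  provided.
* Ventricular delineation is prior-guided thresholding; fully manual
  atlas tracing is not algorithmic and is out of scope.
* The recovery ROI inherits the cross-session alignment assumption
  described above.
* The exchangeable-GEE estimator assumes a common within-subject
  correlation; unstructured working correlation is not implemented.
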