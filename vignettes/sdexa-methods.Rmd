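---
title: "Scout-based dual-energy absorptiometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scout-based dual-energy absorptiometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdexa)
```

This vignette is the package's own account of the science it implements:
the physical models, the tunable parameters and their defaults, what the
synthetic data generator does and does not emulate, the numerical choices,
and the known limitations.

## 1. The measurement chain

A dual-layer spectral CT examination yields two related bone-density
measurements. In three dimensions, virtual monoenergetic volumes at 50 and
200 keV are decomposed per voxel into water and hydroxyapatite densities;
the mean hydroxyapatite density over a vertebra's trabecular compartment is
its volumetric BMD (vBMD, mg/mL). In two dimensions, the low-dose scout
acquired before the scan is spectrally resolved; a projection-domain
decomposition turns it into an areal BMD map (aBMD, g/cm²), the quantity a
DEXA scanner reports. Because both come from the same geometry-calibrated
system, 3D masks and maps can be forward-projected into the scout frame and
compared patient by patient. `sdexa` simulates this chain end to end on
phantoms with known ground truth and reproduces the accompanying
statistical analysis.

## 2. Attenuation model and units

All attenuation physics derives from one tabulation
(`inst/extdata/mass_attenuation.csv`) of water and hydroxyapatite mass
attenuation over 30–200 keV. The tabulation is generated from a
two-component parameterization — photoelectric `(E/30 keV)^-3` plus the
total Klein–Nishina cross section, both normalized to 1 at 30 keV —
anchored to published values at 50 and 200 keV (water 0.2269 / 0.1370
cm²/g; hydroxyapatite 0.586 / 0.125 cm²/g, the latter obtained by elemental
mass-fraction mixing). The anchors are implementation inputs, not asserted
constants; replacing the CSV with any other tabulation covering 30–200 keV
is supported, and `attenuation_model()` refits the basis coefficients by
least squares over 30–150 keV, enforcing a fit residual below 2% per
material and a coefficient-matrix condition number below 10⁶.

Unit conventions throughout: densities g/mL (water) and mg/mL
(hydroxyapatite, i.e. vBMD); attenuation 1/cm; lengths mm in geometry, cm
in path integrals; areal densities g/cm²; equivalent path lengths (EPL) cm
of water.

## 3. Phantom and synthetic cohort

The phantom is deliberately simple: a soft-tissue ellipse extruded along
the table axis, containing one to four vertebrae modelled as cylinders
(trabecular core, cortical shell) with a posterior spinous-process block.
The spinous block exists so that the one anatomical effect central to the
AP-versus-lateral comparison — spinous overlap inflating AP aBMD — is
present; lateral projections separate the process from the body. Defaults:
64×64×40 voxels at 3 mm, body semi-axes 90×70 mm, vertebral body radius
17 mm, height 24 mm, cortical shell 1.5 mm at 450 mg/mL, trabecular core
150 mg/mL, spinous block 10×28×14 mm.

`generate_cohort()` draws per-patient trabecular vBMD uniformly over a
configurable range (the study conditions use 40–200 mg/mL, spanning
osteoporotic to normal) and jitters anatomy within physiological bounds:
body semi-axes ±5%, vertebra position ±3 mm, cortical mineral 350–500
mg/mL, spinous mineral 100–200 mg/mL and length 25–31 mm, all independent
of the trabecular value. These independent nuisance contributions are what
degrade the AP correlation relative to lateral, reproducing the study's
ordering mechanism rather than just its numbers.

What the generator does **not** emulate: realistic trabecular texture,
osteophytes, fractures and degenerative changes, ribs and bowel gas,
contrast agents, polychromatic spectra, scatter, or detector cross-talk. A
passing test suite therefore shows the pipeline is correct under the
modelled physics — linear two-material attenuation with Poisson counting
noise — not that it is robust to everything clinical data contains.

## 4. Scout acquisition and noise genesis

The dual-layer detector's spectral response is proprietary, so the scout is
modelled as two effective monoenergetic channels (defaults 55 and 75 keV)
with independent Poisson counts per pixel, `N ~ Poisson(N0 exp(-L))`. Zero
counts are clamped to one and the clamped fraction recorded. The default
air fluence `N0 = 2×10⁴` per channel pixel was chosen once so that the
photoelectric EPL map of an abdomen-sized water path has a soft-tissue SNR
near 5, the low-dose regime the denoiser is designed for; the simulated
value lands at 5–7. Solving the 2×2 channel system per pixel produces the
photoelectric/Compton EPL pair whose noise is strongly anticorrelated
(r ≈ −0.9 in homogeneous regions) — precisely the phenomenology the
denoiser targets. Channel energies and pixel pitch of the real detector
are not public; both defaults are declared, config-exposed choices.

## 5. Denoising

The pipeline follows the minimum-noise-image construction:

1. **Weight.** `w = (var_c − cov) / (var_p + var_c − 2 cov)` from the
   noise covariance in a bone-free ROI, clamped to [0, 1]. The covariance
   is taken over high-pass residuals (pixel minus 3×3 mean) by default, so
   smooth anatomical gradients crossing the ROI cannot masquerade as noise
   covariance; on truly flat fields `detrend = FALSE` reproduces the plain
   sample-covariance formula. The ROI is auto-detected as the interior box
   minimizing the local |photoelectric − Compton| bone signal, constrained
   to the body's signal plateau; it can always be supplied explicitly.
2. **Dictionary denoising** of the minimum-noise image: 8×8 patches at
   stride 1, 256 atoms initialized from an overcomplete DCT, greedy
   matching pursuit with per-patch residual tolerance `1.1 σ ×
   patch_size`, MOD (least-squares) atom updates, five alternations, at
   most 2000 training patches subsampled with a fixed seed. Patch means
   are excluded from coding and carried through; the global image mean is
   preserved exactly. A constant image has no trainable patches and is
   rejected rather than fitted.
3. **Local linear transform** back to each basis map: per-window ridge
   regression of the raw basis map **on the denoised minimum-noise
   image**, coefficients averaged over overlapping windows (the
   guided-filter construction). Fitting on the denoised rather than the
   raw reference matters: the raw reference's residual noise acts as an
   errors-in-variables perturbation whose slope attenuation biased bone
   aBMD downward by 5–13% in simulation; with the clean guide the bias
   drops to ~1%, consistent with mean-preservation at the few-percent
   level. The ridge defaults to 10⁻³ of the mean local window variance of
   the guide — an image-adaptive scale; a global-variance rule would be
   dominated by the body/air contrast of simulated scouts and over-shrink
   the slope. The window radius defaults to a physical 8 mm converted to
   pixels from the map's pixel spacing, keeping the transform local
   relative to anatomy at any detector sampling.

When the estimated noise level is below 10⁻⁶ of the map scale the input is
already clean and is passed through unchanged, making the noiseless
identity exact. Denoising preserves the weighted recombination of the two
maps at the pixel level (deviations well below half the basis-map noise
sigma) because only the direction orthogonal to the minimum-noise
combination is modified — the mechanism by which quantitative values
survive denoising.

ROI metrics (`roi_metrics()`) report mean/sd/SNR and the between-map
Pearson r as plain statistics of the ROI; they are meaningful noise
diagnostics only in homogeneous regions. On structured bodies the
post-denoising correlation between the two maps is dominated by shared
anatomy and tends toward +1; the anticorrelation-reduction property is
therefore assessed on flat-bodied phantoms.

## 6. Projector

The scout geometry is a fan of 52.5° over `n_columns` detector columns
(512 in the clinical protocol; smaller in fast simulations), source
rotating about the table axis (0° = AP, 90° = lateral), with the table
stepping through a beam collimated to a few detector rows averaged per
cell. Row pitch is referred to the isocenter, which makes path integrals
independent of the source-to-detector distance. Source-to-isocenter /
detector distances default to 570 / 1040 mm (typical clinical fan-beam
values; the protocol does not state them).

The ray integrator accumulates exact voxel-intersection lengths
(Siddon-style plane crossings), so piecewise-constant volumes are
integrated exactly; an interpolating integrator cannot meet the package's
own oracle-equivalence bound (10⁻³ against an exact tracer on random
voxel volumes). Density volumes yield areal density (g/cm²), binary masks
yield path length (cm). 2D vertebra masks are obtained by thresholding
each label's path-length map at `coverage_fraction` (default 0.25 — how
the 2D masks were binarized clinically is unstated) of its maximum, with
overlaps resolved toward the larger path.

Quadrature caveat: summing a projected map times pixel area approximates
the volume integral of the projected quantity; with sharp voxel edges the
column sampling must be fine enough (≈1 mm at the isocenter) for the
mass-conservation property to hold within 1%.

## 7. Registration

Projected and measured maps share units, so the similarity metric is the
mean squared difference; mutual information would only add variance. The
transform is translation-then-affine about the image centre, optimized
with Nelder–Mead over a coarse-to-fine pyramid (3 levels, 200 iterations
per stage). Two safeguards handle the periodic vertebra pattern: an
exhaustive integer-shift scan seeds the coarsest translation stage (evenly
spaced vertebrae create half-period local minima), and the affine
refinement is kept only when it improves on the translation solution.
Determinant bounds (0.5, 2.0) and a final-versus-initial metric check
reject degenerate solutions. Labels are resampled nearest-neighbour;
intensities bilinearly. On noiseless synthetic scouts, injected shifts up
to 10 px and rotations up to 5° are recovered to well under 0.5 px / 0.5°.

## 8. Quantification and statistics

vBMD is the arithmetic mean of the hydroxyapatite map over a vertebra's
trabecular voxels; aBMD the mean of an aBMD map over the vertebra's 2D
mask. Negative noise-driven values are preserved (clipping would bias ROI
means); a QC flag marks masks with more than 20% negative pixels. The
patient-level value is the mean over L1–L4 (the clinical aggregate
combiner is unstated; the mean is this package's declared choice), and
per-patient rows are the default analysis input, with per-vertebra rows
also emitted.

Status thresholds are strict: vBMD < 80 mg/mL osteoporotic, < 120
osteopenic, otherwise normal — boundary values fall in the higher class.

Regressions are ordinary least squares with t-based confidence intervals
(`qt(1 − α/2, n − 2)`); the default direction regresses vBMD on aBMD, so
slopes are mg/mL per g/cm² — numerically the 1/cm convention of the
clinical report (vBMD in mg/mL divided by aBMD in g/cm² carries 1000 ×
cm⁻¹); the reverse direction is available. The two-sample t-test defaults
to the equal-variance form (no correction was specified clinically), with
Welch available. ROC curves sweep the unique scores, integrate by the
trapezoidal rule (equal to the pairwise-concordance estimator with half
credit for ties — an identity the tests verify exactly), and pick the
operating point with minimum Euclidean distance to (FPR 0, TPR 1), ties
toward higher TPR. BMD-like scores classify disease at *low* values, which
is handled by orientation rather than score negation so thresholds stay in
physical units. ROC ground truth uses the 80 mg/mL cut for the projected
arms and the 120 mg/mL cut (osteopenic + osteoporotic versus normal) for
the measured-scout arm, where counting statistics are poorest.

## 9. Problem sizes and determinism

Simulations in the tests and the acceptance script use phantoms of
64×64×40 voxels at 3 mm, scouts of 60–64 rows by 64–256 columns, cohorts
of 40 patients, 20 denoising realizations, 2000 regression replicates and
5000 t-test replicates — sizes chosen so the full chain, including the
exact-intersection projector, runs in minutes on one CPU while every
statistical check retains enough power to be meaningful. All stochastic
stages consume explicit seeds (`withr::with_seed`), and the end-to-end
pipeline derives per-stage seeds from one global seed, so identical
configurations reproduce bit-identical outputs.

## 10. Known limitations

- Two-material decomposition only; no contrast agent, no three-material
  or k-edge extension.
- The effective-channel detector model reproduces the anticorrelation
  phenomenology, not the quantitative spectral response of a dual-layer
  detector; absolute SNR values should be read as regime-matched, not
  calibrated.
- The phantom's cortical shell at 3 mm voxels is one voxel thin and
  partial-volume averaged; cortical quantification is out of scope.
- Registration assumes matched geometry up to a small affine motion; it
  is not a deformable or 2D–3D method.
- No soft-tissue correction factor is applied to aBMD, matching the
  clinical processing choice this package follows.
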