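# sdexa

Scout-based dual-energy absorptiometry (SDEXA) simulation and analysis in R.

## The problem

Osteoporosis screening is limited by access to DEXA scanners, while almost
every CT examination starts with a low-dose 2D scout scan (topogram). On a
dual-layer spectral CT system that scout is spectrally resolved, so it can be
decomposed into material-specific maps and read out as an areal bone mineral
density (aBMD, g/cm²) — a DEXA-like measurement obtained opportunistically,
at no extra dose. The accompanying spectral CT volume provides the reference:
a volumetric trabecular bone mineral density (vBMD, mg/mL) obtained by
per-voxel material decomposition of virtual monoenergetic images.

`sdexa` implements that entire measurement chain on digital lumbar-spine
phantoms with known ground truth, for people who want to study, stress-test
or extend the method: simulation of the dual-energy CT volumes and the
two-channel Poisson-noise scout, both material decompositions, the
anticorrelated-noise dictionary denoiser, fan-beam forward projection of
volumes and masks into scout geometry, 2D registration, per-vertebra
quantification, and the regression / ROC statistics of a screening study.

## The model in brief

**Image domain.** At virtual monoenergetic energies (50 and 200 keV) each
voxel's attenuation is a linear mix of water and hydroxyapatite:

    mu_E = (mu/rho)_water(E) * rho_water + (mu/rho)_bone(E) * rho_bone

Inverting the 2×2 system per voxel yields the water map and the vBMD map.

**Projection domain.** Diagnostic-energy attenuation is spanned by the
photoelectric (~E⁻³) and Compton (Klein–Nishina) cross sections. The
two-channel scout measures Poisson counts `N ~ Poisson(N0 exp(-L_E))` at two
effective energies; solving the per-pixel channel system gives photoelectric
and Compton line integrals (expressed as water-equivalent path lengths, cm),
and a basis change maps them to water and bone areal densities — the aBMD
map. The decomposition strongly anticorrelates the noise of the two maps
(Pearson r near −0.9 at scout dose).

**Denoising.** A weighted sum of the two maps in which the anticorrelated
noise maximally cancels (the *minimum-noise image*) is denoised with a
learned patch dictionary (matching-pursuit sparse coding, MOD updates, DCT
initialization); a local linear transform then carries the denoised
structure back into each basis map without disturbing quantitative values.

**Classification.** Trabecular vBMD thresholds of 80 / 120 mg/mL define
osteoporotic / osteopenic / normal status; aBMD arms (measured AP scout,
projected AP, projected lateral) are scored against that ground truth with
trapezoidal-AUC ROC curves and minimum-distance operating points.

## Worked example

```r
library(sdexa)
model <- attenuation_model()

# digital L1-L4 phantom (150 mg/mL trabecular) and its CT volumes
vol  <- build_phantom(phantom_spec())
mono <- simulate_monoenergetic(vol, model)
vbmd <- decompose_image_domain(mono, decomposition_matrix(model))
vertebra_vbmd(vbmd, vol, "L2")
#> [1] 150

# low-dose spectral scout of a flat-bodied phantom and its denoising
flat  <- build_phantom(phantom_spec(body_ellipse = c(400, 70),
                                    vertebrae = default_vertebrae()[2]))
geo   <- scout_geometry(n_columns = 192, z_collimation_rows = 2,
                        row_pitch = 1, table_step = 2)
scout <- simulate_scout(flat, geo, scout_acquisition(seed = 1), model)
dn    <- denoise_pipeline(scout, model = model)
r     <- dn$report
round(c(weight = r$weight,
        snr_before = r$before$photoelectric$snr,
        snr_after = r$after$photoelectric$snr,
        anticorr_before = r$before$anticorrelation,
        anticorr_after = r$after$anticorrelation,
        abmd_shift_pct = r$mean_abmd_shift_pct), 3)
#>          weight      snr_before       snr_after anticorr_before
#>           0.096           6.323          80.743          -0.901
#>  anticorr_after  abmd_shift_pct
#>           0.017           1.810

abmd <- epl_to_abmd(dn$denoised, model, denoised = TRUE)
mask <- project_mask(flat, geo)
vertebra_abmd(abmd, mask, "L2")
#> [1] 0.605425
#> attr(,"mask_pixel_count")
#> [1] 130
#> attr(,"qc_flag")
#> [1] FALSE
```

That is the g/cm² mean over the vertebra's projected trabecular mask: the
150 mg/mL core plus cortical-shell and spinous overlap along a roughly 4 cm
path.

The scout is acquired in the paper-matched regime: a raw photoelectric
soft-tissue SNR near 5–6 that the denoiser raises by an order of magnitude
while the mean aBMD over the vertebral mask moves by under 2%.

A cohort-level run ties everything together:

```r
geo_c  <- scout_geometry(n_columns = 64, z_collimation_rows = 2, row_pitch = 2)
cohort <- generate_cohort(12, c(40, 200), geometry = geo_c, seed = 2)
tbl    <- build_cohort_table(cohort, geo_c, model)
run_cohort_analysis(tbl)
#> <cohort_analysis> n = 12 patients
#>   measured_ap        r = 0.960, slope 365 [290.3, 439.6]
#>   projected_ap       r = 0.978, slope 427.9 [363.6, 492.3]
#>   projected_lateral  r = 0.969, slope 372 [305.1, 439]
#>   measured_ap        AUC = 1.000
#>   projected_ap       AUC = 1.000
#>   projected_lateral  AUC = 1.000
```

Slopes are vBMD (mg/mL) per aBMD (g/cm²) with 95% confidence intervals from
the inverse Student t-distribution. Results are tibble-friendly:
`tidy()` / `glance()` on regressions and ROC curves, `autoplot()` on ROC
curves, regressions and aBMD maps.

`run_end_to_end(default_pipeline_config())` executes the full pipeline
(simulate → decompose → denoise → project → register → quantify → analyze),
persists every intermediate (NIfTI volumes and maps, CSV cohort table with a
JSON schema, JSON manifest) and reproduces bit-identical outputs for a fixed
seed.

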