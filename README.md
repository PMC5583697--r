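# pwsld

Disorder-strength analysis for partial wave spectroscopic (PWS)
microscopy — the nanocytology technique that detects pre-cancerous
changes in chromatin organisation at 20–200 nm length scales, far below
the diffraction limit, from ordinary bright-field images taken at many
wavelengths.

## Who this is for, and what it computes

A PWS microscope acquires images at ~200 narrow-band wavelengths and
stacks them into a cube R(x, y, λ). Inside each pixel, light backscattered
by nanoscale refractive-index (RI) fluctuations interferes with a
reference wave reflected at the cell surface. Since RI is linear in
macromolecular mass density (n = n_water + αρ, α = 0.18 ml/g), the
statistics of these spectra report the heterogeneity of chromatin packing
that conventional microscopy cannot resolve.

`pwsld` implements the full analysis chain a nanocytology study needs:

1. **Spectral reduction** — per-pixel denoising (zero-phase 6th-order
   Butterworth along λ), polynomial baseline removal, and the spectral
   standard deviation Σ(x, y); then the disorder strength

   L_d = c · Σ² / (k̄² L)

   (variance convention; k̄ = 2π/λ̄, L = cell thickness; a linear
   convention L_d = c·Σ/L is also provided). L_d is proportional to
   σ²_n·l_c — fluctuation amplitude times correlation length — the
   quantity that rises early in field carcinogenesis.
2. **Nuclear segmentation** — maximum-entropy (Kapur) thresholding of the
   transmission image, morphological cleanup, distance-transform-seeded
   watershed for touching nuclei, area gating, and per-nucleus /
   perinuclear L_d statistics.
3. **Cohort statistics** — patient-level aggregation, effect size on the
   cumulative-SD convention (reported as %, e.g. 104% = 1.04 SDs), Welch
   or Mann–Whitney tests, nuclear-vs-cellular correlation, and CSV
   reports.
4. **A physics-grounded simulator** — exact 1D transfer-matrix
   reflectance of Gaussian-correlated random media, 2D cell phantoms with
   ground-truth masks, and synthetic cohorts, so the entire pipeline is
   testable end to end with no instrument data.

Cubes travel as multi-page TIFF (one page per wavelength) with a JSON
sidecar for the wavelength axis, pixel size, and instrument metadata;
maps and label masks as single-page TIFF + sidecar; tables as CSV.

## Worked example

Simulate a small phantom "measurement", reduce it to maps, segment, and
summarise:

```r
library(pwsld)
axis <- default_axis()        # 200 wavelengths, 500-699 nm

ph <- make_phantom_cube(phantom_spec(n_nuclei = 6, dim_px = c(96, 96),
                                     seed = 11), axis)
ph$cube
#> <spectral_cube> 96 x 96 px (0.5 um/px), 200 wavelengths 500.0-699.0 nm [reflectance]

sigma <- compute_sigma_map(ph$cube, filter = filter_spec(), poly_order = 1)
ld <- sigma_to_ld(sigma, thickness = 2, axis, convention = "variance")
ld
#> <ld_map> 96 x 96 px, convention 'variance', calibration 1, L_d in [2.1e-05, 0.0221]

mask <- segment_nuclei(ph$transmission, segmentation_params(),
                       pixel_size_um = 0.5)
region_ld_stats(ld, mask, annulus_width_px = 10)
#>   label area_px area_um2 centroid_row centroid_col mean_ld pixel_count_used mean_cellular_ld
#> 1     1     200     50.0         14.8        81.59 0.00314              200          0.00125
#> 2     2     205     51.2         16.5        31.72 0.00288              205          0.00113
#> ...
```

All six phantom nuclei are found at their true positions (~50 µm² discs),
and the nuclear mean L_d (phantom nucleus class: σ_n = 0.04) is about 2.5×
the cellular mean, which dilutes the nucleus with the quieter cytoplasm
class (σ_n = 0.02) — the contrast the phantom was built with. In arbitrary
units (calibration 1), L_d ≈ Σ²/(k̄²L) ~ 3×10⁻³ nm-scale numbers; only
ratios and effect sizes matter downstream.

Cohort comparison on a synthetic two-arm study:

```r
co <- make_cohort(n_per_group = 20,
                  group_means = c(control = 1.0, case = 1.8),
                  group_sds = 0.35, seed = 2)
compare_groups(co, "control", "case")
#> <group_comparison> control (n=20) vs case (n=20)
#>   effect size: 136% (cumulative SD); p = 8.27e-07 (welch_t, two-sided)
```

The effect size is the difference of group means in units of the SD of
the combined sample; 136% means the groups sit 1.36 cumulative SDs apart.

A thin command-line front end (`inst/cli/pws.R`) exposes `simulate`,
`ld`, `segment`, `compare`, and `report` subcommands over the same
functions.

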