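---
title: "Disorder-strength analysis of PWS microscopy cubes: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disorder-strength analysis of PWS microscopy cubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwsld)
```

## The measurement and its model

Partial wave spectroscopic (PWS) microscopy records a bright-field image at
many narrow-band wavelengths and stacks the frames into a cube
$R(x, y, \lambda)$. Each pixel's spectrum is an interference pattern: a
reference wave reflected at the cell's index-mismatched surface beats
against partial waves backscattered by refractive-index (RI) fluctuations
inside a roughly cylindrical volume through the cell. Because the RI of
cellular material is linear in local macromolecular mass density,
$n = n_\mathrm{water} + \alpha\rho$ with $\alpha = 0.18$ ml/g, the
statistics of those spectra report the spatial statistics of mass density
at length scales (tens of nanometres) far below the diffraction limit.

The pipeline reduces each pixel to two numbers:

* $\Sigma(x,y)$ — the standard deviation over wavelength of the denoised,
  baseline-subtracted spectrum (`compute_sigma_map()`), and
* the disorder strength $L_d(x,y)$ — $\Sigma$ normalised by the local cell
  thickness $L$ (`sigma_to_ld()`).

For a weakly scattering medium whose RI fluctuations have amplitude
$\sigma_n$ and correlation length $l_c$ (both in the "small $l_c$" regime),
the ensemble spectral variance grows as
$\Sigma^2 \propto \sigma_n^2\, l_c\, L\, \bar{k}^2$, with
$\bar{k} = 2\pi/\bar\lambda$. The package therefore defines the default
**variance convention**

$$L_d = c\,\frac{\Sigma^2}{\bar{k}^2 L},$$

which estimates $\sigma_n^2 l_c$ (units of nm) up to the calibration
constant $c$, and is dimensionally consistent with the 1D simulator that
validates it. A **linear convention** $L_d = c\,\Sigma/L$ is also provided,
matching the literal phrasing "$\Sigma \propto \sigma_p l_c L$" that
circulates for this statistic; the two conventions order media identically
in the regimes we simulate, and every cohort-level statistic downstream is
invariant to the choice of $c$ (see *Why arbitrary units suffice* below).

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| wavelength axis | 500–699 nm, 200 pts | nm | visible-band acquisition grid; 200 points at 1 nm spacing span 199 nm, so the grid is taken as 500–699 inclusive |
| filter order / cutoff | 6 / 0.08 | –, cycles/nm | a reflector at depth $z$ oscillates at $\approx 2 n_0 z/\bar\lambda^2 \approx 0.008\,z[\mu m]$ cycles/nm, so 0.08 passes interference from cells up to ~10 µm thick while rejecting pixel noise |
| baseline order | 1 | – | removes the flat Fresnel background and linear lamp drift; higher orders start eating genuine low-frequency interference |
| thickness | user input, scalar or map | µm | the paper of record does not specify how $L(x,y)$ is measured; no internal estimator is offered |
| calibration $c$ | 1 (arbitrary units) | – | fixed only by simulation (`calibrate_ld()`); cohort statistics never need it |
| noise floor | off | (value)² | optional $\Sigma^2$ bias correction; the floor should be the noise variance *surviving the filter passband* |
| area gate | 20–500 | µm² | generous bounds for epithelial nuclei |
| histogram bins | 256 | – | Kapur threshold resolution |
| seed min distance | 5 | px | watershed seed separation for touching nuclei |
| annulus width | 10 | px | "cellular" = nucleus + perinuclear ring of this width |

## Numerical choices

**Zero-phase filtering.** The Butterworth low-pass is applied forward and
backward, so the effective magnitude response is $|H|^2$ (exactly $1/2$ at
the cutoff) and no spectral feature is shifted. Edge handling combines
odd-reflection padding with steady-state initial conditions for the filter
state; with zero initial state the slowest Butterworth poles (radius 0.8)
carry start-up transients of order $10^{-3}$ into the band, which is enough
to break the polynomial-invariance property of $\Sigma$. The per-pixel mean
is removed before filtering and restored afterwards, which makes the DC
response exact by construction. The recursion runs vectorised across all
pixels at once, so filtering a full cube costs a few matrix sweeps.

**Baseline removal** is an exact least-squares polynomial projection (QR
residuals) per pixel; $\Sigma$ is therefore invariant, to numerical
precision, under adding any polynomial of the fitted order to every
spectrum.

**TIFF storage.** The available TIFF codec writes 8/16/32-bit integer
samples only (no floating-point sample format). Cubes and maps are stored
as 32-bit samples on a fixed-point grid: values are divided by a
power-of-two scale recorded in the JSON sidecar, and a compensation factor
aligns the writer's and reader's integer mappings. A write–read roundtrip
reproduces every value to within $\mathrm{scale}\times 2^{-31}$ (about half
a part per billion of full scale) but is not bit-identical for arbitrary
doubles — a documented limitation of the container, not of the analysis.

**Degenerate inputs.** Constant images have no entropy threshold (error);
empty masks are errors for statistics but a *warning* for segmentation (a
blank field of view is data); zero or negative thickness pixels abort the
$L_d$ conversion with a count; axes shorter than 8 samples are rejected
because a spectral variance over fewer points is meaningless.

## The simulator: what it emulates, what it does not

The synthetic layer exists so that every stage of the pipeline can be
tested against ground truth without any instrument data.

* `gaussian_correlated_profile()` draws 1D stationary media: zero-mean
  Gaussian $\delta n(z)$ with marginal SD $\sigma_n$ and Gaussian
  autocorrelation of $1/e$ half-width $l_c$ (white noise convolved with an
  $L^2$-normalised Gaussian kernel of SD $l_c/2$). The grid step is
  $\min(l_c/4, 10\,\mathrm{nm})$.
* `transfer_matrix_reflectance()` solves each stack *exactly* by the
  characteristic-matrix method at normal incidence (compiled inner loop).
  For real indices the stack matrix stays in the form
  $\bigl(\begin{smallmatrix} A & iB\\ iC & D\end{smallmatrix}\bigr)$ with
  $A,B,C,D$ real, so the solver runs in real arithmetic; it matches the
  Airy closed form for homogeneous films at the $10^{-14}$ level and
  conserves $R + T = 1$ to $10^{-10}$ for lossless media.
* The sample geometry follows a cell on an index-matched mount: ambient
  index 1.0 supplies the reference reflection; the substrate is matched to
  the mean cell index $n_0 = 1.38$, so no spurious back-wall fringe is
  added.
* `make_phantom_cube()` builds 2D fields of disc nuclei whose pixels carry
  nucleus-class $(\sigma_n, l_c, L)$ parameters against a cytoplasm-class
  background, each pixel an independent exact simulation, plus a
  transmission rendering (nuclei dark) and the ground-truth label mask.
* `make_cohort()` draws patient-level $L_d$ means per diagnostic group for
  the statistics layer.

What the simulator does **not** emulate: 3D/vectorial light transport and
NA-dependent collection, speckle correlations between neighbouring pixels,
chromatic dispersion, stain absorption, shot noise (the noise model is
additive white Gaussian), and real nuclear morphology (discs instead of
lobed nuclei). Passing phantom tests therefore demonstrates the
*algorithmic* correctness of the pipeline — filters, statistics,
segmentation, calibration — on physically exact 1D interference spectra,
not instrument-level photometric fidelity.

## Validation regimes and problem sizes

Two scaling laws anchor the physics validation, both run as ensembles of
exact simulations: mean $\Sigma^2$ linear in $\sigma_n^2$ at fixed
$(l_c, L)$ with $R^2 > 0.99$ (100 realizations per point at $L = 2$ µm),
and mean $\Sigma^2$ doubling when $L$ doubles. The thickness check is run
at 4 µm → 8 µm: over a finite 500–699 nm band, baseline removal inevitably
suppresses interference from the shallowest ~0.5 µm of the cell (those
components complete less than one oscillation across the band), so the
$2\times$ law is asymptotic in $L$ and measures $\approx 2.35$ at 2 µm →
4 µm but $\approx 2.2$ at 4 µm → 8 µm. Both thicknesses stay inside the
weak-scattering bound $\sigma_n \bar{k} L \le 2$ that
`simulate_pws_ensemble()` warns about.

Calibration (`calibrate_ld()`) fits the single constant mapping measured
$\Sigma^2/(\bar{k}^2 L)$ onto known $\sigma_n^2 l_c$ over a 3×3
$(\sigma_n, l_c)$ grid and is validated by held-out recovery. The linear
law degrades as $l_c$ grows: the backscattering efficiency of a Gaussian
spectrum rolls off as $\exp(-q^2 l_c^2/4)$ with $q = 2\bar{k} n_0 \approx
0.029$ nm⁻¹, i.e. 0.95 at $l_c=15$ nm but 0.77 at 40 nm. The calibration
domain is therefore fixed at $l_c \le 25$ nm (roll-off $\ge 0.88$), the
regime the small-$l_c$ theory actually describes; the grid is
$\sigma_n \in \{0.01, 0.02, 0.03\}$, $l_c \in \{15, 20, 25\}$ nm with 300
realizations per point (the per-realization coefficient of variation of
$\Sigma^2$ is ~0.7, so smaller ensembles let Monte-Carlo noise dominate
the recovery error). Held-out points recover $\sigma_n^2 l_c$ within a few
percent. Outside this domain `calibrate_ld()` refuses (fit $R^2 < 0.9$)
rather than return a silently biased constant.

The end-to-end discrimination study mirrors a two-arm cohort at realistic
size: 20 patients per group, 30 nuclei-equivalents per patient (one exact
spectrum each at $L = 2$ µm), control $\sigma_n = 0.02$ versus cases with
$\sigma_n^2 l_c$ doubled, 100 independent repetitions on a 100-point
wavelength grid. The case/control gap is detected (positive effect size,
$p < 0.05$, Welch) in essentially every repetition, with median effect
size ≈ 180% — comfortably above the ~100% effects reported in clinical
nanocytology, as expected for a phantom with no biological between-patient
variability.

## Segmentation design

The paper trail for nuclear detection names two operators — maximum-entropy
(Kapur) thresholding and watershed — but no parameters, so everything else
is an explicit implementation choice: 256 histogram bins; ties in the
entropy criterion broken toward the lowest threshold; hole filling and a
1-pixel opening between thresholding and watershed (raw thresholded masks
over-fragment); watershed seeded from local maxima of the Euclidean
distance transform with a 5 px minimum separation (the alternative,
seeding from raw image intensity, is noisier); an area gate of 20–500 µm².
`max_entropy_threshold()` is checked against an independent brute-force
maximiser on randomised histograms, and the whole chain against phantom
ground truth (25/25 nuclei, mean IoU ≈ 0.99 on the default phantom).
Labels are renumbered in raster order of centroids, so segmentation is
fully deterministic.

## Cohort statistics: conventions

The reported effect size is the absolute difference of group means divided
by the **cumulative SD** — the sample SD of both groups pooled into one
sample — the convention used in PWS nanocytology tables (values quoted as
percentages: 104% means 1.04 cumulative SDs). The classical pooled
within-group SD (Cohen's d denominator) is available via
`sd_convention = "pooled_within"`. Sample ($n-1$) SDs are used throughout.
The significance test is not fixed by the field's reports; the default is
a two-sided Welch $t$ on patient-level means (it tracks an exact
permutation test within 0.02 at $n = 10+10$ in our checks), with
Mann–Whitney as a rank-based alternative. The patient, never the nucleus,
is the statistical unit.

**Why arbitrary units suffice:** the effect size is invariant under any
common affine transform $y = cx + d$ ($c > 0$) of all values, and Pearson
correlation likewise. Every cohort-level claim is therefore independent of
the calibration constant, the $L_d$ convention's overall scale, and the
instrument's intensity units.

## A worked mini-example

```{r example, eval = FALSE}
axis <- default_axis()

# a phantom measurement with known ground truth
ph <- make_phantom_cube(phantom_spec(seed = 4), axis)

# cube -> Sigma -> L_d
sigma <- compute_sigma_map(ph$cube, filter = filter_spec(), poly_order = 1)
ld <- sigma_to_ld(sigma, thickness = 2, axis, convention = "variance")

# nuclei from the transmission image, then per-nucleus statistics
mask <- segment_nuclei(ph$transmission, segmentation_params(),
                       pixel_size_um = 0.5)
region_ld_stats(ld, mask, annulus_width_px = 10)
```

## Known limitations

* Thickness $L(x,y)$ must be supplied; mis-specified thickness biases
  $L_d$ pixelwise (though not group contrasts if the bias is shared).
* The calibration constant transfers only within the simulated geometry
  (normal incidence, matched substrate, small $l_c$); treat physical-unit
  $L_d$ values as model-based estimates.
* The $2\times$ thickness law carries a finite-band bias at $L \lesssim
  3$ µm (above); comparisons across very different thicknesses should use
  per-pixel thickness maps rather than rely on perfect normalisation.
* TIFF roundtrips are quantised at $\mathrm{scale}\times 2^{-31}$; exact
  archival of doubles requires a floating-point container outside this
  package's scope.
* Segmentation assumes dark, roughly convex, non-overlapping nuclei in
  transmission; heavily clumped cytology fields need curated imaging or
  manual masks.
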