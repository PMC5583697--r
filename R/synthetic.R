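#' @useDynLib pwsld, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run expr under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Macromolecular density to refractive index
#'
#' The refractive index of cellular material is linear in the local
#' macromolecular mass density: `n = n_water + alpha * rho`, with the
#' specific refraction increment `alpha` (ml/g). This is the bridge
#' between the optical fluctuation amplitude `sigma_n` used by the
#' simulator and the mass-density fluctuation amplitude `sigma_p` of the
#' disorder-strength definition: `sigma_n = alpha * sigma_p`.
#'
#' @param rho Mass density (g/ml), any numeric array.
#' @param model A [refractive_model()].
#' @return Refractive index, same shape as `rho`.
#' @export
density_to_ri <- function(rho, model = refractive_model()) {
  stopifnot(inherits(model, "refractive_model"))
  if (any(!is.finite(rho))) stop("density must be finite", call. = FALSE)
  model$n_water + model$alpha_ml_per_g * rho
}

#' @rdname density_to_ri
#' @param n_water Refractive index of water, default 1.333.
#' @param alpha_ml_per_g Specific refraction increment, default 0.18 ml/g.
#' @export
refractive_model <- function(n_water = 1.333, alpha_ml_per_g = 0.18) {
  if (alpha_ml_per_g <= 0) stop("alpha must be positive", call. = FALSE)
  structure(list(n_water = n_water, alpha_ml_per_g = alpha_ml_per_g),
            class = "refractive_model")
}

#' 1D layered random medium
#'
#' A uniform-grid stack of thin homogeneous layers representing one line
#' of sight through a cell: mean index `n0` plus a zero-mean fluctuation
#' `delta_n` per layer. The sample geometry follows a cell on a mounting
#' medium: the refractive index is matched at one surface (substrate side,
#' `n_substrate = n0` by default, so no reference reflection arises there)
#' and mismatched at the other (`n_ambient`, which supplies the reference
#' wave that the internal partial waves interfere with).
#'
#' @param delta_n Numeric vector of per-layer index fluctuations.
#' @param dz_nm Layer thickness (uniform grid step), nm; must satisfy
#'   `dz_nm <= corr_len_nm / 4` and `dz_nm <= 10`.
#' @param n0 Mean refractive index, default 1.38.
#' @param n_ambient Index on the illumination side, default 1.0.
#' @param n_substrate Index beyond the medium, default `n0` (matched).
#' @param sigma_n Target SD of `delta_n` (recorded parameter).
#' @param corr_len_nm Target 1/e correlation length of `delta_n`, nm.
#' @return An object of class `"layered_medium"`.
#' @export
layered_medium <- function(delta_n, dz_nm, n0 = 1.38, n_ambient = 1.0,
                           n_substrate = n0, sigma_n = NA_real_,
                           corr_len_nm = NA_real_) {
  delta_n <- as.numeric(delta_n)
  if (length(delta_n) < 1L) stop("medium needs at least one layer", call. = FALSE)
  if (is.finite(corr_len_nm) && corr_len_nm <= 0)
    stop("corr_len_nm must be positive", call. = FALSE)
  if (is.finite(corr_len_nm) && dz_nm > corr_len_nm / 4 + 1e-12)
    stop("grid step ", dz_nm, " nm too coarse: need dz <= corr_len/4 = ",
         corr_len_nm / 4, " nm", call. = FALSE)
  if (dz_nm > 10 + 1e-12)
    stop("grid step must be <= 10 nm", call. = FALSE)
  if (any(n0 + delta_n <= 0) || n_ambient <= 0 || n_substrate <= 0)
    stop("non-physical refractive index (<= 0)", call. = FALSE)
  structure(list(delta_n = delta_n, dz_nm = dz_nm, n0 = n0,
                 n_ambient = n_ambient, n_substrate = n_substrate,
                 sigma_n = sigma_n, corr_len_nm = corr_len_nm,
                 thickness_nm = length(delta_n) * dz_nm),
            class = "layered_medium")
}

#' @export
print.layered_medium <- function(x, ...) {
  cat(sprintf("<layered_medium> %d layers x %.3g nm = %.3g nm, n0 = %.4g (ambient %.4g / substrate %.4g)\n",
              length(x$delta_n), x$dz_nm, x$thickness_nm, x$n0,
              x$n_ambient, x$n_substrate))
  if (is.finite(x$sigma_n))
    cat(sprintf("  target sigma_n = %.4g, l_c = %.4g nm\n",
                x$sigma_n, x$corr_len_nm))
  invisible(x)
}

# Matrix of Gaussian-correlated zero-mean profiles (nz x n_profiles):
# white noise convolved with a Gaussian kernel of SD l_c/2, which yields a
# Gaussian autocorrelation exp(-(z/l_c)^2) with 1/e half-width l_c; the
# kernel is L2-normalised so every sample has marginal SD sigma_n exactly.
gaussian_profile_matrix <- function(nz, n_profiles, sigma_n, corr_len_nm,
                                    dz_nm) {
  s <- corr_len_nm / 2 / dz_nm               # kernel SD in samples
  m <- max(1L, ceiling(4 * s))
  w <- exp(-((-m:m)^2) / (2 * s^2))
  w <- w / sqrt(sum(w^2))
  e <- matrix(stats::rnorm((nz + 2L * m) * n_profiles), nz + 2L * m,
              n_profiles)
  f <- stats::filter(e, w, method = "convolution", sides = 2L)
  sigma_n * matrix(f[m + seq_len(nz), ], nz, n_profiles)
}

#' Generate a Gaussian-correlated refractive-index profile
#'
#' Draws one realisation of a statistically stationary 1D medium whose
#' index fluctuation `delta_n(z)` is zero-mean Gaussian with marginal SD
#' `sigma_n` and Gaussian autocorrelation `exp(-(z/l_c)^2)` (1/e
#' half-width `corr_len_nm`). Deterministic given `seed`.
#'
#' @inheritParams layered_medium
#' @param sigma_n Marginal SD of the index fluctuation.
#' @param corr_len_nm 1/e correlation length, nm.
#' @param thickness_nm Total medium thickness L, nm.
#' @param dz_nm Grid step; default `min(corr_len_nm / 4, 10)` nm.
#' @param seed Optional RNG seed (caller's RNG state is untouched).
#' @return A [layered_medium()].
#' @export
gaussian_correlated_profile <- function(sigma_n, corr_len_nm, thickness_nm,
                                        dz_nm = NULL, n0 = 1.38,
                                        n_ambient = 1.0, n_substrate = n0,
                                        seed = NULL) {
  if (sigma_n < 0) stop("sigma_n must be >= 0", call. = FALSE)
  if (corr_len_nm <= 0) stop("corr_len_nm must be positive", call. = FALSE)
  if (is.null(dz_nm)) dz_nm <- min(corr_len_nm / 4, 10)
  if (dz_nm > corr_len_nm / 4 + 1e-12 || dz_nm > 10 + 1e-12)
    stop("dz_nm too coarse: need dz <= min(corr_len/4, 10) nm", call. = FALSE)
  nz <- max(1L, round(thickness_nm / dz_nm))
  delta <- if (sigma_n == 0) rep(0, nz) else
    with_seed(seed, gaussian_profile_matrix(nz, 1L, sigma_n, corr_len_nm,
                                            dz_nm)[, 1])
  layered_medium(delta, dz_nm, n0 = n0, n_ambient = n_ambient,
                 n_substrate = n_substrate, sigma_n = sigma_n,
                 corr_len_nm = corr_len_nm)
}

#' Exact 1D reflectance of a layered medium
#'
#' Solves the wave equation for the full stack by the characteristic
#' (transfer) matrix method at normal incidence -- no weak-scattering
#' approximation -- and returns the reflectance spectrum on the given
#' axis. This is the physics oracle of the package: every synthetic
#' spectrum is an exact interference solution.
#'
#' @param medium A [layered_medium()].
#' @param axis A [spectral_axis()].
#' @param transmission If `TRUE`, also return the transmittance (for
#'   lossless media `R + T = 1` to numerical precision).
#' @return Numeric vector `R(lambda)` in `[0, 1]`, or, with
#'   `transmission = TRUE`, a list with elements `R` and `T`.
#' @export
transfer_matrix_reflectance <- function(medium, axis, transmission = FALSE) {
  stopifnot(inherits(medium, "layered_medium"), inherits(axis, "spectral_axis"))
  out <- tm_reflectance_cpp(matrix(medium$n0 + medium$delta_n, ncol = 1),
                            medium$dz_nm, axis$wavelengths_nm,
                            medium$n_ambient, medium$n_substrate,
                            medium$n0, transmission)
  if (transmission) list(R = out$R[, 1], T = out$T[, 1]) else out$R[, 1]
}

# Batch reflectance for a matrix of index profiles (nz x n_profiles).
tm_reflectance_batch <- function(n_matrix, dz_nm, axis, n_ambient,
                                 n_substrate, n_ref) {
  tm_reflectance_cpp(n_matrix, dz_nm, axis$wavelengths_nm, n_ambient,
                     n_substrate, n_ref, FALSE)$R
}

#' Simulate an ensemble of PWS interference spectra
#'
#' Draws `n_realizations` independent Gaussian-correlated media with the
#' given parameters, solves each exactly by the transfer-matrix method,
#' optionally adds white detector noise, and reduces every spectrum to its
#' spectral variance through the same [compute_sigma_map()] pipeline the
#' instrument data would take. In the weak-scattering (Born) regime the
#' ensemble mean of Sigma^2 grows linearly in `sigma_n^2`, `corr_len_nm`
#' and `thickness_nm`; a warning is emitted when `sigma_n * kbar * L`
#' exceeds `weak_scattering_bound`.
#'
#' @inheritParams gaussian_correlated_profile
#' @param axis A [spectral_axis()].
#' @param n_realizations Ensemble size.
#' @param noise_sd SD of additive white Gaussian noise on the reflectance.
#' @param filter,poly_order Passed to [compute_sigma_map()]; `filter =
#'   NULL` skips denoising.
#' @param weak_scattering_bound Threshold on `sigma_n * kbar *
#'   thickness_nm` above which the Born-regime warning fires; default 2.
#' @param seed Optional RNG seed.
#' @return List of class `"pws_ensemble"`: `spectra` (n_lambda x
#'   n_realizations), `sigma` (per-realization Sigma), `mean_sigma2`,
#'   `se_sigma2`, and `params`.
#' @export
simulate_pws_ensemble <- function(sigma_n, corr_len_nm, thickness_nm, axis,
                                  n_realizations = 100, noise_sd = 0,
                                  seed = NULL, filter = filter_spec(),
                                  poly_order = 1L, n0 = 1.38, n_ambient = 1.0,
                                  n_substrate = n0,
                                  weak_scattering_bound = 2) {
  stopifnot(inherits(axis, "spectral_axis"))
  born <- sigma_n * axis$center_wavenumber * thickness_nm
  if (born > weak_scattering_bound)
    warning(sprintf("sigma_n * kbar * L = %.3g exceeds the weak-scattering bound %.3g; Born-regime scaling laws may not hold",
                    born, weak_scattering_bound))
  dz <- min(corr_len_nm / 4, 10)
  nz <- max(1L, round(thickness_nm / dz))
  spectra <- with_seed(seed, {
    delta <- if (sigma_n == 0) matrix(0, nz, n_realizations) else
      gaussian_profile_matrix(nz, n_realizations, sigma_n, corr_len_nm, dz)
    sp <- tm_reflectance_batch(n0 + delta, dz, axis, n_ambient, n_substrate,
                               n0)
    if (noise_sd > 0)
      sp <- pmax(sp + matrix(stats::rnorm(length(sp), sd = noise_sd),
                             nrow(sp), ncol(sp)), 0)
    sp
  })
  cube <- spectral_cube(array(t(spectra), c(n_realizations, 1L, nrow(spectra))),
                        axis)
  sig <- as.vector(compute_sigma_map(cube, filter = filter,
                                     poly_order = poly_order)$values)
  s2 <- sig^2
  structure(list(spectra = spectra, sigma = sig,
                 mean_sigma2 = mean(s2),
                 se_sigma2 = stats::sd(s2) / sqrt(length(s2)),
                 params = list(sigma_n = sigma_n, corr_len_nm = corr_len_nm,
                               thickness_nm = thickness_nm, dz_nm = dz,
                               n0 = n0, n_ambient = n_ambient,
                               n_substrate = n_substrate,
                               noise_sd = noise_sd,
                               n_realizations = n_realizations, seed = seed)),
            class = "pws_ensemble")
}

#' @export
print.pws_ensemble <- function(x, ...) {
  p <- x$params
  cat(sprintf("<pws_ensemble> %d realizations (sigma_n %.3g, l_c %.3g nm, L %.3g nm)\n",
              p$n_realizations, p$sigma_n, p$corr_len_nm, p$thickness_nm))
  cat(sprintf("  mean Sigma^2 = %.4g (SE %.2g)\n", x$mean_sigma2, x$se_sigma2))
  invisible(x)
}

#' Calibrate the disorder-strength constant against the simulator
#'
#' The instrument statistic only determines L_d up to a proportionality
#' constant. This routine fixes it by simulation: over a grid of known
#' `(sigma_n, corr_len_nm)` (and optionally thickness) parameters it
#' measures the thickness-normalised statistic -- `Sigma^2 / (kbar^2 L)`
#' under the variance convention, `Sigma / L` under the linear one -- and
#' fits the single least-squares constant mapping it onto the known
#' ground-truth disorder `sigma_n^2 * l_c` (variance) or `sigma_n * l_c`
#' (linear). The grid must stay inside the weak-scattering, small-`l_c`
#' regime where that mapping is linear; a poor fit triggers an error
#' rather than a silently wrong constant.
#'
#' @param grid Data frame with columns `sigma_n`, `corr_len_nm` and
#'   optionally `thickness_nm` (default 2000 nm); at least 2 distinct
#'   parameter points.
#' @param axis A [spectral_axis()].
#' @param convention `"variance"` or `"linear"` (see [sigma_to_ld()]).
#' @param n_realizations Ensemble size per grid point.
#' @param seed RNG seed.
#' @param min_r_squared Fit-quality gate, default 0.9.
#' @param ... Passed to [simulate_pws_ensemble()].
#' @return List of class `"ld_calibration"`: `constant` (use as the
#'   `calibration` argument of [sigma_to_ld()]), `r_squared`,
#'   `convention`, and the per-point `table`.
#' @export
calibrate_ld <- function(grid, axis, convention = c("variance", "linear"),
                         n_realizations = 80, seed = NULL,
                         min_r_squared = 0.9, ...) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(grid), all(c("sigma_n", "corr_len_nm") %in%
                                     names(grid)))
  if (is.null(grid$thickness_nm)) grid$thickness_nm <- 2000
  if (nrow(unique(grid[c("sigma_n", "corr_len_nm", "thickness_nm")])) < 2L)
    stop("calibration grid is degenerate: need >= 2 distinct parameter points",
         call. = FALSE)
  kbar <- axis$center_wavenumber
  measured <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ens <- simulate_pws_ensemble(grid$sigma_n[i], grid$corr_len_nm[i],
                                 grid$thickness_nm[i], axis,
                                 n_realizations = n_realizations,
                                 seed = if (is.null(seed)) NULL else seed + i,
                                 ...)
    measured[i] <- switch(convention,
                          variance = ens$mean_sigma2 /
                            (kbar^2 * grid$thickness_nm[i]),
                          linear = mean(ens$sigma) / grid$thickness_nm[i])
  }
  target <- switch(convention,
                   variance = grid$sigma_n^2 * grid$corr_len_nm,
                   linear = grid$sigma_n * grid$corr_len_nm)
  constant <- sum(target * measured) / sum(measured^2)
  r2 <- 1 - sum((target - constant * measured)^2) /
    sum((target - mean(target))^2)
  if (!is.finite(r2) || r2 < min_r_squared)
    stop(sprintf("calibration fit R^2 = %.3f < %.2f: grid likely leaves the weak-scattering / small-l_c regime; shrink sigma_n or corr_len_nm",
                 r2, min_r_squared), call. = FALSE)
  structure(list(constant = constant, r_squared = r2,
                 convention = convention,
                 table = cbind(grid, measured = measured, target = target)),
            class = "ld_calibration")
}

#' @export
print.ld_calibration <- function(x, ...) {
  cat(sprintf("<ld_calibration> constant = %.6g (%s convention), fit R^2 = %.4f over %d grid points\n",
              x$constant, x$convention, x$r_squared, nrow(x$table)))
  invisible(x)
}
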