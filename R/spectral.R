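#' Spectral low-pass filter settings
#'
#' Settings for the per-pixel spectral denoiser: a Butterworth low-pass of
#' the given order, applied zero-phase (forward and backward, so the
#' effective magnitude response is |H|^2 and no spectral features are
#' shifted). The cutoff is expressed in cycles per nm of the wavelength
#' axis; the default 0.08 cycles/nm keeps the interference oscillations of
#' micrometre-scale cells (a reflector at optical depth nz contributes
#' about 2nz/lambda^2 ~ 0.008 cycles/nm per micrometre of depth at 600 nm)
#' while suppressing uncorrelated pixel noise.
#'
#' @param order Filter order, default 6.
#' @param cutoff Cutoff, cycles per nm; must lie below the Nyquist
#'   frequency of the wavelength grid (0.5 cycles/nm at 1 nm spacing).
#' @param application Only `"zero_phase"` is implemented.
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(order = 6L, cutoff = 0.08, application = "zero_phase") {
  application <- match.arg(application)
  if (order < 1L) stop("filter order must be >= 1", call. = FALSE)
  if (!is.finite(cutoff) || cutoff <= 0)
    stop("cutoff must be a positive frequency in cycles/nm", call. = FALSE)
  structure(list(order = as.integer(order), cutoff = cutoff,
                 application = application),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> Butterworth order %d, cutoff %.3g cycles/nm, %s\n",
              x$order, x$cutoff, x$application))
  invisible(x)
}

# Steady-state direct-form-II-transposed state for a unit-step input;
# scaling by the first sample suppresses the start-up transient that zero
# initial conditions would inject (the poles of a 6th-order Butterworth
# decay slowly enough to reach past any reasonable padding otherwise).
iir_zi <- function(b, a) {
  n <- length(a)
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1L, n - 1L)
  comp[1L, ] <- -a[-1]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1L) - t(comp), B)
}

# One pass of an IIR filter over every column of X simultaneously
# (direct form II transposed, vectorised across pixels), with the state
# initialised to steady state for each column's first sample.
iir_filter_mat <- function(b, a, X, zi = NULL) {
  n <- length(a)
  Y <- matrix(0, nrow(X), ncol(X))
  z <- if (is.null(zi)) matrix(0, n - 1L, ncol(X)) else zi %o% X[1L, ]
  for (t in seq_len(nrow(X))) {
    xt <- X[t, ]
    yt <- b[1] * xt + z[1L, ]
    if (n > 2L)
      for (k in seq_len(n - 2L))
        z[k, ] <- b[k + 1L] * xt - a[k + 1L] * yt + z[k + 1L, ]
    z[n - 1L, ] <- b[n] * xt - a[n] * yt
    Y[t, ] <- yt
  }
  Y
}

# Zero-phase (forward-backward) application with odd-reflection padding.
# The per-column mean is removed before filtering and restored afterwards,
# which makes the DC response exactly 1 regardless of edge transients.
zero_phase_filter_mat <- function(b, a, X, pad = NULL) {
  N <- nrow(X)
  if (is.null(pad)) pad <- min(N - 1L, 10L * (length(a) - 1L))
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  top <- 2 * Xc[rep(1L, pad), , drop = FALSE] - Xc[pad + 1L - seq_len(pad) + 1L, , drop = FALSE]
  bot <- 2 * Xc[rep(N, pad), , drop = FALSE] - Xc[N - seq_len(pad), , drop = FALSE]
  Xp <- rbind(top, Xc, bot)
  zi <- iir_zi(b, a)
  Y <- iir_filter_mat(b, a, Xp, zi)
  Y <- iir_filter_mat(b, a, Y[rev(seq_len(nrow(Y))), , drop = FALSE], zi)
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  sweep(Y[pad + seq_len(N), , drop = FALSE], 2L, mu, `+`)
}

butter_coeffs <- function(spec, dlambda_nm) {
  nyquist <- 1 / (2 * dlambda_nm)
  if (spec$cutoff >= nyquist)
    stop(sprintf("filter cutoff %.3g cycles/nm is at or above the Nyquist frequency %.3g of this wavelength grid",
                 spec$cutoff, nyquist), call. = FALSE)
  bf <- signal::butter(spec$order, spec$cutoff / nyquist, type = "low")
  list(b = bf$b, a = bf$a)
}

# Cube values as an (n_lambda x n_pixels) matrix and back.
cube_as_spectra <- function(cube) {
  d <- dim(cube$values)
  t(matrix(cube$values, d[1] * d[2], d[3]))
}
spectra_as_cube <- function(S, cube) {
  d <- dim(cube$values)
  cube$values <- array(t(S), d)
  cube
}

#' Low-pass denoise every pixel spectrum of a cube
#'
#' Applies the Butterworth low-pass of `spec` along the wavelength axis of
#' every pixel, zero-phase. The constant (DC) component of each spectrum is
#' preserved exactly. Requires a uniform wavelength grid; resample the cube
#' first if the grid is irregular.
#'
#' @param cube A [spectral_cube()].
#' @param spec A [filter_spec()].
#' @return The denoised [spectral_cube()]. The filter is linear, so small
#'   negative undershoot can appear next to sharp noise spikes; it is left
#'   in place (clipping would break the linearity that the downstream
#'   Sigma statistic relies on) and is irrelevant after baseline removal.
#' @export
denoise_cube <- function(cube, spec = filter_spec()) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(spec, "filter_spec"))
  if (!axis_is_uniform(cube$axis))
    stop("wavelength grid is non-uniform beyond 1% relative; resample the cube onto a uniform grid before denoising",
         call. = FALSE)
  co <- butter_coeffs(spec, mean(diff(cube$axis$wavelengths_nm)))
  S <- zero_phase_filter_mat(co$b, co$a, cube_as_spectra(cube))
  out <- spectra_as_cube(S, cube)
  out$metadata$denoise <- unclass(spec)
  out
}

#' Remove a per-pixel polynomial baseline in wavelength
#'
#' Subtracts, independently at every pixel, the least-squares polynomial of
#' the given order in lambda. This isolates the oscillatory interference
#' component whose standard deviation over wavelength is the Sigma
#' statistic; order 0 removes the mean, order 1 additionally removes a
#' linear lamp/stray-light drift.
#'
#' @param cube A [spectral_cube()].
#' @param poly_order Non-negative integer, less than `n_lambda - 1`.
#' @return A cube of baseline residuals (class `"spectral_cube"` with
#'   `value_kind = "residual"`; residuals may be negative).
#' @export
remove_baseline <- function(cube, poly_order = 1L) {
  stopifnot(inherits(cube, "spectral_cube"))
  nl <- length(cube$axis$wavelengths_nm)
  if (poly_order < 0L || poly_order >= nl - 1L)
    stop("poly_order must be in [0, n_lambda - 2]", call. = FALSE)
  S <- cube_as_spectra(cube)
  if (poly_order == 0L) {
    R <- sweep(S, 2L, colMeans(S))
  } else {
    X <- cbind(1, stats::poly(cube$axis$wavelengths_nm, poly_order))
    R <- qr.resid(qr(X), S)
  }
  d <- dim(cube$values)
  out <- cube
  out$values <- array(t(R), d)
  out$metadata$value_kind <- "residual"
  out$metadata$baseline_order <- as.integer(poly_order)
  # residuals are signed; bypass the non-negativity invariant deliberately
  out
}

#' Per-pixel spectral standard deviation map
#'
#' The central statistic of PWS analysis: at each pixel, the sample SD over
#' wavelength of the denoised, baseline-subtracted spectrum,
#' \eqn{\Sigma(x, y)}. Its square, the spectral variance \eqn{\Sigma^2},
#' quantifies refractive-index fluctuations at sub-diffractional length
#' scales. Optionally an additive noise variance floor is subtracted from
#' \eqn{\Sigma^2} (clamped at zero) before taking the square root.
#'
#' @param cube A [spectral_cube()].
#' @param filter A [filter_spec()], or `NULL` to skip denoising.
#' @param poly_order Baseline polynomial order passed to
#'   [remove_baseline()].
#' @param noise_floor Optional noise variance (same units as cube
#'   values, squared) subtracted from Sigma^2. The floor should be the
#'   noise variance that survives the denoising passband.
#' @return An object of class `"sigma_map"`: list with `values` (2D
#'   matrix, >= 0) and `provenance` (filter/baseline settings).
#' @export
compute_sigma_map <- function(cube, filter = filter_spec(), poly_order = 1L,
                              noise_floor = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (length(cube$axis$wavelengths_nm) < 8L)
    stop("axis shorter than 8 samples: spectral variance unreliable",
         call. = FALSE)
  work <- if (is.null(filter)) cube else denoise_cube(cube, filter)
  resid <- remove_baseline(work, poly_order)
  S <- cube_as_spectra(resid)
  v <- colSums(S^2) / (nrow(S) - 1L)  # baseline removal already centred S
  if (!is.null(noise_floor)) v <- pmax(v - noise_floor, 0)
  d <- dim(cube$values)
  structure(list(values = matrix(sqrt(v), d[1], d[2]),
                 provenance = list(
                   filter = if (is.null(filter)) NULL else unclass(filter),
                   poly_order = as.integer(poly_order),
                   noise_floor = noise_floor)),
            class = "sigma_map")
}

#' @export
print.sigma_map <- function(x, ...) {
  cat(sprintf("<sigma_map> %d x %d px, Sigma in [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Convert a Sigma map into a disorder-strength map
#'
#' The disorder strength \eqn{L_d} measures the product of the amplitude
#' and the correlation length of nanoscale density fluctuations,
#' \eqn{L_d \propto \sigma_p l_c}, obtained from \eqn{\Sigma} by
#' normalising out the cell thickness at each pixel. Two conventions are
#' provided:
#' \describe{
#'   \item{`"variance"` (default)}{\eqn{L_d = c\,\Sigma^2 / (\bar{k}^2 L)},
#'     with \eqn{\bar{k}} the centre wavenumber (1/nm) and \eqn{L} in nm.
#'     Dimensionally consistent with the weak-scattering (Born) regime of
#'     the 1D simulator, where ensemble \eqn{\Sigma^2 \propto
#'     \sigma_n^2 l_c L \bar{k}^2}; L_d then carries units of nm (it
#'     estimates \eqn{\sigma_n^2 l_c} up to calibration).}
#'   \item{`"linear"`}{\eqn{L_d = c\,\Sigma / L}, the literal reading of
#'     "Sigma proportional to sigma_p l_c L".}
#' }
#' With the default calibration constant of 1, L_d is in arbitrary units;
#' all cohort statistics downstream are scale-invariant, so arbitrary
#' units suffice. [calibrate_ld()] estimates a physical constant against
#' the simulator.
#'
#' @param sigma A [sigma_map()][compute_sigma_map].
#' @param thickness Cell thickness: positive scalar (micrometres) or a 2D
#'   matrix matching the map shape.
#' @param axis The [spectral_axis()] the cube was acquired on (supplies
#'   the centre wavenumber).
#' @param convention `"variance"` or `"linear"`.
#' @param calibration Multiplicative calibration constant, default 1.
#' @return An object of class `"ld_map"`: `values` (2D), `convention`,
#'   `calibration_constant`, `provenance`.
#' @export
sigma_to_ld <- function(sigma, thickness, axis,
                        convention = c("variance", "linear"),
                        calibration = 1) {
  stopifnot(inherits(sigma, "sigma_map"), inherits(axis, "spectral_axis"))
  convention <- match.arg(convention)
  v <- sigma$values
  if (is.matrix(thickness)) {
    if (!all(dim(thickness) == dim(v)))
      stop("thickness map shape ", paste(dim(thickness), collapse = "x"),
           " does not match sigma map ", paste(dim(v), collapse = "x"),
           call. = FALSE)
    L <- thickness
  } else {
    L <- matrix(thickness, nrow(v), ncol(v))
  }
  nbad <- sum(!(L > 0))
  if (nbad > 0)
    stop(nbad, " pixel(s) have zero or negative thickness", call. = FALSE)
  L_nm <- L * 1000
  kbar <- axis$center_wavenumber
  ld <- switch(convention,
               variance = calibration * v^2 / (kbar^2 * L_nm),
               linear   = calibration * v / L_nm)
  structure(list(values = ld, convention = convention,
                 calibration_constant = calibration,
                 provenance = sigma$provenance),
            class = "ld_map")
}

#' @export
print.ld_map <- function(x, ...) {
  cat(sprintf("<ld_map> %d x %d px, convention '%s', calibration %.4g, L_d in [%.3g, %.3g]\n",
              nrow(x$values), ncol(x$values), x$convention,
              x$calibration_constant, min(x$values), max(x$values)))
  invisible(x)
}

#' Mean disorder strength over a pixel selection
#'
#' @param ld An [ld_map][sigma_to_ld] (or `sigma_map`).
#' @param mask Logical matrix selecting pixels, or `NULL` for all pixels.
#' @return Arithmetic mean of `L_d` over the selected pixels.
#' @export
mean_ld <- function(ld, mask = NULL) {
  v <- if (is.list(ld)) ld$values else ld
  if (is.null(mask)) return(mean(v))
  if (!is.logical(mask) || !all(dim(mask) == dim(v)))
    stop("mask must be a logical matrix matching the map shape", call. = FALSE)
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  mean(v[mask])
}

#' Write / read a 2D analysis map as 32-bit TIFF + JSON sidecar
#'
#' Persists a [sigma_map][compute_sigma_map] or [ld_map][sigma_to_ld] as a
#' single-page 32-bit TIFF (fixed-point grid of step `scale / 2^32`, as in
#' [write_cube()]); the sidecar records the power-of-two storage scale,
#' the map kind, and the full provenance (filter, baseline, convention,
#' calibration).
#'
#' @param map A `sigma_map` or `ld_map`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  kind <- if (inherits(map, "ld_map")) "ld_map" else "sigma_map"
  scale <- tiff_scale(map$values)
  tiff::writeTIFF(map$values / scale * TIFF_QCOMP, path,
                  bits.per.sample = 32L, compression = "none")
  side <- list(format = "pwsld-map-v1", kind = kind, scale = scale,
               provenance = map$provenance)
  if (kind == "ld_map") {
    side$convention <- map$convention
    side$calibration_constant <- map$calibration_constant
  }
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  img <- tiff::readTIFF(path)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop(structure(class = c("pwsld_missing_sidecar", "error", "condition"),
                   list(message = paste0("missing sidecar metadata: ", sp),
                        call = NULL)))
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  values <- img * side$scale
  prov <- if (is.null(side$provenance)) list() else as.list(side$provenance)
  if (identical(side$kind, "ld_map"))
    structure(list(values = values, convention = side$convention,
                   calibration_constant = side$calibration_constant,
                   provenance = prov), class = "ld_map")
  else
    structure(list(values = values, provenance = prov), class = "sigma_map")
}
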