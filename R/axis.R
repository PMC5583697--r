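#' Spectral axis of a wavelength-resolved acquisition
#'
#' Constructs the wavelength axis attached to a [spectral_cube()]. The axis
#' carries the acquisition wavelengths in nanometres and the derived centre
#' wavenumber \eqn{\bar{k} = 2\pi/\bar{\lambda}} (in 1/nm), which the
#' variance convention of [sigma_to_ld()] uses for thickness normalisation.
#'
#' @param wavelengths_nm Numeric vector of wavelengths in nm. Must be
#'   strictly increasing, finite, and of length at least 8 (shorter axes
#'   make the per-pixel spectral variance meaningless).
#' @return An object of class `"spectral_axis"`: a list with elements
#'   `wavelengths_nm` and `center_wavenumber` (1/nm).
#' @examples
#' ax <- spectral_axis(seq(500, 699, by = 1))
#' ax$center_wavenumber   # 2*pi / 599.5
#' @seealso [default_axis()], [validate_axis()]
#' @export
spectral_axis <- function(wavelengths_nm) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (length(wavelengths_nm) < 8L)
    stop("spectral axis needs at least 8 wavelengths, got ",
         length(wavelengths_nm), call. = FALSE)
  if (any(!is.finite(wavelengths_nm)))
    stop("spectral axis contains non-finite wavelengths", call. = FALSE)
  d <- diff(wavelengths_nm)
  if (any(d <= 0))
    stop("spectral axis must be strictly increasing", call. = FALSE)
  structure(
    list(wavelengths_nm = wavelengths_nm,
         center_wavenumber = 2 * pi / mean(wavelengths_nm)),
    class = "spectral_axis")
}

#' Default PWS acquisition axis: 200 wavelengths, 500-699 nm, 1 nm spacing
#'
#' The canonical visible-band acquisition grid of a PWS microscope: 200
#' images at 1 nm spaced wavelengths. (200 points at 1 nm spacing span
#' 199 nm; the grid is taken as 500-699 nm inclusive.)
#'
#' @return A [spectral_axis()] of length 200.
#' @export
default_axis <- function() spectral_axis(seq(500, 699, by = 1))

#' @export
print.spectral_axis <- function(x, ...) {
  w <- x$wavelengths_nm
  cat(sprintf("<spectral_axis> %d wavelengths, %.1f-%.1f nm, k-bar = %.5f 1/nm\n",
              length(w), w[1], w[length(w)], x$center_wavenumber))
  invisible(x)
}

#' Advisory checks on a spectral axis
#'
#' Flags (but never rejects) axes that depart from the standard PWS
#' acquisition: wavelengths outside the 500-700 nm band, or spacing that is
#' non-uniform by more than 1% relative. Both conditions are tolerated by
#' the readers; non-uniform spacing beyond tolerance is only rejected later
#' by [denoise_cube()], which requires a uniform grid.
#'
#' @param axis A [spectral_axis()].
#' @param range_nm Advisory band, default `c(500, 700)`.
#' @param spacing_rtol Relative non-uniformity that triggers a warning
#'   string, default 0.01.
#' @return Character vector of warning messages (length 0 when clean).
#' @export
validate_axis <- function(axis, range_nm = c(500, 700), spacing_rtol = 0.01) {
  stopifnot(inherits(axis, "spectral_axis"))
  w <- axis$wavelengths_nm
  msgs <- character(0)
  if (w[1] < range_nm[1] || w[length(w)] > range_nm[2])
    msgs <- c(msgs, sprintf(
      "axis %.1f-%.1f nm falls outside the standard %g-%g nm acquisition band",
      w[1], w[length(w)], range_nm[1], range_nm[2]))
  d <- diff(w)
  if ((max(d) - min(d)) / mean(d) > spacing_rtol)
    msgs <- c(msgs, sprintf(
      "axis spacing is non-uniform beyond %.1f%% relative (min %.4g, max %.4g nm)",
      100 * spacing_rtol, min(d), max(d)))
  msgs
}

# TRUE when the grid is uniform within rtol; used by the denoiser.
axis_is_uniform <- function(axis, rtol = 0.01) {
  d <- diff(axis$wavelengths_nm)
  (max(d) - min(d)) / mean(d) <= rtol
}

#' Instrument geometry metadata
#'
#' Records the optical geometry of the acquiring microscope: a small
#' illumination numerical aperture (near-plane-wave illumination), a
#' moderate collection aperture, and the objective magnification. These are
#' metadata only -- the analysis itself is geometry-agnostic -- but they are
#' persisted in the cube sidecar so every map is traceable to its optics.
#'
#' @param na_illumination Illumination NA; default 0.15.
#' @param na_collection Collection NA; default 0.6.
#' @param magnification Objective magnification; default 40.
#' @return An object of class `"instrument_model"`.
#' @export
instrument_model <- function(na_illumination = 0.15, na_collection = 0.6,
                             magnification = 40) {
  if (!(na_illumination > 0 && na_illumination <= na_collection &&
        na_collection < 1.5))
    stop("require 0 < na_illumination <= na_collection < 1.5", call. = FALSE)
  if (magnification <= 0) stop("magnification must be positive", call. = FALSE)
  structure(list(na_illumination = na_illumination,
                 na_collection = na_collection,
                 magnification = magnification),
            class = "instrument_model")
}

#' @export
print.instrument_model <- function(x, ...) {
  cat(sprintf("<instrument_model> NAi = %.3g, NAc = %.3g, %gx\n",
              x$na_illumination, x$na_collection, x$magnification))
  invisible(x)
}
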