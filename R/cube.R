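#' Wavelength-resolved image cube
#'
#' The raw object of a PWS measurement: a stack of bright-field images
#' acquired at successive narrow-band wavelengths and combined into a 3D
#' \eqn{R(x, y, \lambda)} data cube. Values may be lamp-normalised
#' reflectance or raw detector counts; which one is recorded in
#' `metadata$value_kind` and carried through to the sidecar.
#'
#' Spatial coordinates are (row, column) with the origin at the top left;
#' the third array index runs over the wavelength axis in the same order as
#' `axis$wavelengths_nm`.
#'
#' @param values 3D numeric array `[row, col, lambda]`; non-negative and
#'   finite, third extent equal to `length(axis$wavelengths_nm)`.
#' @param axis A [spectral_axis()].
#' @param pixel_size_um Physical size of one pixel, micrometres.
#' @param metadata Named list of free-form metadata. May contain an
#'   [instrument_model()] under `instrument` and a `value_kind` string
#'   (`"reflectance"` or `"counts"`; default `"reflectance"`).
#' @return An object of class `"spectral_cube"`.
#' @export
spectral_cube <- function(values, axis, pixel_size_um = 1, metadata = list()) {
  stopifnot(inherits(axis, "spectral_axis"))
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("cube values must be a 3D [row, col, lambda] array", call. = FALSE)
  if (dim(values)[1] < 1L || dim(values)[2] < 1L)
    stop("cube has degenerate spatial extent ", dim(values)[1], "x",
         dim(values)[2], call. = FALSE)
  nl <- length(axis$wavelengths_nm)
  if (dim(values)[3] != nl)
    stop("cube has ", dim(values)[3], " wavelength pages but the axis lists ",
         nl, " wavelengths", call. = FALSE)
  if (any(!is.finite(values)))
    stop("cube values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("cube values must be non-negative", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("pixel_size_um must be a positive scalar", call. = FALSE)
  if (is.null(metadata$value_kind)) metadata$value_kind <- "reflectance"
  structure(list(values = values, axis = axis,
                 pixel_size_um = pixel_size_um, metadata = metadata),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  w <- x$axis$wavelengths_nm
  cat(sprintf("<spectral_cube> %d x %d px (%.3g um/px), %d wavelengths %.1f-%.1f nm [%s]\n",
              d[1], d[2], x$pixel_size_um, d[3], w[1], w[length(w)],
              x$metadata$value_kind))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$values)

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

# The tiff package stores 32-bit integer samples mapped onto [0, 1]: a
# write quantises x to ~round(x * (2^32 - 1)) (with occasional one-step
# rounding slack from its internal arithmetic) while a read returns
# k / 2^32. Values are divided by a power-of-two scale (exact in binary
# floating point) and pre-multiplied by 2^32/(2^32 - 1) so the stored
# integer is k ~ round(x * 2^32); total quantisation error is bounded by
# scale * 2^-31.
TIFF_QCOMP <- 4294967296 / 4294967295

tiff_scale <- function(values) {
  mx <- max(values, 0)
  if (mx == 0) return(1)
  2^max(0, ceiling(log2(mx * TIFF_QCOMP)))
}

#' Write a spectral cube as a multi-page TIFF with a JSON sidecar
#'
#' Pages are wavelengths, in axis order, stored as 32-bit integer samples
#' on a fixed-point grid of step `scale / 2^32`, where `scale` is a power
#' of two (recorded in the sidecar) chosen so all values fit the TIFF
#' sample range. A write-read roundtrip reproduces every value to within
#' `scale * 2^-31` (about 0.5 part per billion of full scale); values are
#' not bit-identical for arbitrary doubles because the available TIFF
#' codec has no floating-point sample format. The sidecar
#' (`<path-without-ext>.json`) fully reconstructs the wavelength axis,
#' the pixel size, the metadata and any instrument model.
#'
#' @param cube A [spectral_cube()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @seealso [read_cube()]
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  scale <- tiff_scale(cube$values)
  nl <- dim(cube$values)[3]
  pages <- lapply(seq_len(nl),
                  function(k) cube$values[, , k] / scale * TIFF_QCOMP)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  meta <- cube$metadata
  inst <- meta$instrument
  meta$instrument <- NULL
  side <- list(format = "pwsld-cube-v1",
               wavelengths_nm = cube$axis$wavelengths_nm,
               pixel_size_um = cube$pixel_size_um,
               scale = scale,
               metadata = meta)
  if (!is.null(inst)) side$instrument <- unclass(inst)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a spectral cube written by [write_cube()]
#'
#' @param path TIFF path (the sidecar is looked up next to it).
#' @param format Container format; only `"tiff_stack"` is supported.
#' @return A [spectral_cube()].
#' @section Errors: a missing sidecar raises condition class
#'   `pwsld_missing_sidecar`; unreadable image data raises
#'   `pwsld_corrupt_data`; a page count that disagrees with the sidecar
#'   axis raises an error naming both counts.
#' @export
read_cube <- function(path, format = "tiff_stack") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such cube file: ", path, call. = FALSE)
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    stop(structure(class = c("pwsld_missing_sidecar", "error", "condition"),
                   list(message = paste0("missing sidecar metadata: ", sp),
                        call = NULL)))
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = FALSE),
                    error = function(e)
    stop(structure(class = c("pwsld_corrupt_data", "error", "condition"),
                   list(message = paste0("cannot decode image data in ", path,
                                         ": ", conditionMessage(e)),
                        call = NULL))))
  if (!is.list(pages)) pages <- list(pages)
  wl <- as.numeric(side$wavelengths_nm)
  if (length(pages) != length(wl))
    stop("cube has ", length(pages), " TIFF pages but the sidecar lists ",
         length(wl), " wavelengths", call. = FALSE)
  scale <- if (is.null(side$scale)) 1 else side$scale
  values <- array(0, c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) values[, , k] <- pages[[k]] * scale
  meta <- if (is.null(side$metadata)) list() else as.list(side$metadata)
  if (!is.null(side$instrument))
    meta$instrument <- do.call(instrument_model, as.list(side$instrument))
  spectral_cube(values, spectral_axis(wl),
                pixel_size_um = side$pixel_size_um, metadata = meta)
}

#' Write / read an integer label mask as 16-bit TIFF
#'
#' Labels 0..K (0 = background) are stored losslessly for K < 65536; the
#' pixel size travels in a JSON sidecar.
#'
#' @param mask A [label_mask()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  mx <- max(mask$labels)
  if (mx > 65535L) stop("more than 65535 labels", call. = FALSE)
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  jsonlite::write_json(list(format = "pwsld-mask-v1",
                            pixel_size_um = mask$pixel_size_um),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- tiff::readTIFF(path)
  sp <- sidecar_path(path)
  ps <- if (file.exists(sp))
    jsonlite::read_json(sp, simplifyVector = TRUE)$pixel_size_um else 1
  label_mask(matrix(as.integer(round(img * 65535)), nrow(img), ncol(img)),
             pixel_size_um = ps)
}
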