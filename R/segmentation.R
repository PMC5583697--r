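#' Integer label mask of segmented nuclei
#'
#' @param labels 2D integer matrix; 0 = background, 1..K = nuclei.
#' @param pixel_size_um Pixel size, micrometres.
#' @return An object of class `"label_mask"`.
#' @export
label_mask <- function(labels, pixel_size_um = 1) {
  labels <- as.matrix(labels)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers", call. = FALSE)
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, pixel_size_um = pixel_size_um),
            class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("<label_mask> %d x %d px (%.3g um/px), %d region(s)\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Segmentation parameters
#'
#' Defaults target isolated epithelial (e.g. buccal) cells imaged in
#' transmission: nuclei appear dark, occupy roughly 20-500 um^2, and
#' touching nuclei are split by a watershed seeded at distance-transform
#' maxima at least `watershed_seed_min_distance_px` apart.
#'
#' @param histogram_bins Histogram bins for the maximum-entropy threshold.
#' @param min_area_um2,max_area_um2 Area gate for accepted nuclei.
#' @param polarity `"dark_nuclei"` (transmission default) or
#'   `"bright_nuclei"`.
#' @param watershed_seed_min_distance_px Minimum seed separation, pixels.
#' @return An object of class `"segmentation_params"`.
#' @export
segmentation_params <- function(histogram_bins = 256L, min_area_um2 = 20,
                                max_area_um2 = 500,
                                polarity = c("dark_nuclei", "bright_nuclei"),
                                watershed_seed_min_distance_px = 5L) {
  polarity <- match.arg(polarity)
  if (histogram_bins < 8L) stop("need at least 8 histogram bins", call. = FALSE)
  if (!(min_area_um2 > 0 && min_area_um2 < max_area_um2))
    stop("require 0 < min_area_um2 < max_area_um2", call. = FALSE)
  structure(list(histogram_bins = as.integer(histogram_bins),
                 min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
                 polarity = polarity,
                 watershed_seed_min_distance_px =
                   as.integer(watershed_seed_min_distance_px)),
            class = "segmentation_params")
}

#' Maximum-entropy (Kapur) threshold
#'
#' Bins the image into a `bins`-bin histogram over its value range and
#' returns the bin edge that maximises the Kapur criterion: the sum of the
#' Shannon entropies of the normalised background (values <= threshold)
#' and foreground (values > threshold) histograms. Candidate thresholds
#' are all interior bin boundaries with non-empty mass on both sides; ties
#' are broken towards the lowest qualifying threshold.
#'
#' @param image 2D numeric matrix (finite values).
#' @param bins Number of histogram bins, default 256.
#' @return The threshold value (a bin edge on the image's value scale).
#' @export
max_entropy_threshold <- function(image, bins = 256L) {
  v <- as.vector(image)
  if (any(!is.finite(v))) stop("image must be finite", call. = FALSE)
  lo <- min(v); hi <- max(v)
  if (lo == hi)
    stop("constant image: no threshold separates foreground from background",
         call. = FALSE)
  edges <- seq(lo, hi, length.out = bins + 1L)
  h <- tabulate(pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                     bins), nbins = bins)
  p <- h / sum(h)
  cp <- cumsum(p)                      # background mass up to bin t
  cplogp <- cumsum(ifelse(p > 0, p * log(p), 0))
  tot_plogp <- cplogp[bins]
  crit <- rep(-Inf, bins - 1L)
  for (t in seq_len(bins - 1L)) {
    w0 <- cp[t]; w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    h0 <- log(w0) - cplogp[t] / w0
    h1 <- log(w1) - (tot_plogp - cplogp[t]) / w1
    crit[t] <- h0 + h1
  }
  if (!any(is.finite(crit)))
    stop("degenerate histogram: no admissible threshold", call. = FALSE)
  edges[which.max(crit) + 1L]          # lowest maximiser (which.max = first)
}

# Local maxima of the distance transform separated by >= min_dist, via
# grayscale dilation with a disc of diameter ~ min_dist.
distance_seeds <- function(dist, min_dist) {
  r <- max(1L, as.integer(min_dist))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  dil <- EBImage::dilate(dist, brush)
  seeds <- dist > 0 & dist >= dil - 1e-9
  EBImage::bwlabel(seeds)
}

#' Split a binary mask into labelled regions by watershed
#'
#' Computes the Euclidean distance transform of the foreground, finds its
#' local maxima (seeds) with the requested minimum separation, and floods
#' the negated distance transform from those seeds so that merged blobs of
#' touching convex objects are split along their waist. Disjoint components
#' that contain a single seed come out as single labels, so the operation
#' reduces to connected-component labelling for well-separated objects.
#'
#' @param binary 2D logical (or 0/1) matrix; must contain foreground.
#' @param min_seed_distance_px Minimum separation between watershed seeds.
#' @param pixel_size_um Pixel size recorded on the output mask.
#' @return A [label_mask()] in which every foreground pixel carries
#'   exactly one label.
#' @export
watershed_split <- function(binary, min_seed_distance_px = 5L,
                            pixel_size_um = 1) {
  b <- matrix(as.numeric(binary > 0), nrow(binary), ncol(binary))
  if (!any(b > 0)) stop("binary mask is empty", call. = FALSE)
  dist <- EBImage::distmap(b)
  seeds <- distance_seeds(dist, min_seed_distance_px)
  lab <- EBImage::propagate(dist, seeds, mask = b > 0)
  lab <- matrix(as.integer(round(lab)), nrow(b), ncol(b))
  label_mask(renumber_raster(lab), pixel_size_um = pixel_size_um)
}

# Renumber labels 1..K in raster order of their centroids (row-major).
renumber_raster <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  if (length(ids) == 0L) return(lab)
  cent <- t(vapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    colMeans(w)
  }, numeric(2)))
  ord <- order(cent[, 1], cent[, 2])
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (k in seq_along(ord)) out[lab == ids[ord[k]]] <- k
  out
}

#' Segment nuclei in a transmission image
#'
#' The nuclear detection pipeline for isolated cells: polarity
#' normalisation, maximum-entropy thresholding, morphological cleanup
#' (hole filling and a 1-pixel opening, which suppresses threshold
#' speckle), watershed splitting of touching nuclei, and an area gate.
#' Surviving regions are renumbered 1..K in raster order of their
#' centroids.
#'
#' @param transmission 2D numeric matrix (bright-field transmission
#'   image).
#' @param params A [segmentation_params()].
#' @param pixel_size_um Pixel size, micrometres.
#' @return A [label_mask()]. When no region survives, an empty mask is
#'   returned with a warning (a blank field of view is data, not an
#'   error).
#' @export
segment_nuclei <- function(transmission, params = segmentation_params(),
                           pixel_size_um = 1) {
  stopifnot(inherits(params, "segmentation_params"))
  img <- as.matrix(transmission)
  thr <- max_entropy_threshold(img, params$histogram_bins)
  fg <- if (params$polarity == "dark_nuclei") img < thr else img > thr
  if (!any(fg)) {
    warning("no foreground after thresholding; returning empty mask")
    return(label_mask(matrix(0L, nrow(img), ncol(img)), pixel_size_um))
  }
  b <- EBImage::fillHull(matrix(as.numeric(fg), nrow(img), ncol(img)))
  b <- EBImage::opening(b, EBImage::makeBrush(3L, shape = "box"))
  if (!any(b > 0)) {
    warning("no foreground after morphological cleanup; returning empty mask")
    return(label_mask(matrix(0L, nrow(img), ncol(img)), pixel_size_um))
  }
  mask <- watershed_split(b, params$watershed_seed_min_distance_px,
                          pixel_size_um)
  lab <- mask$labels
  px_area <- pixel_size_um^2
  keep <- integer(0)
  for (id in setdiff(sort(unique(as.vector(lab))), 0L)) {
    a <- sum(lab == id) * px_area
    if (a >= params$min_area_um2 && a <= params$max_area_um2)
      keep <- c(keep, id)
  }
  lab[!(lab %in% keep)] <- 0L
  if (length(keep) == 0L)
    warning("no region passed the area gate [", params$min_area_um2, ", ",
            params$max_area_um2, "] um^2; returning empty mask")
  label_mask(renumber_raster(lab), pixel_size_um)
}

#' Per-nucleus disorder-strength statistics
#'
#' Reduces an L_d map over a label mask: one row per nucleus with its
#' geometry and mean nuclear L_d. When `annulus_width_px` is given, a
#' "cellular" mean is also computed over the nucleus plus a perinuclear
#' annulus of that width (the dilation of the nucleus, minus pixels
#' belonging to other nuclei).
#'
#' @param ld An [ld_map][sigma_to_ld] (or any object with a 2D `values`
#'   matrix).
#' @param mask A [label_mask()] of matching shape.
#' @param annulus_width_px Optional perinuclear annulus width in pixels.
#' @return A data frame with columns `label`, `area_px`, `area_um2`,
#'   `centroid_row`, `centroid_col`, `mean_ld`, `pixel_count_used`, and
#'   (when requested) `mean_cellular_ld`.
#' @export
region_ld_stats <- function(ld, mask, annulus_width_px = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  v <- if (is.list(ld)) ld$values else ld
  lab <- mask$labels
  if (!all(dim(v) == dim(lab)))
    stop("L_d map shape ", paste(dim(v), collapse = "x"),
         " does not match mask shape ", paste(dim(lab), collapse = "x"),
         call. = FALSE)
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  px_area <- mask$pixel_size_um^2
  rows <- lapply(ids, function(id) {
    w <- which(lab == id, arr.ind = TRUE)
    cent <- colMeans(w)
    vals <- v[lab == id]
    data.frame(label = id, area_px = nrow(w), area_um2 = nrow(w) * px_area,
               centroid_row = cent[1] - 1, centroid_col = cent[2] - 1,
               mean_ld = mean(vals), pixel_count_used = length(vals))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = integer(0), area_px = integer(0), area_um2 = numeric(0),
               centroid_row = numeric(0), centroid_col = numeric(0),
               mean_ld = numeric(0), pixel_count_used = integer(0))
  rownames(out) <- NULL
  if (!is.null(annulus_width_px) && nrow(out) > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(annulus_width_px) + 1L,
                                shape = "disc")
    out$mean_cellular_ld <- vapply(out$label, function(id) {
      own <- lab == id
      cell <- EBImage::dilate(matrix(as.numeric(own), nrow(lab), ncol(lab)),
                              brush) > 0
      cell[lab != 0 & !own] <- FALSE   # do not bleed into neighbouring nuclei
      mean(v[cell])
    }, numeric(1))
  }
  out
}
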