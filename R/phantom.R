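#' Specification of a 2D cell phantom
#'
#' A synthetic field of isolated cells standing in for a cytology
#' specimen: each nucleus is a disc whose pixels carry nucleus-class
#' disorder parameters, every other pixel carries cytoplasm-class
#' parameters, and a bright-field transmission rendering shows nuclei
#' dark against a bright background. Defaults emulate buccal-type nuclei
#' (radius 4 um on a 0.5 um pixel grid, i.e. ~50 um^2) with nuclear
#' disorder elevated over the cytoplasm.
#'
#' @param dim_px Image size `c(rows, cols)` in pixels.
#' @param pixel_size_um Pixel size, micrometres.
#' @param n_nuclei Number of nuclei.
#' @param nucleus_radius_um Nucleus disc radius, micrometres.
#' @param centers Optional `n_nuclei x 2` matrix of (row, col) centres
#'   (0-based); when `NULL`, centres are placed uniformly at random
#'   without overlap.
#' @param nucleus,cytoplasm Lists with `sigma_n`, `corr_len_nm`,
#'   `thickness_nm` for the two tissue classes.
#' @param noise_sd Additive white noise SD on the spectra.
#' @param trans_levels Transmission rendering levels, named `background`,
#'   `cytoplasm`, `nucleus` (nucleus must be darkest).
#' @param trans_noise_sd Noise SD on the transmission image.
#' @param cytoplasm_radius_factor Cytoplasm disc radius as a multiple of
#'   the nucleus radius (visual only; affects the transmission image).
#' @param max_overlap_fraction Fraction of nucleus pairs allowed to
#'   overlap before [make_phantom_cube()] errors; default 0.
#' @param seed RNG seed making the phantom fully deterministic.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(dim_px = c(160L, 160L), pixel_size_um = 0.5,
                         n_nuclei = 25L, nucleus_radius_um = 4,
                         centers = NULL,
                         nucleus = list(sigma_n = 0.04, corr_len_nm = 40,
                                        thickness_nm = 2000),
                         cytoplasm = list(sigma_n = 0.02, corr_len_nm = 40,
                                          thickness_nm = 2000),
                         noise_sd = 0,
                         trans_levels = c(background = 0.85,
                                          cytoplasm = 0.78, nucleus = 0.35),
                         trans_noise_sd = 0.02,
                         cytoplasm_radius_factor = 1.8,
                         max_overlap_fraction = 0, seed = 1L) {
  stopifnot(length(dim_px) == 2L, n_nuclei >= 1L, nucleus_radius_um > 0)
  r_px <- nucleus_radius_um / pixel_size_um
  if (2 * r_px + 2 > min(dim_px))
    stop("nuclei do not fit in the image", call. = FALSE)
  for (cls in list(nucleus, cytoplasm))
    stopifnot(cls$sigma_n >= 0, cls$corr_len_nm > 0, cls$thickness_nm > 0)
  if (trans_levels[["nucleus"]] >= trans_levels[["background"]])
    stop("transmission must render nuclei darker than background",
         call. = FALSE)
  structure(list(dim_px = as.integer(dim_px), pixel_size_um = pixel_size_um,
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radius_um = nucleus_radius_um, centers = centers,
                 nucleus = nucleus, cytoplasm = cytoplasm,
                 noise_sd = noise_sd, trans_levels = trans_levels,
                 trans_noise_sd = trans_noise_sd,
                 cytoplasm_radius_factor = cytoplasm_radius_factor,
                 max_overlap_fraction = max_overlap_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Random non-overlapping centres by rejection sampling.
place_centers <- function(n, dim_px, r_px, margin = 2) {
  centers <- matrix(NA_real_, n, 2)
  min_d2 <- (2 * r_px + 2 * margin)^2
  placed <- 0L
  for (try in seq_len(20000L)) {
    cand <- c(stats::runif(1, r_px + margin, dim_px[1] - 1 - r_px - margin),
              stats::runif(1, r_px + margin, dim_px[2] - 1 - r_px - margin))
    if (placed == 0L ||
        all((centers[seq_len(placed), 1] - cand[1])^2 +
            (centers[seq_len(placed), 2] - cand[2])^2 >= min_d2)) {
      placed <- placed + 1L
      centers[placed, ] <- cand
      if (placed == n) return(centers)
    }
  }
  stop("could not place ", n, " non-overlapping nuclei of radius ", r_px,
       " px in a ", dim_px[1], "x", dim_px[2], " image", call. = FALSE)
}

disc_mask <- function(dim_px, center, r_px) {
  rows <- matrix(0:(dim_px[1] - 1L), dim_px[1], dim_px[2])
  cols <- matrix(0:(dim_px[2] - 1L), dim_px[1], dim_px[2], byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= r_px^2
}

#' Generate a phantom cube with ground truth
#'
#' Builds the full synthetic measurement for a [phantom_spec()]: a
#' [spectral_cube()] in which every pixel's spectrum is an exact
#' transfer-matrix solution of an independent random medium drawn with
#' that pixel's class parameters, the ground-truth nucleus
#' [label_mask()], and a transmission image for segmentation.
#' Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @param axis A [spectral_axis()].
#' @return List with elements `cube`, `mask` (ground truth), and
#'   `transmission`.
#' @export
make_phantom_cube <- function(spec, axis) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(axis, "spectral_axis"))
  d <- spec$dim_px
  r_px <- spec$nucleus_radius_um / spec$pixel_size_um
  with_seed(spec$seed, {
    centers <- if (is.null(spec$centers))
      place_centers(spec$n_nuclei, d, r_px) else as.matrix(spec$centers)
    if (nrow(centers) != spec$n_nuclei)
      stop("centers must have one row per nucleus", call. = FALSE)
    # overlap check on supplied centres
    if (spec$n_nuclei > 1L) {
      dd <- as.matrix(stats::dist(centers))
      over <- sum(dd[upper.tri(dd)] < 2 * r_px)
      if (over > spec$max_overlap_fraction * sum(upper.tri(dd)))
        stop(over, " nucleus pair(s) overlap, above the allowed fraction ",
             spec$max_overlap_fraction, call. = FALSE)
    }
    lab <- matrix(0L, d[1], d[2])
    for (k in seq_len(spec$n_nuclei)) {
      m <- disc_mask(d, centers[k, ], r_px)
      lab[m] <- k
    }
    lab <- renumber_raster(lab)
    nuc_idx <- which(lab > 0)
    cyt_idx <- which(lab == 0L)
    nl <- length(axis$wavelengths_nm)
    spectra <- matrix(0, nl, d[1] * d[2])
    for (cls in c("nucleus", "cytoplasm")) {
      p <- spec[[cls]]
      idx <- if (cls == "nucleus") nuc_idx else cyt_idx
      if (length(idx) == 0L) next
      dz <- min(p$corr_len_nm / 4, 10)
      nz <- max(1L, round(p$thickness_nm / dz))
      # chunked so profile matrices stay modest
      for (ch in split(idx, ceiling(seq_along(idx) / 8192L))) {
        delta <- gaussian_profile_matrix(nz, length(ch), p$sigma_n,
                                         p$corr_len_nm, dz)
        spectra[, ch] <- tm_reflectance_batch(1.38 + delta, dz, axis,
                                              1.0, 1.38, 1.38)
      }
    }
    if (spec$noise_sd > 0)
      spectra <- pmax(spectra + matrix(stats::rnorm(length(spectra),
                                                    sd = spec$noise_sd),
                                       nrow(spectra), ncol(spectra)), 0)
    cube <- spectral_cube(array(t(spectra), c(d[1], d[2], nl)), axis,
                          pixel_size_um = spec$pixel_size_um,
                          metadata = list(source = "pwsld phantom",
                                          seed = spec$seed))
    trans <- matrix(spec$trans_levels[["background"]], d[1], d[2])
    r_cyt <- r_px * spec$cytoplasm_radius_factor
    for (k in seq_len(nrow(centers)))
      trans[disc_mask(d, centers[k, ], r_cyt)] <-
        spec$trans_levels[["cytoplasm"]]
    trans[lab > 0] <- spec$trans_levels[["nucleus"]]
    if (spec$trans_noise_sd > 0)
      trans <- trans + matrix(stats::rnorm(length(trans),
                                           sd = spec$trans_noise_sd),
                              d[1], d[2])
    list(cube = cube, mask = label_mask(lab, spec$pixel_size_um),
         transmission = trans)
  })
}

#' Generate a synthetic patient cohort
#'
#' Draws patient-level mean nuclear L_d values as Gaussians per diagnostic
#' group -- a lightweight fixture for the cohort-statistics layer. An
#' optional cellular compartment is generated as a linear response to the
#' nuclear value plus independent noise, for correlation studies.
#'
#' @param n_per_group Patients per group (recycled over groups).
#' @param group_means Named numeric vector: group label -> mean L_d.
#' @param group_sds Between-patient SD per group (recycled).
#' @param n_nuclei Nuclei per patient recorded in the summary.
#' @param cellular_slope When non-`NULL`, `mean_cellular_ld = slope *
#'   mean_nuclear_ld + N(0, cellular_noise_sd)`.
#' @param cellular_noise_sd Noise SD of the cellular compartment.
#' @param seed Optional RNG seed.
#' @return A [patient_summary()] data frame.
#' @export
make_cohort <- function(n_per_group = 20L,
                        group_means = c(control = 1, case = 2),
                        group_sds = 0.3, n_nuclei = 30L,
                        cellular_slope = NULL, cellular_noise_sd = 0,
                        seed = NULL) {
  stopifnot(length(group_means) >= 1L, all(group_sds > 0), n_per_group >= 2L)
  groups <- names(group_means)
  if (is.null(groups)) groups <- paste0("group", seq_along(group_means))
  n_per_group <- rep_len(n_per_group, length(group_means))
  group_sds <- rep_len(group_sds, length(group_means))
  with_seed(seed, {
    nuclear <- unlist(lapply(seq_along(group_means), function(g)
      stats::rnorm(n_per_group[g], group_means[g], group_sds[g])))
    cellular <- if (is.null(cellular_slope)) NA_real_ else
      cellular_slope * nuclear + stats::rnorm(length(nuclear),
                                              sd = cellular_noise_sd)
    patient_summary(
      patient_id = sprintf("P%03d", seq_along(nuclear)),
      group = rep(groups, n_per_group),
      mean_nuclear_ld = nuclear,
      mean_cellular_ld = cellular,
      n_nuclei = n_nuclei)
  })
}
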