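#' Pipeline configuration
#'
#' One serialisable object holding every tunable of the cube-to-report
#' pipeline. Validation is delegated to the component constructors, so an
#' invalid sub-setting fails here rather than mid-run.
#'
#' @param filter A [filter_spec()].
#' @param poly_order Baseline polynomial order.
#' @param convention L_d convention, `"variance"` or `"linear"`.
#' @param calibration Calibration constant (1 = arbitrary units).
#' @param thickness_um Scalar cell thickness used when no per-pixel
#'   thickness map is supplied.
#' @param noise_floor Optional noise variance floor (see
#'   [compute_sigma_map()]).
#' @param segmentation A [segmentation_params()].
#' @param annulus_width_px Perinuclear annulus width for the cellular
#'   mean, pixels.
#' @param test,sd_convention Cohort-comparison settings (see
#'   [compare_groups()]).
#' @param seed Seed recorded in run manifests.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(filter = filter_spec(), poly_order = 1L,
                            convention = c("variance", "linear"),
                            calibration = 1, thickness_um = 2,
                            noise_floor = NULL,
                            segmentation = segmentation_params(),
                            annulus_width_px = 10L,
                            test = c("welch_t", "mann_whitney"),
                            sd_convention = c("cumulative", "pooled_within"),
                            seed = NULL) {
  stopifnot(inherits(filter, "filter_spec"),
            inherits(segmentation, "segmentation_params"),
            thickness_um > 0, poly_order >= 0)
  structure(list(filter = filter, poly_order = as.integer(poly_order),
                 convention = match.arg(convention),
                 calibration = calibration, thickness_um = thickness_um,
                 noise_floor = noise_floor, segmentation = segmentation,
                 annulus_width_px = as.integer(annulus_width_px),
                 test = match.arg(test),
                 sd_convention = match.arg(sd_convention), seed = seed),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param config A [pipeline_config()].
#' @param path JSON file path.
#' @return `path` (write) or a [pipeline_config()] (read).
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$filter <- unclass(x$filter)
  x$segmentation <- unclass(x$segmentation)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    filter = do.call(filter_spec, as.list(x$filter)),
    poly_order = x$poly_order, convention = x$convention,
    calibration = x$calibration, thickness_um = x$thickness_um,
    noise_floor = x$noise_floor,
    segmentation = do.call(segmentation_params, as.list(x$segmentation)),
    annulus_width_px = x$annulus_width_px, test = x$test,
    sd_convention = x$sd_convention, seed = x$seed)
}

run_manifest <- function(out_dir, config, extra = list()) {
  m <- c(list(package = "pwsld",
              version = as.character(utils::packageVersion("pwsld")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              config = jsonlite::fromJSON(jsonlite::toJSON(
                {x <- unclass(config); x$filter <- unclass(x$filter)
                 x$segmentation <- unclass(x$segmentation); x},
                auto_unbox = TRUE, digits = NA, null = "null"))),
         extra)
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Run the cube-to-maps pipeline on one measurement
#'
#' Reads a cube, computes the Sigma and L_d maps with the configured
#' filter, baseline order, thickness and convention, and writes both maps
#' (float TIFF + sidecar) plus a reproducibility manifest to `out_dir`.
#'
#' @param cube_path Path to a cube written by [write_cube()].
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @param thickness Optional per-pixel thickness matrix (um) overriding
#'   the scalar `config$thickness_um`.
#' @return Invisibly, a list with the `sigma` and `ld` maps and the paths
#'   written.
#' @export
run_ld <- function(cube_path, config = pipeline_config(), out_dir,
                   thickness = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cube <- read_cube(cube_path)
  sigma <- compute_sigma_map(cube, filter = config$filter,
                             poly_order = config$poly_order,
                             noise_floor = config$noise_floor)
  if (is.null(thickness)) thickness <- config$thickness_um
  ld <- sigma_to_ld(sigma, thickness, cube$axis,
                    convention = config$convention,
                    calibration = config$calibration)
  base <- tools::file_path_sans_ext(basename(cube_path))
  sigma_path <- file.path(out_dir, paste0(base, "_sigma.tif"))
  ld_path <- file.path(out_dir, paste0(base, "_ld.tif"))
  write_map(sigma, sigma_path)
  write_map(ld, ld_path)
  run_manifest(out_dir, config, list(input = cube_path,
                                     outputs = c(sigma_path, ld_path)))
  invisible(list(sigma = sigma, ld = ld,
                 paths = c(sigma = sigma_path, ld = ld_path)))
}

#' Segment, summarise and compare a two-group cohort
#'
#' The full nanocytology workflow over many measurements: for every row
#' of `manifest` the cube is reduced to an L_d map, nuclei are segmented
#' from the transmission image (or, when none is given, from the
#' wavelength-averaged cube intensity), and per-nucleus statistics are
#' pooled into patient-level means. The two diagnostic groups are then
#' contrasted by effect size and significance test, and a per-patient
#' summary CSV plus a report CSV are written to `out_dir`.
#'
#' @param manifest Data frame with columns `patient_id`, `group`,
#'   `cube` (paths), and optionally `transmission` (paths to single-page
#'   TIFF images).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the `summaries` data frame, the
#'   `comparison`, and the paths written.
#' @export
run_segment_compare <- function(manifest, config = pipeline_config(),
                                out_dir) {
  stopifnot(is.data.frame(manifest),
            all(c("patient_id", "group", "cube") %in% names(manifest)))
  groups <- unique(manifest$group)
  if (length(groups) != 2L)
    stop("manifest must contain exactly 2 groups, got: ",
         paste(groups, collapse = ", "), call. = FALSE)
  for (g in groups)
    if (length(unique(manifest$patient_id[manifest$group == g])) < 2L)
      stop("group '", g, "' has fewer than 2 patients", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_patient <- list()
  for (i in seq_len(nrow(manifest))) {
    cube <- read_cube(manifest$cube[i])
    sigma <- compute_sigma_map(cube, filter = config$filter,
                               poly_order = config$poly_order,
                               noise_floor = config$noise_floor)
    ld <- sigma_to_ld(sigma, config$thickness_um, cube$axis,
                      convention = config$convention,
                      calibration = config$calibration)
    trans <- if (!is.null(manifest$transmission) &&
                 !is.na(manifest$transmission[i]))
      tiff::readTIFF(manifest$transmission[i])
    else apply(cube$values, c(1, 2), mean)
    mask <- segment_nuclei(trans, config$segmentation,
                           pixel_size_um = cube$pixel_size_um)
    stats_df <- region_ld_stats(ld, mask,
                                annulus_width_px = config$annulus_width_px)
    pid <- manifest$patient_id[i]
    per_patient[[pid]] <- rbind(per_patient[[pid]],
                                cbind(stats_df, group = manifest$group[i]))
  }
  rows <- lapply(names(per_patient), function(pid) {
    df <- per_patient[[pid]]
    if (nrow(df) == 0L) return(NULL)
    patient_summary(pid, df$group[1], mean(df$mean_ld),
                    if (!is.null(df$mean_cellular_ld))
                      mean(df$mean_cellular_ld) else NA_real_,
                    nrow(df))
  })
  summaries <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  comparison <- compare_groups(summaries, groups[1], groups[2],
                               test = config$test,
                               sd_convention = config$sd_convention)
  sum_path <- file.path(out_dir, "patient_summaries.csv")
  utils::write.csv(summaries, sum_path, row.names = FALSE)
  rep_path <- file.path(out_dir, "report.csv")
  cohort_report(comparison, rep_path)
  run_manifest(out_dir, config,
               list(n_measurements = nrow(manifest),
                    groups = as.list(table(summaries$group))))
  invisible(list(summaries = summaries, comparison = comparison,
                 paths = c(summaries = sum_path, report = rep_path)))
}
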