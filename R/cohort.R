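#' Patient-level summary table
#'
#' Cohort statistics operate on one row per patient: the patient-level
#' mean nuclear disorder strength (averaged over that patient's segmented
#' nuclei), an optional cellular (nucleus + perinuclear annulus) mean, and
#' the nucleus count. The patient -- not the nucleus -- is the statistical
#' unit of every group comparison.
#'
#' @param patient_id Character vector.
#' @param group Character vector of diagnostic group labels.
#' @param mean_nuclear_ld Numeric vector, finite.
#' @param mean_cellular_ld Optional numeric vector (NA allowed).
#' @param n_nuclei Integer vector, >= 1.
#' @return A data frame with class `c("patient_summary", "data.frame")`.
#' @export
patient_summary <- function(patient_id, group, mean_nuclear_ld,
                            mean_cellular_ld = NA_real_, n_nuclei = 1L) {
  out <- data.frame(patient_id = as.character(patient_id),
                    group = as.character(group),
                    mean_nuclear_ld = as.numeric(mean_nuclear_ld),
                    mean_cellular_ld = as.numeric(mean_cellular_ld),
                    n_nuclei = as.integer(n_nuclei))
  if (any(!is.finite(out$mean_nuclear_ld)))
    stop("mean_nuclear_ld must be finite", call. = FALSE)
  if (any(out$n_nuclei < 1L))
    stop("every patient needs at least one nucleus", call. = FALSE)
  class(out) <- c("patient_summary", "data.frame")
  out
}

#' Two-group effect size on the cumulative-SD convention
#'
#' The absolute difference of the two group means divided by a standard
#' deviation. The default divisor is the "cumulative" SD -- the sample SD
#' of the two groups pooled into one sample -- which is the convention
#' used for reporting PWS nanocytology contrasts; the classical
#' pooled-within-group SD (Cohen's d divisor) is available as an
#' alternative. Sample (n-1) SDs are used throughout. The statistic is
#' invariant under any common affine rescaling `y = c*x + d` (c > 0) of
#' all values, which is what makes arbitrary-unit L_d valid for cohort
#' claims.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param sd_convention `"cumulative"` (default) or `"pooled_within"`.
#' @return Non-negative effect size (1.0 = 100%).
#' @export
effect_size <- function(a, b, sd_convention = c("cumulative", "pooled_within")) {
  sd_convention <- match.arg(sd_convention)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values", call. = FALSE)
  s <- switch(sd_convention,
              cumulative = stats::sd(c(a, b)),
              pooled_within = sqrt(((length(a) - 1) * stats::var(a) +
                                    (length(b) - 1) * stats::var(b)) /
                                   (length(a) + length(b) - 2)))
  if (!is.finite(s) || s == 0)
    stop("zero ", sd_convention, " SD: effect size undefined", call. = FALSE)
  abs(mean(a) - mean(b)) / s
}

#' Compare two diagnostic groups of patients
#'
#' Computes the effect size ([effect_size()]) on patient-level mean
#' nuclear L_d and a two-sided p-value from the chosen test (Welch t by
#' default, Mann-Whitney as a rank-based alternative). Symmetric in the
#' two group labels.
#'
#' @param summaries A [patient_summary()] data frame.
#' @param group_a,group_b Group labels to contrast.
#' @param test `"welch_t"` or `"mann_whitney"`.
#' @param sd_convention Passed to [effect_size()].
#' @return An object of class `"group_comparison"`: group labels and
#'   sizes, `effect_size_fraction` (1.0 = 100%), `p_value`, `test`,
#'   `sd_convention`.
#' @export
compare_groups <- function(summaries, group_a, group_b,
                           test = c("welch_t", "mann_whitney"),
                           sd_convention = c("cumulative", "pooled_within")) {
  test <- match.arg(test)
  sd_convention <- match.arg(sd_convention)
  for (g in c(group_a, group_b))
    if (!g %in% summaries$group)
      stop("unknown group '", g, "'; available: ",
           paste(unique(summaries$group), collapse = ", "), call. = FALSE)
  a <- summaries$mean_nuclear_ld[summaries$group == group_a]
  b <- summaries$mean_nuclear_ld[summaries$group == group_b]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 patients (", group_a, ": ", length(a),
         ", ", group_b, ": ", length(b), ")", call. = FALSE)
  p <- switch(test,
              welch_t = stats::t.test(a, b, var.equal = FALSE)$p.value,
              mann_whitney = stats::wilcox.test(a, b, exact = FALSE)$p.value)
  structure(list(group_a = group_a, group_b = group_b,
                 n_a = length(a), n_b = length(b),
                 effect_size_fraction = effect_size(a, b, sd_convention),
                 sd_convention = sd_convention,
                 p_value = p, test = test),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d) vs %s (n=%d)\n",
              x$group_a, x$n_a, x$group_b, x$n_b))
  cat(sprintf("  effect size: %.0f%% (%s SD); p = %.3g (%s, two-sided)\n",
              100 * x$effect_size_fraction, x$sd_convention, x$p_value,
              x$test))
  invisible(x)
}

#' Correlation between nuclear and cellular disorder strength
#'
#' Pearson correlation, across patients, of the mean nuclear L_d against
#' the mean cellular (nucleus + perinuclear) L_d. Requires at least three
#' patients with both compartment means.
#'
#' @param summaries A [patient_summary()] data frame.
#' @return Pearson R.
#' @export
correlate_compartments <- function(summaries) {
  ok <- is.finite(summaries$mean_nuclear_ld) &
        is.finite(summaries$mean_cellular_ld)
  if (sum(ok) < 3L)
    stop("need >= 3 patients with both nuclear and cellular means, got ",
         sum(ok), call. = FALSE)
  stats::cor(summaries$mean_nuclear_ld[ok], summaries$mean_cellular_ld[ok])
}

#' Write a cohort comparison report as CSV
#'
#' One row per contrast with the effect size rendered as a percentage
#' (104% means the group means differ by 1.04 cumulative SDs).
#'
#' @param comparisons A list of [compare_groups()] results (a single
#'   result is accepted).
#' @param out_path CSV output path.
#' @return `out_path`, invisibly.
#' @export
cohort_report <- function(comparisons, out_path) {
  if (inherits(comparisons, "group_comparison"))
    comparisons <- list(comparisons)
  if (length(comparisons) == 0L)
    stop("no comparisons to report", call. = FALSE)
  rows <- lapply(comparisons, function(x) {
    stopifnot(inherits(x, "group_comparison"))
    data.frame(contrast = paste(x$group_a, "vs", x$group_b),
               effect_size_pct = 100 * x$effect_size_fraction,
               p_value = x$p_value,
               n_a = x$n_a, n_b = x$n_b,
               test = x$test, sd_convention = x$sd_convention)
  })
  utils::write.csv(do.call(rbind, rows), out_path, row.names = FALSE)
  invisible(out_path)
}
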