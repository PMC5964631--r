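#' Summarise a per-base profile into region-level metrics
#'
#' Reduces a profile to the region summary metrics: RC (reads overlapping
#' the region), MEDCOV/MINCOV (median/minimum of COV), MEDQCOV/MINQCOV
#' (median/minimum of QCOV) and MAXFLMQ/MAXFLBQ (maxima of the low-quality
#' fractions). Medians, minima and maxima are taken over all positions of
#' the region; MAXFLMQ/MAXFLBQ are `NA` only when the underlying fraction
#' is undefined at every position.
#'
#' RC counts each eligible read once if its alignment overlaps the region
#' by at least one reference base; it is computed from the read list, not
#' the profile, so a read overlapping only via soft-clipped bases still
#' counts toward RC while covering no position.
#'
#' @param profile Per-base profile from [compute_profile()].
#' @param rc Region read count; defaults to the `RC` attribute that
#'   [compute_profile()] attaches.
#' @return A list of class `region_summary` with the metrics above plus
#'   `region`, `chrom`, `status` (unset: `NA`) and `failed_metrics`.
#' @export
summarize_region <- function(profile, rc = attr(profile, "RC")) {
  stopifnot(nrow(profile) > 0L)
  max_or_na <- function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  structure(list(
    region = attr(profile, "region"),
    chrom = attr(profile, "chrom"),
    start = profile$pos[1L],
    end = profile$pos[nrow(profile)],
    RC = as.integer(rc),
    MEDCOV = stats::median(profile$COV),
    MINCOV = min(profile$COV),
    MEDQCOV = stats::median(profile$QCOV),
    MINQCOV = min(profile$QCOV),
    MAXFLMQ = max_or_na(profile$FLMQ),
    MAXFLBQ = max_or_na(profile$FLBQ),
    status = NA_character_,
    failed_metrics = character(0)
  ), class = "region_summary")
}

#' Apply PASS/FLAG criteria to a region summary
#'
#' Evaluates each [flag_criteria()] bound against the summary metrics. A
#' minimum bound fails when the metric is below the threshold; a maximum
#' bound fails when the metric exceeds it. An undefined (`NA`) metric never
#' fails a maximum bound (no evidence of low quality) and always fails a
#' minimum bound (no evidence of sufficient coverage) — the conservative
#' choice for clinical review. The region is `"FLAG"` iff at least one
#' criterion fails, otherwise `"PASS"`.
#'
#' @param summary A `region_summary` from [summarize_region()].
#' @param criteria A [flag_criteria()] object (possibly empty).
#' @return The summary with `status` and `failed_metrics` set.
#' @export
apply_flags <- function(summary, criteria = flag_criteria()) {
  failed <- character(0)
  for (metric in names(criteria)) {
    if (!metric %in% SUMMARY_METRICS)
      stop("unknown summary metric in flag criterion: ", metric)
    v <- summary[[metric]]
    cr <- criteria[[metric]]
    bad <- if (cr$bound == "min") is.na(v) || v < cr$threshold
           else !is.na(v) && v > cr$threshold
    if (bad) failed <- c(failed, metric)
  }
  summary$failed_metrics <- failed
  summary$status <- if (length(failed)) "FLAG" else "PASS"
  summary
}

#' @export
print.region_summary <- function(x, ...) {
  cat(sprintf("Region %s (%s:%d-%d)\n", x$region, x$chrom, x$start, x$end))
  cat(sprintf("  RC=%d MEDCOV=%s MINCOV=%d MEDQCOV=%s MINQCOV=%d MAXFLMQ=%s MAXFLBQ=%s\n",
              x$RC, fmt_med(x$MEDCOV), x$MINCOV, fmt_med(x$MEDQCOV), x$MINQCOV,
              fmt_frac(x$MAXFLMQ), fmt_frac(x$MAXFLBQ)))
  if (!is.na(x$status))
    cat(sprintf("  status: %s%s\n", x$status,
                if (length(x$failed_metrics))
                  paste0(" (", paste(x$failed_metrics, collapse = ","), ")")
                else ""))
  invisible(x)
}
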