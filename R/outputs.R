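# Pipeline orchestration and the four tab-separated output writers.

#' Run the full panel QC evaluation
#'
#' End-to-end driver: parses the BED, computes per-base profiles, region
#' summaries with PASS/FLAG status, chromosome-level on/off-target read
#' accounting and poor-quality intervals (optionally annotated with
#' transcript c. coordinates), and writes the four output files when an
#' output prefix is given:
#' \describe{
#'   \item{`<prefix>_summary.txt`}{per-chromosome RC/RCIN/RCOUT and
#'     genome-wide mapped/unmapped/total counts}
#'   \item{`<prefix>_regions.txt`}{one row per BED region with the summary
#'     metrics and a PASS/FLAG column}
#'   \item{`<prefix>_profiles.txt`}{per-base metric rows, regions separated
#'     by a `# region=` header line}
#'   \item{`<prefix>_poor.txt`}{poor-quality intervals with genomic and
#'     transcript coordinates}
#' }
#' All files are tab-separated with a `#`-prefixed column header; undefined
#' values are written as `"."`. Outputs contain no timestamps, so repeated
#' runs on identical inputs are byte-identical.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param bed Path to the target-region BED file.
#' @param config Path to an INI file, a `run_config` from [parse_config()],
#'   or `NULL` for defaults.
#' @param output_prefix Output path prefix; `NULL` to skip writing.
#' @return Invisibly, a list with `regions` (summary `data.frame`),
#'   `chrom` ([summarize_chromosomes()] result), `profiles` (named list of
#'   per-base profiles, plus `forward`/`reverse` attributes when direction
#'   is enabled), `poor` (annotated interval `data.frame`) and `config`.
#' @export
run_coverage_qc <- function(bam, bed, config = NULL, output_prefix = NULL) {
  run_cfg <- if (is.null(config)) parse_config(NULL)
             else if (inherits(config, "run_config")) config
             else parse_config(config)
  cfg <- run_cfg$quality

  # Fail fast before any computation.
  if (!file.exists(bam)) stop("input BAM not found: ", bam)
  check_bam_index(bam)
  if (!file.exists(bed)) stop("BED file not found: ", bed)
  txdb_path <- run_cfg$outputs$transcript_db
  if (!is.null(txdb_path) && !file.exists(txdb_path))
    stop("transcript database not found: ", txdb_path)
  if (!is.null(output_prefix)) {
    dir <- dirname(output_prefix)
    if (!dir.exists(dir)) stop("output directory does not exist: ", dir)
    if (file.access(dir, 2L) != 0L) stop("output directory not writable: ", dir)
  }

  log_msg("reading target regions from %s", bed)
  regions <- read_bed(bed)
  log_msg("%d target regions; computing per-base profiles", nrow(regions))

  txdb <- if (!is.null(txdb_path)) load_transcript_db(txdb_path) else NULL

  profiles <- vector("list", nrow(regions))
  names(profiles) <- regions$name
  summaries <- vector("list", nrow(regions))
  poor_list <- list()
  for (i in seq_len(nrow(regions))) {
    region <- regions[i, ]
    prof <- compute_profile(bam, region, cfg)
    if (cfg$direction) {
      dirp <- compute_directional_profiles(bam, region, cfg)
      attr(prof, "forward") <- dirp$forward
      attr(prof, "reverse") <- dirp$reverse
    }
    profiles[[i]] <- prof
    summaries[[i]] <- apply_flags(summarize_region(prof), run_cfg$criteria)
    poor_list[[i]] <- find_poor_intervals(prof, cfg)
  }
  poor <- if (length(poor_list))
    do.call(rbind, c(poor_list, list(make.row.names = FALSE)))
  else NULL
  if (is.null(poor))
    poor <- data.frame(region = character(0), chrom = character(0),
                       start = integer(0), end = integer(0),
                       min_qcov = integer(0), stringsAsFactors = FALSE)
  poor <- annotate_poor_intervals(poor, txdb)

  region_df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(region = s$region, chrom = s$chrom, start = s$start,
               end = s$end, RC = s$RC, MEDCOV = s$MEDCOV, MINCOV = s$MINCOV,
               MEDQCOV = s$MEDQCOV, MINQCOV = s$MINQCOV, MAXFLMQ = s$MAXFLMQ,
               MAXFLBQ = s$MAXFLBQ, status = s$status,
               failed_metrics = paste(s$failed_metrics, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(region_df))
    region_df <- data.frame(region = character(0))

  log_msg("computing chromosome-level read accounting")
  chrom <- summarize_chromosomes(bam, regions, cfg)

  results <- list(regions = region_df, chrom = chrom, profiles = profiles,
                  poor = poor, config = run_cfg)
  if (!is.null(output_prefix)) {
    write_outputs(results, output_prefix)
    log_msg("outputs written to %s_{summary,regions,profiles,poor}.txt",
            output_prefix)
  }
  invisible(results)
}

#' Write the four QC output files
#'
#' @param results Result list from [run_coverage_qc()].
#' @param prefix Output path prefix.
#' @return Invisibly, the four file paths.
#' @export
write_outputs <- function(results, prefix) {
  paths <- paste0(prefix, "_", c("summary", "regions", "profiles", "poor"),
                  ".txt")
  names(paths) <- c("summary", "regions", "profiles", "poor")
  write_summary_file(results$chrom, paths["summary"])
  write_regions_file(results$regions, paths["regions"])
  opts <- results$config$outputs
  if (isTRUE(opts$profiles)) {
    prof <- results$profiles
    if (isTRUE(opts$profiles_flagged_only)) {
      flagged <- results$regions$region[results$regions$status == "FLAG"]
      prof <- prof[names(prof) %in% flagged]
    }
    write_profiles_file(prof, paths["profiles"],
                        direction = results$config$quality$direction)
  } else {
    writeLines(profile_header(FALSE), paths["profiles"])
  }
  if (isTRUE(opts$poor)) write_poor_file(results$poor, paths["poor"])
  else writeLines(poor_header(), paths["poor"])
  invisible(paths)
}

write_summary_file <- function(chrom_stats, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tRC\tRCIN\tRCOUT", con)
  df <- chrom_stats$chrom
  if (nrow(df))
    writeLines(sprintf("%s\t%d\t%d\t%d", df$chrom, df$RC, df$RCIN, df$RCOUT), con)
  tt <- chrom_stats$totals
  writeLines(c(sprintf("total_mapped\t%d\t.\t.", tt[["mapped"]]),
               sprintf("total_unmapped\t%d\t.\t.", tt[["unmapped"]]),
               sprintf("total\t%d\t.\t.", tt[["total"]])), con)
}

write_regions_file <- function(region_df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#region\tchrom\tstart\tend\tRC\tMEDCOV\tMINCOV\t",
                    "MEDQCOV\tMINQCOV\tMAXFLMQ\tMAXFLBQ\tstatus\tfailed_metrics"),
             con)
  if (!nrow(region_df)) return(invisible())
  writeLines(sprintf("%s\t%s\t%d\t%d\t%d\t%s\t%d\t%s\t%d\t%s\t%s\t%s\t%s",
                     region_df$region, region_df$chrom, region_df$start,
                     region_df$end, region_df$RC, fmt_med(region_df$MEDCOV),
                     region_df$MINCOV, fmt_med(region_df$MEDQCOV),
                     region_df$MINQCOV, fmt_frac(region_df$MAXFLMQ),
                     fmt_frac(region_df$MAXFLBQ), region_df$status,
                     ifelse(nzchar(region_df$failed_metrics),
                            region_df$failed_metrics, ".")),
             con)
}

profile_header <- function(direction) {
  base <- "#region\tchrom\tpos\tCOV\tQCOV\tMEDBQ\tFLBQ\tMEDMQ\tFLMQ"
  if (!direction) return(base)
  paste0(base, "\tCOV+\tQCOV+\tMEDBQ+\tFLBQ+\tMEDMQ+\tFLMQ+",
         "\tCOV-\tQCOV-\tMEDBQ-\tFLBQ-\tMEDMQ-\tFLMQ-")
}

profile_cols <- function(p) {
  sprintf("%d\t%d\t%s\t%s\t%s\t%s", p$COV, p$QCOV, fmt_med(p$MEDBQ),
          fmt_frac(p$FLBQ), fmt_med(p$MEDMQ), fmt_frac(p$FLMQ))
}

write_profiles_file <- function(profiles, path, direction = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(profile_header(direction), con)
  for (name in names(profiles)) {
    p <- profiles[[name]]
    writeLines(sprintf("# region=%s", name), con)
    if (!nrow(p)) next
    lead <- sprintf("%s\t%s\t%d", name, attr(p, "chrom"), p$pos)
    if (direction) {
      fwd <- attr(p, "forward"); rev <- attr(p, "reverse")
      writeLines(paste(lead, profile_cols(p), profile_cols(fwd),
                       profile_cols(rev), sep = "\t"), con)
    } else {
      writeLines(paste(lead, profile_cols(p), sep = "\t"), con)
    }
  }
}

poor_header <- function() "#region\ttranscripts\tchrom\tstart\tend\tmin_qcov"

write_poor_file <- function(poor, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(poor_header(), con)
  if (!nrow(poor)) return(invisible())
  writeLines(sprintf("%s\t%s\t%s\t%d\t%d\t%d", poor$region,
                     ifelse(nzchar(poor$transcripts), poor$transcripts, "."),
                     poor$chrom, poor$start, poor$end, poor$min_qcov),
             con)
}
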