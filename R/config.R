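#' Quality thresholds controlling metric computation
#'
#' Holds the Phred cutoffs and toggles used by every metric. A read base
#' passes the base-quality test when `BQ >= bq_cutoff`; a read passes the
#' mapping-quality test when `MQ >= mq_cutoff` (inclusive comparisons; "low"
#' in FLBQ/FLMQ means strictly below the cutoff). A mapping quality recorded
#' as unavailable (SAM value 255) fails any `mq_cutoff > 0`.
#'
#' @param bq_cutoff Phred base-quality threshold (default 10).
#' @param mq_cutoff Phred mapping-quality threshold (default 20).
#' @param count_duplicates Include duplicate-marked reads (flag 0x400)?
#'   Default `TRUE`.
#' @param direction Also compute forward/reverse strand-split profiles?
#'   Default `FALSE`.
#' @param qcov_poor_cutoff QCOV threshold below which a position belongs to
#'   a poor-quality interval (default 15).
#' @return A list of class `quality_config`.
#' @export
quality_config <- function(bq_cutoff = 10, mq_cutoff = 20,
                           count_duplicates = TRUE, direction = FALSE,
                           qcov_poor_cutoff = 15) {
  for (v in c(bq_cutoff, mq_cutoff, qcov_poor_cutoff))
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("quality cutoffs must be single non-negative numbers")
  structure(list(bq_cutoff = bq_cutoff, mq_cutoff = mq_cutoff,
                 count_duplicates = isTRUE(count_duplicates),
                 direction = isTRUE(direction),
                 qcov_poor_cutoff = qcov_poor_cutoff),
            class = "quality_config")
}

#' Define PASS/FLAG criteria on region summary metrics
#'
#' Each argument is named `<METRIC>_min` or `<METRIC>_max` where `<METRIC>`
#' is one of RC, MEDCOV, MINCOV, MEDQCOV, MINQCOV, MAXFLMQ, MAXFLBQ. A
#' minimum bound fails when the metric is below the threshold; a maximum
#' bound fails when it exceeds the threshold. Minimum bounds are meaningful
#' for the coverage metrics and maximum bounds for the low-quality
#' fractions; other combinations are accepted with a warning.
#'
#' @param ... Named numeric thresholds, e.g. `MINQCOV_min = 50`.
#' @return A named list of class `flag_criteria`; each element is
#'   `list(bound, threshold)`.
#' @examples
#' flag_criteria(MINQCOV_min = 50, MAXFLBQ_max = 0.2)
#' @export
flag_criteria <- function(...) {
  args <- list(...)
  if (length(args) && (is.null(names(args)) || any(!nzchar(names(args)))))
    stop("all flag criteria must be named <METRIC>_min or <METRIC>_max")
  crit <- list()
  for (key in names(args)) {
    m <- regmatches(key, regexec("^(.*)_(min|max)$", key))[[1]]
    if (length(m) != 3L)
      stop("flag criterion key must end in _min or _max: ", key)
    metric <- m[2L]; bound <- m[3L]
    if (!metric %in% SUMMARY_METRICS)
      stop("unknown summary metric in flag criterion: ", metric)
    thr <- suppressWarnings(as.numeric(args[[key]]))
    if (length(thr) != 1L || is.na(thr))
      stop("non-numeric threshold for flag criterion ", key)
    natural_min <- metric %in% c("RC", "MEDCOV", "MINCOV", "MEDQCOV", "MINQCOV")
    if ((bound == "min") != natural_min)
      warning(sprintf("unusual bound '%s' for metric %s (accepted)", bound, metric))
    crit[[metric]] <- list(bound = bound, threshold = thr)
  }
  structure(crit, class = "flag_criteria")
}

# Minimal INI reader: [section] headers, key = value pairs, ';'/'#' comments.
read_ini <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  out <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    line <- sub("[;#].*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      section <- sub("^\\[(.*)\\]$", "\\1", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (!grepl("=", line, fixed = TRUE))
      stop(sprintf("config line %d is not 'key = value': '%s'", i, lines[i]))
    if (is.null(section))
      stop(sprintf("config line %d: key outside any [section]", i))
    kv <- regmatches(line, regexpr("=", line, fixed = TRUE), invert = TRUE)[[1]]
    out[[section]][[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  out
}

ini_bool <- function(x, key) {
  v <- tolower(x)
  if (v %in% c("true", "yes", "on", "1")) return(TRUE)
  if (v %in% c("false", "no", "off", "0")) return(FALSE)
  stop(sprintf("config key %s: expected a boolean, got '%s'", key, x))
}

ini_num <- function(x, key) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop(sprintf("config key %s: expected a number, got '%s'", key, x))
  v
}

#' Parse an INI run configuration
#'
#' Reads the `[quality]`, `[flags]` and `[outputs]` sections of an INI file.
#' Missing keys take documented defaults (`bq_cutoff` 10, `mq_cutoff` 20,
#' `qcov_poor_cutoff` 15, duplicates included, direction off, profiles on);
#' unknown keys produce a warning; non-numeric thresholds are hard errors.
#'
#' Recognised keys: `[quality]` `bq_cutoff`, `mq_cutoff`, `qcov_poor_cutoff`,
#' `count_duplicates`, `direction`; `[flags]` `<METRIC>_min` / `<METRIC>_max`
#' (e.g. `MINQCOV_min = 50`); `[outputs]` `profiles`, `poor`,
#' `profiles_flagged_only`, `transcript_db`.
#'
#' @param path Path to an INI file, or `NULL` for all defaults.
#' @return A list of class `run_config` with elements `quality`
#'   ([quality_config()]), `criteria` ([flag_criteria()]) and `outputs`.
#' @export
parse_config <- function(path = NULL) {
  ini <- if (is.null(path)) list() else read_ini(path)

  unknown_sec <- setdiff(names(ini), c("quality", "flags", "outputs"))
  if (length(unknown_sec))
    warning("ignoring unknown config section(s): ",
            paste(unknown_sec, collapse = ", "))

  q <- ini[["quality"]]
  qargs <- list()
  for (key in names(q)) {
    switch(key,
      bq_cutoff = ,
      mq_cutoff = ,
      qcov_poor_cutoff = { qargs[[key]] <- ini_num(q[[key]], key) },
      count_duplicates = ,
      direction = { qargs[[key]] <- ini_bool(q[[key]], key) },
      warning("ignoring unknown [quality] key: ", key)
    )
  }
  quality <- do.call(quality_config, qargs)

  criteria <- do.call(flag_criteria, lapply(ini[["flags"]], function(x) x))

  outputs <- list(profiles = TRUE, poor = TRUE, profiles_flagged_only = FALSE,
                  transcript_db = NULL)
  o <- ini[["outputs"]]
  for (key in names(o)) {
    switch(key,
      profiles = ,
      poor = ,
      profiles_flagged_only = { outputs[[key]] <- ini_bool(o[[key]], key) },
      transcript_db = { outputs$transcript_db <- o[[key]] },
      warning("ignoring unknown [outputs] key: ", key)
    )
  }

  structure(list(quality = quality, criteria = criteria, outputs = outputs),
            class = "run_config")
}
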