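#' @keywords internal
log_msg <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  sprintf(fmt, ...)))
}

# Region-level metric names eligible for flag criteria
SUMMARY_METRICS <- c("RC", "MEDCOV", "MINCOV", "MEDQCOV", "MINQCOV",
                     "MAXFLMQ", "MAXFLBQ")

# Formatters used by all writers: fixed precision keeps outputs diffable.
fmt_med <- function(x) ifelse(is.na(x), ".", formatC(x, format = "f", digits = 1))
fmt_frac <- function(x) ifelse(is.na(x), ".", formatC(x, format = "f", digits = 3))
fmt_int <- function(x) ifelse(is.na(x), ".", format(x, scientific = FALSE, trim = TRUE))
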