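#' Read target regions from a BED file
#'
#' Parses a BED file of target regions (typically exons of a gene panel).
#' Coordinates follow the BED convention: 0-based start, exclusive end
#' (half-open). All downstream per-base output positions are reported as
#' 1-based inclusive genomic coordinates.
#'
#' Track/browser lines and lines starting with `#` are skipped. When the
#' fourth (name) column is absent, a name of the form `chrom:start-end` is
#' synthesized. Duplicate region names are permitted but reported with a
#' warning.
#'
#' @param path Path to a tab-separated BED file with at least three columns
#'   (chrom, start, end); the optional fourth column is the region name.
#' @return A `data.frame` with columns `name`, `chrom`, `start` (0-based),
#'   `end` (exclusive) and `length`, one row per region in file order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("7\t6026555\t6026708\tPMS2_12", bed)
#' read_bed(bed)
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("BED file is empty: ", path)
  keep <- !grepl("^\\s*$", lines) & !grepl("^#", lines) &
    !grepl("^(track|browser)\\b", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    warning("BED file contains no region records: ", path)
    return(data.frame(name = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  }

  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(fields)
  name <- chrom <- character(n)
  start <- end <- integer(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("BED line %d: expected >= 3 tab-separated fields, got %d",
                   lineno[i], length(f)))
    s <- suppressWarnings(as.integer(f[2L]))
    e <- suppressWarnings(as.integer(f[3L]))
    if (is.na(s) || is.na(e))
      stop(sprintf("BED line %d: non-integer coordinates '%s'/'%s'",
                   lineno[i], f[2L], f[3L]))
    if (e <= s)
      stop(sprintf("BED line %d: start (%d) must be < end (%d); zero-length regions are not allowed",
                   lineno[i], s, e))
    chrom[i] <- f[1L]
    start[i] <- s
    end[i] <- e
    name[i] <- if (length(f) >= 4L && nzchar(f[4L])) f[4L] else
      sprintf("%s:%d-%d", f[1L], s, e)
  }
  dup <- unique(name[duplicated(name)])
  if (length(dup))
    warning("duplicate region names in BED: ", paste(dup, collapse = ", "))
  data.frame(name = name, chrom = chrom, start = start, end = end,
             length = end - start, stringsAsFactors = FALSE)
}

#' Write target regions back to BED
#'
#' Inverse of [read_bed()]: writes `chrom`, `start`, `end`, `name`
#' tab-separated, preserving the 0-based half-open convention so that a
#' write/read round-trip is the identity.
#'
#' @param regions Region `data.frame` as returned by [read_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", regions$chrom, regions$start,
                     regions$end, regions$name), path)
  invisible(path)
}

#' Gene label of a region name
#'
#' Panel BEDs commonly name regions `GENE_EXON` (e.g. `PMS2_12`). The gene
#' label is taken as the text before the last underscore when one is
#' present, otherwise the full region name. This is a convention of this
#' package, used only for grouping flagged regions by gene.
#'
#' @param name Character vector of region names.
#' @return Character vector of gene labels.
#' @examples
#' gene_label(c("PMS2_12", "TP53"))
#' @export
gene_label <- function(name) {
  ifelse(grepl("_", name), sub("_[^_]*$", "", name), name)
}
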