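# Poor-quality intervals and simplified transcript (c.) coordinates.

#' Find poor-quality intervals in a per-base profile
#'
#' A poor-quality interval is a maximal run of consecutive positions whose
#' quality coverage falls below the configured cutoff (default QCOV < 15).
#' Such intervals localise the stretches of a region where variant calls
#' cannot be supported by enough good-quality reads.
#'
#' @param profile Per-base profile from [compute_profile()].
#' @param cfg A [quality_config()]; the cutoff is `cfg$qcov_poor_cutoff`.
#' @return A `data.frame` with columns `region`, `chrom`, `start`, `end`
#'   (1-based inclusive genomic), `min_qcov`; zero rows when no position is
#'   below the cutoff.
#' @export
find_poor_intervals <- function(profile, cfg = quality_config()) {
  poor <- profile$QCOV < cfg$qcov_poor_cutoff
  empty <- data.frame(region = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      min_qcov = integer(0), stringsAsFactors = FALSE)
  if (!any(poor)) return(empty)
  r <- rle(poor)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    region = attr(profile, "region"),
    chrom = attr(profile, "chrom"),
    start = profile$pos[starts[keep]],
    end = profile$pos[ends[keep]],
    min_qcov = mapply(function(a, b) min(profile$QCOV[a:b]),
                      starts[keep], ends[keep]),
    stringsAsFactors = FALSE)
}

#' Load a transcript database
#'
#' Reads the package's tab-separated transcript format: one transcript per
#' line with columns `id`, `gene`, `chrom`, `strand` (+/-), `coding_start`,
#' `coding_end` (1-based inclusive genomic positions of the first and last
#' coding base, `coding_start < coding_end` regardless of strand),
#' comma-separated exon starts (0-based) and comma-separated exon ends
#' (exclusive), exons sorted and non-overlapping.
#'
#' @param path Path to the transcript TSV.
#' @return An object of class `transcript_db`: a list of transcript records
#'   plus an interval index supporting overlap queries.
#' @export
load_transcript_db <- function(path) {
  if (!file.exists(path)) stop("transcript database not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*$", lines) & !grepl("^#", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  tx <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 8L)
      stop(sprintf("transcript db line %d: expected 8 tab-separated fields, got %d",
                   lineno[i], length(f)))
    starts <- suppressWarnings(as.integer(strsplit(f[7L], ",")[[1L]]))
    ends <- suppressWarnings(as.integer(strsplit(f[8L], ",")[[1L]]))
    cs <- suppressWarnings(as.integer(f[5L]))
    ce <- suppressWarnings(as.integer(f[6L]))
    if (anyNA(starts) || anyNA(ends) || is.na(cs) || is.na(ce) ||
        length(starts) != length(ends) || length(starts) == 0L)
      stop(sprintf("transcript db line %d: malformed coordinates", lineno[i]))
    if (!f[4L] %in% c("+", "-"))
      stop(sprintf("transcript db line %d: strand must be + or -", lineno[i]))
    if (any(ends <= starts) || is.unsorted(starts, strictly = TRUE) ||
        any(starts[-1L] < ends[-length(ends)]))
      stop(sprintf("transcript db line %d: exons must be sorted and non-overlapping",
                   lineno[i]))
    if (cs > ce || cs < starts[1L] + 1L || ce > ends[length(ends)])
      stop(sprintf("transcript db line %d: CDS boundaries outside exon span",
                   lineno[i]))
    tx[[i]] <- list(id = f[1L], gene = f[2L], chrom = f[3L], strand = f[4L],
                    coding_start = cs, coding_end = ce,
                    exon_start = starts + 1L,  # 1-based inclusive internally
                    exon_end = ends,
                    span_start = starts[1L] + 1L,
                    span_end = ends[length(ends)])
  }
  structure(list(
    transcripts = tx,
    chrom = vapply(tx, `[[`, "", "chrom"),
    spans = IRanges::IRanges(
      vapply(tx, `[[`, 0L, "span_start"),
      vapply(tx, `[[`, 0L, "span_end"))
  ), class = "transcript_db")
}

#' Transcripts overlapping a genomic interval
#'
#' @param db A [load_transcript_db()] object.
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive genomic interval.
#' @return List of transcript records (possibly empty).
#' @export
transcripts_overlapping <- function(db, chrom, start, end) {
  hit <- db$chrom == chrom &
    IRanges::overlapsAny(db$spans, IRanges::IRanges(start, end))
  db$transcripts[hit]
}

# Transcript-space position (1..sum of exon lengths) of genomic position g,
# or NA when g is not exonic. Transcript order follows the strand.
tx_pos_of_genomic <- function(g, tx) {
  es <- tx$exon_start; ee <- tx$exon_end
  if (tx$strand == "-") { es <- rev(es); ee <- rev(ee) }
  cum <- 0L
  for (i in seq_along(es)) {
    w <- ee[i] - es[i] + 1L
    if (g >= es[i] && g <= ee[i]) {
      off <- if (tx$strand == "+") g - es[i] + 1L else ee[i] - g + 1L
      return(cum + off)
    }
    cum <- cum + w
  }
  NA_integer_
}

# c.-style label of a transcript-space position given the CDS bounds in
# transcript space: "-N" (5'UTR), "N" (CDS), "*N" (3'UTR).
c_label_of_tx_pos <- function(t, ct1, ct2) {
  if (t < ct1) paste0("-", ct1 - t)
  else if (t <= ct2) as.character(t - ct1 + 1L)
  else paste0("*", t - ct2)
}

#' Map a genomic position to a simplified transcript c. coordinate
#'
#' Exonic coding positions map to `c.N` counting coding bases 5'->3' along
#' the transcript strand; 5' UTR positions to `c.-N`; 3' UTR positions to
#' `c.*N`. Intronic positions anchor to the nearer exon boundary: the 5'
#' half of an intron (transcript orientation) yields `c.N+k` from the
#' upstream exon edge, the 3' half `c.N-k` from the downstream edge, with
#' the exact midpoint of an odd-length intron anchoring upstream. Positions
#' outside the transcript span return the sentinel `"out-of-transcript"`.
#'
#' This is a simplified coordinate scheme for localising intervals on a
#' transcript, not a full HGVS/CSN implementation.
#'
#' @param pos 1-based genomic position.
#' @param tx A transcript record from [load_transcript_db()].
#' @return A character c. coordinate such as `"c.100+3"`.
#' @export
genomic_to_transcript <- function(pos, tx) {
  if (pos < tx$span_start || pos > tx$span_end) return("out-of-transcript")

  ct1 <- tx_pos_of_genomic(
    if (tx$strand == "+") tx$coding_start else tx$coding_end, tx)
  ct2 <- tx_pos_of_genomic(
    if (tx$strand == "+") tx$coding_end else tx$coding_start, tx)

  t <- tx_pos_of_genomic(pos, tx)
  if (!is.na(t)) return(paste0("c.", c_label_of_tx_pos(t, ct1, ct2)))

  # Intronic: locate the flanking exons in transcript orientation.
  es <- tx$exon_start; ee <- tx$exon_end
  if (tx$strand == "-") { es <- rev(es); ee <- rev(ee) }
  widths <- ee - es + 1L
  cumw <- cumsum(widths)
  for (i in seq_len(length(es) - 1L)) {
    up_edge <- if (tx$strand == "+") ee[i] else es[i]       # last base of exon i
    dn_edge <- if (tx$strand == "+") es[i + 1L] else ee[i + 1L]  # first base of exon i+1
    inside <- if (tx$strand == "+") pos > up_edge && pos < dn_edge
              else pos < up_edge && pos > dn_edge
    if (!inside) next
    d <- abs(pos - up_edge)               # offset from upstream exon edge
    n <- abs(dn_edge - up_edge) - 1L      # intron length
    if (d <= ceiling(n / 2)) {
      anchor <- c_label_of_tx_pos(cumw[i], ct1, ct2)
      return(sprintf("c.%s+%d", anchor, d))
    }
    anchor <- c_label_of_tx_pos(cumw[i] + 1L, ct1, ct2)
    return(sprintf("c.%s-%d", anchor, n - d + 1L))
  }
  "out-of-transcript"  # unreached for well-formed transcripts
}

#' Annotate poor-quality intervals with transcript coordinates
#'
#' For every interval, all transcripts overlapping it are reported
#' (semicolon-separated) as `id(gene):c.A_c.B` where A/B are the interval
#' end points in transcript 5'->3' order, clamped to the transcript span
#' when the interval extends beyond it. Intervals overlapping no transcript
#' (or when `db` is `NULL`) get an empty annotation.
#'
#' @param poor Interval `data.frame` from [find_poor_intervals()].
#' @param db A [load_transcript_db()] object, or `NULL`.
#' @return `poor` with an added character column `transcripts`.
#' @export
annotate_poor_intervals <- function(poor, db = NULL) {
  ann <- character(nrow(poor))
  if (!is.null(db) && nrow(poor) > 0L) {
    for (i in seq_len(nrow(poor))) {
      txs <- transcripts_overlapping(db, poor$chrom[i], poor$start[i], poor$end[i])
      parts <- vapply(txs, function(tx) {
        a <- max(poor$start[i], tx$span_start)
        b <- min(poor$end[i], tx$span_end)
        if (tx$strand == "-") { tmp <- a; a <- b; b <- tmp }
        sprintf("%s(%s):%s_%s", tx$id, tx$gene,
                genomic_to_transcript(a, tx), genomic_to_transcript(b, tx))
      }, "")
      ann[i] <- paste(parts, collapse = ";")
    }
  }
  poor$transcripts <- ann
  poor
}
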