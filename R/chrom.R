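#' Chromosome-level on/off-target read accounting
#'
#' Quantifies how much sequencing data falls outside the targeted regions:
#' for each chromosome in BAM header order it reports the total eligible
#' mapped reads (RC), the reads overlapping at least one target region on
#' that chromosome (RCIN) and the remainder (RCOUT), plus genome-wide
#' mapped/unmapped/total counts. A read is on-target iff its aligned
#' reference span (including deletions and N-skips) overlaps any region on
#' its chromosome; each read is counted once even when it overlaps several
#' regions. Eligibility matches the pileup metrics (primary, non-QC-fail
#' alignments; duplicates per `cfg$count_duplicates`); unmapped reads enter
#' only the totals row.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param regions Region `data.frame` from [read_bed()] (may have 0 rows).
#' @param cfg A [quality_config()].
#' @return A list of class `chrom_stats`: `chrom`, a `data.frame` with
#'   columns `chrom`, `RC`, `RCIN`, `RCOUT` (one row per header contig, in
#'   header order, including zero-read contigs), and `totals`, a named
#'   vector with `mapped`, `unmapped`, `total`.
#' @export
summarize_chromosomes <- function(bam, regions, cfg = quality_config()) {
  check_bam_index(bam)
  contigs <- bam_contigs(bam)

  param <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "cigar"),
    flag = Rsamtools::scanBamFlag(
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE,
      isNotPassingQualityControls = FALSE,
      isDuplicate = if (cfg$count_duplicates) NA else FALSE))
  res <- Rsamtools::scanBam(Rsamtools::BamFile(bam), param = param)[[1L]]

  unmapped <- bitwAnd(res$flag, 4L) != 0L
  mapped <- !unmapped

  m_rname <- as.character(res$rname[mapped])
  m_pos <- res$pos[mapped]
  m_end <- m_pos +
    GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar[mapped]) - 1L

  rows <- lapply(names(contigs), function(chrom) {
    on_chrom <- which(m_rname == chrom)
    rc <- length(on_chrom)
    reg <- regions[regions$chrom == chrom, , drop = FALSE]
    rcin <- if (rc == 0L || nrow(reg) == 0L) 0L else {
      spans <- IRanges::IRanges(m_pos[on_chrom], m_end[on_chrom])
      targets <- IRanges::IRanges(reg$start + 1L, reg$end)
      sum(IRanges::overlapsAny(spans, targets))
    }
    data.frame(chrom = chrom, RC = rc, RCIN = rcin, RCOUT = rc - rcin,
               stringsAsFactors = FALSE)
  })

  chrom_df <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(chrom = character(0), RC = integer(0), RCIN = integer(0),
               RCOUT = integer(0), stringsAsFactors = FALSE)

  structure(list(
    chrom = chrom_df,
    totals = c(mapped = sum(mapped), unmapped = sum(unmapped),
               total = length(res$flag))
  ), class = "chrom_stats")
}

#' @export
print.chrom_stats <- function(x, ...) {
  print(x$chrom, row.names = FALSE)
  cat(sprintf("mapped=%d unmapped=%d total=%d\n",
              x$totals["mapped"], x$totals["unmapped"], x$totals["total"]))
  invisible(x)
}
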