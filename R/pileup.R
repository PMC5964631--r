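# Per-base pileup metric engine.
#
# Per-position definitions (cutoffs from quality_config; comparisons
# inclusive, "low" = strictly below cutoff):
#   COV    reads whose alignment covers the position (M/=/X base or
#          spanning D; N-skips and soft clips do not cover)
#   MEDBQ  median BQ of aligned read bases (deletion-spanning reads
#          contribute no base)
#   FLBQ   (# aligned bases with BQ < bq_cutoff) / (# aligned bases)
#   MEDMQ  median MQ of covering reads (255 reported as-is)
#   FLMQ   (# covering reads with low MQ) / COV; MQ 255 counts as low
#          whenever mq_cutoff > 0
#   QCOV   covering reads with MQ >= mq_cutoff contributing an aligned
#          base with BQ >= bq_cutoff
# Eligible reads: mapped, primary, not supplementary, not QC-fail;
# duplicates excluded iff count_duplicates is FALSE.

eligible_bam_flag <- function(cfg) {
  Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isNotPassingQualityControls = FALSE,
    isDuplicate = if (cfg$count_duplicates) NA else FALSE)
}

bam_contigs <- function(bam) {
  Rsamtools::scanBamHeader(bam)[[1L]]$targets
}

check_bam_index <- function(bam) {
  if (!file.exists(paste0(bam, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index (.bai) not found for ", bam,
         "; the input must be coordinate-sorted and indexed")
  invisible(TRUE)
}

# Diagnose "chr7" vs "7" naming dialects instead of silently reconciling.
missing_chrom_diag <- function(chrom, contigs) {
  alt <- if (grepl("^chr", chrom)) sub("^chr", "", chrom) else paste0("chr", chrom)
  hint <- if (alt %in% names(contigs))
    sprintf(" (BAM header has '%s'; chromosome-name dialects are not auto-reconciled)", alt)
  else ""
  sprintf("chromosome '%s' absent from BAM header%s; region reported with zero coverage",
          chrom, hint)
}

fetch_region_reads <- function(bam, region, cfg) {
  check_bam_index(bam)
  contigs <- bam_contigs(bam)
  if (!region$chrom %in% names(contigs)) {
    warning(missing_chrom_diag(region$chrom, contigs))
    return(NULL)
  }
  param <- Rsamtools::ScanBamParam(
    which = GenomicRanges::GRanges(region$chrom,
                                   IRanges::IRanges(region$start + 1L, region$end)),
    what = c("flag", "strand", "pos", "mapq", "cigar", "qual"),
    flag = eligible_bam_flag(cfg))
  Rsamtools::scanBam(Rsamtools::BamFile(bam), param = param)[[1L]]
}

empty_profile <- function(region) {
  p <- (region$start + 1L):region$end
  data.frame(pos = p,
             COV = 0L, QCOV = 0L,
             MEDBQ = NA_real_, FLBQ = NA_real_,
             MEDMQ = NA_real_, FLMQ = NA_real_)
}

# Core per-base computation from a scanBam record list restricted to `sel`.
profile_from_reads <- function(reads, region, cfg, sel = NULL) {
  p1 <- region$start + 1L
  p2 <- region$end
  L <- p2 - p1 + 1L
  prof <- empty_profile(region)
  attr(prof, "region") <- region$name
  attr(prof, "chrom") <- region$chrom
  attr(prof, "RC") <- 0L
  if (is.null(reads) || length(reads$pos) == 0L) return(prof)

  if (is.null(sel)) sel <- seq_along(reads$pos)
  if (length(sel) == 0L) return(prof)
  pos <- reads$pos[sel]
  cig <- reads$cigar[sel]
  mq <- reads$mapq[sel]

  # Read count: eligible reads whose reference span overlaps the region.
  rend <- pos + GenomicAlignments::cigarWidthAlongReferenceSpace(cig) - 1L
  attr(prof, "RC") <- sum(pos <= p2 & rend >= p1)

  # Reference/query geometry per CIGAR run; D is zero-width in query space.
  refr <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cig, pos = pos, ops = c("M", "=", "X", "D"), with.ops = TRUE)
  qryr <- GenomicAlignments::cigarRangesAlongQuerySpace(
    cig, ops = c("M", "=", "X", "D"), with.ops = TRUE)
  nrun <- S4Vectors::elementNROWS(refr)
  fr <- unlist(refr, use.names = FALSE)
  fq <- unlist(qryr, use.names = FALSE)
  op <- unlist(lapply(refr, names), use.names = FALSE)
  rid <- rep(seq_along(refr), nrun)

  w <- IRanges::width(fr)
  posv <- sequence(w, from = IRanges::start(fr))
  qidx <- sequence(w, from = IRanges::start(fq))  # bogus for D runs; masked below
  isdel <- rep(op == "D", w)
  ridv <- rep(rid, w)

  inreg <- posv >= p1 & posv <= p2
  if (!any(inreg)) return(prof)
  posv <- posv[inreg]; qidx <- qidx[inreg]
  isdel <- isdel[inreg]; ridv <- ridv[inreg]

  quals <- as(reads$qual[sel], "IntegerList")
  qlen <- S4Vectors::elementNROWS(quals)
  qall <- unlist(quals, use.names = FALSE)
  qoff <- cumsum(c(0L, qlen[-length(qlen)]))
  bq <- qall[qoff[ridv] + qidx]
  bq[isdel] <- NA_integer_

  mqv <- mq[ridv]
  mq_unavail <- is.na(mqv) | mqv == 255L
  low_mq <- (!mq_unavail & mqv < cfg$mq_cutoff) | (mq_unavail & cfg$mq_cutoff > 0)

  pf <- factor(posv, levels = p1:p2)
  cnt <- function(cond) tabulate(pf[cond], nbins = L)

  COV <- tabulate(pf, nbins = L)
  hasb <- !is.na(bq)
  nbase <- cnt(hasb)
  nlowbq <- cnt(hasb & bq < cfg$bq_cutoff)
  QCOV <- cnt(hasb & bq >= cfg$bq_cutoff & !low_mq)
  nlowmq <- cnt(low_mq)

  med_by_pos <- function(v, keep) {
    out <- rep(NA_real_, L)
    if (!any(keep)) return(out)
    m <- tapply(as.numeric(v[keep]), pf[keep], stats::median)
    out[!is.na(m)] <- m[!is.na(m)]
    out
  }

  prof$COV <- COV
  prof$QCOV <- QCOV
  prof$MEDBQ <- med_by_pos(bq, hasb)
  prof$FLBQ <- ifelse(nbase > 0L, nlowbq / nbase, NA_real_)
  prof$MEDMQ <- med_by_pos(ifelse(is.na(mqv), 255, as.numeric(mqv)),
                           rep(TRUE, length(mqv)))
  prof$FLMQ <- ifelse(COV > 0L, nlowmq / COV, NA_real_)
  prof
}

#' Compute the per-base quality profile of a target region
#'
#' Walks all eligible alignments overlapping the region and returns the six
#' position-specific metrics: COV, QCOV, MEDBQ, FLBQ, MEDMQ and FLMQ (see
#' the package vignette for exact definitions). Positions are 1-based
#' inclusive genomic coordinates. Metrics whose denominator is zero at a
#' position (e.g. base-quality metrics where only deletions span) are `NA`
#' and serialise as `"."` in output files.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param region A single region: one row of [read_bed()] output, or any
#'   list with `name`, `chrom`, `start` (0-based), `end` (exclusive).
#' @param cfg A [quality_config()].
#' @return A `data.frame` with columns `pos`, `COV`, `QCOV`, `MEDBQ`,
#'   `FLBQ`, `MEDMQ`, `FLMQ` and one row per region position, carrying the
#'   region read count in `attr(, "RC")`.
#' @export
compute_profile <- function(bam, region, cfg = quality_config()) {
  reads <- fetch_region_reads(bam, region, cfg)
  profile_from_reads(reads, region, cfg)
}

#' Strand-split per-base profiles
#'
#' Computes [compute_profile()] restricted to forward reads and to reverse
#' reads, to expose strand-specific coverage or quality biases. At every
#' position the strand-split COV and QCOV sum to the unsplit values.
#'
#' @inheritParams compute_profile
#' @return A list with elements `forward` and `reverse`, each a profile
#'   `data.frame` as from [compute_profile()].
#' @export
compute_directional_profiles <- function(bam, region, cfg = quality_config()) {
  reads <- fetch_region_reads(bam, region, cfg)
  if (is.null(reads) || length(reads$pos) == 0L) {
    return(list(forward = profile_from_reads(NULL, region, cfg),
                reverse = profile_from_reads(NULL, region, cfg)))
  }
  list(forward = profile_from_reads(reads, region, cfg,
                                    sel = which(reads$strand == "+")),
       reverse = profile_from_reads(reads, region, cfg,
                                    sel = which(reads$strand == "-")))
}
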