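# Brute-force oracle: re-states every metric definition by direct nested
# iteration over read specs and positions. Deliberately naive and entirely
# separate from the pileup engine (its own CIGAR walker, its own median);
# the test suite asserts exact engine/oracle agreement.

oracle_cigar_ops <- function(cigar) {
  n <- nchar(cigar)
  lens <- integer(0); ops <- character(0)
  num <- 0L
  for (ch in strsplit(cigar, "", fixed = TRUE)[[1L]]) {
    if (ch >= "0" && ch <= "9") {
      num <- num * 10L + as.integer(ch)
    } else {
      lens <- c(lens, num); ops <- c(ops, ch); num <- 0L
    }
  }
  list(len = lens, op = ops)
}

# Per-base layout of one read: reference position and query index (NA over
# deletions) for every reference position the alignment covers.
oracle_read_layout <- function(rd) {
  co <- oracle_cigar_ops(rd$cigar)
  refpos <- integer(0); qidx <- integer(0)
  r <- rd$pos; q <- 1L
  for (k in seq_along(co$op)) {
    l <- co$len[k]
    switch(co$op[k],
      "M" = , "=" = , "X" = {
        refpos <- c(refpos, r:(r + l - 1L))
        qidx <- c(qidx, q:(q + l - 1L))
        r <- r + l; q <- q + l
      },
      "D" = {
        refpos <- c(refpos, r:(r + l - 1L))
        qidx <- c(qidx, rep(NA_integer_, l))
        r <- r + l
      },
      "N" = { r <- r + l },
      "I" = , "S" = { q <- q + l },
      "H" = , "P" = { })
  }
  list(refpos = refpos, qidx = qidx)
}

oracle_ref_span <- function(rd) {
  co <- oracle_cigar_ops(rd$cigar)
  w <- sum(co$len[co$op %in% c("M", "=", "X", "D", "N")])
  c(rd$pos, rd$pos + w - 1L)
}

oracle_eligible <- function(rd, cfg) {
  rd$mapped && !rd$secondary && !rd$supplementary && !rd$qcfail &&
    (cfg$count_duplicates || !rd$duplicate)
}

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n == 0L) return(NA_real_)
  if (n %% 2L == 1L) as.numeric(s[(n + 1L) / 2L])
  else (s[n / 2L] + s[n / 2L + 1L]) / 2
}

oracle_low_mq <- function(mq, cfg) {
  if (mq == 255L) cfg$mq_cutoff > 0 else mq < cfg$mq_cutoff
}

#' Brute-force per-base profile from read specifications
#'
#' Independent re-computation of the per-base metrics by exhaustively
#' iterating every read over every region position; used by the test suite
#' as the oracle the pileup engine must match exactly. Intended for small
#' fixtures (at most a few hundred reads).
#'
#' @param reads List of [read_spec()] objects.
#' @param region Region row/list with `name`, `chrom`, `start` (0-based),
#'   `end` (exclusive).
#' @param cfg A [quality_config()].
#' @param strand Restrict to reads on `"+"` or `"-"`; `NULL` for all.
#' @return A profile `data.frame` matching [compute_profile()] layout,
#'   with the region read count in `attr(, "RC")`.
#' @export
oracle_profile <- function(reads, region, cfg = quality_config(),
                           strand = NULL) {
  p1 <- region$start + 1L
  p2 <- region$end
  L <- p2 - p1 + 1L
  bq_at <- vector("list", L)
  mq_at <- vector("list", L)
  rc <- 0L

  for (rd in reads) {
    if (!oracle_eligible(rd, cfg)) next
    if (!is.null(strand) && rd$strand != strand) next
    if (rd$chrom != region$chrom) next
    span <- oracle_ref_span(rd)
    if (span[1L] <= p2 && span[2L] >= p1) rc <- rc + 1L
    lay <- oracle_read_layout(rd)
    for (k in seq_along(lay$refpos)) {
      p <- lay$refpos[k]
      if (p < p1 || p > p2) next
      i <- p - p1 + 1L
      b <- if (is.na(lay$qidx[k])) NA_integer_ else rd$bq[lay$qidx[k]]
      bq_at[[i]] <- c(bq_at[[i]], b)
      mq_at[[i]] <- c(mq_at[[i]], rd$mq)
    }
  }

  prof <- data.frame(pos = p1:p2, COV = 0L, QCOV = 0L, MEDBQ = NA_real_,
                     FLBQ = NA_real_, MEDMQ = NA_real_, FLMQ = NA_real_)
  for (i in seq_len(L)) {
    mqs <- mq_at[[i]]
    bqs <- bq_at[[i]]
    cov <- length(mqs)
    prof$COV[i] <- cov
    if (cov == 0L) next
    low <- vapply(mqs, oracle_low_mq, NA, cfg = cfg)
    prof$MEDMQ[i] <- oracle_median(mqs)
    prof$FLMQ[i] <- sum(low) / cov
    hasb <- !is.na(bqs)
    if (any(hasb)) {
      prof$MEDBQ[i] <- oracle_median(bqs[hasb])
      prof$FLBQ[i] <- sum(bqs[hasb] < cfg$bq_cutoff) / sum(hasb)
    }
    prof$QCOV[i] <- sum(hasb & !is.na(bqs) & bqs >= cfg$bq_cutoff & !low)
  }
  attr(prof, "region") <- region$name
  attr(prof, "chrom") <- region$chrom
  attr(prof, "RC") <- rc
  prof
}

#' Brute-force region summary from read specifications
#'
#' @inheritParams oracle_profile
#' @return A list with the region summary metrics (RC, MEDCOV, MINCOV,
#'   MEDQCOV, MINQCOV, MAXFLMQ, MAXFLBQ), computed with the oracle's own
#'   median/extrema code.
#' @export
oracle_region_summary <- function(reads, region, cfg = quality_config()) {
  prof <- oracle_profile(reads, region, cfg)
  max_def <- function(x) { x <- x[!is.na(x)]; if (length(x)) max(x) else NA_real_ }
  list(RC = attr(prof, "RC"),
       MEDCOV = oracle_median(prof$COV),
       MINCOV = min(prof$COV),
       MEDQCOV = oracle_median(prof$QCOV),
       MINQCOV = min(prof$QCOV),
       MAXFLMQ = max_def(prof$FLMQ),
       MAXFLBQ = max_def(prof$FLBQ))
}

#' Brute-force chromosome-level accounting from read specifications
#'
#' @inheritParams oracle_profile
#' @param regions Region `data.frame` (may have zero rows).
#' @param contig_order Character vector giving the output chromosome order
#'   (the BAM header order).
#' @return A `chrom_stats`-shaped list (`chrom` data.frame and `totals`).
#' @export
oracle_chrom_stats <- function(reads, regions, contig_order,
                               cfg = quality_config()) {
  rc <- rcin <- stats::setNames(integer(length(contig_order)), contig_order)
  mapped <- unmapped <- 0L
  for (rd in reads) {
    if (rd$secondary || rd$supplementary || rd$qcfail) next
    if (!cfg$count_duplicates && rd$duplicate) next
    if (!rd$mapped) { unmapped <- unmapped + 1L; next }
    mapped <- mapped + 1L
    rc[rd$chrom] <- rc[rd$chrom] + 1L
    span <- oracle_ref_span(rd)
    hit <- FALSE
    for (j in seq_len(nrow(regions))) {
      if (regions$chrom[j] != rd$chrom) next
      if (span[1L] <= regions$end[j] && span[2L] >= regions$start[j] + 1L) {
        hit <- TRUE
        break
      }
    }
    if (hit) rcin[rd$chrom] <- rcin[rd$chrom] + 1L
  }
  list(chrom = data.frame(chrom = contig_order, RC = as.integer(rc),
                          RCIN = as.integer(rcin),
                          RCOUT = as.integer(rc - rcin),
                          stringsAsFactors = FALSE),
       totals = c(mapped = mapped, unmapped = unmapped,
                  total = mapped + unmapped))
}
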