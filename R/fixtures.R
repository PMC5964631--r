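# Synthetic BAM fixture generation. Fixtures are written as real sorted,
# indexed BAM files so flag handling, index access and pileup semantics are
# exercised end-to-end, not mocked.

cigar_query_len <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  if (!length(toks) || nchar(paste(toks, collapse = "")) != nchar(cigar))
    stop("invalid CIGAR: ", cigar)
  len <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  sum(len[op %in% c("M", "I", "S", "=", "X")])
}

cigar_ref_len <- function(cigar) {
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1L]]
  len <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  sum(len[op %in% c("M", "D", "N", "=", "X")])
}

#' Specify one synthetic read
#'
#' Describes a single alignment record for [build_bam()]: position, CIGAR,
#' per-base Phred base qualities, mapping quality, strand and SAM flag
#' toggles. The base-quality vector must have exactly one entry per
#' sequence-consuming CIGAR base (M/I/S/=/X).
#'
#' @param chrom Chromosome name (ignored for unmapped reads).
#' @param pos 1-based leftmost aligned position.
#' @param cigar CIGAR string (e.g. `"40M20D60M"`).
#' @param bq Integer vector of Phred base qualities (0..93).
#' @param mq Mapping quality (0..255; 255 = unavailable).
#' @param strand `"+"` or `"-"`.
#' @param duplicate,secondary,supplementary,qcfail,mapped SAM flag toggles.
#' @param name Read name; auto-generated when `NULL`.
#' @return A list of class `read_spec`.
#' @export
read_spec <- function(chrom, pos, cigar, bq, mq = 60L, strand = "+",
                      duplicate = FALSE, secondary = FALSE,
                      supplementary = FALSE, qcfail = FALSE, mapped = TRUE,
                      name = NULL) {
  bq <- as.integer(bq)
  if (any(is.na(bq)) || any(bq < 0L) || any(bq > 93L))
    stop("base qualities must be integers in 0..93")
  if (mapped) {
    qlen <- cigar_query_len(cigar)
    if (length(bq) != qlen)
      stop(sprintf("BQ vector length (%d) does not match CIGAR query length (%d) for %s",
                   length(bq), qlen, cigar))
  }
  structure(list(chrom = chrom, pos = as.integer(pos), cigar = cigar,
                 bq = bq, mq = as.integer(mq), strand = strand,
                 duplicate = isTRUE(duplicate), secondary = isTRUE(secondary),
                 supplementary = isTRUE(supplementary),
                 qcfail = isTRUE(qcfail), mapped = isTRUE(mapped),
                 name = name),
            class = "read_spec")
}

read_spec_flag <- function(rd) {
  fl <- 0L
  if (!rd$mapped) fl <- fl + 4L
  if (rd$strand == "-") fl <- fl + 16L
  if (rd$secondary) fl <- fl + 256L
  if (rd$qcfail) fl <- fl + 512L
  if (rd$duplicate) fl <- fl + 1024L
  if (rd$supplementary) fl <- fl + 2048L
  fl
}

#' Build a sorted, indexed BAM from read specifications
#'
#' Serialises the specs to SAM, then converts, coordinate-sorts and indexes
#' via htslib. Sequences are all-`A` placeholders (the metrics depend only
#' on qualities and geometry).
#'
#' @param reads List of [read_spec()] objects (any order).
#' @param path Destination BAM path (`.bam`).
#' @param contigs Named integer vector of contig lengths for the header;
#'   derived from the reads (with margin) when `NULL`. Include every
#'   chromosome the companion BED uses.
#' @return The BAM path, invisibly.
#' @export
build_bam <- function(reads, path, contigs = NULL) {
  stopifnot(grepl("\\.bam$", path))
  if (is.null(contigs)) {
    contigs <- integer(0)
    for (rd in reads) {
      if (!rd$mapped) next
      e <- rd$pos + cigar_ref_len(rd$cigar) - 1L
      contigs[rd$chrom] <- max(contigs[rd$chrom], e + 1000L, na.rm = TRUE)
    }
  }
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), as.integer(contigs)))
  for (i in seq_along(reads)) {
    rd <- reads[[i]]
    qname <- if (!is.null(rd$name)) rd$name else sprintf("read%05d", i)
    seq <- strrep("A", length(rd$bq))
    qual <- rawToChar(as.raw(rd$bq + 33L))
    if (rd$mapped) {
      if (!rd$chrom %in% names(contigs))
        stop("read on contig absent from header: ", rd$chrom)
      lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                                qname, read_spec_flag(rd), rd$chrom, rd$pos,
                                rd$mq, rd$cigar, seq, qual))
    } else {
      lines <- c(lines, sprintf("%s\t%d\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                                qname, read_spec_flag(rd), seq, qual))
    }
  }
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  writeLines(lines, sam)
  Rsamtools::asBam(sam, sub("\\.bam$", "", path), overwrite = TRUE,
                   indexDestination = TRUE)
  invisible(path)
}

# Helper: n full-span reads over [p1, p2] (1-based inclusive) with uniform
# BQ, cycling alignment start positions so coverage is not ragged.
full_span_reads <- function(n, chrom, p1, p2, read_len, mq, bq_val,
                            strand = NULL, dup = FALSE) {
  if (read_len < p2 - p1 + 1L) stop("read_len shorter than span")
  starts_lo <- p2 - read_len + 1L
  starts <- rep(seq(starts_lo, p1, by = 2L), length.out = n)
  lapply(seq_len(n), function(i) {
    read_spec(chrom, starts[i], sprintf("%dM", read_len),
              rep(bq_val, read_len), mq = mq,
              strand = if (is.null(strand)) c("+", "-")[1L + i %% 2L] else strand,
              duplicate = dup)
  })
}

#' Generate the deterministic multi-region panel fixture
#'
#' Builds a small synthetic gene panel exercising the main quality
#' pathologies seen in targeted sequencing, with the expected PASS/FLAG
#' status (under a MINQCOV >= 50 rule) recorded alongside:
#' \itemize{
#'   \item `BRCA1_1` — well covered, good qualities (PASS); includes
#'     duplicate-marked and low-BQ reads.
#'   \item `PMS2_12` — high raw coverage but mostly low-MQ reads, the
#'     pseudogene-homology pattern: MINCOV high, MINQCOV well below 50
#'     (FLAG).
#'   \item `MLH1_5` — zero coverage (FLAG; whole-region poor interval).
#'   \item `GENE2_1` — strand-biased coverage, still passing (PASS).
#'   \item `GENE3_7` — a 20 bp deletion carried by most reads drops QCOV
#'     below the poor-interval cutoff mid-region (FLAG).
#' }
#' All names, transcripts and coordinates are synthetic. Generation is pure
#' in `seed` (the seed only jitters base qualities of good reads within the
#' passing range).
#'
#' @param seed Integer seed.
#' @param dir Directory to create the fixture in.
#' @return A list with paths (`bam`, `bed`, `tx_db`, `config_ini`), the
#'   `read_spec` list (`reads`), the region table (`regions`), the flag
#'   `criteria`, the [quality_config()] used (`cfg`) and
#'   `expected_status`, a named character vector of PASS/FLAG per region.
#' @export
make_panel_fixture <- function(seed = 1L, dir = tempfile("panelfix")) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reads <- list()
  jitter_bq <- function(len) sample(30:40, len, replace = TRUE)

  # BRCA1_1: 1:1000-1100 (BED), well covered.
  reads <- c(reads,
             lapply(full_span_reads(60, "1", 1001L, 1100L, 150L, 60L, 35L),
                    function(rd) { rd$bq <- jitter_bq(150L); rd }),
             full_span_reads(5, "1", 1001L, 1100L, 150L, 60L, 5L),
             full_span_reads(10, "1", 1001L, 1100L, 150L, 60L, 35L, dup = TRUE))

  # PMS2_12: 1:2000-2120, high COV / low QCOV (pseudogene-homology pattern).
  reads <- c(reads,
             full_span_reads(35, "1", 2001L, 2120L, 200L, 60L, 35L),
             lapply(seq_len(170), function(i) {
               read_spec("1", 1921L + (i %% 60L), "200M", rep(35L, 200L),
                         mq = i %% 10L, strand = c("+", "-")[1L + i %% 2L])
             }))

  # GENE2_1: 2:500-560, strand-biased.
  reads <- c(reads,
             full_span_reads(60, "2", 501L, 560L, 100L, 60L, 35L, strand = "+"),
             full_span_reads(8, "2", 501L, 560L, 100L, 60L, 35L, strand = "-"))

  # GENE3_7: 2:1500-1560, deletion 1521..1540 carried by 45/57 reads.
  reads <- c(reads,
             full_span_reads(12, "2", 1501L, 1560L, 150L, 60L, 35L),
             lapply(seq_len(45), function(i) {
               read_spec("2", 1481L, "40M20D60M", rep(35L, 100L), mq = 60L,
                         strand = c("+", "-")[1L + i %% 2L])
             }))

  # Off-target and unmapped reads.
  reads <- c(reads,
             lapply(seq_len(30), function(i)
               read_spec("1", 5000L + 3L * i, "100M", rep(35L, 100L), mq = 60L)),
             lapply(seq_len(20), function(i)
               read_spec("2", 3000L + 5L * i, "100M", rep(35L, 100L), mq = 60L)),
             lapply(seq_len(5), function(i)
               read_spec("*", 0L, "*", rep(35L, 50L), mapped = FALSE)))

  bam <- file.path(dir, "panel.bam")
  build_bam(reads, bam, contigs = c("1" = 10000L, "2" = 10000L))

  bed <- file.path(dir, "panel.bed")
  writeLines(c("1\t1000\t1100\tBRCA1_1",
               "1\t2000\t2120\tPMS2_12",
               "1\t3000\t3050\tMLH1_5",
               "2\t500\t560\tGENE2_1",
               "2\t1500\t1560\tGENE3_7"), bed)

  tx_db <- file.path(dir, "transcripts_synthetic.tsv")
  writeLines(c(
    # id  gene  chrom strand cds_start cds_end exon_starts exon_ends
    "TX_PMS2\tPMS2\t1\t-\t1910\t2250\t1900,1990,2200\t1960,2130,2260",
    "TX_G3\tGENE3\t2\t+\t1490\t1650\t1480,1600\t1565,1700"), tx_db)

  config_ini <- file.path(dir, "run.ini")
  writeLines(c("[quality]", "bq_cutoff = 10", "mq_cutoff = 20",
               "qcov_poor_cutoff = 15", "count_duplicates = true",
               "", "[flags]", "MINQCOV_min = 50",
               "", "[outputs]", "profiles = true", "poor = true",
               sprintf("transcript_db = %s", tx_db)), config_ini)

  list(bam = bam, bed = bed, tx_db = tx_db, config_ini = config_ini,
       reads = reads,
       regions = read_bed(bed),
       criteria = flag_criteria(MINQCOV_min = 50),
       cfg = quality_config(),
       expected_status = c(BRCA1_1 = "PASS", PMS2_12 = "FLAG",
                           MLH1_5 = "FLAG", GENE2_1 = "PASS",
                           GENE3_7 = "FLAG"))
}

#' Generate a randomized small fixture for equivalence testing
#'
#' Draws up to three target regions over two synthetic contigs and up to
#' ~100 reads whose CIGARs cover plain matches, internal deletions,
#' internal insertions and soft-clip variants, with base and mapping
#' qualities straddling the default cutoffs (including MQ 255), plus a few
#' off-target and unmapped reads. The reads are written to a real sorted,
#' indexed BAM. Pure in `seed`.
#'
#' @param seed Integer seed.
#' @param dir Directory to create the fixture in.
#' @return A list with `reads` (the [read_spec()] list), `regions` (region
#'   `data.frame`), `bam` (path) and `dir`.
#' @export
random_fixture <- function(seed, dir = tempfile("randfix")) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  random_read <- function(chrom, center) {
    shape <- sample(c("M", "MDM", "MIM", "SM", "MS", "SMS"), 1L)
    m1 <- sample(5:30, 1L)
    m2 <- sample(5:30, 1L)
    l <- sample(1:8, 1L)
    s1 <- sample(1:6, 1L)
    s2 <- sample(1:6, 1L)
    cigar <- switch(shape,
      M = sprintf("%dM", m1),
      MDM = sprintf("%dM%dD%dM", m1, l, m2),
      MIM = sprintf("%dM%dI%dM", m1, l, m2),
      SM = sprintf("%dS%dM", s1, m1),
      MS = sprintf("%dM%dS", m1, s2),
      SMS = sprintf("%dS%dM%dS", s1, m1, s2))
    read_spec(chrom,
              pos = max(1L, center + sample(-40:40, 1L)),
              cigar = cigar,
              bq = sample(0:45, cigar_query_len(cigar), replace = TRUE),
              mq = sample(c(0L, 5L, 10L, 19L, 20L, 30L, 60L, 255L), 1L),
              strand = sample(c("+", "-"), 1L),
              duplicate = stats::runif(1) < 0.15,
              qcfail = stats::runif(1) < 0.05,
              secondary = stats::runif(1) < 0.05)
  }

  n_regions <- sample(1:3, 1L)
  chroms <- sample(c("c1", "c2"), n_regions, replace = TRUE)
  starts <- sample(seq(100L, 2000L, by = 200L), n_regions)
  lens <- sample(20:60, n_regions, replace = TRUE)
  regions <- data.frame(name = sprintf("G%d_%d", seq_len(n_regions), seq_len(n_regions)),
                        chrom = chroms, start = starts, end = starts + lens,
                        length = lens, stringsAsFactors = FALSE)

  n_reads <- sample(10:90, 1L)
  reads <- lapply(seq_len(n_reads), function(i) {
    j <- sample(n_regions, 1L)
    random_read(regions$chrom[j], regions$start[j] + regions$length[j] %/% 2L)
  })
  reads <- c(reads,
             lapply(seq_len(sample(0:5, 1L)), function(i)
               random_read(sample(c("c1", "c2"), 1L), 5000L)),
             lapply(seq_len(sample(0:3, 1L)), function(i)
               read_spec("*", 0L, "*", rep(30L, 10L), mapped = FALSE)))

  bam <- file.path(dir, "fix.bam")
  build_bam(reads, bam, contigs = c(c1 = 8000L, c2 = 8000L))
  list(reads = reads, regions = regions, bam = bam, dir = dir)
}
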