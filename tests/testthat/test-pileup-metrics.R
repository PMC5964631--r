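# Unit tests of the per-base metric engine on hand-enumerable read sets.

simple_bam <- function(reads, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  bam <- file.path(dir, "reads.bam")
  build_bam(reads, bam, contigs = c("1" = 5000L, "2" = 5000L))
  bam
}

test_that("three-read pileup matches hand enumeration", {
  # (MQ, BQ) per read at every position: (60,30), (60,5), (0,30)
  reads <- list(read_spec("1", 101L, "5M", rep(30L, 5), mq = 60L),
                read_spec("1", 101L, "5M", rep(5L, 5), mq = 60L, strand = "-"),
                read_spec("1", 101L, "5M", rep(30L, 5), mq = 0L))
  bam <- simple_bam(reads)
  p <- compute_profile(bam, list(name = "R", chrom = "1", start = 100L, end = 105L))
  expect_equal(p$COV, rep(3L, 5))
  expect_equal(p$QCOV, rep(1L, 5))
  expect_equal(p$FLBQ, rep(1 / 3, 5))
  expect_equal(p$FLMQ, rep(1 / 3, 5))
  expect_equal(p$MEDBQ, rep(30, 5))
  expect_equal(p$MEDMQ, rep(60, 5))
  expect_equal(attr(p, "RC"), 3L)
})

test_that("uncovered positions have zero counts and undefined ratios", {
  reads <- list(read_spec("1", 101L, "5M", rep(30L, 5)))
  bam <- simple_bam(reads)
  p <- compute_profile(bam, list(name = "R", chrom = "1", start = 200L, end = 205L))
  expect_equal(p$COV, rep(0L, 5))
  expect_equal(p$QCOV, rep(0L, 5))
  expect_true(all(is.na(p$MEDBQ)) && all(is.na(p$FLBQ)))
  expect_true(all(is.na(p$MEDMQ)) && all(is.na(p$FLMQ)))
})

test_that("deletion-spanning reads cover but contribute no base", {
  reads <- list(read_spec("1", 101L, "2M2D2M", rep(30L, 4), mq = 60L))
  bam <- simple_bam(reads)
  p <- compute_profile(bam, list(name = "R", chrom = "1", start = 100L, end = 106L))
  del <- p$pos %in% c(103L, 104L)
  expect_equal(p$COV, rep(1L, 6))
  expect_equal(p$QCOV[del], c(0L, 0L))
  expect_equal(p$QCOV[!del], rep(1L, 4))
  expect_true(all(is.na(p$MEDBQ[del])) && all(is.na(p$FLBQ[del])))
  expect_equal(p$MEDMQ[del], c(60, 60))
  expect_equal(p$FLMQ[del], c(0, 0))
})

test_that("insertions and skips do not cover reference positions", {
  reads <- list(read_spec("1", 101L, "2M3I2M", rep(30L, 7)),
                read_spec("1", 101L, "2M2N2M", rep(30L, 4)))
  bam <- simple_bam(reads)
  p <- compute_profile(bam, list(name = "R", chrom = "1", start = 100L, end = 106L))
  # insertion read covers 101-104 contiguously; N read covers 101,102,105,106
  expect_equal(p$COV, c(2L, 2L, 1L, 1L, 1L, 1L))
  expect_equal(p$QCOV, p$COV)
})

test_that("soft-clipped bases neither cover nor shift the aligned bases", {
  reads <- list(read_spec("1", 101L, "3S4M2S", c(rep(2L, 3), 30L, 5L, 30L, 30L, rep(2L, 2))))
  bam <- simple_bam(reads)
  p <- compute_profile(bam, list(name = "R", chrom = "1", start = 98L, end = 106L))
  expect_equal(p$COV, c(0L, 0L, 1L, 1L, 1L, 1L, 0L, 0L))
  # the aligned BQs are 30,5,30,30 -> low-BQ base sits at position 102
  expect_equal(p$FLBQ[p$pos == 102L], 1)
  expect_equal(p$FLBQ[p$pos %in% c(101L, 103L, 104L)], rep(0, 3))
})

test_that("secondary, supplementary and QC-fail reads are never counted", {
  reads <- list(read_spec("1", 101L, "5M", rep(30L, 5)),
                read_spec("1", 101L, "5M", rep(30L, 5), secondary = TRUE),
                read_spec("1", 101L, "5M", rep(30L, 5), supplementary = TRUE),
                read_spec("1", 101L, "5M", rep(30L, 5), qcfail = TRUE))
  bam <- simple_bam(reads)
  p <- compute_profile(bam, list(name = "R", chrom = "1", start = 100L, end = 105L))
  expect_equal(p$COV, rep(1L, 5))
  expect_equal(attr(p, "RC"), 1L)
})

test_that("mapping quality 255 fails any positive cutoff but passes zero", {
  reads <- list(read_spec("1", 101L, "5M", rep(30L, 5), mq = 255L))
  bam <- simple_bam(reads)
  p <- compute_profile(bam, list(name = "R", chrom = "1", start = 100L, end = 105L),
                       quality_config(mq_cutoff = 20))
  expect_equal(p$QCOV, rep(0L, 5))
  expect_equal(p$FLMQ, rep(1, 5))
  p0 <- compute_profile(bam, list(name = "R", chrom = "1", start = 100L, end = 105L),
                        quality_config(mq_cutoff = 0, bq_cutoff = 0))
  expect_equal(p0$QCOV, rep(1L, 5))
  expect_equal(p0$FLMQ, rep(0, 5))
})

test_that("quality comparisons are inclusive at the cutoff", {
  reads <- list(read_spec("1", 101L, "3M", rep(10L, 3), mq = 20L),
                read_spec("1", 101L, "3M", rep(9L, 3), mq = 19L))
  bam <- simple_bam(reads)
  p <- compute_profile(bam, list(name = "R", chrom = "1", start = 100L, end = 103L),
                       quality_config(bq_cutoff = 10, mq_cutoff = 20))
  expect_equal(p$QCOV, rep(1L, 3))   # BQ=10/MQ=20 passes, BQ=9/MQ=19 fails
  expect_equal(p$FLBQ, rep(1 / 2, 3))
  expect_equal(p$FLMQ, rep(1 / 2, 3))
})

test_that("even-sized pileups use the mean-of-middle median", {
  reads <- list(read_spec("1", 101L, "2M", c(10L, 10L), mq = 10L),
                read_spec("1", 101L, "2M", c(21L, 21L), mq = 30L))
  bam <- simple_bam(reads)
  p <- compute_profile(bam, list(name = "R", chrom = "1", start = 100L, end = 102L))
  expect_equal(p$MEDBQ, c(15.5, 15.5))
  expect_equal(p$MEDMQ, c(20, 20))
})

test_that("strand-split profiles partition the unsplit profile", {
  reads <- list(read_spec("1", 101L, "5M", rep(30L, 5), strand = "+"),
                read_spec("1", 102L, "5M", rep(30L, 5), strand = "+"),
                read_spec("1", 103L, "5M", rep(8L, 5), strand = "-", mq = 5L))
  bam <- simple_bam(reads)
  region <- list(name = "R", chrom = "1", start = 100L, end = 110L)
  p <- compute_profile(bam, region)
  d <- compute_directional_profiles(bam, region)
  expect_equal(d$forward$COV + d$reverse$COV, p$COV)
  expect_equal(d$forward$QCOV + d$reverse$QCOV, p$QCOV)
  expect_equal(d$forward$COV[d$forward$pos == 103L], 2L)
  expect_equal(d$reverse$COV[d$reverse$pos == 103L], 1L)
})

test_that("all-forward fixtures give an empty reverse profile", {
  reads <- list(read_spec("1", 101L, "5M", rep(30L, 5), strand = "+"))
  bam <- simple_bam(reads)
  d <- compute_directional_profiles(bam, list(name = "R", chrom = "1",
                                              start = 100L, end = 105L))
  expect_equal(d$reverse$COV, rep(0L, 5))
  expect_true(all(is.na(d$reverse$MEDBQ)))
})

test_that("regions on contigs missing from the BAM header warn and zero out", {
  reads <- list(read_spec("1", 101L, "5M", rep(30L, 5)))
  bam <- simple_bam(reads)
  expect_warning(
    p <- compute_profile(bam, list(name = "R", chrom = "chr1",
                                   start = 100L, end = 105L)),
    "absent from BAM header.*'1'")
  expect_equal(p$COV, rep(0L, 5))
})

test_that("a missing BAM index is a hard error", {
  dir <- withr::local_tempdir()
  bam <- file.path(dir, "noindex.bam")
  build_bam(list(read_spec("1", 101L, "5M", rep(30L, 5))), bam,
            contigs = c("1" = 5000L))
  file.remove(paste0(bam, ".bai"))
  expect_error(compute_profile(bam, list(name = "R", chrom = "1",
                                         start = 100L, end = 105L)),
               "index")
})
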