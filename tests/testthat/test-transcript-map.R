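mk_qcov_profile <- function(qcov, name = "R", chrom = "1", pos1 = 101L) {
  p <- data.frame(pos = seq(pos1, length.out = length(qcov)),
                  COV = as.integer(qcov) + 5L, QCOV = as.integer(qcov),
                  MEDBQ = 30, FLBQ = 0, MEDMQ = 60, FLMQ = 0)
  attr(p, "region") <- name
  attr(p, "chrom") <- chrom
  p
}

test_that("poor intervals are the maximal runs below the cutoff", {
  p <- mk_qcov_profile(c(20L, 3L, 4L, 20L, 1L))
  iv <- find_poor_intervals(p, quality_config(qcov_poor_cutoff = 15))
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$start, c(102L, 105L))
  expect_equal(iv$end, c(103L, 105L))
  expect_equal(iv$min_qcov, c(3L, 1L))

  expect_equal(nrow(find_poor_intervals(mk_qcov_profile(rep(20L, 5)))), 0L)

  all_poor <- find_poor_intervals(mk_qcov_profile(rep(2L, 5)))
  expect_equal(nrow(all_poor), 1L)
  expect_equal(c(all_poor$start, all_poor$end), c(101L, 105L))
})

test_that("poor intervals tile the region: complement is exactly QCOV >= cutoff", {
  for (seed in 1:20) {
    set.seed(seed)
    qcov <- sample(0:30, 40, replace = TRUE)
    p <- mk_qcov_profile(qcov)
    iv <- find_poor_intervals(p, quality_config(qcov_poor_cutoff = 15))
    in_poor <- rep(FALSE, 40)
    for (i in seq_len(nrow(iv)))
      in_poor[p$pos >= iv$start[i] & p$pos <= iv$end[i]] <- TRUE
    expect_identical(in_poor, qcov < 15)
  }
})

# Toy plus-strand transcript: exons 101-110 and 121-130 (1-based inclusive),
# first coding base at 104, last at 126. Expected c. labels below were
# enumerated by hand, position by position.
plus_tx_db <- function(path) {
  writeLines("TXP\tGENEP\t1\t+\t104\t126\t100,120\t110,130", path)
  load_transcript_db(path)
}

test_that("plus-strand c. mapping matches the hand-built per-base table", {
  db <- plus_tx_db(withr::local_tempfile(fileext = ".tsv"))
  tx <- db$transcripts[[1]]
  expected <- c(
    "101" = "c.-3", "102" = "c.-2", "103" = "c.-1",
    "104" = "c.1", "105" = "c.2", "106" = "c.3", "107" = "c.4",
    "108" = "c.5", "109" = "c.6", "110" = "c.7",
    # intron of length 10: first half anchors upstream, second half downstream
    "111" = "c.7+1", "112" = "c.7+2", "113" = "c.7+3", "114" = "c.7+4",
    "115" = "c.7+5", "116" = "c.8-5", "117" = "c.8-4", "118" = "c.8-3",
    "119" = "c.8-2", "120" = "c.8-1",
    "121" = "c.8", "122" = "c.9", "123" = "c.10", "124" = "c.11",
    "125" = "c.12", "126" = "c.13",
    "127" = "c.*1", "128" = "c.*2", "129" = "c.*3", "130" = "c.*4")
  got <- vapply(101:130, genomic_to_transcript, "", tx = tx)
  expect_equal(unname(got), unname(expected))
  expect_equal(genomic_to_transcript(100L, tx), "out-of-transcript")
  expect_equal(genomic_to_transcript(131L, tx), "out-of-transcript")
})

# Toy minus-strand transcript: exons 201-210 and 221-230; transcript runs
# 230 -> 201; first coding base (transcript 5') at genomic 227, last at 204.
minus_tx_db <- function(path) {
  writeLines("TXM\tGENEM\t1\t-\t204\t227\t200,220\t210,230", path)
  load_transcript_db(path)
}

test_that("minus-strand c. mapping matches the hand-built per-base table", {
  db <- minus_tx_db(withr::local_tempfile(fileext = ".tsv"))
  tx <- db$transcripts[[1]]
  expected <- c(
    "230" = "c.-3", "229" = "c.-2", "228" = "c.-1",
    "227" = "c.1", "226" = "c.2", "225" = "c.3", "224" = "c.4",
    "223" = "c.5", "222" = "c.6", "221" = "c.7",
    "220" = "c.7+1", "219" = "c.7+2", "218" = "c.7+3", "217" = "c.7+4",
    "216" = "c.7+5", "215" = "c.8-5", "214" = "c.8-4", "213" = "c.8-3",
    "212" = "c.8-2", "211" = "c.8-1",
    "210" = "c.8", "209" = "c.9", "208" = "c.10", "207" = "c.11",
    "206" = "c.12", "205" = "c.13", "204" = "c.14",
    "203" = "c.*1", "202" = "c.*2", "201" = "c.*3")
  got <- vapply(as.integer(names(expected)), genomic_to_transcript, "", tx = tx)
  expect_equal(unname(got), unname(expected))
  expect_equal(genomic_to_transcript(200L, tx), "out-of-transcript")
  expect_equal(genomic_to_transcript(231L, tx), "out-of-transcript")
})

test_that("c. mapping is injective over exonic positions", {
  db <- minus_tx_db(withr::local_tempfile(fileext = ".tsv"))
  tx <- db$transcripts[[1]]
  exonic <- c(201:210, 221:230)
  labels <- vapply(exonic, genomic_to_transcript, "", tx = tx)
  expect_equal(anyDuplicated(labels), 0L)
})

test_that("transcript database loading validates its format", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("TX1\tG\t1\t+\t104\t126\t100,120\t110", f)  # ragged exon lists
  expect_error(load_transcript_db(f), "line 1")
  writeLines("TX1\tG\t1\t?\t104\t126\t100,120\t110,130", f)
  expect_error(load_transcript_db(f), "strand")
  writeLines("TX1\tG\t1\t+\t104\t200\t100,120\t110,130", f)  # CDS outside exons
  expect_error(load_transcript_db(f), "CDS")
  writeLines("TX1\tG\t1\t+\t104\t126", f)
  expect_error(load_transcript_db(f), "8 tab-separated")
})

test_that("overlap queries return all and only overlapping transcripts", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TX1\tG\t1\t+\t104\t126\t100,120\t110,130",
               "TX2\tG\t1\t+\t105\t125\t100,118\t112,130",
               "TXZ\tH\t2\t+\t104\t126\t100,120\t110,130"), f)
  db <- load_transcript_db(f)
  hits <- transcripts_overlapping(db, "1", 105L, 107L)
  expect_setequal(vapply(hits, `[[`, "", "id"), c("TX1", "TX2"))
  expect_length(transcripts_overlapping(db, "1", 500L, 600L), 0L)
  expect_length(transcripts_overlapping(db, "3", 105L, 107L), 0L)
})

test_that("poor-interval annotation lists every overlapping transcript", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("TX1\tG\t1\t+\t104\t126\t100,120\t110,130",
               "TX2\tG\t1\t+\t105\t125\t100,118\t112,130"), f)
  db <- load_transcript_db(f)
  poor <- data.frame(region = "R", chrom = "1", start = 105L, end = 107L,
                     min_qcov = 2L, stringsAsFactors = FALSE)
  ann <- annotate_poor_intervals(poor, db)
  expect_match(ann$transcripts, "TX1\\(G\\):c\\.2_c\\.4")
  expect_match(ann$transcripts, "TX2\\(G\\):c\\.1_c\\.3")
  expect_equal(length(strsplit(ann$transcripts, ";")[[1]]), 2L)

  # no database: annotation column present but empty
  ann0 <- annotate_poor_intervals(poor, NULL)
  expect_equal(ann0$transcripts, "")
})
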