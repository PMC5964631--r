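# Shared helpers for the suite. Randomised fixtures come from the
# package's own generator (panelqc::random_fixture); everything here is
# assertion plumbing.

random_fixture <- panelqc::random_fixture

# Convenience: region list from a regions data.frame row.
region_row <- function(regions, i) as.list(regions[i, ])

expect_profiles_identical <- function(p, o, label = "") {
  expect_identical(p$COV, o$COV, label = paste(label, "COV"))
  expect_identical(p$QCOV, o$QCOV, label = paste(label, "QCOV"))
  expect_equal(p$MEDBQ, o$MEDBQ, label = paste(label, "MEDBQ"))
  expect_equal(p$FLBQ, o$FLBQ, label = paste(label, "FLBQ"))
  expect_equal(p$MEDMQ, o$MEDMQ, label = paste(label, "MEDMQ"))
  expect_equal(p$FLMQ, o$FLMQ, label = paste(label, "FLMQ"))
}
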