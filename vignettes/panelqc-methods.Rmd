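---
title: "Quality evaluation of targeted sequencing panels: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality evaluation of targeted sequencing panels: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelqc)
```

## The problem

Variant calling in clinical panel sequencing fails quietly in two ways:
false negatives where depth of coverage is insufficient, and both false
negatives and false positives where reads are present but unreliable —
systematically mis-mapped over segmental duplications and pseudogenes, or
carrying low-confidence base calls in difficult sequence contexts. Raw
depth alone distinguishes neither. `panelqc` therefore evaluates three
Phred-scored quantities jointly — depth of coverage, base quality (BQ) and
mapping quality (MQ) — and reduces them to a *quality coverage* (QCOV): the
number of reads at a position that would actually support a confident call.

## Per-base model

For each position $p$ of a target region, over all eligible reads
(mapped, primary, not supplementary, not QC-fail; duplicate-marked reads
included or excluded by a toggle):

* $\mathrm{COV}(p)$ — reads whose alignment covers $p$, i.e. place an
  aligned base (CIGAR `M`/`=`/`X`) or a spanning deletion (`D`) at $p$.
  Soft-clipped bases and `N` skips do not cover: an `N` gap denotes absent
  sequence (e.g. splicing), whereas a `D` is an allele of the covering read.
* $\mathrm{MEDBQ}(p)$, $\mathrm{FLBQ}(p)$ — median and low fraction of the
  BQs of read bases aligned to $p$. Deletion-spanning reads contribute no
  base, so they enter neither statistic.
* $\mathrm{MEDMQ}(p)$, $\mathrm{FLMQ}(p)$ — median and low fraction of the
  MQs of *all* covering reads, deletion-spanning reads included (they do
  cover the position, and their mapping confidence is exactly what is in
  question over homologous regions).
* $\mathrm{QCOV}(p)$ — covering reads with $MQ \ge$ `mq_cutoff` that
  contribute an aligned base with $BQ \ge$ `bq_cutoff`. A deletion-spanning
  read can never satisfy the BQ condition (there is no base), so it counts
  toward COV but not QCOV; this is deliberate — a deletion allele does not
  support a reference-confirming call at that base.

Comparisons are inclusive: a read *passes* at the cutoff and "low" means
strictly below. The defaults (`bq_cutoff` 10, `mq_cutoff` 20,
`qcov_poor_cutoff` 15) correspond to the conventional "good quality"
operating point for Illumina panel data: MQ 20 is a 1% mis-mapping
probability, BQ 10 a 10% base-error probability, and 15 good reads is a
common floor for confident heterozygote detection. A mapping quality
recorded as 255 means "unavailable" in the SAM specification; it fails any
positive MQ cutoff and is counted in FLMQ's numerator, because an unknown
mapping confidence must not silently pass a clinical threshold.

Medians of even-sized multisets are the mean of the two middle values.
Ratios with zero denominators are undefined, kept as `NA` internally and
serialised as `"."`; a position covered only by deletion-spanning reads has
defined MQ metrics but undefined BQ metrics.

Mates of the same fragment overlapping a position are counted as two
independent reads. Fragment-aware de-duplication of overlapping mates is a
known refinement and an explicit non-goal here; the metrics are defined at
read level.

## Region summaries and flagging

Per region the profile is reduced to RC (eligible reads overlapping the
region by at least one reference base — computed from the read list, since
a fully soft-clipped read overlaps while covering nothing), MEDCOV, MINCOV,
MEDQCOV, MINQCOV, MAXFLMQ and MAXFLBQ. Any of these can be constrained by a
minimum or maximum threshold; a region is FLAG when at least one constraint
fails, with the failing metrics listed, else PASS. The flagship criterion
in practice is a floor on MINQCOV: *every* base of the region must be
covered by at least that many good-quality reads.

Undefined summary values need a rule the user never has to think about:
an undefined metric **passes** a maximum bound (there is no evidence of low
quality — e.g. MAXFLBQ over a zero-coverage region) and **fails** a minimum
bound (there is no evidence of sufficient coverage). Both choices are the
conservative ones for clinical review.

Fixed output precision (medians to 1 decimal, fractions to 3) keeps the
tab-separated outputs diffable across runs; statuses depend on the
full-precision values, not the printed ones.

## Chromosome accounting and poor intervals

To quantify how much sequencing is not usable for on-target calling, reads
are accounted per chromosome: RC (eligible mapped reads), RCIN (reference
span — including deletions and skips — overlaps at least one target region
on that chromosome) and RCOUT, with RCIN + RCOUT = RC by construction, plus
genome-wide mapped/unmapped/total counts. Only primary alignments are
counted, so each template end contributes exactly one count; unmapped reads
appear only in the totals.

Maximal runs of positions with QCOV below `qcov_poor_cutoff` are reported
as poor-quality intervals with their minimum QCOV. When a transcript
database is supplied, each interval is localised on *all* overlapping
transcripts in simplified transcript coordinates: `c.N` for coding bases
counted 5'→3' on the transcript strand, `c.-N`/`c.*N` for UTRs, and
`c.N±k` for intronic positions anchored to the nearer exon boundary (5'
half of the intron anchors upstream as `+k`, 3' half downstream as `-k`,
the odd-intron midpoint anchoring upstream). This is a deliberate
simplification for localisation — no repeat normalisation, protein
notation, or non-coding `n.` coordinates. Interval end points beyond the
transcript span are clamped to it, so a partially overlapping transcript
still yields an informative range. The transcript file format is a plain
TSV (documented in `?load_transcript_db`) that an export script against any
annotation source can produce; fetching annotation releases is out of
scope.

## Coordinate conventions

BED input is 0-based half-open (the standard). Every output position —
per-base profile rows, region start/end in the regions file, poor-interval
bounds — is 1-based inclusive genomic, matching genome-browser and clinical
reporting conventions. Chromosome-name dialects (`chr7` vs `7`) are *not*
auto-reconciled: a BED region on a contig absent from the BAM header is
kept, reported with all-zero coverage, and diagnosed with a warning that
names the likely dialect counterpart. Silent renaming or silent dropping
both hide clinically relevant failures; a loud zero does not.

## Verification strategy and the synthetic data generator

The package contains its own fixture generator and a brute-force oracle,
and the test suite's central property is exact agreement between the two
computations:

* `build_bam()` writes read specifications to a real coordinate-sorted,
  indexed BAM, so flag handling, index access and pileup semantics are
  tested at the file boundary, not against mocks.
* `oracle_profile()` / `oracle_region_summary()` / `oracle_chrom_stats()`
  restate every metric definition by direct nested iteration over reads and
  positions, with their own character-level CIGAR walker and their own
  median — no code shared with the engine (which derives per-read geometry
  from CIGAR range algebra and aggregates vectorised per position).
* `random_fixture()` draws up to 3 regions (20–60 bp) and up to ~100 reads
  per fixture with CIGAR shapes spanning plain matches, internal deletions,
  internal insertions and soft-clip variants; MQs are drawn from a grid
  straddling the default cutoff (including the boundary values 19/20 and
  the sentinel 255) and BQs from 0–45 across the BQ cutoff. The suite
  asserts engine ≡ oracle for every metric at every position over 200
  seeded fixtures, plus the structural invariants (QCOV ≤ COV, strand-split
  sums, RCIN + RCOUT = RC, mapped + unmapped = total), cutoff monotonicity
  of QCOV, and equality of the duplicate toggle with physical duplicate
  removal. Fixture sizes were chosen so the whole battery completes in
  about a minute and a half while still covering every CIGAR/flag/boundary
  combination the engine branches on.
* `make_panel_fixture()` fixes the study conditions for end-to-end runs:
  a well-covered region (~75× good reads), a high-coverage/low-MQ region
  (205× raw, 35× quality coverage — the pseudogene-homology pattern, built
  to sit well below a MINQCOV ≥ 50 floor), a zero-coverage region, a
  strand-biased region (60 forward / 8 reverse) and a region where a 20 bp
  deletion carried by 45 of 57 reads produces a mid-region poor interval.
  Expected PASS/FLAG statuses are recorded with the fixture and verified
  against the oracle, not assumed.

What the synthetic generator emulates is alignment *geometry and quality
structure*; it does not emulate sequence-context error models, GC bias,
fragment-size distributions or real aligner MQ profiles. Passing tests
therefore demonstrate that the metrics are computed exactly as defined on
any legal BAM — they do not validate that the default cutoffs are the right
operating point for a particular chemistry or pipeline, which remains a
laboratory decision.

## Numerical and degenerate-input choices

* Zero-length BED regions are rejected (hard error naming the line);
  a BED with only comment/track lines yields zero regions and header-only
  outputs, while a fully empty file is an error.
* Overlapping BED regions are profiled independently; a read may count in
  several regions but is counted once in RCIN.
* Duplicate region names are allowed (panels do re-use names) but warned
  about; gene grouping uses the text before the last underscore of the
  region name when present — a convention, not an annotation lookup.
* Output files carry no timestamps; repeated runs are byte-identical.
* The whole-file chromosome accounting pass reads flags/positions/CIGARs
  only. For very large genomes a chunked pass would be the next step; at
  panel scale a single pass is simpler and fast.

## Known limitations

CRAM input, BAQ recalibration, per-fragment overlap-aware counting, BED12
block structure and full HGVS/CSN normalisation are out of scope. MQ/BQ
semantics are taken at face value from the BAM; the tool evaluates, but
cannot repair, aligner-specific quality conventions.
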