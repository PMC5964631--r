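# panelqc

Coverage and sequence-quality evaluation for targeted NGS panels.

Clinical gene-panel sequencing needs more than raw depth of coverage: a
position covered by 200 reads can still be uncallable if most of those reads
are ambiguously mapped (low mapping quality, MQ) or carry unreliable base
calls (low base quality, BQ) — the classic situation over pseudogene
homologies. `panelqc` evaluates a coordinate-sorted BAM against a BED file of
target regions at three levels of detail, so that regions meeting declared
quality requirements proceed automatically and everything else is flagged
for review. It is written for clinical and research labs running capture
panels, and for anyone comparing capture designs.

## Metrics

Per base (1-based genomic positions over each region), with Phred cutoffs
`bq_cutoff` (default 10) and `mq_cutoff` (default 20), comparisons
inclusive:

| metric | definition |
|---|---|
| COV | mapped reads covering the position (aligned base or spanning deletion) |
| QCOV | covering reads with MQ ≥ `mq_cutoff` contributing an aligned base with BQ ≥ `bq_cutoff` |
| MEDBQ | median BQ of read bases aligned to the position |
| FLBQ | fraction of aligned read bases with BQ < `bq_cutoff` |
| MEDMQ | median MQ of covering reads |
| FLMQ | fraction of covering reads with MQ < `mq_cutoff` |

Per region: RC (reads overlapping the region), MEDCOV/MINCOV,
MEDQCOV/MINQCOV and MAXFLMQ/MAXFLBQ, with a PASS/FLAG status against
user-declared minimum/maximum thresholds (e.g. `MINQCOV_min = 50` requires
every base to be covered by ≥ 50 good-quality reads). Per chromosome: total,
on-target and off-target read counts, plus genome-wide mapped/unmapped
totals. Maximal runs of positions with QCOV below a cutoff (default 15) are
reported as *poor-quality intervals*, optionally localised in simplified
transcript `c.` coordinates.

All profiles can additionally be computed for forward and reverse reads
separately to expose strand-specific biases.

## Worked example

The package ships a deterministic synthetic panel fixture whose five
regions exercise the main quality pathologies (all names and coordinates
are synthetic):

```r
library(panelqc)
fix <- make_panel_fixture(seed = 1)
res <- run_coverage_qc(fix$bam, fix$bed, config = fix$config_ini,
                       output_prefix = tempfile("qc"))
res$regions[, c("region","RC","MEDCOV","MINCOV","MEDQCOV","MINQCOV",
                "MAXFLMQ","status","failed_metrics")]
```

```
  region  RC MEDCOV MINCOV MEDQCOV MINQCOV   MAXFLMQ status failed_metrics
 BRCA1_1  75     75     75      70      70 0.0000000   PASS
 PMS2_12 205    205    205      35      35 0.8292683   FLAG        MINQCOV
  MLH1_5   0      0      0       0       0        NA   FLAG        MINQCOV
 GENE2_1  68     68     68      68      68 0.0000000   PASS
 GENE3_7  57     57     57      57      12 0.0000000   FLAG        MINQCOV
```

`PMS2_12` is the instructive row: every base is covered by 205 reads
(MINCOV = 205), yet only 35 of them are of good quality (MINQCOV = 35),
because at the worst position 83% of reads fall below MQ 20
(MAXFLMQ = 0.829) — the pseudogene-homology pattern in which raw coverage
looks fine but the region fails a `MINQCOV ≥ 50` requirement. `MLH1_5` has
no coverage at all, and in `GENE3_7` a 20 bp deletion carried by most reads
drops QCOV to 12 mid-region, which also surfaces as a poor-quality
interval with its transcript location:

```r
res$poor
```

```
  region chrom start  end min_qcov            transcripts
  MLH1_5     1  3001 3050        0
 GENE3_7     2  1521 1540       12 TX_G3(GENE3):c.32_c.51
```

Chromosome-level accounting (`res$chrom`) reports 455 mapped reads of
which 405 are on-target, and 5 unmapped reads.

## Command line

```sh
Rscript inst/scripts/panelqc --input reads.bam --bed targets.bed \
    --config run.ini --output results/sample1
```

writes `results/sample1_{summary,regions,profiles,poor}.txt`. The INI file
sets quality cutoffs (`[quality]`), PASS/FLAG thresholds (`[flags]`, e.g.
`MINQCOV_min = 50`) and output options (`[outputs]`, including
`transcript_db`). The transcript database is a TSV with columns id, gene,
chrom, strand, coding_start, coding_end (1-based genomic CDS bounds),
comma-separated exon starts (0-based) and exon ends — see
`?load_transcript_db`.

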