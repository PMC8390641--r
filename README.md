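# tp53junctions

Exon–exon junction read analysis of TP53 alternative isoforms from aligned
short-read RNA-seq data.

TP53's predominant transcript NM_000546.6 (p53α) coexists with rare
alternative isoforms. The C-terminal family (p53β, Δ40p53β, Δ133p53β,
Δ160p53β) shares one C-terminal splice alteration that removes the
tetramerization domain; NM_001126112.2 uses an alternate 5′UTR acceptor
3 bp into exon 2. Because these isoforms are rare and mostly identical to
the main transcript, this package quantifies them through *unambiguous*
evidence only: spliced reads crossing junctions unique to an alternative
isoform. This repository implements that analysis as a tested R package
(`R/`) driven by a numbered analysis workflow (`analysis/`).

## The statistic

A read counts toward a junction only if its alignment (a) skips an intron
with block boundaries exactly at the annotated donor/acceptor pair, (b) has
at least 10 aligned nucleotides on both sides of the breakpoint, (c) is at
most half soft-clipped, and (d) has zero mismatches and no indels. Per
sample, the exonic fraction of the C-terminal alternative isoforms is

    f = D̄ / (M + D̄),   D̄ = (D₁ + D₂) / 2

where D₁ and D₂ are the read counts of the two junctions unique to p53β
(exon 9→10 and 10→11 in its own numbering) and M is the count of the
competing main-isoform exon 9→10 junction. The analogous ratio with a
single D covers NM_001126112.2. Samples are stratified by TP53 status —
wild type (no mutations, log2(CN-ratio) > −0.9, RSEM expression > 300,
strict inequalities), missense, or truncating (nonsense/frameshift/splice
site) — and groups are compared per stratum with two-tailed Welch t-tests
(paired t-tests for tumor–normal pairs) at a Bonferroni-adjusted
significance level.

## Worked example

Everything below runs on synthetic data generated in-repo — no downloads.
The numbered scripts run in order:

```sh
Rscript analysis/01_simulate_data.R     # toy locus + 24 samples + 25 pairs
Rscript analysis/02_count_junctions.R   # strict junction-read counting
Rscript analysis/03_fractions.R         # per-sample exonic fractions
Rscript analysis/04_classify_compare.R  # TP53 status + Welch/paired tests
Rscript analysis/05_gtex_summaries.R    # bundled per-tissue table summaries
```

Stage 4 prints, for a cohort simulated with a 3-point C-terminal spike in
the truncating group and none in the missense group:

```
groups: missense=8, truncating=8, WT=8
m = 2 tests, adjusted alpha = 0.025
  WT vs missense   mean 0.0191 vs 0.0210  p = 0.691  ns
  WT vs truncating mean 0.0191 vs 0.0524  p = 0.000111  SIGNIFICANT
paired WT tumors vs normals: 0.613% vs 0.638%, p = 0.214
```

Read: the wild-type and missense groups share the simulated baseline
fraction (~2%) and correctly test as indistinguishable; the truncating
group's injected aberrant C-terminal splicing is recovered (5.2% vs 1.9%)
and flagged at the Bonferroni-adjusted level; the paired wild-type
tumor/normal fractions (simulated at 0.62%/0.66%) show no significant
difference. Stage 5 summarizes the bundled 53-tissue table:

```
53 tissues; mean of per-tissue means = 2.10%; max per-tissue median = 4.2% (Spleen)
```

In code, the core loop is three calls:

```r
library(tp53junctions)
model   <- builtin_tp53_model()          # packaged TP53 GRCh38 model
catalog <- derive_junctions(model)       # junction catalog, classes labeled
counts  <- count_junction_reads("sample.bam", catalog, sample_id = "s1")
fractions_table(list(counts), catalog)
```

## Layout

```
R/                  package code: gene model & junction catalog, counting,
                    fractions, classification, comparisons, simulators,
                    pipeline orchestration (run_pipeline / validate_inputs)
analysis/           numbered workflow drivers (thin; all logic is in R/)
inst/extdata/       packaged TP53 model (JSON) and per-tissue summary table
tests/testthat/     unit, property and acceptance tests
scripts/            acceptance.R
vignettes/          methods vignette: model, assumptions, design choices
```
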