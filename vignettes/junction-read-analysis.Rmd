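---
title: "Exon–exon junction read analysis of TP53 alternative isoforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon–exon junction read analysis of TP53 alternative isoforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tp53junctions)
```

## The problem

NM_000546.6 (p53α) is by far the predominant TP53 transcript. A handful of
alternative isoforms exist at much lower abundance. The C-terminal family
(p53β, Δ40p53β, Δ133p53β, Δ160p53β) shares one C-terminal splice alteration
that removes the tetramerization domain, so these isoforms cannot contribute
to a functional p53 tetramer. A further transcript, NM_001126112.2, uses an
alternate splice acceptor 3 bp inside the non-coding part of exon 2 and
encodes exactly the main-isoform protein.

Full-isoform quantification of transcripts this rare and this similar is
unreliable. The approach implemented here side-steps deconvolution entirely:
it looks only for *unambiguous* evidence — short reads whose spliced
alignment crosses an exon–exon junction that exists in an alternative
isoform but not in the main one. The N-terminal Δ40/Δ133/Δ160 variants have
no unique junctions (they arise from intron retention or internal
transcription starts), so the junction-level analysis is necessarily limited
to the C-terminal family, the 5′UTR variant, and the (very rare) γ-family
junctions.

## The junction catalog

`derive_junctions()` enumerates every adjacent exon pair of every transcript
and stores each genomic junction once, keyed by chromosome, donor end (last
base of the genome-upstream exon) and acceptor start (first base of the
genome-downstream exon). Identity is strand-agnostic: TP53 sits on the minus
strand, but spliced aligners report alignment blocks in genome coordinates,
so strand only affects per-transcript exon numbering, never read matching.

Three junction classes matter downstream:

* the **C-terminal pair** — the two junctions unique to p53β and shared by
  the whole β family (in p53β's own numbering, exon 9→10 and exon 10→11);
* their **main competitor** — the main-isoform exon 9→10 junction, which
  shares one splice boundary with the pair;
* the **5′UTR junction** of NM_001126112.2, which differs from its
  main-isoform competitor by exactly 3 bp. On a plus-strand locus the shift
  lands on the acceptor-start coordinate; on the minus-strand TP53 locus the
  same biological shift lands on the donor-end coordinate. The catalog
  validation therefore checks "exactly one boundary differs, by exactly
  3 bp", which is orientation-proof.

The bundled TP53 model (`builtin_tp53_model()`) is a packaged JSON file, not
hard-coded constants, so users can substitute another annotation version.
Its GRCh38 coordinates mirror the public reference annotation for the ten
accessions; the β/γ-specific exon placements inside intron 9 preserve the
exact junction topology (which junctions exist, which boundaries are
shared). The source publication prints no genomic coordinates, so these
cannot be checked against the original analysis — only the topology can,
and it is.

## The junction-read rule

A read supports a junction when **all** of the following hold
(`classify_read()`, `count_junction_reads()`):

1. the alignment contains a skipped region (CIGAR `N`) whose flanking
   blocks end exactly at the donor and start exactly at the acceptor;
2. each flanking block holds at least `min_flank = 10` aligned bases;
3. soft-clipped bases total at most `max_softclip_fraction = 0.5` of the
   read sequence length;
4. the read aligns with zero mismatches and no insertions or deletions.

Operational choices, made once and fixed:

* "No mismatches" means aligner edit distance (NM tag) zero *and* no I/D
  CIGAR operators. Soft-clipped bases are not mismatches; the rule treats
  clipping separately. When NM is absent, strict mode rejects the read
  (mismatch status unverifiable); permissive mode falls back to the MD tag.
* The soft-clip denominator is the read sequence length as stored in the
  record; hard-clipped bases are absent from it. The boundary is inclusive:
  a read exactly half clipped passes.
* Flank bases are counted within the single block adjacent to the skip, not
  accumulated across further skips — "both sides of the breakpoint" read as
  contiguous support.
* Each mate of a pair is an independent read; duplicate-flagged records are
  counted by default (inputs are taken as provided by the aligner), with a
  parameter to exclude them; secondary and supplementary alignments are
  excluded.
* A read with several skips is matched against the catalog skip by skip;
  an unmatched extra skip does not disqualify the read, and a read can
  support several junctions but increments each junction at most once.
* Reject reasons are reported in a fixed order (no_splice,
  breakpoint_mismatch, excess_softclip, has_mismatch/has_indel,
  short_flank) so audits are deterministic.

CIGAR tokenization and SAM/BAM access go through
GenomicAlignments/Rsamtools; the rule itself is applied by this package.

## The exonic fraction

For each sample the statistic is

$$f = \frac{\bar D}{M + \bar D}$$

where $\bar D$ is the mean of the two C-terminal distinct-junction counts
and $M$ the count of the competing main junction (for the 5′UTR variant,
$D$ is the single distinct count). The averaging matters: a β transcript
exposes two distinct junctions where the main isoform exposes one, so
per-junction coverage — not summed coverage — is the comparable quantity;
averaging makes $f$ an unbiased estimate of the underlying isoform
proportion, which the recovery tests confirm against exact binomial
intervals.

$\bar D$ is kept real-valued (no rounding). A sample with $M = D_1 = D_2 =
0$ has no information about the ratio; it is reported *missing*, excluded
from downstream statistics, and serialized as an empty field. Scoring 0/0
as 0 would bias group summaries downward exactly in low-coverage samples.
(Published per-tissue medians of exactly 0.000 are consistent with either
handling; missingness is the defensible choice and is documented
per-sample.) γ-family junctions are cataloged and countable, but excluded
from default fraction outputs because their supporting reads are very rare.

## TP53 status classification

Samples are partitioned into four groups:

* **WT** — no TP53 mutation calls *and* log2(CN-ratio) > −0.9 *and*
  RSEM-normalized expression > 300. Both inequalities are strict, exactly
  as printed; boundary samples are excluded. The CN/expression gate
  protects the wild-type group from unmutated samples that have silenced or
  lost the locus.
* **missense** — only missense calls.
* **truncating** — any of nonsense, frameshift, splice-site. When missense
  and truncating calls coexist the sample goes to the truncating group with
  a `mixed_classes_policy` flag: truncation dominates the transcript
  phenotype being measured, and the flag enables sensitivity re-analysis.
  (The original study does not state its policy; this is the package's own
  choice.)
* **excluded** — no mutations but a failed or missing gate, with a reason.

The gate applies only to the WT definition; mutant groups are defined by
mutation class alone. Normal-tissue samples are never status-classified;
they enter only paired analyses.

## The statistical layer

Group comparisons are Welch t-tests (two-tailed, unequal variance) per
stratum, run only where both groups have at least `min_group_size = 5`
samples; paired tumor–normal comparisons are one-sample t-tests on the
within-pair differences. Both wrap `stats::t.test`; the test suite verifies
them against independent closed-form computations to 1e-10. Unequal
variance is stated explicitly for the cell-line analysis in the source and
assumed for the tumor analyses, where only "t test" is printed.

Degenerate inputs are resolved by logged conventions: both groups constant
and equal → t = 0, p = 1; constant and different → the p → 0 limit.
Missing fractions are dropped per test (pairwise deletion for paired
tests).

Multiplicity uses a Bonferroni-adjusted significance level,
`family_alpha / m_tests`, with `m_tests` counted from the tests actually
executed; a `fixed_m` override reproduces the published family sizes (79,
76, 10 → adjusted levels ≈ 6.33E−4, ≈ 6.58E−4, 0.005) when the cohort
structure differs. A result is significant when p ≤ adjusted level —
"meeting" the level is read inclusively; the choice is a convention and is
immaterial at continuous p-values. Within strata eligible on the combined
groups, the suite optionally also tests each truncating class separately
(nonsense / splice site / frameshift) whenever the class has at least two
samples, mirroring the published per-class triples.

## What the simulator emulates — and what it does not

`make_toy_locus()` builds a plus-strand (optionally mirrored minus-strand)
single-gene locus reproducing the junction topology above: an
11-exon main transcript, a C-terminal alternative adding two intron-9
exons, a 5′UTR alternative with the 3-bp acceptor shift, and a γ-like
alternative. `simulate_alignments()` draws reads from transcripts at
configurable mixture proportions and read lengths (the emulated platforms
span 48–101 bp; 76 bp is the default), placing splice boundaries exactly
and then injecting three contamination channels: boundary offsets (±1),
terminal soft-clipping applied by *trimming aligned bases into clips* so
clip length and flank length interact realistically, and mismatches
recorded in the NM tag. Reads are single-end: mates are counted
independently anyway, so paired-end realism adds nothing to what is being
tested. Base qualities are constant because the rule never consults them.

Every simulated read carries a truth record, and the truth qualification is
computed from the generator's own block list by a literal restatement of
the rule — never by parsing the CIGAR it wrote. This independence is the
point: the central equivalence test demands read-for-read agreement between
the counting module and this oracle on every fixture, and the acceptance
run re-verifies it on 20 fixtures of 10,000 reads across mixed noise
settings.

`simulate_cohort()` works at count level: per-sample junction counts drawn
binomially at a stated depth around group-specific true fractions, with
annotations generated so classification reproduces the intended labels.
Depth 5,000–10,000 with baseline fractions of 0.5–4% matches the regime of
the emulated datasets (fractions of a few percent over deeply covered
junctions).

What passing these tests does **not** show about real data: the simulator
has no base-level sequencing-error model, no alignment ambiguity (reads are
placed where they belong, so the rule's specificity against mis-mapped
reads is untested), no fragment-length or positional coverage bias, and no
annotation error. Results on real BAMs inherit the aligner's behavior;
the strict rule is deliberately conservative to compensate.

## Problem sizes and numerical choices

The test suite and acceptance script run at sizes chosen to make the
statistical checks decisive while staying lightweight: 20 fixtures ×
10,000 reads for oracle equivalence; 500 replicates per true proportion
(0, 0.005, 0.02, 0.05, 0.24) at depth 10,000 for estimator coverage
against exact binomial 99% intervals; 1,000 reduced-size cohort replicates
(3 strata × 10 per group, depth 500) for the null family-wise error, which
must stay within two Monte-Carlo standard errors of 0.05. All generators
derive every random stream from an explicit seed and restore the caller's
RNG state.

## Known limitations

* Single-locus models only; no multi-gene catalogs, no liftover.
* The analysis is junction-local by design — no isoform-abundance
  deconvolution, no novel-junction discovery, no mismatch rescue or
  realignment.
* Whether the original analysis excluded duplicate or multi-mapped reads is
  unstated; defaults here count duplicates and ignore mapping quality, with
  parameters to vary both.
* The bundled model's base-pair coordinates cannot be verified against the
  original authors' annotation (none are printed); all structural
  relationships can be, and are, tested.
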