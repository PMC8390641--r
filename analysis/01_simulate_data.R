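#!/usr/bin/env Rscript
# Stage 1: generate the study inputs in-silico.
#
# Builds the toy TP53-like locus, simulates per-sample spliced alignments for
# a three-group tumor cohort (wild type / missense / truncating) plus a
# paired tumor-normal set, and writes everything under results/simdata/.
# Downstream stages (02-04) consume only these files.

suppressPackageStartupMessages(library(tp53junctions))

seed <- 101L
outdir <- "results/simdata"
readdir <- "scratch/sim_reads"   # bulky alignment files, regenerated on demand
dir.create(readdir, recursive = TRUE, showWarnings = FALSE)
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

loc <- make_toy_locus(seed = seed, outdir = outdir)
catalog <- derive_junctions(loc$model)
export_junction_catalog(catalog, file.path(outdir, "catalog.tsv"))
message("locus: ", nrow(catalog$junctions), " junctions (",
        sum(catalog$junctions$klass == "main"), " main)")

# read-level cohort: 8 samples per group, modest depth; the truncating group
# carries a 3-point spike in the C-terminal isoform proportion, emulating
# aberrant C-terminal splicing
groups <- c(WT = 0, missense = 0, truncating = 0.03)
ann <- NULL
aln <- character(0)
k <- 0L
for (g in names(groups)) for (i in 1:8) {
  k <- k + 1L
  sid <- sprintf("s%02d", k)
  p_ct <- 0.02 + groups[[g]]
  mix <- mixture_config(c(MAIN = 1 - p_ct - 0.02, ALTCT = p_ct, ALTU5 = 0.02),
                        read_length = 76L, n_reads = 5000L, seed = seed + k)
  sam <- file.path(readdir, paste0(sid, ".sam"))
  simulate_alignments(loc, mix, catalog, sam_path = sam)
  aln[sid] <- sam
  ann <- rbind(ann, data.frame(
    sample_id = sid, cohort = "tumor", stratum = "SIM",
    mutation_class = switch(g, WT = "", missense = "missense",
                            truncating = "nonsense"),
    log2_cn_ratio = 0, expression_rsem = 1000, pair_id = NA))
}
write.table(ann, file.path(outdir, "annotations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")
writeLines(paste(names(aln), aln, sep = "\t"),
           file.path(outdir, "alignments.tsv"))
message("simulated ", length(aln), " samples x 5000 reads -> ", outdir)

# count-level paired tumor-normal cohort for the paired analysis in stage 04
paired <- simulate_cohort(catalog, strata = "SIM", n_per_group = 25L,
                          groups = "WT", baseline_fraction = 0.0062,
                          paired = TRUE, normal_effect = 0.0004,
                          depth = 8000L, seed = seed + 500L)
write.table(paired$annotations, file.path(outdir, "paired_annotations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, na = "")
write_junction_counts(paired$counts, file.path(outdir, "paired_counts.tsv"))
message("simulated ", nrow(paired$annotations) / 2, " tumor-normal pairs")
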