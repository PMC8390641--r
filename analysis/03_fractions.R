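#!/usr/bin/env Rscript
# Stage 3: per-sample exonic fractions for the C-terminal alternative
# isoforms and the 5'UTR variant, from the stage-2 counts. Zero-denominator
# samples stay missing (empty fields), never 0.

suppressPackageStartupMessages(library(tp53junctions))

catalog <- derive_junctions(load_gene_model("results/simdata/model.json"))
counts <- read_junction_counts("results/counts.tsv")
tab <- fractions_table(counts, catalog)
write_fractions_table(tab, "results/fractions.tsv")
message("fractions for ", nrow(tab), " samples; C-terminal range ",
        sprintf("%.4f..%.4f", min(tab$cterm_fraction, na.rm = TRUE),
                max(tab$cterm_fraction, na.rm = TRUE)),
        "; missing: ", sum(is.na(tab$cterm_fraction)))

paired_counts <- read_junction_counts("results/simdata/paired_counts.tsv")
paired_tab <- fractions_table(paired_counts, catalog)
write_fractions_table(paired_tab, "results/paired_fractions.tsv")
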