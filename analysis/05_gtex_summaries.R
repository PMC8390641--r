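#!/usr/bin/env Rscript
# Stage 5: cross-tissue summaries of the bundled per-tissue GTEx table
# (median/mean C-terminal isoform fraction for 53 tissue types): unweighted
# mean of the per-tissue means and the largest per-tissue median.

suppressPackageStartupMessages(library(tp53junctions))

tab <- gtex_table1()
s <- gtex_summary(tab)
message(sprintf("%d tissues; mean of per-tissue means = %.2f%%; ",
                s$n_tissues, s$mean_of_means_percent),
        sprintf("max per-tissue median = %.1f%% (%s)",
                s$max_median_percent,
                paste(tab$tissue[tab$median_fraction ==
                                 max(tab$median_fraction)], collapse = ", ")))
dir.create("results", showWarnings = FALSE)
write.table(data.frame(n_tissues = s$n_tissues,
                       mean_of_means_percent = s$mean_of_means_percent,
                       max_median_percent = s$max_median_percent),
            "results/gtex_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
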