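#!/usr/bin/env Rscript
# Stage 4: TP53 status classification and the Bonferroni-corrected
# comparison layer: per-group summaries, Welch tests (wild type vs missense,
# wild type vs truncating) and the paired tumor-normal t-test.

suppressPackageStartupMessages(library(tp53junctions))

fr <- read_fractions_table("results/fractions.tsv")
ann <- classify_samples(read_annotations("results/simdata/annotations.tsv"))
write.table(ann, "results/status.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE, na = "")
message("groups: ", paste(names(table(ann$group)), table(ann$group),
                          sep = "=", collapse = ", "))

gs <- group_summaries(fr, ann, grouping = "group")
write.table(gs, "results/group_summaries.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

out <- run_comparison_suite(fr, ann, contrasts = c("missense", "truncating"))
write.table(out$results, "results/comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE, na = "")
message(sprintf("m = %d tests, adjusted alpha = %.4g",
                out$correction$m_tests, out$correction$adjusted_alpha))
for (i in seq_len(nrow(out$results)))
  message(sprintf("  WT vs %-10s mean %.4f vs %.4f  p = %.3g  %s",
                  out$results$contrast[i], out$results$mean_a[i],
                  out$results$mean_b[i], out$results$p_value[i],
                  if (out$results$significant[i]) "SIGNIFICANT" else "ns"))

# paired tumor vs adjacent normal
pfr <- read_fractions_table("results/paired_fractions.tsv")
pann <- classify_samples(read_annotations("results/simdata/paired_annotations.tsv"))
pairs <- build_pairs(pann, status_filter = "WT")
pc <- paired_comparison(pfr, pairs)
message(sprintf("paired WT tumors vs normals: %.3f%% vs %.3f%%, p = %.3g",
                100 * pc$mean_a, 100 * pc$mean_b, pc$p_value))
write.table(data.frame(n_pairs = pc$n_pairs, mean_tumor = pc$mean_a,
                       mean_normal = pc$mean_b, t = pc$t_statistic,
                       p_value = pc$p_value),
            "results/paired_comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
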