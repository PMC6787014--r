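#!/usr/bin/env Rscript
# qPCR group comparison: 2^-dCt relative expression against GAPDH, per-gene
# two-sided Mann-Whitney tests and Benjamini-Hochberg FDR across the panel.

suppressMessages(library(gliomaTIL))
ct <- read_ct_tsv("results/data/qpcr_ct.tsv")
rel <- relative_expression(ct, housekeeping_gene = "GAPDH")
write_tsv_file(rel, "results/qpcr_relative_expression.tsv")

cmp <- compare_expression(rel, group_a = "LGG", group_b = "HGG")
write_tsv_file(cmp, "results/qpcr_comparison.tsv")

for (i in seq_len(nrow(cmp))) {
  message(sprintf("%s: fold change %.1f, U = %g, p = %.3g, q = %.3g",
                  cmp$gene[i], cmp$fold_change[i], cmp$U[i], cmp$p[i],
                  cmp$q[i]))
}
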