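#!/usr/bin/env Rscript
# TCR-Vbeta repertoire: productive frequency, dominant-clone count at the
# cumulative 30% read threshold ("diversity") and top-10 clone abundance
# ("convergence") per sample, compared between LGG and HGG.

suppressMessages(library(gliomaTIL))
data_dir <- "results/data"
samples <- read_tsv_file(file.path(data_dir, "samples.tsv"))

stats <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
  sid <- samples$sample_id[i]
  r <- read_repertoire_tsv(file.path(data_dir, paste0(sid, "_tcr.tsv")),
                           sample_id = sid, group = samples$group[i])
  repertoire_stats(r)
}))
write_tsv_file(stats, "results/tcr_stats.tsv")

cmp <- compare_repertoire_stats(stats[stats$group == "LGG", ],
                                stats[stats$group == "HGG", ])
write_tsv_file(cmp, "results/tcr_comparison.tsv")

message(sprintf(
  "dominant clones at 30%%: LGG mean %.1f vs HGG mean %.1f (MW p = %.2f); top-10 abundance %.1f%% vs %.1f%%",
  mean(stats$dominant_clone_count[stats$group == "LGG"]),
  mean(stats$dominant_clone_count[stats$group == "HGG"]),
  cmp$p[cmp$statistic == "dominant_clone_count"],
  mean(stats$top10_abundance_pct[stats$group == "LGG"]),
  mean(stats$top10_abundance_pct[stats$group == "HGG"])
))
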