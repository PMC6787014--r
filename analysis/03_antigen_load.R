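#!/usr/bin/env Rscript
# Antigen load: coding SNVs are edited into the CDS, translated, and
# windowed into mutation-spanning 9-mers; candidates are scored per HLA
# allele (deterministic mock scorer) and filtered on the strict
# FPKM > 0 and all-scores > 0.5 cascade. Also counts expressed
# nonsynonymous mutations and expressed cancer germline antigens.

suppressMessages(library(gliomaTIL))
data_dir <- "results/data"
samples <- read_tsv_file(file.path(data_dir, "samples.tsv"))

rows <- list()
cand_rows <- list()
for (i in seq_len(nrow(samples))) {
  sid <- samples$sample_id[i]
  tx <- read_cds_fasta(file.path(data_dir, paste0(sid, "_cds.fasta")))
  v <- read_variants(file.path(data_dir, paste0(sid, "_variants.vcf")),
                     dialect = "vcf_minimal", transcripts = tx)
  expr <- read_expression_tsv(file.path(data_dir, paste0(sid, "_expression.tsv")))
  hla <- read_gene_list(file.path(data_dir, paste0(sid, "_hla.txt")))
  res <- neoepitope_pipeline(tx, v, hla, expr)
  cand_rows[[sid]] <- cbind(sample_id = sid, res$candidates)
  rows[[sid]] <- data.frame(
    sample_id = sid, group = samples$group[i],
    n_variants = nrow(v),
    n_nonsynonymous = sum(res$annotated$consequence != "synonymous"),
    n_expressed_nonsynonymous = count_expressed_mutations(res$annotated, expr),
    n_neoepitopes = res$n_neoepitopes
  )
}
counts <- do.call(rbind, rows)
write_tsv_file(counts, "results/antigen_counts.tsv")
write_tsv_file(do.call(rbind, cand_rows), "results/neoepitope_candidates.tsv")

# group comparison of the per-sample counts
is_lgg <- counts$group == "LGG"
mw <- mann_whitney_u(counts$n_expressed_nonsynonymous[is_lgg],
                     counts$n_expressed_nonsynonymous[!is_lgg])
message(sprintf(
  "expressed nonsynonymous mutations: LGG mean %.1f vs HGG mean %.1f (MW p = %.3g); neo-epitopes per tumor: %.1f",
  mean(counts$n_expressed_nonsynonymous[is_lgg]),
  mean(counts$n_expressed_nonsynonymous[!is_lgg]),
  mw$p.value, mean(counts$n_neoepitopes)
))

# CGA counting demo on the pooled expression tables against the bundled list
expr_all <- do.call(rbind, lapply(samples$sample_id, function(sid) {
  read_expression_tsv(file.path(data_dir, paste0(sid, "_expression.tsv")))
}))
# synthetic gene ids do not overlap the CGA catalogue; rename a few genes to
# CGA symbols to exercise the counter end to end
cga <- cga_gene_list()
expr_all$gene_id[expr_all$gene_id %in% sprintf("GENE%03d", 1:10)] <-
  rep(cga[1:10], length.out = sum(expr_all$gene_id %in% sprintf("GENE%03d", 1:10)))
cga_counts <- count_expressed_cgas(expr_all, cga)
write_tsv_file(data.frame(sample_id = names(cga_counts),
                          n_expressed_cgas = as.integer(cga_counts)),
               "results/cga_counts.tsv")
message("wrote antigen tables to results/")
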