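#!/usr/bin/env Rscript
# Generate the synthetic two-group glioma cohort (LGG vs HGG) used by the
# downstream analysis scripts, and write every input in its on-disk format:
# vessel masks (PNG) + cell centroids (CSV), transcript CDS (FASTA) +
# variants (minimal VCF) + expression (TSV), TCR clone tables (TSV), and a
# long-format qPCR Ct table (TSV).

suppressMessages(library(gliomaTIL))
seed <- 20260921L
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

groups <- list(
  # LGG: fewer T cells hugging the vasculature; HGG: deeper infiltration
  LGG = list(rho0 = 1500, lambda = 30, n_variants = 34L),
  HGG = list(rho0 = 3000, lambda = 80, n_variants = 59L)
)
n_per_group <- 3L

manifest <- list()
for (g in names(groups)) {
  for (i in seq_len(n_per_group)) {
    sid <- sprintf("%s_T%02d", g, i)
    s <- seed + 10L * (g == "HGG") + i

    ts <- simulate_tissue(spatial_sim_params(
      image_size_px = c(1200L, 1200L), pixel_size_um = 0.5, n_vessels = 6L,
      baseline_density_per_mm2 = groups[[g]]$rho0,
      decay_length_um = groups[[g]]$lambda, seed = s
    ), sample_id = sid, group = g)
    write_mask_png(ts$vessel_mask, file.path(data_dir, paste0(sid, "_vessels.png")))
    write_centroids_csv(ts$cells, file.path(data_dir, paste0(sid, "_cells.csv")))

    vs <- simulate_variant_set(genome_sim_params(
      n_transcripts = 40L, cds_length_codons = c(50L, 150L),
      n_variants = groups[[g]]$n_variants, fraction_synonymous = 0.3,
      fraction_expressed = 0.5, seed = s + 2000L
    ), sample_id = sid)
    write_cds_fasta(vs$transcripts, file.path(data_dir, paste0(sid, "_cds.fasta")))
    write_variants_vcf(vs$variants, file.path(data_dir, paste0(sid, "_variants.vcf")))
    write_tsv_file(vs$expression, file.path(data_dir, paste0(sid, "_expression.tsv")))
    writeLines(vs$hla_alleles, file.path(data_dir, paste0(sid, "_hla.txt")))

    sr <- simulate_repertoire(repertoire_sim_params(
      n_clones = 200L, frequency_model = "powerlaw", model_parameter = 1.2,
      nonproductive_fraction = 0.15, total_reads = 20000L, seed = s + 3000L
    ), sample_id = sid, group = g)
    write_tsv_file(as.data.frame(sr$repertoire),
                   file.path(data_dir, paste0(sid, "_tcr.tsv")))
    manifest[[sid]] <- data.frame(sample_id = sid, group = g)
  }
}

# trafficking genes expressed lower in LGG: positive fold planted as a
# negative HGG Ct shift
ct <- simulate_qpcr(qpcr_sim_params(
  genes = c("CXCL9", "CXCL10", "ICAM1", "GZMK"),
  n_per_group = c(20L, 20L),
  group_delta_ct_shift = c(-2, -2, -1.5, -1),
  ct_noise_sd = 0.8, seed = seed + 4000L
))
write_tsv_file(as.data.frame(ct), file.path(data_dir, "qpcr_ct.tsv"))
write_tsv_file(do.call(rbind, manifest), file.path(data_dir, "samples.tsv"))

message("wrote synthetic cohort for ", length(manifest),
        " tumors (plus a 20+20 qPCR panel) to ", data_dir)
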