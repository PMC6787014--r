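# Variant -> protein -> 9-mer candidate cascade

toy_tx <- function(cds, id = "TX1", gene = "G1") {
  data.frame(transcript_id = id, gene_id = gene, cds = cds,
             stringsAsFactors = FALSE)
}

test_that("variant editing and translation classify consequences correctly", {
  # synonymous: GCT -> GCC at codon 2
  tx <- toy_tx(cds_from_codons(c("ATG", "GCT", "TGG", "TAA")))
  mp <- build_mutant_protein(tx, list(transcript_id = "TX1",
                                      cds_position = 6, ref_base = "T",
                                      alt_base = "C"))
  expect_equal(mp$consequence, "synonymous")
  expect_identical(mp$ref_protein, mp$mut_protein)

  # R132H missense: CGT -> CAT at codon 132
  codons <- c("ATG", rep("GGT", 130), "CGT", rep("AAA", 20), "TAA")
  tx <- toy_tx(cds_from_codons(codons))
  mp <- build_mutant_protein(tx, list(transcript_id = "TX1",
                                      cds_position = 3 * 132 - 1,
                                      ref_base = "G", alt_base = "A"))
  expect_equal(mp$consequence, "missense")
  expect_equal(mp$protein_position, 132)
  expect_equal(substr(mp$ref_protein, 132, 132), "R")
  expect_equal(substr(mp$mut_protein, 132, 132), "H")

  # stop gain truncates: TGG -> TGA
  tx <- toy_tx(cds_from_codons(c("ATG", "TGG", "AAA", "CCC", "TAA")))
  mp <- build_mutant_protein(tx, list(transcript_id = "TX1",
                                      cds_position = 6, ref_base = "G",
                                      alt_base = "A"))
  expect_equal(mp$consequence, "stop_gain")
  expect_equal(mp$mut_protein, "M")
  expect_equal(mp$ref_protein, "MWKP")

  # errors: ref mismatch names the site; non-ACGT rejected
  expect_error(
    build_mutant_protein(tx, list(transcript_id = "TX1", cds_position = 6,
                                  ref_base = "C", alt_base = "A")),
    "ref mismatch.*TX1:6"
  )
  expect_error(
    build_mutant_protein(tx, list(transcript_id = "TX1", cds_position = 6,
                                  ref_base = "G", alt_base = "N")),
    "non-ACGT"
  )
})

test_that("Biostrings translation agrees with the codon-table oracle", {
  set.seed(42)
  for (i in 1:20) {
    vs <- simulate_variant_set(genome_sim_params(
      n_transcripts = 2, cds_length_codons = c(10L, 60L), n_variants = 0,
      seed = 1000 + i
    ))
    for (j in seq_len(nrow(vs$transcripts))) {
      cds <- vs$transcripts$cds[j]
      via_pkg <- build_mutant_protein(
        vs$transcripts[j, ],
        list(transcript_id = vs$transcripts$transcript_id[j],
             cds_position = 1, ref_base = "A", alt_base = "A")
      )
      expect_identical(via_pkg$ref_protein,
                       sub("\\*.*$", "", translate_codon_table(cds)))
    }
  }
})

test_that("mutant windows are centered and truncated at the termini", {
  prot <- paste(rep("A", 400), collapse = "")
  w <- extract_window(prot, 100)
  expect_equal(nchar(w$peptide), 17)
  expect_equal(w$mutated_index, 8)
  expect_false(w$truncated)

  w2 <- extract_window(prot, 3)
  expect_equal(nchar(w2$peptide), 11)
  expect_equal(w2$mutated_index, 2)
  expect_true(w2$truncated)

  prot17 <- paste(rep("L", 17), collapse = "")
  w3 <- extract_window(prot17, 9)
  expect_equal(w3$peptide, prot17)
  expect_equal(w3$mutated_index, 8)

  expect_error(extract_window(prot17, 18), "outside protein")
})

test_that("9-mer enumeration keeps exactly the mutation-spanning peptides", {
  # distinct residues so every 9-mer is unique
  pep17 <- "ACDEFGHIKLMNPQRST"
  w <- structure(list(peptide = pep17, mutated_index = 8,
                      protein_position = 50, truncated = FALSE),
                 class = "mutant_window")
  expect_length(enumerate_9mers(w), 9)

  w11 <- structure(list(peptide = substr(pep17, 1, 11), mutated_index = 2,
                        protein_position = 3, truncated = TRUE),
                   class = "mutant_window")
  expect_length(enumerate_9mers(w11), 3)

  w9 <- structure(list(peptide = substr(pep17, 1, 9), mutated_index = 4,
                       protein_position = 5, truncated = TRUE),
                  class = "mutant_window")
  expect_length(enumerate_9mers(w9), 1)

  w8 <- structure(list(peptide = substr(pep17, 1, 8), mutated_index = 2,
                       protein_position = 3, truncated = TRUE),
                  class = "mutant_window")
  out <- enumerate_9mers(w8)
  expect_length(out, 0)
  expect_true(attr(out, "flag_short"))

  # homopolymer window: duplicate 9-mers collapse
  wA <- structure(list(peptide = paste(rep("A", 17), collapse = ""),
                       mutated_index = 8, protein_position = 50,
                       truncated = FALSE), class = "mutant_window")
  expect_length(enumerate_9mers(wA), 1)

  # brute-force check of the coverage rule on the 11-mer case
  all9 <- substring(w11$peptide, 1:3, 9:11)
  expect_setequal(enumerate_9mers(w11), all9[1:3])
})

test_that("candidate scoring crosses peptides with alleles deterministically", {
  peps <- data.frame(peptide = c("ACDEFGHIK", "LMNPQRSTV"),
                     gene_id = c("G1", "G2"), transcript_id = c("T1", "T2"),
                     cds_position = c(10L, 20L), protein_position = c(4L, 7L))
  expr <- data.frame(gene_id = "G1", fpkm = 2.5)
  sc <- mock_scorer()
  expect_warning(
    cand <- score_candidates(peps, c("A*02:01", "B*07:02", "C*07:01"),
                             sc, expr),
    "FPKM treated as 0"
  )
  expect_equal(nrow(cand), 6)
  expect_true(all(cand$fpkm[cand$gene_id == "G2"] == 0))
  expect_true(all(cand$fpkm_missing[cand$gene_id == "G2"]))
  # deterministic on rerun and consistent with the scorer contract
  cand2 <- suppressWarnings(
    score_candidates(peps, c("A*02:01", "B*07:02", "C*07:01"), sc, expr))
  expect_identical(cand, cand2)
  expect_equal(unname(sc("ACDEFGHIK", "A*02:01")),
               unname(sc("ACDEFGHIK", "A*02:01")))
  expect_true(all(cand$mhc_binding_score >= 0 & cand$mhc_binding_score <= 1))
})

test_that("the filter cascade applies strict thresholds", {
  cand <- data.frame(
    peptide = c("P1", "P2", "P3", "P4"),
    hla_allele = "A*02:01", gene_id = "G1",
    mhc_binding_score = c(0.6, 0.5, 0.9, 0.7),
    cleavage_score = c(0.7, 0.9, 0.8, 0.6),
    tap_score = c(0.55, 0.9, 0.7, 0.8),
    fpkm = c(2.1, 3.0, 0.0, 5.0),
    fpkm_missing = FALSE,
    contains_mutation = c(TRUE, TRUE, TRUE, FALSE)
  )
  out <- filter_neoepitopes(cand)
  expect_equal(out$passes, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(count_neoepitopes(out), 1)
  expect_equal(count_neoepitopes(out, unit = "peptide"), 1)
})

test_that("raising thresholds never increases the passing count", {
  set.seed(7)
  vs <- simulate_variant_set(genome_sim_params(n_variants = 12, seed = 77))
  res <- neoepitope_pipeline(vs$transcripts, vs$variants, vs$hla_alleles,
                             vs$expression)
  counts <- vapply(seq(0, 1, 0.1), function(thr) {
    count_neoepitopes(filter_neoepitopes(res$candidates,
                                         score_threshold = thr))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  fp <- vapply(c(0, 0.5, 1, 5), function(thr) {
    count_neoepitopes(filter_neoepitopes(res$candidates,
                                         fpkm_threshold = thr))
  }, numeric(1))
  expect_true(all(diff(fp) <= 0))
})

test_that("pipeline output equals the generator's brute-force truth", {
  for (s in 1:10) {
    vs <- simulate_variant_set(genome_sim_params(
      n_transcripts = 4, cds_length_codons = c(15L, 60L), n_variants = 6,
      fraction_synonymous = 0.3, seed = 500 + s
    ))
    res <- neoepitope_pipeline(vs$transcripts, vs$variants, vs$hla_alleles,
                               vs$expression)
    got <- unique(res$candidates[res$candidates$passes,
                                 c("peptide", "hla_allele", "gene_id")])
    got <- got[order(got$peptide, got$hla_allele), ]
    want <- vs$truth$passing[order(vs$truth$passing$peptide,
                                   vs$truth$passing$hla_allele), ]
    rownames(got) <- rownames(want) <- NULL
    expect_identical(got, want)
    expect_equal(
      count_expressed_mutations(res$annotated, vs$expression),
      vs$truth$n_expressed_nonsynonymous
    )
  }
})

test_that("synonymous-only variant sets never yield candidates", {
  vs <- simulate_variant_set(genome_sim_params(
    n_variants = 10, fraction_synonymous = 1, seed = 9
  ))
  expect_true(all(vs$variants$intended_consequence == "synonymous"))
  expect_equal(nrow(vs$truth$passing), 0)
  res <- neoepitope_pipeline(vs$transcripts, vs$variants, vs$hla_alleles,
                             vs$expression)
  expect_equal(nrow(res$candidates), 0)
  expect_equal(res$n_neoepitopes, 0)
})

test_that("unexpressed genes contribute no neo-epitopes", {
  vs <- simulate_variant_set(genome_sim_params(
    n_variants = 8, fraction_synonymous = 0, fraction_expressed = 0,
    seed = 13
  ))
  expect_equal(nrow(vs$truth$passing), 0)
  res <- neoepitope_pipeline(vs$transcripts, vs$variants, vs$hla_alleles,
                             vs$expression)
  expect_equal(res$n_neoepitopes, 0)
  expect_true(any(res$annotated$consequence == "missense"))
})

test_that("mutation and CGA expression counting follow the FPKM > 0 rule", {
  ann <- data.frame(
    consequence = c("missense", "missense", "missense", "missense",
                    "synonymous"),
    gene_id = c("G1", "G2", "G3", "G4", "G1")
  )
  expr <- data.frame(gene_id = c("G1", "G2", "G3", "G4"),
                     fpkm = c(1.2, 0, 3.4, 0))
  expect_equal(count_expressed_mutations(ann, expr), 2)
  expect_equal(count_expressed_mutations(
    ann[ann$consequence == "synonymous", ], expr), 0)

  em <- data.frame(
    gene_id = rep(c("MAGEA1", "CTAG1B", "PRAME"), 2),
    sample_id = rep(c("S1", "S2"), each = 3),
    fpkm = c(0, 0.2, 5, 0, 0, 0)
  )
  cg <- c("MAGEA1", "CTAG1B", "PRAME")
  expect_equal(count_expressed_cgas(em, cg)[["S1"]], 2)
  expect_equal(count_expressed_cgas(em, cg)[["S2"]], 0)
  expect_equal(count_expressed_cgas(em, cg, fpkm_threshold = 1)[["S1"]], 1)
  expect_error(count_expressed_cgas(em, c("NOPE1", "NOPE2")), "unmatched")
  # the bundled snapshot is well-formed
  expect_gt(length(cga_gene_list()), 50)
  expect_true("MAGEA1" %in% cga_gene_list())
})
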