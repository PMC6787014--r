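# Synthetic transcriptome/variant, repertoire and qPCR generators with
# ground truth computed by independent brute force.

# minimal codon table translator, independent of the Biostrings route used
# by the analysis pipeline
codon_table <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Table-driven codon translation
#'
#' A minimal standard-genetic-code translator used by the synthetic-data
#' generator (and available as an independent cross-check of the
#' Biostrings-based translation in the analysis path).
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @return Amino-acid string including `*` for stop codons.
#' @export
translate_codon_table <- function(cds) {
  cds <- toupper(cds)
  stopifnot(nchar(cds) %% 3 == 0)
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- codon_table[codons]
  if (anyNA(aa)) stop("non-ACGT codon in CDS")
  paste(aa, collapse = "")
}

#' Simulate a toy transcriptome with planted coding SNVs
#'
#' Generates random coding sequences (ATG start, stop-free body, terminal
#' stop), plants single-nucleotide variants with controlled consequence
#' (synonymous or missense), assigns per-gene FPKM values, and computes the
#' ground-truth list of neo-epitope candidates expected to pass the filter
#' cascade under the mock scorer.
#'
#' The truth list is computed by independent brute force: every 9-mer of
#' the full mutant protein (its own codon-table translation, no windowing)
#' that contains the mutated residue is scored and filtered directly.
#'
#' @param params A [genome_sim_params()] object.
#' @param sample_id Sample annotation for the expression table.
#' @return A list: `transcripts` (data.frame `transcript_id`, `gene_id`,
#'   `cds`), `variants` (`transcript_id`, `cds_position`, `ref_base`,
#'   `alt_base`, `sample_id`, `intended_consequence`), `expression`
#'   (`gene_id`, `sample_id`, `fpkm`), `hla_alleles`, and `truth` — a list
#'   with `passing` (data.frame `peptide`, `hla_allele`, `gene_id`) and
#'   `n_expressed_nonsynonymous`.
#' @export
simulate_variant_set <- function(params, sample_id = "S1") {
  stopifnot(inherits(params, "genome_sim_params"))
  set.seed(params$seed)
  n_tx <- params$n_transcripts
  lens <- sample(seq(params$cds_length_codons[1], params$cds_length_codons[2]),
                 n_tx, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  make_codon <- function() {
    repeat {
      cod <- paste(sample(bases, 3, replace = TRUE), collapse = "")
      if (!cod %in% stops) return(cod)
    }
  }
  transcripts <- data.frame(
    transcript_id = sprintf("TX%03d", seq_len(n_tx)),
    gene_id = sprintf("GENE%03d", seq_len(n_tx)),
    cds = vapply(lens, function(L) {
      paste0("ATG",
             paste(replicate(L - 2L, make_codon()), collapse = ""),
             sample(stops, 1))
    }, character(1)),
    stringsAsFactors = FALSE
  )

  # internal codons (not start, not stop) available for variant placement
  slots <- do.call(rbind, lapply(seq_len(n_tx), function(i) {
    data.frame(tx = i, codon = seq(2L, lens[i] - 1L))
  }))
  if (params$n_variants > nrow(slots)) {
    stop("n_variants (", params$n_variants,
         ") exceeds available codon positions (", nrow(slots), ")")
  }
  pick <- slots[sample(nrow(slots), params$n_variants), , drop = FALSE]
  want_syn <- stats::runif(params$n_variants) < params$fraction_synonymous

  variants <- NULL
  for (i in seq_len(params$n_variants)) {
    tx <- pick$tx[i]
    codon_i <- pick$codon[i]
    cds <- transcripts$cds[tx]
    codon <- substr(cds, 3 * codon_i - 2, 3 * codon_i)
    v <- plant_snv(codon, want_syn[i])
    if (is.null(v)) { # codon admits no substitution of the wanted class
      v <- plant_snv(codon, !want_syn[i])
    }
    variants <- rbind(variants, data.frame(
      transcript_id = transcripts$transcript_id[tx],
      cds_position = 3L * (codon_i - 1L) + v$offset,
      ref_base = v$ref, alt_base = v$alt,
      sample_id = sample_id,
      intended_consequence = v$consequence,
      stringsAsFactors = FALSE
    ))
  }
  if (is.null(variants)) {
    variants <- data.frame(transcript_id = character(0),
                           cds_position = integer(0),
                           ref_base = character(0), alt_base = character(0),
                           sample_id = character(0),
                           intended_consequence = character(0))
  }

  expressed <- stats::runif(n_tx) < params$fraction_expressed
  expression <- data.frame(
    gene_id = transcripts$gene_id,
    sample_id = sample_id,
    fpkm = ifelse(expressed, round(stats::rlnorm(n_tx, 1, 1), 3), 0),
    stringsAsFactors = FALSE
  )

  truth <- variant_set_truth(transcripts, variants, expression,
                             params$hla_alleles)
  list(transcripts = transcripts, variants = variants,
       expression = expression, hla_alleles = params$hla_alleles,
       truth = truth)
}

# choose a single-base substitution in `codon` with the requested
# consequence class; NULL if impossible (e.g. no synonymous change exists)
plant_snv <- function(codon, synonymous) {
  bases <- c("A", "C", "G", "T")
  ref_aa <- unname(codon_table[codon])
  opts <- NULL
  for (off in 1:3) {
    ref <- substr(codon, off, off)
    for (alt in setdiff(bases, ref)) {
      mut <- codon
      substr(mut, off, off) <- alt
      alt_aa <- unname(codon_table[mut])
      cls <- if (alt_aa == ref_aa) "synonymous"
             else if (alt_aa == "*") "stop_gain"
             else "missense"
      keep <- if (synonymous) cls == "synonymous" else cls == "missense"
      if (keep) {
        opts <- rbind(opts, data.frame(offset = off, ref = ref, alt = alt,
                                       consequence = cls))
      }
    }
  }
  if (is.null(opts)) return(NULL)
  opts[sample(nrow(opts), 1), ]
}

# brute-force truth: all mutation-containing 9-mers of the full mutant
# protein, scored with the mock scorer and filtered
variant_set_truth <- function(transcripts, variants, expression,
                              hla_alleles, score_threshold = 0.5,
                              fpkm_threshold = 0, k = 9L) {
  scorer <- mock_scorer()
  passing <- NULL
  n_expr_nonsyn <- 0L
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    tx <- transcripts[transcripts$transcript_id == v$transcript_id, ]
    cds <- tx$cds
    mut <- cds
    substr(mut, v$cds_position, v$cds_position) <- v$alt_base
    ref_aa_full <- sub("\\*.*$", "", translate_codon_table(cds))
    mut_aa_full <- sub("\\*.*$", "", translate_codon_table(mut))
    codon_i <- (v$cds_position - 1L) %/% 3L + 1L
    ref_aa <- substr(translate_codon_table(cds), codon_i, codon_i)
    alt_aa <- substr(translate_codon_table(mut), codon_i, codon_i)
    fpkm <- expression$fpkm[match(tx$gene_id, expression$gene_id)]
    if (ref_aa != alt_aa && alt_aa != "*" && ref_aa != "*") {
      if (fpkm > fpkm_threshold) n_expr_nonsyn <- n_expr_nonsyn + 1L
      if (codon_i > nchar(mut_aa_full)) next
      n <- nchar(mut_aa_full)
      for (s in seq_len(max(0, n - k + 1))) {
        if (!(s <= codon_i && codon_i <= s + k - 1)) next
        pep <- substr(mut_aa_full, s, s + k - 1)
        for (al in hla_alleles) {
          sc <- scorer(pep, al)
          if (fpkm > fpkm_threshold && all(sc > score_threshold)) {
            passing <- rbind(passing, data.frame(
              peptide = pep, hla_allele = al, gene_id = tx$gene_id,
              stringsAsFactors = FALSE
            ))
          }
        }
      }
    } else if (alt_aa == "*" || ref_aa == "*") {
      if (fpkm > fpkm_threshold) n_expr_nonsyn <- n_expr_nonsyn + 1L
    }
  }
  if (is.null(passing)) {
    passing <- data.frame(peptide = character(0), hla_allele = character(0),
                          gene_id = character(0))
  } else {
    passing <- unique(passing)
  }
  rownames(passing) <- NULL
  list(passing = passing, n_expressed_nonsynonymous = n_expr_nonsyn)
}

#' Simulate a TCR-Vbeta repertoire with known statistics
#'
#' Draws unique CDR3 clonotypes, assigns clone frequencies from a uniform,
#' geometric or power-law model, and multinomially distributes reads over
#' clones (with a floor of one read per clone so every clonotype is
#' observed). Nonproductive clonotypes carry a planted premature stop codon.
#' Ground-truth statistics are recomputed directly on the emitted counts by
#' prefix sums.
#'
#' @param params A [repertoire_sim_params()] object.
#' @param sample_id,group Sample annotation.
#' @return A list: `repertoire` (a [repertoire()] clone table) and `truth`
#'   (`productive_frequency_pct`, `dominant_clone_count`,
#'   `top10_abundance_pct` computed by direct calculation).
#' @export
simulate_repertoire <- function(params, sample_id = "R1", group = "LGG") {
  stopifnot(inherits(params, "repertoire_sim_params"))
  set.seed(params$seed)
  n <- params$n_clones
  aa_len <- sample(12:16, n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  stops <- c("TAA", "TAG", "TGA")
  nonprod <- stats::runif(n) < params$nonproductive_fraction
  make_cdr3 <- function(L, productive) {
    codons <- character(L)
    for (j in seq_len(L)) {
      repeat {
        cod <- paste(sample(bases, 3, replace = TRUE), collapse = "")
        if (!cod %in% stops) break
      }
      codons[j] <- cod
    }
    if (!productive) codons[max(2L, L %/% 2L)] <- sample(stops, 1)
    paste(codons, collapse = "")
  }
  nt <- character(n)
  for (i in seq_len(n)) {
    repeat {
      s <- make_cdr3(aa_len[i], !nonprod[i])
      if (!s %in% nt) break
    }
    nt[i] <- s
  }
  aa <- vapply(nt, translate_codon_table, character(1), USE.NAMES = FALSE)

  probs <- switch(params$frequency_model,
    uniform = rep(1 / n, n),
    geometric = {
      p <- params$model_parameter
      w <- p * (1 - p)^(seq_len(n) - 1)
      w / sum(w)
    },
    powerlaw = {
      w <- seq_len(n)^(-params$model_parameter)
      w / sum(w)
    }
  )
  extra <- stats::rmultinom(1, params$total_reads - n, probs)[, 1]
  reads <- 1L + extra

  rep_tab <- repertoire(
    data.frame(cdr3_nt = nt, cdr3_aa = aa, reads = reads,
               productive = !nonprod, stringsAsFactors = FALSE),
    sample_id = sample_id, group = group
  )

  # direct recomputation on the sampled counts (prefix sums)
  truth <- list(
    productive_frequency_pct = 100 * sum(!nonprod) / n,
    dominant_clone_count = NA_integer_,
    top10_abundance_pct = NA_real_
  )
  pr <- which(!nonprod)
  if (length(pr) > 0) {
    o <- pr[order(-reads[pr], nt[pr])]
    fr <- reads[o] / sum(reads[o])
    truth$dominant_clone_count <-
      as.integer(which(cumsum(fr) >= 0.30 - 1e-12)[1])
    truth$top10_abundance_pct <- 100 * sum(fr[seq_len(min(10, length(fr)))])
  }
  list(repertoire = rep_tab, truth = truth)
}

#' Simulate a qPCR Ct table with planted group shifts
#'
#' Emits a long-format Ct table (sample, group, gene, Ct) including a
#' housekeeping row for every sample. Target Cts are
#' `housekeeping_mean + base_delta_ct + shift * [group == HGG] + noise`;
#' a positive shift lowers the second group's 2^-dCt by `2^-shift`.
#'
#' @param params A [qpcr_sim_params()] object.
#' @return Data.frame `sample_id`, `group`, `gene`, `ct`, plus attribute
#'   `truth` with the planted per-gene expected fold ratio
#'   (group LGG / group HGG) `2^shift`.
#' @export
simulate_qpcr <- function(params) {
  stopifnot(inherits(params, "qpcr_sim_params"))
  set.seed(params$seed)
  groups <- c("LGG", "HGG")
  samples <- data.frame(
    sample_id = sprintf("%s%02d", rep(c("L", "H"), params$n_per_group),
                        c(seq_len(params$n_per_group[1]),
                          seq_len(params$n_per_group[2]))),
    group = rep(groups, params$n_per_group),
    stringsAsFactors = FALSE
  )
  rows <- list()
  hk_ct <- params$housekeeping_ct_mean +
    stats::rnorm(nrow(samples), 0, params$ct_noise_sd)
  rows[[1]] <- data.frame(
    sample_id = samples$sample_id, group = samples$group,
    gene = params$housekeeping_gene, ct = hk_ct,
    stringsAsFactors = FALSE
  )
  for (j in seq_along(params$genes)) {
    ct <- params$housekeeping_ct_mean + params$base_delta_ct[j] +
      params$group_delta_ct_shift[j] * (samples$group == "HGG") +
      stats::rnorm(nrow(samples), 0, params$ct_noise_sd)
    rows[[j + 1]] <- data.frame(
      sample_id = samples$sample_id, group = samples$group,
      gene = params$genes[j], ct = ct, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(
    gene = params$genes,
    expected_fold_lgg_over_hgg = 2^params$group_delta_ct_shift
  )
  out
}
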