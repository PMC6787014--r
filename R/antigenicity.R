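#' Apply a coding SNV to a transcript and translate
#'
#' Edits a single-nucleotide variant into a CDS, translates the reference
#' and mutant sequences with the standard genetic code (translation stops at
#' the first stop codon), and classifies the consequence from the amino
#' acids of the affected codon.
#'
#' @param transcript A list or one-row data.frame with `transcript_id`,
#'   `gene_id` and `cds` (nucleotide string, 5'->3', length divisible by 3,
#'   ATG start).
#' @param variant A list or one-row data.frame with `transcript_id`,
#'   `cds_position` (1-based nucleotide index), `ref_base`, `alt_base`.
#'
#' @return A list: `ref_protein`, `mut_protein` (both truncated at the first
#'   stop), `consequence` (`"synonymous"`, `"missense"`, `"stop_gain"` or
#'   `"stop_loss"`), `protein_position` (1-based codon index),
#'   `transcript_id`, `gene_id`.
#' @export
build_mutant_protein <- function(transcript, variant) {
  cds <- toupper(as.character(transcript$cds))
  pos <- as.integer(variant$cds_position)
  ref <- toupper(as.character(variant$ref_base))
  alt <- toupper(as.character(variant$alt_base))
  if (!grepl("^[ACGT]+$", cds)) stop("CDS contains non-ACGT characters")
  if (!all(c(ref, alt) %in% c("A", "C", "G", "T"))) {
    stop("non-ACGT variant base for ", transcript$transcript_id, ":", pos)
  }
  if (pos < 1 || pos > nchar(cds)) {
    stop("cds_position out of range for ", transcript$transcript_id, ":", pos)
  }
  if (substr(cds, pos, pos) != ref) {
    stop("ref mismatch at ", transcript$transcript_id, ":", pos,
         " (expected ", ref, ", CDS has ", substr(cds, pos, pos), ")")
  }
  mut <- cds
  substr(mut, pos, pos) <- alt
  codon_idx <- (pos - 1L) %/% 3L + 1L
  ref_aa <- translate_dna(substr(cds, 3 * codon_idx - 2, 3 * codon_idx))
  alt_aa <- translate_dna(substr(mut, 3 * codon_idx - 2, 3 * codon_idx))
  consequence <-
    if (ref_aa == alt_aa) "synonymous"
    else if (alt_aa == "*") "stop_gain"
    else if (ref_aa == "*") "stop_loss"
    else "missense"
  list(
    ref_protein = truncate_at_stop(translate_dna(cds)),
    mut_protein = truncate_at_stop(translate_dna(mut)),
    consequence = consequence,
    protein_position = codon_idx,
    transcript_id = as.character(transcript$transcript_id),
    gene_id = as.character(transcript$gene_id)
  )
}

translate_dna <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     no.init.codon = TRUE))
}

truncate_at_stop <- function(aa) sub("\\*.*$", "", aa)

#' Extract the mutated-residue window from a mutant protein
#'
#' Cuts the (by default) 17-residue window centered on the mutated amino
#' acid, truncated at the protein termini when the mutation lies within 8
#' residues of an end.
#'
#' @param mut_protein Mutant protein string (no stop symbol).
#' @param protein_position 1-based position of the mutated residue.
#' @param size Window size, odd, 17 by default.
#' @return A `mutant_window` list: `peptide`, `mutated_index` (0-based index
#'   of the mutated residue within the window), `protein_position`,
#'   `truncated` (TRUE when the window is shorter than `size`).
#' @export
extract_window <- function(mut_protein, protein_position, size = 17L) {
  stopifnot(size %% 2 == 1, size >= 1)
  L <- nchar(mut_protein)
  p <- as.integer(protein_position)
  if (p < 1 || p > L) {
    stop("protein_position ", p, " outside protein of length ", L)
  }
  flank <- (size - 1L) %/% 2L
  lo <- max(1L, p - flank)
  hi <- min(L, p + flank)
  structure(list(
    peptide = substr(mut_protein, lo, hi),
    mutated_index = p - lo,
    protein_position = p,
    truncated = (hi - lo + 1L) < size
  ), class = "mutant_window")
}

#' Enumerate mutation-spanning 9-mers of a window
#'
#' All 9-mers of the window whose span covers the mutated residue,
#' deduplicated. Windows shorter than the peptide length yield an empty
#' result with a flag attribute rather than an error.
#'
#' @param window A [extract_window()] result.
#' @param k Peptide length, 9 for MHC class I.
#' @return Character vector of distinct `k`-mers containing the mutated
#'   amino acid; attribute `flag_short` is TRUE when the window was shorter
#'   than `k`.
#' @export
enumerate_9mers <- function(window, k = 9L) {
  stopifnot(inherits(window, "mutant_window"))
  n <- nchar(window$peptide)
  if (n < k) {
    return(structure(character(0), flag_short = TRUE))
  }
  starts0 <- 0:(n - k) # 0-based
  covers <- starts0 <= window$mutated_index &
    window$mutated_index <= starts0 + k - 1L
  peps <- substring(window$peptide, starts0[covers] + 1L,
                    starts0[covers] + k)
  structure(unique(peps), flag_short = FALSE)
}

#' Enumerate mutation-containing 9-mers for a set of variants
#'
#' Runs [build_mutant_protein()], [extract_window()] and [enumerate_9mers()]
#' over a variant table. Only missense variants produce peptides; stop-gain
#' and stop-loss variants have no single mutated-residue 9-mer semantics and
#' are excluded (recorded in the returned annotation).
#'
#' @param transcripts Data frame with `transcript_id`, `gene_id`, `cds`.
#' @param variants Data frame with `transcript_id`, `cds_position`,
#'   `ref_base`, `alt_base` and optionally `sample_id`.
#' @return A list: `peptides` (data.frame `peptide`, `gene_id`,
#'   `transcript_id`, `cds_position`, `protein_position`) and `annotated`
#'   (the variant table with `consequence`, `gene_id`, `protein_position`
#'   added).
#' @export
enumerate_candidate_peptides <- function(transcripts, variants) {
  tx <- split(transcripts, transcripts$transcript_id)
  ann <- variants
  ann$consequence <- NA_character_
  ann$gene_id <- NA_character_
  ann$protein_position <- NA_integer_
  peps <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    t <- tx[[as.character(v$transcript_id)]]
    if (is.null(t)) stop("unknown transcript: ", v$transcript_id)
    mp <- build_mutant_protein(t[1, ], v)
    ann$consequence[i] <- mp$consequence
    ann$gene_id[i] <- mp$gene_id
    ann$protein_position[i] <- mp$protein_position
    if (mp$consequence != "missense") next
    win <- extract_window(mp$mut_protein, mp$protein_position)
    nine <- enumerate_9mers(win)
    if (length(nine) == 0) next
    peps[[length(peps) + 1L]] <- data.frame(
      peptide = nine,
      gene_id = mp$gene_id,
      transcript_id = mp$transcript_id,
      cds_position = v$cds_position,
      protein_position = mp$protein_position,
      stringsAsFactors = FALSE
    )
  }
  peptides <- if (length(peps)) do.call(rbind, peps) else
    data.frame(peptide = character(0), gene_id = character(0),
               transcript_id = character(0), cds_position = integer(0),
               protein_position = integer(0))
  list(peptides = peptides, annotated = ann)
}

#' Deterministic mock epitope scorer
#'
#' Returns a scorer function mapping each (peptide, allele) pair to three
#' reproducible pseudo-uniform scores in \[0, 1\] — MHC class I binding,
#' proteasomal C-terminal cleavage and TAP transport — via a deterministic
#' string hash. It stands behind the pluggable scorer interface so the
#' filter cascade can be exercised and brute-force-verified without an
#' external predictor; scores carry no biochemical meaning.
#'
#' @return A function `(peptide, allele) -> c(binding, cleavage, tap)`.
#' @export
mock_scorer <- function() {
  function(peptide, allele) {
    c(binding = hash01(paste0(peptide, "|", allele, "|B")),
      cleavage = hash01(paste0(peptide, "|", allele, "|C")),
      tap = hash01(paste0(peptide, "|", allele, "|T")))
  }
}

# deterministic string hash -> [0, 1). A polynomial rolling hash seeds a
# Mersenne-Twister draw (nonlinear scrambling, so near-identical keys give
# independent-looking scores); the caller's RNG state is left untouched.
hash01 <- function(key) {
  v <- utf8ToInt(key)
  h <- 7
  for (ch in v) h <- (h * 131 + ch) %% 2147483647
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(h))
  stats::runif(1)
}

#' Score candidate peptides against a sample's HLA alleles
#'
#' Builds one `EpitopeCandidate` row per (peptide, allele) pair, attaches
#' the three scorer channels and joins gene-level expression. Genes missing
#' from the expression table are treated as unexpressed (FPKM 0) and
#' flagged.
#'
#' @param peptides Data frame from [enumerate_candidate_peptides()]
#'   (`peptide`, `gene_id`, ...).
#' @param hla_alleles Character vector of class I alleles (up to 6).
#' @param scorer A scorer function, e.g. [mock_scorer()].
#' @param expression Data frame with `gene_id` and `fpkm` for this sample.
#' @return Data frame with columns `peptide`, `hla_allele`, `gene_id`,
#'   `mhc_binding_score`, `cleavage_score`, `tap_score`, `fpkm`,
#'   `fpkm_missing`, `contains_mutation`.
#' @export
score_candidates <- function(peptides, hla_alleles, scorer, expression) {
  stopifnot(is.function(scorer), length(hla_alleles) >= 1)
  if (nrow(peptides) == 0) {
    return(data.frame(peptide = character(0), hla_allele = character(0),
                      gene_id = character(0), mhc_binding_score = numeric(0),
                      cleavage_score = numeric(0), tap_score = numeric(0),
                      fpkm = numeric(0), fpkm_missing = logical(0),
                      contains_mutation = logical(0)))
  }
  grid <- merge(peptides, data.frame(hla_allele = hla_alleles), by = NULL)
  sc <- t(vapply(seq_len(nrow(grid)),
                 function(i) scorer(grid$peptide[i], grid$hla_allele[i]),
                 numeric(3)))
  grid$mhc_binding_score <- sc[, 1]
  grid$cleavage_score <- sc[, 2]
  grid$tap_score <- sc[, 3]
  m <- match(grid$gene_id, expression$gene_id)
  grid$fpkm_missing <- is.na(m)
  if (any(grid$fpkm_missing)) {
    warning("no expression value for gene(s): ",
            paste(unique(grid$gene_id[grid$fpkm_missing]), collapse = ", "),
            "; FPKM treated as 0")
  }
  grid$fpkm <- ifelse(is.na(m), 0, expression$fpkm[m])
  grid$contains_mutation <- TRUE
  grid[, c("peptide", "hla_allele", "gene_id", "mhc_binding_score",
           "cleavage_score", "tap_score", "fpkm", "fpkm_missing",
           "contains_mutation")]
}

#' Apply the neo-epitope filter cascade
#'
#' A candidate passes when it contains the mutated amino acid, derives from
#' an expressed gene (FPKM strictly above `fpkm_threshold`), and all three
#' prediction scores are strictly above `score_threshold`.
#'
#' @param candidates Data frame from [score_candidates()].
#' @param score_threshold Strict lower bound on each of the three scores
#'   (default 0.5).
#' @param fpkm_threshold Strict lower bound on FPKM (default 0).
#' @return The candidate table with a logical `passes` column.
#' @export
filter_neoepitopes <- function(candidates, score_threshold = 0.5,
                               fpkm_threshold = 0) {
  candidates$passes <- candidates$contains_mutation &
    candidates$fpkm > fpkm_threshold &
    candidates$mhc_binding_score > score_threshold &
    candidates$cleavage_score > score_threshold &
    candidates$tap_score > score_threshold
  candidates
}

#' Count passing neo-epitopes
#'
#' @param candidates Output of [filter_neoepitopes()].
#' @param unit Counting unit: distinct `(peptide, allele)` pairs (default)
#'   or distinct peptides.
#' @return Integer count.
#' @export
count_neoepitopes <- function(candidates,
                              unit = c("peptide_allele", "peptide")) {
  unit <- match.arg(unit)
  pass <- candidates[candidates$passes, , drop = FALSE]
  if (unit == "peptide_allele") {
    nrow(unique(pass[, c("peptide", "hla_allele")]))
  } else {
    length(unique(pass$peptide))
  }
}

#' Run the neo-epitope pipeline for one sample
#'
#' Convenience wrapper: enumerate mutation-spanning 9-mers, score them
#' against the sample's HLA alleles, and apply the filter cascade.
#'
#' @inheritParams enumerate_candidate_peptides
#' @inheritParams score_candidates
#' @inheritParams filter_neoepitopes
#' @return A list: `candidates` (scored and filtered table), `annotated`
#'   (variant annotation), `n_neoepitopes` (distinct passing
#'   peptide-allele pairs).
#' @export
neoepitope_pipeline <- function(transcripts, variants, hla_alleles,
                                expression, scorer = mock_scorer(),
                                score_threshold = 0.5, fpkm_threshold = 0) {
  enum <- enumerate_candidate_peptides(transcripts, variants)
  cand <- score_candidates(enum$peptides, hla_alleles, scorer, expression)
  cand <- filter_neoepitopes(cand, score_threshold, fpkm_threshold)
  list(candidates = cand, annotated = enum$annotated,
       n_neoepitopes = count_neoepitopes(cand))
}

#' Count expressed nonsynonymous mutations
#'
#' @param annotated Variant table with a `consequence` and `gene_id` column
#'   (from [enumerate_candidate_peptides()] or [build_mutant_protein()]).
#' @param expression Data frame with `gene_id`, `fpkm`.
#' @param fpkm_threshold Strict lower bound on FPKM.
#' @param consequences Consequence classes counted as nonsynonymous.
#' @return Integer count of nonsynonymous variants in expressed genes.
#' @export
count_expressed_mutations <- function(annotated, expression,
                                      fpkm_threshold = 0,
                                      consequences = c("missense",
                                                       "stop_gain",
                                                       "stop_loss")) {
  sel <- annotated[annotated$consequence %in% consequences, , drop = FALSE]
  m <- match(sel$gene_id, expression$gene_id)
  fpkm <- ifelse(is.na(m), 0, expression$fpkm[m])
  sum(fpkm > fpkm_threshold)
}

#' Count expressed cancer germline antigens per sample
#'
#' @param expression Long-format expression table with columns `gene_id`,
#'   `sample_id`, `fpkm`.
#' @param cga_genes Character vector of CGA gene symbols (see
#'   [cga_gene_list()]).
#' @param fpkm_threshold Strict lower bound on FPKM for a gene to count as
#'   expressed.
#' @return Named integer vector, one count per sample.
#' @export
count_expressed_cgas <- function(expression, cga_genes, fpkm_threshold = 0) {
  stopifnot(all(c("gene_id", "sample_id", "fpkm") %in% names(expression)))
  hit <- intersect(unique(expression$gene_id), cga_genes)
  if (length(hit) == 0) {
    stop("no CGA genes found in the expression table; unmatched symbols: ",
         paste(utils::head(cga_genes, 10), collapse = ", "),
         if (length(cga_genes) > 10) ", ..." else "")
  }
  sub <- expression[expression$gene_id %in% hit, , drop = FALSE]
  counts <- tapply(sub$fpkm > fpkm_threshold, sub$sample_id, sum,
                   default = 0L)
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Bundled cancer germline antigen symbols
#'
#' Returns the curated snapshot of well-known cancer/testis antigen gene
#' symbols shipped with the package (a partial snapshot of the community CT
#' antigen catalogue, not the full database). Supply your own list to
#' [count_expressed_cgas()] to use a different catalogue.
#'
#' @return Character vector of gene symbols.
#' @export
cga_gene_list <- function() {
  path <- system.file("extdata", "cga_genes.txt", package = "gliomaTIL")
  read_gene_list(path)
}
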