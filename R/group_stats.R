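#' Relative expression by the 2^-dCt method
#'
#' Normalizes each target gene's Ct to the sample's housekeeping Ct:
#' `value = 2^-(Ct_gene - Ct_housekeeping)`. Missing target Cts propagate as
#' missing values (they are never imputed to zero); a sample without a
#' housekeeping row is an error.
#'
#' @param ct_table Long-format data.frame with columns `sample_id`, `group`,
#'   `gene`, `ct`.
#' @param housekeeping_gene Housekeeping gene name, `"GAPDH"` by default.
#' @param ct_max Optional cycle cutoff: Ct values above it are treated as
#'   undetermined (set to `NA`) before normalization. `NULL` (default)
#'   disables the cutoff.
#' @return Data.frame `sample_id`, `group`, `gene`, `value` for all target
#'   genes.
#' @export
relative_expression <- function(ct_table, housekeeping_gene = "GAPDH",
                                ct_max = NULL) {
  stopifnot(all(c("sample_id", "group", "gene", "ct") %in% names(ct_table)))
  if (!is.null(ct_max)) ct_table$ct[ct_table$ct > ct_max] <- NA_real_
  hk <- ct_table[ct_table$gene == housekeeping_gene, , drop = FALSE]
  targets <- ct_table[ct_table$gene != housekeeping_gene, , drop = FALSE]
  miss <- setdiff(unique(targets$sample_id), hk$sample_id[!is.na(hk$ct)])
  if (length(miss) > 0) {
    stop("missing housekeeping (", housekeeping_gene, ") Ct for sample(s): ",
         paste(miss, collapse = ", "))
  }
  hk_ct <- hk$ct[match(targets$sample_id, hk$sample_id)]
  data.frame(
    sample_id = targets$sample_id,
    group = targets$group,
    gene = targets$gene,
    value = 2^-(targets$ct - hk_ct),
    stringsAsFactors = FALSE
  )
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact p-value (by the null distribution of U, equivalent to full
#' permutation enumeration) when the smaller group has at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie and continuity correction. The degenerate case where every
#' value in both groups is identical returns `p = 1`.
#'
#' @param x,y Numeric vectors (NAs dropped).
#' @param exact_max Largest `min(n_x, n_y)` for which the exact null
#'   distribution is used (ties permitting).
#' @return List with `U` (number of (x, y) pairs with x > y, plus half the
#'   ties), `p.value`, and `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  U <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = U, p.value = 1, method = "degenerate"))
  }
  use_exact <- !ties && min(length(x), length(y)) <= exact_max
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  )
  p <- min(1, ht$p.value)
  list(U = U, p.value = p,
       method = if (use_exact) "exact" else "normal_approx")
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted q-values with monotone enforcement; NAs pass through.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  stopifnot(all(p_values[ok] >= 0 & p_values[ok] <= 1))
  stats::p.adjust(p_values, method = "BH")
}

#' Fold change of two group means
#'
#' `mean_a / mean_b`, rounded half-away-from-zero to `decimals` digits for
#' printed-table replication. Note: when the supplied means are on a log2
#' scale (as in published summary tables), this is a ratio of log-scale
#' means, reproduced as printed; set `decimals = NULL` to skip rounding.
#'
#' @param mean_a,mean_b Group means; `mean_b` must be nonzero.
#' @param decimals Digits for half-away-from-zero rounding, 1 by default;
#'   `NULL` returns the unrounded ratio.
#' @return The (optionally rounded) ratio; `NA` with a warning when
#'   `mean_b` is 0.
#' @export
fold_change <- function(mean_a, mean_b, decimals = 1) {
  if (isTRUE(all.equal(mean_b, 0)) || mean_b == 0) {
    warning("fold change undefined: denominator mean is 0")
    return(NA_real_)
  }
  r <- mean_a / mean_b
  if (is.null(decimals)) return(r)
  round_half_away(r, decimals)
}

# round half away from zero (conventional table rounding, unlike R's
# round-half-even)
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Cells per gram of tissue
#'
#' @param cell_count Nonnegative cell count.
#' @param tissue_mass_g Tissue mass in grams, strictly positive.
#' @return Cells per gram.
#' @export
cells_per_gram <- function(cell_count, tissue_mass_g) {
  if (any(tissue_mass_g <= 0)) stop("tissue mass must be > 0")
  cell_count / tissue_mass_g
}

#' Per-gene two-group expression comparison
#'
#' For each gene: two-sided Mann-Whitney U on the per-sample values of the
#' two groups, Benjamini-Hochberg q across the gene panel, and the fold
#' change of group means. Genes observed in only one group are skipped with
#' a warning; genes with fewer than 2 samples in a group are tested but
#' flagged.
#'
#' @param values Long-format data.frame with columns `sample_id`, `group`,
#'   `gene`, `value` (e.g. from [relative_expression()], or FPKM).
#' @param group_a,group_b The two group labels to compare (defaults: first
#'   two levels encountered, in order).
#' @param fdr `"bh"` (default) or `"none"`.
#' @param fold_change_scale `"ratio_of_means"` (default) divides the group
#'   means of the values as given — this reproduces published-table
#'   arithmetic when the values are log2-scale means; `"log2_diff"` treats
#'   the values as log2 expression and returns the linear-scale fold change
#'   `2^(mean_a - mean_b)`.
#' @return Data.frame with one row per gene: `gene`, `n_a`, `n_b`,
#'   `mean_a`, `mean_b`, `fold_change`, `U`, `p`, `q`, `flag_small_n`.
#' @export
compare_expression <- function(values, group_a = NULL, group_b = NULL,
                               fdr = c("bh", "none"),
                               fold_change_scale = c("ratio_of_means",
                                                     "log2_diff")) {
  fdr <- match.arg(fdr)
  fold_change_scale <- match.arg(fold_change_scale)
  stopifnot(all(c("sample_id", "group", "gene", "value") %in% names(values)))
  grps <- unique(values$group)
  if (is.null(group_a)) group_a <- grps[1]
  if (is.null(group_b)) group_b <- grps[2]
  stopifnot(!is.na(group_a), !is.na(group_b), group_a != group_b)
  genes <- unique(values$gene)
  rows <- list()
  for (g in genes) {
    xa <- values$value[values$gene == g & values$group == group_a]
    xb <- values$value[values$gene == g & values$group == group_b]
    xa <- xa[!is.na(xa)]
    xb <- xb[!is.na(xb)]
    if (length(xa) == 0 || length(xb) == 0) {
      warning("gene ", g, " absent in one group; comparison skipped")
      next
    }
    mw <- mann_whitney_u(xa, xb)
    fc <- if (fold_change_scale == "ratio_of_means") {
      fold_change(mean(xa), mean(xb))
    } else {
      round_half_away(2^(mean(xa) - mean(xb)), 1)
    }
    rows[[g]] <- data.frame(
      gene = g, n_a = length(xa), n_b = length(xb),
      mean_a = mean(xa), mean_b = mean(xb),
      fold_change = fc,
      U = mw$U, p = mw$p.value,
      flag_small_n = length(xa) < 2 || length(xb) < 2,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- if (fdr == "bh") bh_fdr(out$p) else NA_real_
  out[, c("gene", "n_a", "n_b", "mean_a", "mean_b", "fold_change", "U",
          "p", "q", "flag_small_n")]
}
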