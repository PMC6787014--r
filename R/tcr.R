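#' Construct a TCR repertoire object
#'
#' @param clones Data frame with columns `cdr3_nt`, `cdr3_aa`, `reads`
#'   (positive integers) and `productive` (logical).
#' @param sample_id,group Sample annotation.
#' @return A `repertoire` data.frame (clone table with attributes).
#' @export
repertoire <- function(clones, sample_id = NA_character_,
                       group = NA_character_) {
  stopifnot(all(c("cdr3_nt", "cdr3_aa", "reads", "productive") %in%
                  names(clones)))
  if (anyDuplicated(clones$cdr3_nt)) {
    stop("duplicate cdr3_nt clonotypes in repertoire")
  }
  if (any(clones$reads < 1)) stop("clone read counts must be >= 1")
  structure(clones, sample_id = sample_id, group = group,
            class = c("repertoire", "data.frame"))
}

#' Productive frequency of a repertoire
#'
#' Fraction (%) of unique clonotypes without a premature stop codon. The
#' conventional unit is unique rearrangements; `weight = "reads"` gives the
#' read-weighted variant.
#'
#' @param rep A clone table (`repertoire` or plain data.frame).
#' @param weight `"unique"` (default) or `"reads"`.
#' @return Percent in \[0, 100\]; `NA` with a warning for an empty table.
#' @export
productive_frequency <- function(rep, weight = c("unique", "reads")) {
  weight <- match.arg(weight)
  if (nrow(rep) == 0) {
    warning("empty repertoire: productive frequency undefined")
    return(NA_real_)
  }
  if (weight == "unique") {
    100 * sum(rep$productive) / nrow(rep)
  } else {
    100 * sum(rep$reads[rep$productive]) / sum(rep$reads)
  }
}

# productive clones sorted by descending reads, ties broken by cdr3_nt
sorted_clone_fractions <- function(rep, denominator) {
  keep <- if (denominator == "productive") rep$productive else
    rep(TRUE, nrow(rep))
  cl <- rep[keep, , drop = FALSE]
  if (nrow(cl) == 0) return(NULL)
  cl <- cl[order(-cl$reads, cl$cdr3_nt), , drop = FALSE]
  cl$reads / sum(cl$reads)
}

#' Dominant clone count at a cumulative threshold
#'
#' The number of top clonotypes whose cumulative read fraction reaches the
#' threshold (the repertoire "diversity" summary): clones are restricted to
#' productive rearrangements, sorted by read count (ties broken by CDR3-nt),
#' and `k` is the smallest prefix length whose cumulative fraction is `>=`
#' the threshold. The clone that crosses the threshold is counted.
#'
#' @param rep A clone table.
#' @param cumulative_threshold Fraction of total reads, 0.30 by default.
#' @param denominator `"productive"` (default) restricts both the clone set
#'   and the read total to productive clones; `"all"` uses every clone.
#' @return Integer `k`; `NA` with a warning when no clone qualifies.
#' @export
dominant_clone_count <- function(rep, cumulative_threshold = 0.30,
                                 denominator = c("productive", "all")) {
  denominator <- match.arg(denominator)
  stopifnot(cumulative_threshold > 0, cumulative_threshold <= 1)
  fr <- sorted_clone_fractions(rep, denominator)
  if (is.null(fr)) {
    warning("no ", denominator, " clones: dominant clone count undefined")
    return(NA_integer_)
  }
  cum <- cumsum(fr)
  as.integer(which(cum >= cumulative_threshold - 1e-12)[1])
}

#' Cumulative abundance of the top n clones
#'
#' The repertoire "convergence" summary: percent of reads carried by the
#' `n` most frequent clonotypes (all clones when fewer than `n` exist).
#'
#' @inheritParams dominant_clone_count
#' @param n Number of top clones, 10 by default.
#' @return Percent in \[0, 100\]; `NA` with a warning when no clone
#'   qualifies.
#' @export
top_n_abundance <- function(rep, n = 10L,
                            denominator = c("productive", "all")) {
  denominator <- match.arg(denominator)
  fr <- sorted_clone_fractions(rep, denominator)
  if (is.null(fr)) {
    warning("no ", denominator, " clones: top-n abundance undefined")
    return(NA_real_)
  }
  100 * sum(fr[seq_len(min(n, length(fr)))])
}

#' Summary statistics of one repertoire
#'
#' @inheritParams dominant_clone_count
#' @param top_n Number of top clones for the convergence summary.
#' @return One-row data.frame: `sample_id`, `group`, `total_reads`,
#'   `n_clones`, `productive_frequency_pct`, `dominant_clone_count`,
#'   `top10_abundance_pct`.
#' @export
repertoire_stats <- function(rep, cumulative_threshold = 0.30, top_n = 10L,
                             denominator = "productive") {
  data.frame(
    sample_id = attr(rep, "sample_id") %||% NA_character_,
    group = attr(rep, "group") %||% NA_character_,
    total_reads = sum(rep$reads),
    n_clones = nrow(rep),
    productive_frequency_pct = productive_frequency(rep),
    dominant_clone_count = dominant_clone_count(rep, cumulative_threshold,
                                                denominator),
    top10_abundance_pct = top_n_abundance(rep, top_n, denominator),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare repertoire statistics between two groups
#'
#' Two-sided Mann-Whitney U tests on dominant clone count, top-10 abundance
#' and productive frequency across the samples of two groups.
#'
#' @param stats_a,stats_b Data frames of per-sample [repertoire_stats()]
#'   rows.
#' @return Data frame with one row per statistic: `statistic`, `n_a`, `n_b`,
#'   `U`, `p`.
#' @export
compare_repertoire_stats <- function(stats_a, stats_b) {
  feats <- c("dominant_clone_count", "top10_abundance_pct",
             "productive_frequency_pct")
  out <- lapply(feats, function(f) {
    xa <- stats_a[[f]][!is.na(stats_a[[f]])]
    xb <- stats_b[[f]][!is.na(stats_b[[f]])]
    if (length(xa) < 2 || length(xb) < 2) {
      warning("fewer than 2 samples per group for ", f, "; p reported as NA")
      return(data.frame(statistic = f, n_a = length(xa), n_b = length(xb),
                        U = NA_real_, p = NA_real_))
    }
    mw <- mann_whitney_u(xa, xb)
    data.frame(statistic = f, n_a = length(xa), n_b = length(xb),
               U = mw$U, p = mw$p.value)
  })
  do.call(rbind, out)
}
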