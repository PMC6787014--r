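#' Published TCGA summary table of T-cell recruitment genes
#'
#' Printed group summary statistics (log2 FPKM means and SDs, LGG n = 232,
#' HGG n = 246) for chemo-attractants, adhesion/motility molecules and CD8
#' T-cell genes, bundled as package data. These are inputs for fold-change
#' replication; the underlying per-sample TCGA data are not redistributed.
#'
#' @return Data frame with columns `gene`, `category`,
#'   `lgg_mean_log2_fpkm`, `lgg_sd`, `hgg_mean_log2_fpkm`, `hgg_sd`,
#'   `printed_fold_change`.
#' @export
tcga_table1_means <- function() {
  read_tsv_file(system.file("extdata", "tcga_table1_means.tsv",
                            package = "gliomaTIL"))
}

#' Recompute Table-style fold changes from printed group means
#'
#' Applies [fold_change()] (LGG mean divided by HGG mean, rounded
#' half-away-from-zero to one decimal) to each row of a printed summary
#' table, reproducing the published fold-change column. Per the published
#' footnote this ratio is taken on the log2-scale means as printed.
#'
#' @param means Data frame as returned by [tcga_table1_means()].
#' @return The table with a `fold_change` column appended.
#' @export
replicate_fold_changes <- function(means = tcga_table1_means()) {
  means$fold_change <- vapply(
    seq_len(nrow(means)),
    function(i) fold_change(means$lgg_mean_log2_fpkm[i],
                            means$hgg_mean_log2_fpkm[i]),
    numeric(1)
  )
  means
}
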