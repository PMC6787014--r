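# Independent oracles and fixture builders used across the suite. These are
# deliberately naive implementations (brute force, enumeration, closed
# forms) kept separate from the package's computational paths.

# brute-force per-cell distance (um) to the nearest vessel pixel center;
# cells are continuous 0-based px coordinates mapped to their pixel center
oracle_cell_distances <- function(cells, mask, pixel_size_um) {
  vp <- which(mask > 0, arr.ind = TRUE)
  vapply(seq_len(nrow(cells)), function(i) {
    ix <- min(floor(cells$x_px[i]) + 1, nrow(mask))
    iy <- min(floor(cells$y_px[i]) + 1, ncol(mask))
    if (mask[ix, iy] > 0) return(0)
    sqrt(min((vp[, 1] - ix)^2 + (vp[, 2] - iy)^2)) * pixel_size_um
  }, numeric(1))
}

# brute-force annulus bin of each cell: -1 inside vessel, 0..n-1 annuli,
# n beyond the last annulus
oracle_bin_assignment <- function(cells, mask, pixel_size_um,
                                  bin_width_um = 30, max_distance_um = 180) {
  n_bins <- max_distance_um %/% bin_width_um
  d <- oracle_cell_distances(cells, mask, pixel_size_um)
  b <- floor(d / bin_width_um)
  b[b > n_bins] <- n_bins
  ix <- pmin(floor(cells$x_px) + 1, nrow(mask))
  iy <- pmin(floor(cells$y_px) + 1, ncol(mask))
  b[mask[cbind(ix, iy)] > 0] <- -1
  as.integer(b)
}

# full enumeration two-sided Mann-Whitney p: all C(n1+n2, n1) group
# relabelings of the pooled data, symmetric-tail probability of U
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * length(y) / 2
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# step-up Benjamini-Hochberg by the textbook formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# prefix-sum repertoire statistics on a clone table
oracle_dominant_k <- function(clones, threshold = 0.30) {
  pr <- clones[clones$productive, , drop = FALSE]
  pr <- pr[order(-pr$reads, pr$cdr3_nt), , drop = FALSE]
  fr <- cumsum(pr$reads) / sum(pr$reads)
  which(fr >= threshold - 1e-12)[1]
}

oracle_top_n <- function(clones, n = 10) {
  pr <- clones[clones$productive, , drop = FALSE]
  fr <- sort(pr$reads, decreasing = TRUE) / sum(pr$reads)
  100 * sum(fr[seq_len(min(n, length(fr)))])
}

# binary disk mask (x-by-y), center in continuous px coordinates
disk_mask <- function(w, h, cx, cy, r_px) {
  m <- outer((seq_len(w) - 0.5 - cx)^2, (seq_len(h) - 0.5 - cy)^2, "+") <=
    r_px^2
  storage.mode(m) <- "integer"
  m
}

# random clone table with unique CDR3s
random_repertoire <- function(n, max_reads = 200, p_productive = 0.8) {
  nt <- replicate(n, paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                           collapse = ""))
  while (anyDuplicated(nt)) {
    nt[duplicated(nt)] <- replicate(sum(duplicated(nt)),
      paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""))
  }
  data.frame(
    cdr3_nt = nt,
    cdr3_aa = substr(nt, 1, 10),
    reads = sample.int(max_reads, n, replace = TRUE),
    productive = stats::runif(n) < p_productive,
    stringsAsFactors = FALSE
  )
}

# CDS built from an explicit codon vector
cds_from_codons <- function(codons) paste(codons, collapse = "")
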