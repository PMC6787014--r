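#' Segment vessels from a single-channel image
#'
#' Thresholds a grayscale vessel channel (autofluorescence or CD31), fills
#' holes, and removes connected components smaller than `min_area_um2`.
#'
#' @param vessel_channel Numeric matrix (x by y), a single-channel image, or
#'   an already-binary mask.
#' @param threshold_method `"otsu"`, `"mean"`, or a numeric cutoff on the
#'   image intensity scale.
#' @param min_area_um2 Components below this area are discarded.
#' @param pixel_size_um Pixel edge length in micrometers.
#'
#' @return A list with `mask` (integer matrix, 1 = vessel), `stats` (one row
#'   per retained vessel: `label`, `area_um2`, `equivalent_diameter_um`), and
#'   `warning_flag` (TRUE when no vessel survives; an empty image is not an
#'   error).
#' @export
segment_vessels <- function(vessel_channel, threshold_method = "otsu",
                            min_area_um2 = 50, pixel_size_um = 0.5) {
  stopifnot(is.matrix(vessel_channel), pixel_size_um > 0)
  img <- vessel_channel
  if (is.numeric(threshold_method)) {
    thr <- threshold_method
  } else if (identical(threshold_method, "otsu")) {
    rng <- range(img)
    if (rng[1] == rng[2]) {
      thr <- rng[2] # flat image: nothing exceeds the threshold
    } else {
      sc <- (img - rng[1]) / (rng[2] - rng[1])
      thr <- rng[1] + EBImage::otsu(EBImage::Image(sc), range = c(0, 1)) *
        (rng[2] - rng[1])
    }
  } else if (identical(threshold_method, "mean")) {
    thr <- mean(img)
  } else {
    stop("unknown threshold_method: ", threshold_method)
  }
  bin <- img > thr
  storage.mode(bin) <- "integer"
  if (any(bin > 0L)) {
    bin <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bin)))
  }
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin)))
  px_area_um2 <- pixel_size_um^2
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes * px_area_um2 >= min_area_um2)
  mask <- matrix(0L, nrow = nrow(img), ncol = ncol(img))
  mask[lab %in% keep] <- 1L
  stats <- data.frame(
    label = seq_along(keep),
    area_um2 = sizes[keep] * px_area_um2,
    equivalent_diameter_um = 2 * sqrt(sizes[keep] * px_area_um2 / pi)
  )
  list(mask = mask, stats = stats, warning_flag = length(keep) == 0L)
}

#' Build concentric annulus geometry around vessels
#'
#' Computes the per-pixel Euclidean distance (um) to the nearest vessel
#' pixel and partitions the tissue into half-open distance annuli
#' `[k*w, (k+1)*w)` up to `max_distance_um`. Pixels inside vessels belong to
#' no annulus; annuli of nearby vessels are merged through the single
#' nearest-vessel distance map, so no pixel or cell is double counted.
#'
#' @param vessel_mask Binary matrix, nonzero inside vessels.
#' @param pixel_size_um Pixel edge length (um).
#' @param bin_width_um Annulus width, 30 um by default.
#' @param max_distance_um Outer limit of the last annulus, 180 um by default.
#'
#' @return An `annulus_geometry` list: `distance_um` (matrix), `bin_index`
#'   (integer matrix: -1 inside vessels, 0..n_bins-1 for annuli, n_bins
#'   beyond the last annulus), `bin_width_um`, `max_distance_um`, `n_bins`,
#'   `annulus_areas_mm2`, `pixel_size_um`, `n_vessels`.
#' @export
build_annuli <- function(vessel_mask, pixel_size_um, bin_width_um = 30,
                         max_distance_um = 180) {
  stopifnot(is.matrix(vessel_mask), pixel_size_um > 0, bin_width_um > 0,
            max_distance_um >= bin_width_um)
  if (!any(vessel_mask > 0)) stop("no vessels: mask is empty")
  n_bins <- as.integer(max_distance_um %/% bin_width_um)
  dist_um <- vessel_distance_map(vessel_mask > 0) * pixel_size_um
  bin_index <- matrix(floor(dist_um / bin_width_um),
                      nrow = nrow(vessel_mask))
  bin_index[bin_index > n_bins] <- n_bins
  bin_index[vessel_mask > 0] <- -1L
  storage.mode(bin_index) <- "integer"
  counts <- tabulate(bin_index[bin_index >= 0L & bin_index < n_bins] + 1L,
                     nbins = n_bins)
  areas <- counts * pixel_size_um^2 / 1e6
  n_vessels <- max(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(matrix(as.integer(vessel_mask > 0),
                                           nrow = nrow(vessel_mask))))
  ))
  structure(list(
    distance_um = dist_um,
    bin_index = bin_index,
    bin_width_um = bin_width_um,
    max_distance_um = max_distance_um,
    n_bins = n_bins,
    annulus_areas_mm2 = areas,
    pixel_size_um = pixel_size_um,
    n_vessels = as.integer(n_vessels)
  ), class = "annulus_geometry")
}

#' Count cells per annulus and form a perimeter profile
#'
#' Assigns each cell centroid to the annulus of its pixel's distance to the
#' nearest vessel, and reports per-annulus counts, areas and densities.
#' Cells inside vessel lumina or beyond the last annulus are excluded from
#' the bins but reported as counts, so cells are conserved:
#' `sum(count) + inside_vessel + beyond_max == total`.
#'
#' @param cells Data frame with `x_px`, `y_px` (continuous 0-based pixel
#'   coordinates) and `marker`.
#' @param geometry An [build_annuli()] result.
#' @param marker Marker to count (`"CD3"` or `"CD8"`).
#' @param min_vessels Profiles from samples with fewer analyzable vessels
#'   than this are QC-flagged (not dropped).
#'
#' @return A `perimeter_profile` data.frame with columns `bin_lo_um`,
#'   `bin_hi_um`, `count`, `area_mm2`, `density_per_mm2`, and attributes
#'   `inside_vessel_count`, `beyond_max_count`, `n_vessels_analyzed`,
#'   `qc_flag`, `marker`.
#' @export
count_cells_per_annulus <- function(cells, geometry, marker = "CD3",
                                    min_vessels = 5L) {
  stopifnot(inherits(geometry, "annulus_geometry"))
  stopifnot(all(c("x_px", "y_px", "marker") %in% names(cells)))
  cells <- cells[cells$marker == marker, , drop = FALSE]
  w <- nrow(geometry$bin_index)
  h <- ncol(geometry$bin_index)
  if (nrow(cells) > 0 &&
      (any(cells$x_px < 0 | cells$x_px >= w) ||
       any(cells$y_px < 0 | cells$y_px >= h))) {
    stop("cell coordinates outside raster bounds")
  }
  n_bins <- geometry$n_bins
  if (nrow(cells) > 0) {
    ix <- pmin(floor(cells$x_px) + 1L, w)
    iy <- pmin(floor(cells$y_px) + 1L, h)
    b <- geometry$bin_index[cbind(ix, iy)]
  } else {
    b <- integer(0)
  }
  counts <- tabulate(b[b >= 0L & b < n_bins] + 1L, nbins = n_bins)
  prof <- data.frame(
    bin_lo_um = (0:(n_bins - 1)) * geometry$bin_width_um,
    bin_hi_um = (1:n_bins) * geometry$bin_width_um,
    count = counts,
    area_mm2 = geometry$annulus_areas_mm2
  )
  prof$density_per_mm2 <- ifelse(prof$area_mm2 > 0,
                                 prof$count / prof$area_mm2, NA_real_)
  structure(prof,
    inside_vessel_count = sum(b == -1L),
    beyond_max_count = sum(b == n_bins),
    n_vessels_analyzed = geometry$n_vessels,
    qc_flag = geometry$n_vessels < min_vessels,
    marker = marker,
    class = c("perimeter_profile", "data.frame")
  )
}

#' Normalize a perimeter profile to its first annulus
#'
#' Adds a `normalized_pct` column with the first annulus set to 100% and the
#' remaining annuli expressed relative to it. If the first-annulus density
#' is zero (or missing) the profile is flagged and left unnormalized. The
#' operation is idempotent: normalized percentages are always recomputed
#' from the densities.
#'
#' @param profile A `perimeter_profile` (any data.frame with a
#'   `density_per_mm2` column).
#' @return The profile with `normalized_pct` added and attribute
#'   `normalization_flag` (TRUE when normalization was skipped).
#' @export
normalize_profile <- function(profile) {
  stopifnot("density_per_mm2" %in% names(profile))
  d0 <- profile$density_per_mm2[1]
  flagged <- is.na(d0) || d0 <= 0
  if (flagged) {
    warning("first-annulus density is zero or missing; normalization skipped")
    profile$normalized_pct <- NA_real_
  } else {
    profile$normalized_pct <- 100 * profile$density_per_mm2 / d0
  }
  attr(profile, "normalization_flag") <- flagged
  profile
}

#' Compare perimeter profiles between two groups
#'
#' Runs a two-sided Mann-Whitney U test per annulus on per-sample densities
#' (or normalized percentages), mirroring the per-perimeter LGG-vs-HGG
#' comparison. P-values are not multiplicity-corrected by default; set
#' `fdr = TRUE` for Benjamini-Hochberg correction across annuli.
#'
#' @param group_a,group_b Lists of `perimeter_profile` objects.
#' @param use_normalized Compare `normalized_pct` instead of density.
#' @param fdr Apply BH correction across the annuli.
#' @return Data frame with one row per annulus: `bin_lo_um`, `bin_hi_um`,
#'   `n_a`, `n_b`, `U`, `p`, and `q` when `fdr = TRUE`. Annuli where either
#'   group has fewer than 2 usable values get `p = NA` with a warning.
#' @export
compare_profiles <- function(group_a, group_b, use_normalized = FALSE,
                             fdr = FALSE) {
  stopifnot(length(group_a) >= 1, length(group_b) >= 1)
  col <- if (use_normalized) "normalized_pct" else "density_per_mm2"
  bins <- group_a[[1]][, c("bin_lo_um", "bin_hi_um")]
  n_bins <- nrow(bins)
  get_bin <- function(g, k) {
    v <- vapply(g, function(p) p[[col]][k], numeric(1))
    v[!is.na(v)]
  }
  res <- bins
  res$n_a <- res$n_b <- NA_integer_
  res$U <- res$p <- NA_real_
  degenerate <- FALSE
  for (k in seq_len(n_bins)) {
    xa <- get_bin(group_a, k)
    xb <- get_bin(group_b, k)
    res$n_a[k] <- length(xa)
    res$n_b[k] <- length(xb)
    if (length(xa) < 2 || length(xb) < 2) {
      degenerate <- TRUE
      next
    }
    mw <- mann_whitney_u(xa, xb)
    res$U[k] <- mw$U
    res$p[k] <- mw$p.value
  }
  if (degenerate) {
    warning("annuli with fewer than 2 samples in a group: p reported as NA")
  }
  if (fdr) res$q <- bh_fdr(res$p)
  res
}

#' Estimate the perivascular decay length of a profile
#'
#' Fits `ln(density) ~ distance` by least squares over the annulus midpoints
#' with positive density; the decay length is `lambda_hat = -1/slope`. Flat
#' or increasing profiles give `lambda_hat = Inf` (no decay).
#'
#' @param profile A `perimeter_profile`.
#' @return A list with `lambda_hat_um`, `slope`, `n_bins_used`, and `flag`
#'   (TRUE when fewer than 3 positive bins are available and the estimate is
#'   undefined, `lambda_hat_um = NA`).
#' @export
estimate_decay_length <- function(profile) {
  stopifnot(all(c("bin_lo_um", "bin_hi_um", "density_per_mm2") %in%
                  names(profile)))
  mid <- (profile$bin_lo_um + profile$bin_hi_um) / 2
  d <- profile$density_per_mm2
  use <- !is.na(d) & d > 0
  if (sum(use) < 3) {
    warning("fewer than 3 annuli with positive density; decay length undefined")
    return(list(lambda_hat_um = NA_real_, slope = NA_real_,
                n_bins_used = sum(use), flag = TRUE))
  }
  fit <- stats::lm(log(d[use]) ~ mid[use])
  slope <- unname(stats::coef(fit)[2])
  lambda <- if (slope >= 0) Inf else -1 / slope
  list(lambda_hat_um = lambda, slope = slope, n_bins_used = sum(use),
       flag = FALSE)
}

#' Per-vessel mean aggregation of a tissue sample's spatial profile
#'
#' Alternative to the default pooled aggregation: computes one profile per
#' vessel (pixels and cells assigned to their nearest vessel) and averages
#' the per-vessel densities. Exposed because the aggregation rule from
#' vessel-level counts to a tumor-level profile is a reporting choice.
#'
#' @param tissue A `tissue_sample` (or list with `vessel_mask`, `cells`,
#'   `pixel_size_um`).
#' @param marker Marker to count.
#' @param bin_width_um,max_distance_um Annulus geometry.
#' @return A `perimeter_profile`-like data.frame where `density_per_mm2` is
#'   the mean of per-vessel densities; counts and areas are totals.
#' @export
profile_per_vessel_mean <- function(tissue, marker = "CD3",
                                    bin_width_um = 30, max_distance_um = 180) {
  mask <- tissue$vessel_mask
  psz <- tissue$pixel_size_um
  lab <- EBImage::imageData(EBImage::bwlabel(
    EBImage::Image(matrix(as.integer(mask > 0), nrow = nrow(mask)))
  ))
  lab <- matrix(lab, nrow = nrow(mask))
  n_v <- max(lab)
  if (n_v == 0) stop("no vessels: mask is empty")
  n_bins <- as.integer(max_distance_um %/% bin_width_um)
  # distance and nearest-vessel label per pixel via per-vessel distance maps
  dist_stack <- array(NA_real_, dim = c(nrow(mask), ncol(mask), n_v))
  for (v in seq_len(n_v)) {
    dist_stack[, , v] <- vessel_distance_map(lab == v) * psz
  }
  nearest <- apply(dist_stack, c(1, 2), which.min)
  dens <- matrix(NA_real_, nrow = n_v, ncol = n_bins)
  counts <- areas <- matrix(0, nrow = n_v, ncol = n_bins)
  cells <- tissue$cells[tissue$cells$marker == marker, , drop = FALSE]
  ix <- pmin(floor(cells$x_px) + 1L, nrow(mask))
  iy <- pmin(floor(cells$y_px) + 1L, ncol(mask))
  for (v in seq_len(n_v)) {
    dv <- dist_stack[, , v]
    own <- nearest == v & mask == 0L
    bin_px <- floor(dv / bin_width_um)
    for (k in seq_len(n_bins)) {
      sel <- own & bin_px == (k - 1)
      areas[v, k] <- sum(sel) * psz^2 / 1e6
    }
    if (nrow(cells) > 0) {
      cell_own <- nearest[cbind(ix, iy)] == v & mask[cbind(ix, iy)] == 0L
      cb <- floor(dv[cbind(ix, iy)] / bin_width_um)
      for (k in seq_len(n_bins)) {
        counts[v, k] <- sum(cell_own & cb == (k - 1))
      }
    }
    dens[v, ] <- ifelse(areas[v, ] > 0, counts[v, ] / areas[v, ], NA_real_)
  }
  prof <- data.frame(
    bin_lo_um = (0:(n_bins - 1)) * bin_width_um,
    bin_hi_um = (1:n_bins) * bin_width_um,
    count = colSums(counts),
    area_mm2 = colSums(areas),
    density_per_mm2 = colMeans(dens, na.rm = TRUE)
  )
  structure(prof,
    n_vessels_analyzed = n_v,
    qc_flag = n_v < 5L,
    marker = marker,
    aggregation = "per_vessel_mean",
    class = c("perimeter_profile", "data.frame")
  )
}
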