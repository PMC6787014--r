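# Perivascular annulus quantification

test_that("vessel segmentation handles empty, clean and sub-threshold cases", {
  blank <- matrix(0, 100, 100)
  seg <- segment_vessels(blank, threshold_method = 0.5, pixel_size_um = 1)
  expect_equal(nrow(seg$stats), 0)
  expect_true(seg$warning_flag)
  expect_true(all(seg$mask == 0L))

  # one disk of radius 20 um at 1 um/px: area within 5% of pi r^2
  img <- disk_mask(120, 120, 60, 60, 20) * 1.0
  seg <- segment_vessels(img, threshold_method = 0.5, pixel_size_um = 1)
  expect_equal(nrow(seg$stats), 1)
  expect_lt(abs(seg$stats$area_um2 - pi * 20^2) / (pi * 20^2), 0.05)
  expect_lt(abs(seg$stats$equivalent_diameter_um - 40), 1)

  # min-area filter: the smaller of two disks is dropped
  img2 <- pmax(disk_mask(200, 200, 50, 50, 15),
               disk_mask(200, 200, 150, 150, 3)) * 1.0
  seg2 <- segment_vessels(img2, threshold_method = 0.5,
                          min_area_um2 = 100, pixel_size_um = 1)
  expect_equal(nrow(seg2$stats), 1)

  # otsu on a bimodal image recovers the disk
  img3 <- img * 0.8 + 0.1
  seg3 <- segment_vessels(img3, threshold_method = "otsu", pixel_size_um = 1)
  expect_equal(nrow(seg3$stats), 1)
})

test_that("annulus geometry uses half-open 30 um bins and excludes vessels", {
  mask <- disk_mask(450, 450, 225, 225, 20)
  geom <- build_annuli(mask, pixel_size_um = 1)
  expect_equal(geom$n_bins, 6L)
  # half-open binning on the distance map itself
  sel <- geom$distance_um >= 30 & geom$distance_um < 60
  expect_true(all(geom$bin_index[sel] == 1L))
  expect_true(all(geom$bin_index[mask > 0] == -1L))
  expect_true(all(geom$bin_index[geom$distance_um >= 180 & mask == 0L] == 6L))
  expect_error(build_annuli(matrix(0L, 10, 10), 1), "no vessels")
})

test_that("annulus areas of a single disk match the closed form within 5%", {
  r <- 20
  mask <- disk_mask(450, 450, 225, 225, r)
  geom <- build_annuli(mask, pixel_size_um = 1)
  analytic <- pi * ((r + geom$bin_width_um * (1:6))^2 -
                      (r + geom$bin_width_um * (0:5))^2) / 1e6
  rel <- abs(geom$annulus_areas_mm2 - analytic) / analytic
  expect_true(all(rel < 0.05))
})

test_that("cell binning matches the brute-force distance oracle", {
  for (s in 1:5) {
    set.seed(300 + s)
    mask <- matrix(0L, 200, 200)
    for (v in 1:3) {
      mask <- pmax(mask, disk_mask(200, 200, runif(1, 30, 170),
                                   runif(1, 30, 170), runif(1, 5, 15)))
    }
    cells <- data.frame(x_px = runif(400, 0, 200), y_px = runif(400, 0, 200),
                        marker = "CD3")
    geom <- build_annuli(mask, pixel_size_um = 1)
    ix <- floor(cells$x_px) + 1
    iy <- floor(cells$y_px) + 1
    got <- geom$bin_index[cbind(ix, iy)]
    expect_equal(got, oracle_bin_assignment(cells, mask, 1))
    # conservation: binned + inside + beyond = total
    prof <- count_cells_per_annulus(cells, geom)
    expect_equal(sum(prof$count) + attr(prof, "inside_vessel_count") +
                   attr(prof, "beyond_max_count"), nrow(cells))
  }
})

test_that("densities are count/area and cells out of bounds are rejected", {
  mask <- disk_mask(450, 450, 225, 225, 20)
  geom <- build_annuli(mask, pixel_size_um = 1)
  cells <- data.frame(x_px = c(250, 251, 252), y_px = rep(225, 3),
                      marker = "CD3")
  prof <- count_cells_per_annulus(cells, geom)
  expect_equal(prof$count[1], 3)
  expect_equal(prof$density_per_mm2[1], 3 / prof$area_mm2[1])
  expect_equal(prof$density_per_mm2[1], 3 / prof$area_mm2[1])
  expect_error(
    count_cells_per_annulus(
      data.frame(x_px = 500, y_px = 10, marker = "CD3"), geom),
    "outside raster"
  )
  # no cells: an all-zero profile is valid
  prof0 <- count_cells_per_annulus(
    data.frame(x_px = numeric(0), y_px = numeric(0),
               marker = character(0)), geom)
  expect_true(all(prof0$count == 0))
  # a single vessel is flagged against the 5-vessel inclusion rule
  expect_true(attr(prof0, "qc_flag"))
})

test_that("profile normalization sets the first annulus to 100%", {
  prof <- data.frame(
    bin_lo_um = seq(0, 150, 30), bin_hi_um = seq(30, 180, 30),
    count = c(50, 25, 10, 5, 5, 5), area_mm2 = 1,
    density_per_mm2 = c(50, 25, 10, 5, 5, 5)
  )
  np <- normalize_profile(prof)
  expect_equal(np$normalized_pct, c(100, 50, 20, 10, 10, 10))
  # idempotent
  expect_equal(normalize_profile(np)$normalized_pct, np$normalized_pct)
  # constant profile: all 100
  prof$density_per_mm2 <- rep(7, 6)
  expect_equal(normalize_profile(prof)$normalized_pct, rep(100, 6))
  # zero first annulus: flagged, unnormalized
  prof$density_per_mm2 <- c(0, 1, 1, 1, 1, 1)
  expect_warning(np0 <- normalize_profile(prof), "skipped")
  expect_true(attr(np0, "normalization_flag"))
  expect_true(all(is.na(np0$normalized_pct)))
})

test_that("per-annulus group comparison behaves at the degenerate limits", {
  mk <- function(d) {
    structure(data.frame(
      bin_lo_um = seq(0, 150, 30), bin_hi_um = seq(30, 180, 30),
      count = d, area_mm2 = 1, density_per_mm2 = d
    ), class = c("perimeter_profile", "data.frame"))
  }
  set.seed(1)
  base <- lapply(1:8, function(i) mk(runif(6, 10, 20)))
  # identical groups: exact test, even split, p = 1 everywhere
  cmp <- compare_profiles(base, base)
  expect_true(all(cmp$p == 1))
  # strong shift at n = 8 vs 8: p < 0.01 in every annulus
  shifted <- lapply(base, function(p) mk(p$density_per_mm2 * 10))
  cmp2 <- compare_profiles(shifted, base)
  expect_true(all(cmp2$p < 0.01))
  expect_false(any(is.na(cmp2$p)))
  # single-sample groups: missing p with a warning
  expect_warning(cmp3 <- compare_profiles(base[1], base[1]), "fewer than 2")
  expect_true(all(is.na(cmp3$p)))
  # optional BH correction across annuli
  cmp4 <- compare_profiles(shifted, base, fdr = TRUE)
  expect_true(all(cmp4$q >= cmp4$p))
})

test_that("decay length estimation is exact on noiseless profiles", {
  mid <- seq(15, 165, 30)
  prof <- data.frame(
    bin_lo_um = seq(0, 150, 30), bin_hi_um = seq(30, 180, 30),
    count = 1, area_mm2 = 1,
    density_per_mm2 = 500 * exp(-mid / 40)
  )
  est <- estimate_decay_length(prof)
  expect_equal(est$lambda_hat_um, 40, tolerance = 1e-10)
  # constant profile: no decay
  prof$density_per_mm2 <- rep(3, 6)
  expect_identical(estimate_decay_length(prof)$lambda_hat_um, Inf)
  # fewer than 3 positive annuli: undefined and flagged
  prof$density_per_mm2 <- c(5, 2, 0, 0, 0, 0)
  expect_warning(est2 <- estimate_decay_length(prof), "fewer than 3")
  expect_true(est2$flag)
  expect_true(is.na(est2$lambda_hat_um))
})

test_that("per-vessel mean aggregation agrees with pooling for one vessel", {
  ts <- simulate_tissue(spatial_sim_params(
    image_size_px = c(500L, 500L), pixel_size_um = 1, n_vessels = 1L,
    vessel_radius_um = c(20, 20), baseline_density_per_mm2 = 5000,
    decay_length_um = 50, seed = 5
  ))
  geom <- build_annuli(ts$vessel_mask, 1)
  pooled <- count_cells_per_annulus(ts$cells, geom)
  pv <- profile_per_vessel_mean(ts)
  expect_equal(pv$count, pooled$count)
  expect_equal(pv$density_per_mm2, pooled$density_per_mm2)
})
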