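# 2^-dCt, Mann-Whitney U, BH-FDR, fold change

test_that("relative expression follows 2^-dCt", {
  ct <- data.frame(
    sample_id = rep(c("S1", "S2"), each = 3),
    group = "LGG",
    gene = rep(c("GAPDH", "GENEA", "GENEB"), 2),
    ct = c(20, 20, 23, 21, 22, 24)
  )
  rel <- relative_expression(ct)
  expect_equal(rel$value[rel$sample_id == "S1" & rel$gene == "GENEA"], 1)
  expect_equal(rel$value[rel$sample_id == "S1" & rel$gene == "GENEB"], 0.125)
  expect_equal(rel$value[rel$sample_id == "S2" & rel$gene == "GENEA"], 0.5)
  # scale-free: shifting all Cts of a sample leaves values unchanged
  ct2 <- ct
  ct2$ct <- ct2$ct + 5
  expect_equal(relative_expression(ct2)$value, rel$value)
  # missing target Ct propagates as missing, never zero
  ct$ct[2] <- NA
  expect_true(is.na(relative_expression(ct)$value[1]))
  # missing housekeeping row errors with the sample named
  expect_error(relative_expression(ct[ct$gene != "GAPDH", ]), "S1")
  # optional undetermined-cycle cutoff
  ct3 <- data.frame(sample_id = "S1", group = "LGG",
                    gene = c("GAPDH", "GENEA"), ct = c(20, 39.5))
  expect_true(is.na(relative_expression(ct3, ct_max = 35)$value))
})

test_that("exact Mann-Whitney matches enumeration and known cases", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p.value, 0.1)
  expect_equal(mw$method, "exact")
  # symmetry under swapping groups
  expect_equal(mann_whitney_u(c(4, 5, 6), c(1, 2, 3))$p.value, 0.1)
  # identical multisets give p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  # all values tied across both groups: degenerate, p = 1
  deg <- mann_whitney_u(c(5, 5, 5), c(5, 5))
  expect_equal(deg$p.value, 1)
  # exact path agrees with full permutation enumeration for all n <= 6
  set.seed(14)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      x <- sample(seq_len(100), n1)
      y <- sample(setdiff(seq_len(100), x), n2)
      expect_equal(mann_whitney_u(x, y)$p.value, oracle_mw_p(x, y),
                   tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
  # large samples switch to the corrected normal approximation
  set.seed(15)
  big <- mann_whitney_u(rnorm(40), rnorm(40) + 0.2)
  expect_equal(big$method, "normal_approx")
  expect_true(big$p.value > 0 && big$p.value <= 1)
})

test_that("BH q-values reproduce the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  set.seed(16)
  for (i in 1:100) {
    p <- runif(sample(2:30, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # monotone in p ranks
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
  }
})

test_that("fold change reproduces printed-table arithmetic", {
  expect_equal(fold_change(6.1, 7.6), 0.8) # CCL5 row
  expect_equal(fold_change(9.1, 7.6), 1.2) # CCL3 row
  expect_equal(fold_change(3, 3), 1.0)
  expect_equal(fold_change(1.6, 1.5), 1.1) # rounds half away from zero
  expect_equal(fold_change(0.25, 1, decimals = 1), 0.3)
  expect_equal(fold_change(1, 3, decimals = NULL), 1 / 3)
  expect_warning(fc0 <- fold_change(2, 0), "undefined")
  expect_true(is.na(fc0))

  tab <- replicate_fold_changes()
  seven <- c(CCL5 = 0.8, CCL3 = 1.2, CXCL4 = 1.1, ICAM1 = 0.9,
             GZMK = 0.6, ICOS = 0.4, CD8A = 0.8)
  got <- tab$fold_change[match(names(seven), tab$gene)]
  expect_equal(got, unname(seven))
})

test_that("cells per gram scales inversely with mass", {
  expect_equal(cells_per_gram(1000, 0.5), 2000)
  expect_equal(cells_per_gram(0, 0.3), 0)
  expect_equal(cells_per_gram(1200, 0.4 * 2), cells_per_gram(1200, 0.4) / 2)
  expect_error(cells_per_gram(10, 0), "> 0")
})

test_that("per-gene group comparison joins U, p, q and fold change", {
  mk <- function(vals, group) {
    do.call(rbind, lapply(names(vals), function(g) {
      data.frame(sample_id = paste0(group, seq_along(vals[[g]])),
                 group = group, gene = g, value = vals[[g]])
    }))
  }
  a <- mk(list(GENEA = 1:10, GENEB = 11:20), "LGG")
  # identical groups: p = 1, fold change 1.0
  same <- compare_expression(rbind(a, transform(mk(
    list(GENEA = 1:10, GENEB = 11:20), "HGG"))), "LGG", "HGG")
  expect_true(all(same$p == 1))
  expect_true(all(same$fold_change == 1.0))
  # planted 8-fold separation at n = 10/10: significant after FDR
  b <- mk(list(GENEA = (1:10) / 8, GENEB = (11:20) / 8), "HGG")
  cmp <- compare_expression(rbind(a, b), "LGG", "HGG")
  expect_true(all(cmp$fold_change == 8.0))
  expect_true(all(cmp$q < 0.05))
  # gene order invariance
  shuf <- rbind(a, b)
  shuf <- shuf[sample(nrow(shuf)), ]
  cmp2 <- compare_expression(shuf, "LGG", "HGG")
  cmp2 <- cmp2[match(cmp$gene, cmp2$gene), ]
  expect_equal(cmp$p, cmp2$p)
  # gene absent in one group is skipped with a warning
  extra <- data.frame(sample_id = "L99", group = "LGG", gene = "GENEC",
                      value = 5)
  expect_warning(cmp3 <- compare_expression(rbind(a, b, extra),
                                            "LGG", "HGG"), "skipped")
  expect_false("GENEC" %in% cmp3$gene)
  # log2-scale alternative fold change
  cmp4 <- compare_expression(rbind(a, b), "LGG", "HGG",
                             fold_change_scale = "log2_diff")
  expect_equal(cmp4$fold_change,
               round(2^(cmp$mean_a - cmp$mean_b), 1), tolerance = 0.06)
})

test_that("qPCR simulator plants recoverable group shifts", {
  # zero shift, zero noise: both groups identical
  q0 <- simulate_qpcr(qpcr_sim_params(group_delta_ct_shift = 0,
                                      ct_noise_sd = 0, seed = 4))
  r0 <- relative_expression(q0)
  for (g in unique(r0$gene)) {
    expect_equal(unique(r0$value[r0$gene == g & r0$group == "LGG"]),
                 unique(r0$value[r0$gene == g & r0$group == "HGG"]))
  }
  # +3 cycle shift in HGG, zero noise: HGG expression is exactly 1/8
  q3 <- simulate_qpcr(qpcr_sim_params(group_delta_ct_shift = 3,
                                      ct_noise_sd = 0, seed = 4))
  r3 <- relative_expression(q3)
  m <- tapply(r3$value, list(r3$gene, r3$group), mean)
  expect_equal(unname(m[, "HGG"] / m[, "LGG"]), rep(1 / 8, nrow(m)))
  # housekeeping rows present for every sample
  expect_setequal(unique(q3$sample_id[q3$gene == "GAPDH"]),
                  unique(q3$sample_id))
  # determinism
  expect_identical(simulate_qpcr(qpcr_sim_params(seed = 6)),
                   simulate_qpcr(qpcr_sim_params(seed = 6)))
})

test_that("a one-cycle shift is detected in most replicates at n = 20/20", {
  hits <- 0
  for (s in 1:100) {
    q <- simulate_qpcr(qpcr_sim_params(genes = "CXCL9",
                                       group_delta_ct_shift = 1,
                                       ct_noise_sd = 0.3,
                                       n_per_group = c(20L, 20L),
                                       seed = 9000 + s))
    rel <- relative_expression(q)
    p <- mann_whitney_u(rel$value[rel$group == "LGG"],
                        rel$value[rel$group == "HGG"])$p.value
    if (p < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
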