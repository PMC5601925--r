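test_that("z-scores match hand computation and flag constants", {
  # X = (1,2,3) with sample SD -> z = (-1, 0, 1)
  zs <- zscore_matrix(cbind(m1 = c(1, 2, 3)))
  expect_equal(as.numeric(zs$z), c(-1, 0, 1))
  # population-SD convention
  zp <- zscore_matrix(cbind(m1 = c(1, 2, 3)), sd_type = "population")
  expect_equal(as.numeric(zp$z), c(-1, 0, 1) * sqrt(3 / 2))
  # any valid column: mean 0 (1e-12) and sample SD 1
  set.seed(2)
  x <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("m", 1:4)))
  z <- zscore_matrix(x)$z
  expect_true(all(abs(colMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-12))
  # constant marker flagged, not zeroed
  zc <- zscore_matrix(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  expect_true(zc$constant[["b"]])
  expect_true(all(is.na(zc$z[, "b"])))
  expect_error(zscore_matrix(cbind(a = 1)), class = "combitet_data_error")
})

test_that("z-scores are invariant to positive affine rescaling", {
  set.seed(3)
  x <- matrix(rexp(120), 30, 4, dimnames = list(NULL, paste0("m", 1:4)))
  g <- rep(c("mLama4", "mAlg8"), 15)
  z1 <- zscore_matrix(x, group = g)
  z2 <- zscore_matrix(sweep(sweep(x, 2, c(2, 3, 0.5, 10), `*`), 2,
                            c(-1, 4, 0, 2), `+`), group = g)
  expect_equal(z1$z, z2$z)
  expect_equal(z1$averaged, z2$averaged)
  expect_equal(dim(z1$averaged), c(2, 4))
})

test_that("pooled t + Holm-Sidak matches the Sidak closed form", {
  set.seed(4)
  # family of m identical comparisons -> all raw p equal p0,
  # adjusted p = 1 - (1 - p0)^m for every member
  x <- rnorm(10); y <- rnorm(10, 1)
  fam <- replicate(5, list(list(x, y)))
  res <- t_test_holm_sidak(fam)
  p0 <- res$p[1]
  expect_true(all(abs(res$p - p0) < 1e-12))
  expect_equal(res$p_adjusted, rep(1 - (1 - p0)^5, 5))
  # single-test family: adjusted equals raw
  res1 <- t_test_holm_sidak(list(list(x, y)))
  expect_equal(res1$p_adjusted, res1$p)
  # identical groups: t = 0, p = 1
  res0 <- t_test_holm_sidak(list(list(c(1, 2, 3), c(1, 2, 3))))
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p, 1)
  # pooled-variance t matches stats::t.test(var.equal = TRUE)
  ref <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res1$statistic, unname(ref$statistic))
  expect_equal(res1$p, ref$p.value)
  expect_error(t_test_holm_sidak(list(list(1, c(1, 2)))),
               class = "combitet_data_error")
})

test_that("Holm-Sidak adjustment is a monotone step-down procedure", {
  set.seed(6)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- holm_sidak_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-12))
    # step-down definition checked directly
    m <- length(p)
    expect_equal(adj[o][1], 1 - (1 - p[o][1])^m)
  }
})

test_that("BH flags equal brute-force step-up on random p-vectors", {
  set.seed(7)
  for (i in 1:200) {
    m <- sample(1:20, 1)
    p <- round(runif(m), sample(c(1, 2, 6), 1))  # include ties
    q <- sample(c(0.05, 0.25, 0.5), 1)
    expect_identical(bh_fdr(p, q), oracle_bh(p, q))
  }
  expect_identical(bh_fdr(rep(1, 5), 0.25), rep(FALSE, 5))
  expect_identical(bh_fdr(rep(0, 5), 0.25), rep(TRUE, 5))
  expect_identical(bh_fdr(c(0.01, 0.02, 0.9), 0.25),
                   c(TRUE, TRUE, FALSE))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "combitet_data_error")
})

test_that("Fisher exact agrees with enumeration for all margins <= 12", {
  # exact worked example: [[5,0],[0,5]] -> 2/252
  expect_equal(fisher_exact_test(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
  expect_equal(fisher_exact_test(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact_test(matrix(c(0, 0, 3, 4), 2)), 1)
  # exhaustive sweep over all tables with n <= 12 against stats::fisher.test
  for (n in c(6, 9, 12)) {
    for (r1 in 0:n) for (c1 in 0:n) {
      for (a in max(0, r1 + c1 - n):min(r1, c1)) {
        tab <- matrix(c(a, c1 - a, r1 - a, n - r1 - c1 + a), 2)
        expect_equal(fisher_exact_test(tab),
                     stats::fisher.test(tab)$p.value, tolerance = 1e-9)
      }
    }
  }
  expect_error(fisher_exact_test(matrix(c(0.5, 1, 1, 1), 2)),
               class = "combitet_data_error")
})

test_that("family-wise error stays controlled under the null", {
  set.seed(8)
  n_fam <- 400
  rejections <- vapply(seq_len(n_fam), function(i) {
    fam <- replicate(8, list(list(rnorm(5), rnorm(5))))
    any(t_test_holm_sidak(fam)$significant)
  }, logical(1))
  fwer <- mean(rejections)
  mc_sd <- sqrt(0.05 * 0.95 / n_fam)
  expect_lte(fwer, 0.05 + 2 * mc_sd)
})

test_that("summarize_markers reports per-group medians on decoded cells", {
  sch <- assign_codes(tiny_panel(), seed = 1)
  ts <- default_tissue_spec("tumour", 4000)
  ts$composition[] <- c(cd8_t = 1, cd4_t = 0, b_cell = 0, other_cd45 = 0,
                        dead = 0, bead = 0)
  ts$antigen_freq <- c(mLama4 = 0, mAlg8 = 0)
  ts$cluster_mix <- list(tetneg = c(C3 = 1, stats::setNames(rep(0, 9),
                           setdiff(paste0("C", 1:10), "C3"))))
  spec <- experiment_spec(ts, seed = 31)
  ev <- simulate_experiment(spec, sch, noise_model(), seed = 31)$tumour$A
  sm <- summarize_markers(ev, groups = ev$truth$cluster)
  # C3-pure group: PD-1 ~100% positive, KLRG-1 ~0%
  expect_gt(sm$pct_positive[sm$marker == "PD1"], 95)
  expect_lt(sm$pct_positive[sm$marker == "KLRG1"], 5)
  # single-cell group median equals that cell's value
  one <- subset_events(ev, 1)
  sm1 <- summarize_markers(one, groups = "solo")
  expect_equal(sm1$median[sm1$marker == "PD1"],
               unname(logicle_transform(one$exprs[1, "PD1"])))
  # empty groups are flagged, not dropped
  g <- factor(rep("a", n_events(ev)), levels = c("a", "b"))
  sm2 <- summarize_markers(ev, groups = g)
  expect_true(all(sm2$n[sm2$group == "b"] == 0))
  expect_true(all(is.na(sm2$median[sm2$group == "b"])))
})

test_that("fold changes report treated/control ratios with replicates", {
  t1 <- data.frame(antigen = "mLama4", tissue = "tumour",
                   frequency = 0.204)
  c1 <- data.frame(antigen = "mLama4", tissue = "tumour",
                   frequency = 0.102)
  fc <- frequency_fold_change(t1, c1)
  expect_equal(fc$fold_change, 2.0)
  # replicate inputs: mean and SEM
  tr <- data.frame(antigen = "mLama4", tissue = "tumour",
                   replicate = 1:4, frequency = c(0.20, 0.21, 0.19, 0.20))
  co <- data.frame(antigen = "mLama4", tissue = "tumour",
                   replicate = 1:4, frequency = c(0.10, 0.10, 0.11, 0.09))
  fcr <- frequency_fold_change(tr, co)
  ratios <- tr$frequency / co$frequency
  expect_equal(fcr$fold_change, mean(ratios))
  expect_equal(fcr$sem, sd(ratios) / 2)
  # zero control frequency flagged undefined
  c0 <- c1; c0$frequency <- 0
  fc0 <- frequency_fold_change(t1, c0)
  expect_true(is.na(fc0$fold_change))
  expect_true(fc0$undefined)
  expect_error(frequency_fold_change(t1, data.frame(antigen = "x",
                                                    tissue = "tumour",
                                                    frequency = 1)),
               class = "combitet_data_error")
})
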