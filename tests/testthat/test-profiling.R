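test_that("downsampling is uniform, capped, seeded and duplicate-free", {
  panel <- default_channels()
  ex <- matrix(seq_len(25000 * 2), nrow = 25000, ncol = 2,
               dimnames = list(NULL, c("PD1", "CD8")))
  small_panel <- channel_panel(c("PD1", "CD8"), c("Nd148", "Nd146"),
                               c("phenotype", "lineage"),
                               marker = c("PD1", "CD8"))
  ev <- event_table(ex, small_panel)
  ds <- downsample_events(ev, cap = 10000, seed = 2)
  expect_equal(n_events(ds), 10000)
  expect_equal(anyDuplicated(ds$exprs[, 1]), 0L)
  expect_identical(downsample_events(ev, cap = 10000, seed = 2)$exprs,
                   ds$exprs)
  # below the cap everything is retained
  ev500 <- subset_events(ev, 1:500)
  expect_equal(n_events(downsample_events(ev500, cap = 10000)), 500)
})

test_that("downsampling does not bias decoded frequencies (< 3 binomial SD)", {
  sch <- assign_codes(fixture_panel(), seed = 1)
  ts <- default_tissue_spec("tumour", 25000)
  ts$composition[] <- c(cd8_t = 1, cd4_t = 0, b_cell = 0, other_cd45 = 0,
                        dead = 0, bead = 0)
  spec <- experiment_spec(ts, seed = 13)
  ev <- simulate_experiment(spec, sch, noise_model(), seed = 13)$tumour$A
  dec_full <- decode_cells(ev, sch)
  f_full <- mean(dec_full$antigen == "mLama4", na.rm = FALSE)
  f_full <- sum(dec_full$antigen == "mLama4", na.rm = TRUE) / n_events(ev)
  ds <- downsample_events(ev, cap = 10000, seed = 3)
  dec_ds <- decode_cells(ds, sch)
  f_ds <- sum(dec_ds$antigen == "mLama4", na.rm = TRUE) / n_events(ds)
  tol <- 3 * sqrt(f_full * (1 - f_full) / 10000)
  expect_lt(abs(f_ds - f_full), tol)
})

test_that("t-SNE separates labelled Gaussian blobs (silhouette > 0.5)", {
  set.seed(7)
  n <- 1000
  centers <- matrix(rnorm(2 * 20, sd = 4), nrow = 2)
  lab <- rep(1:2, each = n / 2)
  mat <- centers[lab, ] + matrix(rnorm(n * 20, sd = 0.4), n, 20)
  pp <- profile_params(perplexity = 30, iterations = 500, seed = 5)
  emb <- run_tsne(mat, pp)
  expect_equal(dim(emb$Y), c(n, 2))
  sub <- sample.int(n, 300)
  expect_gt(mean_silhouette(emb$Y[sub, ], lab[sub]), 0.5)
  # determinism under seed
  emb2 <- run_tsne(mat, pp)
  expect_identical(emb$Y, emb2$Y)
  # KL divergence non-increasing across post-exaggeration checkpoints
  costs <- emb$itercosts[-(1:5)]
  expect_true(all(diff(costs) <= 1e-8))
  # duplicate rows embed close to each other
  mat_dup <- rbind(mat, mat[1, ])
  emb3 <- run_tsne(mat_dup, pp)
  d_dup <- sqrt(sum((emb3$Y[n + 1, ] - emb3$Y[1, ])^2))
  d_typ <- stats::median(as.matrix(stats::dist(emb3$Y[sample.int(n, 200), ])))
  expect_lt(d_dup, d_typ / 10)
  # too few rows for the perplexity errors
  expect_error(run_tsne(mat[1:50, ], pp), class = "combitet_data_error")
})

test_that("k-means on separable blobs recovers truth; WCSS monotone in restarts", {
  set.seed(11)
  k <- 10
  centers <- cbind(rep(seq(0, 45, by = 5), 1), rep(c(0, 50), each = 5))
  lab <- rep(1:k, each = 60)
  emb <- centers[lab, ] + matrix(rnorm(600 * 2, sd = 0.3), 600, 2)
  cm <- cluster_embedding(emb, k = 10, restarts = 50, seed = 2)
  expect_equal(adjusted_rand(cm$labels, lab), 1.0)
  expect_identical(cluster_embedding(emb, k = 10, restarts = 50,
                                     seed = 2)$labels, cm$labels)
  # k = 1: WCSS equals the total sum of squares
  cm1 <- cluster_embedding(emb, k = 1, restarts = 1, seed = 1)
  expect_equal(cm1$wcss, sum(scale(emb, scale = FALSE)^2))
  # best-of-restarts is non-increasing in restart count (same stream)
  w <- vapply(c(1, 5, 25, 100), function(r)
    cluster_embedding(emb, k = 10, restarts = r, seed = 3)$wcss, numeric(1))
  expect_true(all(diff(w) <= 1e-9))
  expect_error(cluster_embedding(emb[1:5, ], k = 10),
               class = "combitet_data_error")
})

test_that("rule-based labels recover archetypes (>= 95%) at default noise", {
  sch <- assign_codes(tiny_panel(), seed = 1)
  ts <- default_tissue_spec("tumour", 12000)
  ts$composition[] <- c(cd8_t = 1, cd4_t = 0, b_cell = 0, other_cd45 = 0,
                        dead = 0, bead = 0)
  # uniform mixture over all 10 archetypes for tetramer-negative cells
  ts$antigen_freq <- c(mLama4 = 0, mAlg8 = 0)
  ts$cluster_mix <- list(tetneg = stats::setNames(rep(0.1, 10),
                                                  paste0("C", 1:10)))
  spec <- experiment_spec(ts, seed = 17)
  ev <- simulate_experiment(spec, sch, noise_model(), seed = 17)$tumour$A
  lab <- assign_rule_clusters(ev)
  acc <- mean(lab == ev$truth$cluster)
  expect_gte(acc, 0.95)
  # per-archetype accuracy also holds
  per <- tapply(lab == ev$truth$cluster, ev$truth$cluster, mean)
  expect_true(all(per >= 0.90))
})

test_that("all-background cells fall in C1/C2 by CD27, never C3-C10", {
  panel <- default_channels()
  ex <- matrix(0, nrow = 200, ncol = nrow(panel),
               dimnames = list(NULL, panel$label))
  ex[1:100, "CD27"] <- 150
  ev <- event_table(ex, panel)
  lab <- assign_rule_clusters(ev)
  expect_true(all(lab[1:100] == "C1"))
  expect_true(all(lab[101:200] == "C2"))
})

test_that("rule labels are invariant to monotone rescaling of data + thresholds", {
  sch <- assign_codes(tiny_panel(), seed = 1)
  spec <- quick_spec(n_cells = 3000, seed = 19)
  ev <- simulate_experiment(spec, sch, noise_model(), seed = 19)$tumour$A
  cd8 <- subset_events(ev, ev$truth$population == "cd8_t")
  thr <- rule_thresholds()
  lab <- assign_rule_clusters(cd8, thresholds = thr)
  # double every raw intensity and push the thresholds through the same
  # monotone map on the transformed scale: y -> f(2 * f^-1(y))
  cd8x <- cd8
  cd8x$exprs <- cd8x$exprs * 2
  lp <- logicle_params()
  remap <- function(y) logicle_transform(2 * logicle_inverse(y, lp), lp)
  thr2 <- list(positive = remap(thr$positive), high = remap(thr$high))
  lab2 <- assign_rule_clusters(cd8x, thresholds = thr2)
  expect_identical(lab, lab2)
})

test_that("anti-CTLA-4 simulation collapses C3-C5 and fills C7-C10", {
  sch <- assign_codes(tiny_panel(), seed = 1)
  base <- default_experiment(n_cells = c(tumour = 20000, spleen = 1000,
                                         dLN = 1000, ndLN = 1000), seed = 23)
  trt <- apply_treatment_effect(base, "anti-CTLA-4")
  sims <- lapply(list(base, trt), function(sp)
    simulate_experiment(sp, sch, noise_model(), seed = 23)$tumour$A)
  occupancy <- lapply(sims, function(ev) {
    cd8 <- subset_events(ev, ev$truth$population == "cd8_t" &
                           ev$truth$antigen != "tetneg")
    lab <- assign_rule_clusters(cd8)
    tab <- table(factor(lab, levels = c(paste0("C", 1:10), "unclassified")))
    tab / sum(tab)
  })
  lo <- paste0("C", 1:5); hi <- paste0("C", 7:10)
  expect_lt(sum(occupancy[[2]][lo]), 0.3 * sum(occupancy[[1]][lo]))
  # >= 50% of the mass moves into C7-C10
  expect_gt(sum(occupancy[[2]][hi]) - sum(occupancy[[1]][hi]), 0.5 *
              (sum(occupancy[[1]][lo]) - sum(occupancy[[2]][lo])) - 0.05)
})

test_that("chi-square concordance matches the closed form on the diagonal", {
  a <- rep(c("x", "y", "z"), each = 100)
  cc <- compare_clusterings(a, a)
  expect_equal(cc$statistic, 600)   # 2 * n for a 3x3 diagonal table
  expect_equal(cc$dof, 4)
  expect_lt(cc$p, 1e-10)
  # agrees with stats::chisq.test without continuity correction
  b <- sample(rep(c("x", "y", "z"), c(120, 90, 90)))
  ref <- suppressWarnings(stats::chisq.test(table(a, b), correct = FALSE))
  cc2 <- compare_clusterings(a, b)
  expect_equal(cc2$statistic, unname(ref$statistic))
  expect_equal(cc2$p, ref$p.value)
  expect_error(compare_clusterings(a, a[-1]),
               class = "combitet_data_error")
  expect_error(compare_clusterings(a, rep("x", 300)),
               class = "combitet_data_error")
})

test_that("independent labelings give approximately uniform chi-square p", {
  set.seed(5)
  ps <- replicate(400, {
    a <- sample(letters[1:3], 150, replace = TRUE)
    b <- sample(letters[1:4], 150, replace = TRUE)
    compare_clusterings(a, b)$p
  })
  # uniformity: binned chi-square GOF at alpha = 0.01
  counts <- table(cut(ps, seq(0, 1, by = 0.1)))
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("cluster_profile summarizes medians and percent-positive", {
  panel <- default_channels()
  ex <- matrix(0, nrow = 60, ncol = nrow(panel),
               dimnames = list(NULL, panel$label))
  ex[1:30, "PD1"] <- 150   # identical cells
  ev <- event_table(ex, panel)
  labels <- rep(c("hi", "lo"), each = 30)
  prof <- cluster_profile(ev, labels)
  expect_equal(sum(unique(prof[, c("cluster", "n")])$n), 60)
  hi_pd1 <- prof[prof$cluster == "hi" & prof$marker == "PD1", ]
  expect_equal(hi_pd1$median, logicle_transform(150))
  expect_equal(hi_pd1$pct_positive, 100)
  lo_pd1 <- prof[prof$cluster == "lo" & prof$marker == "PD1", ]
  expect_equal(lo_pd1$pct_positive, 0)
})

test_that("two-cluster profiles reproduce the generating archetype ordering", {
  sch <- assign_codes(tiny_panel(), seed = 1)
  ts <- default_tissue_spec("tumour", 6000)
  ts$composition[] <- c(cd8_t = 1, cd4_t = 0, b_cell = 0, other_cd45 = 0,
                        dead = 0, bead = 0)
  ts$antigen_freq <- c(mLama4 = 0, mAlg8 = 0)
  ts$cluster_mix <- list(tetneg = c(C2 = 0.5, C5 = 0.5,
                                    stats::setNames(rep(0, 8),
                                                    setdiff(paste0("C", 1:10),
                                                            c("C2", "C5")))))
  spec <- experiment_spec(ts, seed = 29)
  ev <- simulate_experiment(spec, sch, noise_model(), seed = 29)$tumour$A
  prof <- cluster_profile(ev, ev$truth$cluster)
  arch <- default_archetypes()
  for (mk in c("PD1", "Tim3", "CD39", "Sca1")) {
    m5 <- prof$median[prof$cluster == "C5" & prof$marker == mk]
    m2 <- prof$median[prof$cluster == "C2" & prof$marker == mk]
    if (arch["C5", mk] == "high" && arch["C2", mk] == "neg")
      expect_gt(m5, m2 + 1)
  }
})
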