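panel81 <- fixture_panel()
sch81 <- assign_codes(panel81, seed = 1)

# noise-free CD8-only tumour world shared by the exact-decode tests
nf_spec <- local({
  ts <- default_tissue_spec("tumour", 8000)
  ts$composition[] <- c(cd8_t = 1, cd4_t = 0, b_cell = 0, other_cd45 = 0,
                        dead = 0, bead = 0)
  experiment_spec(ts, seed = 5)
})
nf_ev <- simulate_experiment(nf_spec, sch81, noise_model_noise_free(),
                             seed = 5)$tumour$A

test_that("noise-free decode is exact and matches the brute-force oracle", {
  res <- decode_cells(nf_ev, sch81)
  tru <- nf_ev$truth$antigen
  tru[tru == "tetneg"] <- NA
  expect_identical(res$antigen, unname(tru))   # 0 misses, 0 misassignments
  # brute-force oracle: every cell against every code
  thr <- attr(res, "thresholds")
  oracle <- oracle_decode(nf_ev, sch81, positivity = min(thr),
                          separation = 0.5)
  expect_identical(res$antigen, oracle)
  # assigned + unassigned conserve the CD8 total
  fr <- compute_frequencies(res)
  expect_equal(sum(fr$count), nrow(res))
  expect_equal(sum(fr$frequency), 1)
})

test_that("noisy decode matches the brute-force oracle cell by cell", {
  ts <- default_tissue_spec("tumour", 3000)
  ts$composition[] <- c(cd8_t = 1, cd4_t = 0, b_cell = 0, other_cd45 = 0,
                        dead = 0, bead = 0)
  spec <- experiment_spec(ts, seed = 6)
  ev <- simulate_experiment(spec, sch81, noise_model(), seed = 6)$tumour$A
  params <- decode_params(positivity = 1.3, separation = 0.5)
  res <- decode_cells(ev, sch81, params)
  oracle <- oracle_decode(ev, sch81, positivity = 1.3, separation = 0.5)
  expect_identical(res$antigen, oracle)
})

test_that("partial and tied reporter patterns stay unassigned", {
  ex <- matrix(0, nrow = 3, ncol = nrow(nf_ev$panel),
               dimnames = list(NULL, nf_ev$panel$label))
  code <- sch81$code_map$mLama4
  ex[1, code[1:2]] <- 150                     # only 2 channels high
  ex[2, code] <- 150                          # valid triple
  ex[3, sch81$channels[1:4]] <- 150           # 4-way saturated tie
  ev <- event_table(ex, nf_ev$panel)
  res <- decode_cells(ev, sch81, decode_params(positivity = 1.3))
  expect_true(is.na(res$antigen[1]))
  expect_equal(res$antigen[2], "mLama4")
  expect_true(is.na(res$antigen[3]))          # fails rank3-rank4 separation
})

test_that("compute_frequencies does the arithmetic and flags empties", {
  res <- data.frame(antigen = c(rep("mLama4", 10), rep(NA, 990)),
                    top3 = "", separation = 0, decoy = FALSE)
  fr <- compute_frequencies(res, n_cd8 = 1000)
  expect_equal(fr$frequency[fr$antigen == "mLama4"], 0.01)
  expect_equal(fr$frequency[fr$antigen == "unassigned"], 0.99)
  none <- compute_frequencies(res[11:1000, , drop = FALSE], n_cd8 = 990)
  expect_equal(none$frequency, 1)  # only the unassigned row
  expect_error(compute_frequencies(res, n_cd8 = 0),
               class = "combitet_data_error")
})

test_that("hit calling applies the strict >0.15% rule per tissue", {
  freqs <- data.frame(
    antigen = rep(c("mLama4", "candX"), each = 2),
    tissue = rep(c("tumour", "spleen"), 2),
    frequency = c(0.102, 0.008, 0.0015, 0.002))
  hits <- call_hits(freqs)
  expect_true(all(hits$is_hit[hits$antigen == "mLama4"]))
  # exactly 0.15% is NOT a hit
  expect_false(hits$is_hit[hits$antigen == "candX" &
                             hits$tissue == "tumour"])
  expect_false(any(hits$consistent_hit[hits$antigen == "candX"]))
  # relaxed k-of-n consistency
  hits1 <- call_hits(freqs, min_tissues = 1)
  expect_true(all(hits1$consistent_hit[hits1$antigen == "candX"]))
  # all-zero tissue yields zero hits
  wt <- data.frame(antigen = c("a", "b"), tissue = "spleen", frequency = 0)
  expect_false(any(call_hits(wt)$is_hit))
})

test_that("hit counts are monotone in the cutoff and separation", {
  ts <- default_tissue_spec("tumour", 20000)
  spec <- experiment_spec(ts, seed = 9)
  ev <- simulate_experiment(spec, sch81, noise_model(), seed = 9)$tumour$A
  g <- apply_gate_tree(ev, default_gate_tree(ev$panel))
  cd8 <- subset_events(ev, g$mask)
  freqs_at <- function(sep) {
    dec <- decode_cells(cd8, sch81, decode_params(separation = sep))
    fr <- compute_frequencies(dec, antigens = screened_antigens(panel81))
    fr$tissue <- "tumour"
    fr
  }
  fr0 <- freqs_at(0.5)
  n_hits <- vapply(c(0.0005, 0.0015, 0.05, 0.2),
                   function(cut) sum(call_hits(
                     fr0, decode_params(hit_cutoff = cut))$is_hit),
                   numeric(1))
  expect_true(all(diff(n_hits) <= 0))
  n_sep <- vapply(c(0, 0.5, 2, 4), function(s) {
    sum(call_hits(freqs_at(s))$is_hit)
  }, numeric(1))
  expect_true(all(diff(n_sep) <= 0))
})

test_that("frequency recovery is unbiased over 5 replicates (3 SEM)", {
  freqs <- vapply(1:5, function(r) {
    spec <- quick_spec(n_cells = 20000, seed = 100 + r)
    ev <- simulate_experiment(spec, sch81, noise_model(),
                              seed = 100 + r)$tumour$A
    g <- apply_gate_tree(ev, default_gate_tree(ev$panel))
    cd8 <- subset_events(ev, g$mask)
    dec <- decode_cells(cd8, sch81)
    fr <- compute_frequencies(dec, antigens = c("mLama4", "mAlg8"))
    fr$frequency[fr$antigen == "mLama4"]
  }, numeric(1))
  sem <- stats::sd(freqs) / sqrt(5)
  expect_lt(abs(mean(freqs) - 0.102), 3 * sem)
})

test_that("dual-configuration concordance flags agreement", {
  ha <- call_hits(data.frame(antigen = c("mLama4", "decoyX"),
                             tissue = "tumour",
                             frequency = c(0.1, 0.002)))
  hb <- call_hits(data.frame(antigen = c("mLama4", "decoyX"),
                             tissue = "tumour",
                             frequency = c(0.09, 0.0001)))
  cc <- hit_concordance(ha, hb)
  expect_true(cc$concordant[cc$antigen == "mLama4"])
  expect_false(cc$concordant[cc$antigen == "decoyX"])
  hb2 <- hb[hb$antigen == "mLama4", ]
  expect_error(hit_concordance(ha, hb2), class = "combitet_data_error")
})

test_that("dual configurations suppress decoy false positives", {
  # force a permissive decode (no positivity floor, tiny separation) so
  # background can produce decoy positives, then check concordance culls
  # them harder than either single configuration
  schB <- assign_codes(panel81, config_id = "B", seed = 2, avoid = sch81)
  ts <- default_tissue_spec("tumour", 4000)
  ts$antigen_freq <- c(mLama4 = 0.05, mAlg8 = 0.05)
  spec <- experiment_spec(ts, seed = 11)
  loose <- decode_params(positivity = 0.4, separation = 0.01,
                         hit_cutoff = 0.0015)
  rates <- replicate(3, {
    seed <- sample.int(1e6, 1)
    sim <- simulate_experiment(spec, list(A = sch81, B = schB),
                               noise_model(), seed = seed)
    per_cfg <- lapply(c("A", "B"), function(cfg) {
      ev <- sim$tumour[[cfg]]
      g <- apply_gate_tree(ev, default_gate_tree(ev$panel))
      cd8 <- subset_events(ev, g$mask)
      sch <- if (cfg == "A") sch81 else schB
      dec <- decode_cells(cd8, sch, loose)
      fr <- compute_frequencies(dec, antigens = screened_antigens(panel81))
      fr$tissue <- "tumour"
      call_hits(fr, loose)
    })
    truth_pos <- c("mLama4", "mAlg8")
    fp_a <- sum(per_cfg[[1]]$is_hit & !per_cfg[[1]]$antigen %in% truth_pos)
    cc <- hit_concordance(per_cfg[[1]], per_cfg[[2]])
    fp_cc <- sum(cc$concordant & !cc$antigen %in% truth_pos)
    c(fp_a, fp_cc)
  })
  expect_lte(sum(rates[2, ]), sum(rates[1, ]))
})
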