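# Shared fixtures and independent oracles for the test suite.
# Everything is generated in code; no binary fixtures.

fixture_panel <- function() {
  build_default_panel(system.file("extdata", "panel_candidates_synthetic.csv",
                                  package = "combitet"))
}

# small two-antigen panel for fast decode tests
tiny_panel <- function() {
  antigen_panel(data.frame(
    antigen_id = c("mLama4", "mAlg8"),
    peptide = c("VGFNFRTL", "ITYTWTRL"),
    category = "known"))
}

# one-tissue experiment spec with controllable size/frequencies
quick_spec <- function(tissue = "tumour", n_cells = 20000, seed = 1,
                       replicates = 1L, arm = "isotype") {
  experiment_spec(default_tissue_spec(tissue, n_cells), arm = arm,
                  replicates = replicates, seed = seed)
}

# independent recursive subset enumerator (oracle for enumerate_codes)
oracle_subsets <- function(n, k) {
  if (k == 0) return(list(integer(0)))
  if (n < k) return(list())
  with_last <- lapply(oracle_subsets(n - 1, k - 1), function(s) c(s, n))
  c(oracle_subsets(n - 1, k), with_last)
}

# brute-force decoder: test every cell against every code of the scheme
# (independent of the ranking shortcut in decode_cells)
oracle_decode <- function(cd8_events, scheme, positivity, separation,
                          params = logicle_params()) {
  tx <- logicle_transform(
    cd8_events$exprs[, sort(scheme$channels), drop = FALSE], params)
  labs <- colnames(tx)
  out <- rep(NA_character_, nrow(tx))
  for (i in seq_len(nrow(tx))) {
    v <- tx[i, ]
    for (ag in names(scheme$code_map)) {
      cd <- scheme$code_map[[ag]]
      inside <- v[cd]
      outside <- v[setdiff(labs, cd)]
      if (all(inside > positivity) &&
          (min(inside) - max(outside)) >= separation) {
        out[i] <- ag
        break
      }
    }
  }
  out
}

# brute-force BH step-up by definition
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  kmax <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) kmax <- i
  rej <- logical(m)
  if (kmax > 0) rej[o[seq_len(kmax)]] <- TRUE
  rej
}

# mean silhouette of a 2-group labelled embedding
mean_silhouette <- function(emb, labels) {
  d <- as.matrix(dist(emb))
  sil <- vapply(seq_len(nrow(emb)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(emb)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(d[i, labels == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}
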