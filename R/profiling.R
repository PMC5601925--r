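# Phenotype profiling: downsampling, Barnes-Hut t-SNE on the logicle scale,
# k-means of the embedding (best of many restarts), rule-based C1-C10
# annotation, chi-square concordance between labelings, and per-cluster
# marker summaries.

#' Profiling parameters
#'
#' @param downsample_cap maximum CD8+ T cells per tissue entering the
#'   embedding (default 10,000).
#' @param markers marker subset for the embedding; default all phenotype
#'   markers. `exclude` removes markers (e.g. PD-1 under anti-PD-1
#'   treatment, where the therapeutic antibody can mask staining).
#' @param exclude markers to drop from `markers`.
#' @param perplexity,iterations,theta Barnes-Hut t-SNE controls (defaults
#'   30, 1000, 0.5).
#' @param k k-means centres (default 10).
#' @param restarts k-means random restarts (default 1000).
#' @param seed RNG seed for embedding and clustering.
#' @return a `profile_params` list.
#' @export
profile_params <- function(downsample_cap = 10000, markers = PHENO_MARKERS,
                           exclude = character(0), perplexity = 30,
                           iterations = 1000, theta = 0.5, k = 10,
                           restarts = 1000, seed = 1L) {
  if (downsample_cap < 1) ct_config_error("downsample_cap must be >= 1")
  if (k < 1) ct_config_error("k must be >= 1")
  if (restarts < 1) ct_config_error("restarts must be >= 1")
  structure(list(downsample_cap = downsample_cap,
                 markers = setdiff(markers, exclude),
                 perplexity = perplexity, iterations = iterations,
                 theta = theta, k = k, restarts = restarts,
                 seed = as.integer(seed)),
            class = "profile_params")
}

#' Downsample events uniformly without replacement
#'
#' @param events an `event_table`.
#' @param cap maximum events retained (default 10,000).
#' @param seed RNG seed.
#' @return an `event_table` with `min(n, cap)` events.
#' @export
downsample_events <- function(events, cap = 10000, seed = 1L) {
  if (cap < 1) ct_config_error("cap must be >= 1")
  n <- n_events(events)
  if (n <= cap) return(events)
  idx <- with_seed(seed, sort(sample.int(n, cap)))
  subset_events(events, idx)
}

#' Barnes-Hut t-SNE embedding
#'
#' Wraps the Rtsne implementation (the same Barnes-Hut code path the
#' original analysis used) on a transformed marker matrix. Deterministic
#' under `seed`.
#'
#' @param mat numeric matrix (cells x markers, transformed scale).
#' @param params a [profile_params()].
#' @return list with `Y` (n x 2 coordinates) and `itercosts` (KL divergence
#'   at the optimizer's 50-iteration checkpoints).
#' @export
run_tsne <- function(mat, params = profile_params()) {
  mat <- as.matrix(mat)
  need <- 3 * params$perplexity + 1
  if (nrow(mat) < need)
    ct_data_error("t-SNE needs at least %d rows at perplexity %g",
                  need, params$perplexity)
  fit <- with_seed(params$seed,
    Rtsne::Rtsne(mat, dims = 2, perplexity = params$perplexity,
                 theta = params$theta, max_iter = params$iterations,
                 check_duplicates = FALSE, pca = FALSE, verbose = FALSE))
  list(Y = fit$Y, itercosts = fit$itercosts)
}

#' k-means clustering of a 2-D embedding, best of many restarts
#'
#' Runs `restarts` independent k-means fits under one seeded RNG stream and
#' keeps the solution with the lowest within-cluster sum of squares, so the
#' best-of-restarts WCSS is non-increasing in the restart count.
#'
#' @param embedding numeric matrix (n x 2 t-SNE coordinates).
#' @param k centres (default 10).
#' @param restarts random restarts (default 1000).
#' @param seed RNG seed.
#' @return a `cluster_model`: list with `labels` (1..k), `centers`, `wcss`,
#'   `k`, `restarts`.
#' @export
cluster_embedding <- function(embedding, k = 10, restarts = 1000, seed = 1L) {
  embedding <- as.matrix(embedding)
  if (nrow(embedding) < k)
    ct_data_error("need at least k = %d rows", k)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      km <- suppressWarnings(
        stats::kmeans(embedding, centers = k, nstart = 1, iter.max = 100))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  structure(list(labels = best$cluster, centers = best$centers,
                 wcss = best$tot.withinss, k = k, restarts = restarts),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("k-means model: k=%d, best of %d restarts, WCSS=%.4g\n",
              x$k, x$restarts, x$wcss))
  invisible(x)
}

#' Positivity / high-level thresholds for the rule classifier
#'
#' Positivity reuses the gating definition (midpoint between the background
#' and positive modes); the low-vs-high split is the midpoint between the
#' transformed "low" and "high" archetype medians of the noise model.
#'
#' @param noise a [noise_model()] (defaults give thresholds matching the
#'   default generator).
#' @param params logicle parameters.
#' @param positivity optional fixed positivity threshold.
#' @return list with numeric scalars `positive` and `high`.
#' @export
rule_thresholds <- function(noise = noise_model(), params = logicle_params(),
                            positivity = NULL) {
  lo <- logicle_transform(exp(noise$low[[1]]), params)
  hi <- logicle_transform(exp(noise$high[[1]]), params)
  bg <- logicle_transform(noise$bg_mean, params)
  list(positive = positivity %||% mean(c(bg, lo)),
       high = mean(c(lo, hi)))
}

#' Rule-based C1-C10 cluster assignment
#'
#' Applies the sequential biaxial rule table (see
#' [default_cluster_rules()]) to logicle-transformed phenotype channels.
#' Cells matching no rule are labelled "unclassified".
#'
#' @param events an `event_table` of CD8+ T cells.
#' @param rules a `cluster_rules` object.
#' @param thresholds list with `positive` and `high` transformed-scale
#'   thresholds (scalar or named per marker), e.g. [rule_thresholds()].
#' @param params logicle parameters.
#' @return character vector of labels C1..C10 / "unclassified".
#' @export
assign_rule_clusters <- function(events, rules = default_cluster_rules(),
                                 thresholds = rule_thresholds(),
                                 params = logicle_params()) {
  mk <- rules$markers
  miss <- setdiff(mk, colnames(events$exprs))
  if (length(miss))
    ct_config_error("rule markers missing from events: %s",
                    paste(miss, collapse = ", "))
  tx <- transform_channels(events, mk, params)
  thr_of <- function(x) {
    if (length(x) == 1L && is.null(names(x))) {
      stats::setNames(rep(x, length(mk)), mk)
    } else {
      if (!all(mk %in% names(x)))
        ct_config_error("per-marker thresholds must cover all rule markers")
      x[mk]
    }
  }
  tp <- thr_of(thresholds$positive)
  th <- thr_of(thresholds$high)
  pos <- sweep(tx, 2L, tp, `>`)
  hi <- sweep(tx, 2L, th, `>`)
  .apply_rules(pos, hi)
}

#' Pearson chi-square concordance between two labelings
#'
#' @param labels_a,labels_b equal-length label vectors (>= 2 categories
#'   each).
#' @return list with `statistic`, `dof` ((r-1)(c-1)), `p`, and the
#'   contingency `table`.
#' @export
compare_clusterings <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    ct_data_error("labelings differ in length")
  tab <- table(labels_a, labels_b)
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    ct_data_error("chi-square undefined: fewer than 2 categories")
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - expd)^2 / expd)
  dof <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  list(statistic = stat, dof = dof,
       p = stats::pchisq(stat, dof, lower.tail = FALSE), table = tab)
}

#' Per-cluster marker medians and percent-positive
#'
#' @param events an `event_table` aligned with `labels`.
#' @param labels cluster labels (any labeling: k-means or rules).
#' @param markers markers to profile (default phenotype markers).
#' @param positivity transformed-scale positivity threshold (scalar or
#'   named per marker); reuses the gating/rule definition of "positive".
#' @param params logicle parameters.
#' @return a `cluster_profile` data.frame: cluster, n, marker, median
#'   (transformed), pct_positive; empty clusters keep a row with n = 0 and
#'   NA summaries.
#' @export
cluster_profile <- function(events, labels, markers = PHENO_MARKERS,
                            positivity = rule_thresholds()$positive,
                            params = logicle_params()) {
  if (length(labels) != n_events(events))
    ct_data_error("labels do not align with events")
  tx <- transform_channels(events, markers, params)
  if (is.null(names(positivity)))
    positivity <- stats::setNames(rep_len(positivity, length(markers)),
                                  markers)
  lv <- sort(unique(as.character(labels)))
  out <- do.call(rbind, lapply(lv, function(cl) {
    i <- which(labels == cl)
    data.frame(cluster = cl, n = length(i), marker = markers,
               median = if (length(i)) apply(tx[i, , drop = FALSE], 2,
                                             stats::median)
                        else NA_real_,
               pct_positive = if (length(i))
                 100 * colMeans(tx[i, , drop = FALSE] >
                                  matrix(positivity[markers], length(i),
                                         length(markers), byrow = TRUE))
                 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("cluster_profile", "data.frame")
  out
}
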