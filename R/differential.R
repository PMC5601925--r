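# Marker summaries, z-score matrices, and the hypothesis-testing toolkit:
# pooled-variance t tests with Holm-Sidak step-down adjustment, the
# Benjamini-Hochberg step-up FDR rule (threshold 0.25 in the source
# analysis), Fisher's exact test by hypergeometric enumeration, and
# treatment/control frequency fold changes.

#' Per-group marker medians and percent-positive
#'
#' @param events an `event_table` (typically decoded CD8+ T cells).
#' @param groups data.frame of per-cell keys (e.g. specificity, tissue,
#'   arm, replicate) aligned with `events`, or a single vector.
#' @param markers markers to summarize (default phenotype markers).
#' @param positivity transformed-scale positivity threshold (scalar or
#'   named per marker).
#' @param params logicle parameters.
#' @return long data.frame: key columns, `marker`, `n`, `median`,
#'   `pct_positive`. Keys with zero cells are kept, flagged by `n = 0` and
#'   NA summaries.
#' @export
summarize_markers <- function(events, groups, markers = PHENO_MARKERS,
                              positivity = rule_thresholds()$positive,
                              params = logicle_params()) {
  if (!is.data.frame(groups)) groups <- data.frame(group = groups)
  if (nrow(groups) != n_events(events))
    ct_data_error("groups do not align with events")
  tx <- transform_channels(events, markers, params)
  if (is.null(names(positivity)))
    positivity <- stats::setNames(rep_len(positivity, length(markers)),
                                  markers)
  key <- interaction(groups, drop = FALSE, sep = "\r")
  out <- do.call(rbind, lapply(levels(key), function(k) {
    i <- which(key == k)
    kv <- strsplit(k, "\r", fixed = TRUE)[[1]]
    keydf <- as.data.frame(as.list(kv), col.names = names(groups),
                           stringsAsFactors = FALSE)
    cbind(keydf[rep(1, length(markers)), , drop = FALSE],
          data.frame(marker = markers, n = length(i),
                     median = if (length(i))
                       apply(tx[i, , drop = FALSE], 2, stats::median)
                     else NA_real_,
                     pct_positive = if (length(i))
                       100 * colMeans(tx[i, , drop = FALSE] >
                         matrix(positivity[markers], length(i),
                                length(markers), byrow = TRUE))
                     else NA_real_,
                     stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}

#' z-score standardization of a marker matrix
#'
#' Applies X -> (X - m) / s per marker column, where m and s are the mean
#' and SD of the column, then (optionally) averages the z-scores within
#' groups such as T-cell specificities. Sample SD (n-1) is the default
#' convention; population SD is available via `sd_type`. Constant markers
#' are flagged, not silently zeroed.
#'
#' @param x numeric matrix, observations x markers.
#' @param group optional grouping vector (length nrow(x)) to average z
#'   within.
#' @param sd_type "sample" (n-1, default) or "population".
#' @return list with `z` (full standardized matrix), `averaged` (group x
#'   marker means, NULL without `group`), `constant` (logical per marker).
#' @export
zscore_matrix <- function(x, group = NULL, sd_type = c("sample",
                                                       "population")) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(x)
  if (nrow(x) < 2L) ct_data_error("z-scores need >= 2 observations")
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  if (sd_type == "population") s <- s * sqrt((nrow(x) - 1) / nrow(x))
  const <- !is.finite(s) | s == 0
  z <- sweep(x, 2, m)
  z[, !const] <- sweep(z[, !const, drop = FALSE], 2, s[!const], `/`)
  z[, const] <- NA_real_
  averaged <- NULL
  if (!is.null(group)) {
    averaged <- apply(z, 2, function(col) tapply(col, group, mean))
    averaged <- matrix(averaged, ncol = ncol(z),
                       dimnames = list(levels(factor(group)), colnames(z)))
  }
  list(z = z, averaged = averaged, constant = const)
}

#' Holm-Sidak step-down adjustment
#'
#' @param p raw p-values of one comparison family.
#' @return adjusted p-values: step-down Sidak,
#'   `1 - (1 - p_(i))^(m - i + 1)` with monotonicity enforcement.
#' @export
holm_sidak_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    ct_data_error("p-values must lie in [0,1]")
  m <- length(p)
  o <- order(p)
  adj <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- pmin(cummax(adj), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Pooled-variance t tests with Holm-Sidak family adjustment
#'
#' @param groups list of comparisons, each a list/pair of two numeric
#'   vectors (the two groups), each of length >= 2.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame per comparison: `statistic`, `df`, `p`, `p_adjusted`,
#'   `significant`, `procedure`.
#' @export
t_test_holm_sidak <- function(groups, alpha = 0.05) {
  if (!length(groups)) ct_data_error("empty comparison family")
  res <- lapply(groups, function(g) {
    x <- g[[1]]; y <- g[[2]]
    if (length(x) < 2L || length(y) < 2L)
      ct_data_error("each group needs n >= 2")
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) /
      (nx + ny - 2)
    se <- sqrt(sp2 * (1 / nx + 1 / ny))
    stat <- if (se == 0) 0 else (mean(x) - mean(y)) / se
    df <- nx + ny - 2
    p <- if (se == 0 && mean(x) == mean(y)) 1
         else 2 * stats::pt(abs(stat), df, lower.tail = FALSE)
    c(statistic = stat, df = df, p = p)
  })
  out <- as.data.frame(do.call(rbind, res))
  out$p_adjusted <- holm_sidak_adjust(out$p)
  out$significant <- out$p_adjusted < alpha
  out$procedure <- "holm_sidak"
  out
}

#' Benjamini-Hochberg step-up rejection flags
#'
#' Standard step-up rule: reject all `p_(i)` with `i <= max{i : p_(i) <=
#' i q / m}`.
#'
#' @param pvalues raw p-values.
#' @param q false discovery rate threshold (default 0.25, the source
#'   analysis' setting).
#' @return logical rejection flags aligned with `pvalues`.
#' @export
bh_fdr <- function(pvalues, q = 0.25) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    ct_data_error("p-values must lie in [0,1]")
  m <- length(pvalues)
  o <- order(pvalues)
  ps <- pvalues[o]
  below <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(below)) rej[o[seq_len(max(below))]] <- TRUE
  rej
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p by hypergeometric enumeration: with margins fixed, all
#' tables whose probability does not exceed that of the observed table
#' contribute to p.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return two-sided p-value.
#' @export
fisher_exact_test <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) ct_data_error("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    ct_data_error("table entries must be non-negative integers")
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  kk <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(kk, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Treatment vs control frequency fold changes
#'
#' @param hit_treated,hit_control frequency or hit tables with columns
#'   `antigen`, `tissue`, `frequency` and optionally `replicate`.
#' @return data.frame of per antigen/tissue `fold_change`; with replicate
#'   inputs, the per-replicate ratios are averaged and their SEM reported.
#'   Zero control frequencies yield `fold_change = NA` with `undefined =
#'   TRUE`.
#' @export
frequency_fold_change <- function(hit_treated, hit_control) {
  keys <- c("antigen", "tissue",
            intersect("replicate", intersect(names(hit_treated),
                                             names(hit_control))))
  kt <- do.call(paste, hit_treated[keys])
  kc <- do.call(paste, hit_control[keys])
  if (!setequal(kt, kc))
    ct_data_error("treated and control tables cover different antigen/tissue rows")
  mt <- match(kc, kt)
  ratio <- ifelse(hit_control$frequency > 0,
                  hit_treated$frequency[mt] / hit_control$frequency, NA_real_)
  base <- data.frame(antigen = hit_control$antigen,
                     tissue = hit_control$tissue,
                     fold_change = ratio,
                     undefined = hit_control$frequency == 0,
                     stringsAsFactors = FALSE)
  if ("replicate" %in% keys) {
    agg <- stats::aggregate(fold_change ~ antigen + tissue, data = base,
                            FUN = function(v) c(mean = mean(v),
                                                sem = stats::sd(v) /
                                                  sqrt(length(v))),
                            na.action = stats::na.omit)
    out <- data.frame(antigen = agg$antigen, tissue = agg$tissue,
                      fold_change = agg$fold_change[, "mean"],
                      sem = agg$fold_change[, "sem"],
                      stringsAsFactors = FALSE)
    und <- stats::aggregate(undefined ~ antigen + tissue, data = base,
                            FUN = any)
    out$undefined <- und$undefined[match(paste(out$antigen, out$tissue),
                                         paste(und$antigen, und$tissue))]
    return(out)
  }
  base
}
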