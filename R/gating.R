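# Sequential gating hierarchy isolating live CD8+ T cells:
# exclude beads -> cisplatin- -> DNA+ -> CD45+ -> CD19- -> TCRb+ CD90+ ->
# CD8+ CD4-. Manual gates are replaced by per-channel automatic 1-D
# thresholds (two-component split on the logicle scale) with a config
# override, so the hierarchy is reproducible without interactive gating.

#' Fit a 1-D gating threshold
#'
#' @param x transformed intensity values of one channel.
#' @param method "two_component_split" (1-D 2-means partition; threshold is
#'   the midpoint of the two cluster means) or "quantile".
#' @param q quantile for method "quantile".
#' @param channel channel name used in error messages.
#' @return numeric threshold on the transformed scale.
#' @export
fit_threshold <- function(x, method = c("two_component_split", "quantile"),
                          q = 0.5, channel = "channel") {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(x) < 100L)
    ct_data_error("fit_threshold: need >= 100 events for %s", channel)
  if (method == "quantile") return(stats::quantile(x, q, names = FALSE))
  rng <- range(x)
  if (diff(rng) < 1e-12)
    ct_data_error("fit_threshold: channel %s is constant", channel)
  # deterministic 1-D 2-means, Lloyd iterations seeded at the data range
  # endpoints (robust when the positive mode is rare)
  cen <- rng
  for (i in seq_len(100)) {
    cut <- mean(cen)
    lo <- x <= cut
    new <- c(mean(x[lo]), mean(x[!lo]))
    if (any(!is.finite(new))) break
    if (max(abs(new - cen)) < 1e-10) { cen <- new; break }
    cen <- new
  }
  mean(cen)
}

#' A single gate node
#'
#' @param name gate name.
#' @param channels 1 or 2 channel labels.
#' @param polarity "+" or "-" per channel.
#' @param threshold transformed-scale threshold per channel (NA = fit
#'   automatically when the tree is applied).
#' @return a `gate_node`.
#' @export
gate_node <- function(name, channels, polarity, threshold = NA_real_) {
  if (length(channels) < 1L || length(channels) > 2L)
    ct_config_error("gate %s: 1 or 2 channels required", name)
  polarity <- rep_len(polarity, length(channels))
  threshold <- rep_len(threshold, length(channels))
  if (!all(polarity %in% c("+", "-")))
    ct_config_error("gate %s: polarity must be '+' or '-'", name)
  if (any(!is.na(threshold) & !is.finite(threshold)))
    ct_config_error("gate %s: thresholds must be finite", name)
  structure(list(name = name, channels = channels, polarity = polarity,
                 threshold = threshold),
            class = "gate_node")
}

#' Default gating hierarchy to live CD8+ T cells
#'
#' @param panel a `channel_panel` (for the bead/dna/viability labels).
#' @return a `gate_tree` (ordered list of [gate_node()]s).
#' @export
default_gate_tree <- function(panel = default_channels()) {
  bead <- channels_by_role(panel, "bead")
  dna <- channels_by_role(panel, "dna")[1]
  via <- channels_by_role(panel, "viability")[1]
  nodes <- list(
    gate_node("not_bead", bead[1:2], c("-", "-")),
    gate_node("live", via, "-"),
    gate_node("dna_pos", dna, "+"),
    gate_node("cd45_pos", "CD45", "+"),
    gate_node("not_b", "CD19", "-"),
    gate_node("t_cell", c("TCRb", "CD90"), c("+", "+")),
    gate_node("cd8_t", c("CD8", "CD4"), c("+", "-"))
  )
  structure(list(nodes = nodes), class = "gate_tree")
}

#' @export
print.gate_tree <- function(x, ...) {
  for (nd in x$nodes)
    cat(sprintf("  %-10s %s\n", nd$name,
                paste0(nd$channels, nd$polarity, collapse = " & ")))
  invisible(x)
}

#' Apply a gate tree
#'
#' Gates have conjunctive semantics: the final mask is the intersection of
#' all single-gate masks, so reordering the tree cannot change it. Missing
#' thresholds are fitted per channel by [fit_threshold()] on the
#' logicle-transformed values; `overrides` pins individual channels.
#'
#' @param events an `event_table`.
#' @param tree a `gate_tree` (default [default_gate_tree()]).
#' @param overrides named numeric vector channel -> fixed threshold.
#' @param params logicle parameters.
#' @return list with `mask` (logical, final CD8+ T-cell mask), `counts`
#'   (data.frame gate x events remaining), and `thresholds` used.
#' @export
apply_gate_tree <- function(events, tree = default_gate_tree(events$panel),
                            overrides = NULL, params = logicle_params()) {
  chans <- unique(unlist(lapply(tree$nodes, `[[`, "channels")))
  miss <- setdiff(chans, colnames(events$exprs))
  if (length(miss))
    ct_config_error("gate tree references missing channels: %s",
                    paste(miss, collapse = ", "))
  tx <- transform_channels(events, chans, params)
  thresholds <- numeric(0)
  get_thr <- function(ch, fixed) {
    if (!is.na(fixed)) return(fixed)
    if (!is.null(overrides) && ch %in% names(overrides))
      return(overrides[[ch]])
    if (ch %in% names(thresholds)) return(thresholds[[ch]])
    thr <- fit_threshold(tx[, ch], channel = ch)
    thresholds[[ch]] <<- thr
    thr
  }
  mask <- rep(TRUE, n_events(events))
  counts <- data.frame(gate = character(0), events = integer(0))
  for (nd in tree$nodes) {
    for (i in seq_along(nd$channels)) {
      ch <- nd$channels[i]
      thr <- get_thr(ch, nd$threshold[i])
      thresholds[[ch]] <- thr
      m <- if (nd$polarity[i] == "+") tx[, ch] > thr else tx[, ch] <= thr
      mask <- mask & m
    }
    counts <- rbind(counts,
                    data.frame(gate = nd$name, events = sum(mask)))
  }
  list(mask = mask, counts = counts, thresholds = thresholds)
}
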