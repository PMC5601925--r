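# Preprocessing: bead identification and normalization, zero randomization,
# and automated sample-barcode deconvolution.

#' Identify equilibration bead events
#'
#' Flags events positive in all bead channels. Thresholds are fitted per
#' bead channel by a two-component split on the logicle scale unless fixed
#' values are supplied.
#'
#' @param events an `event_table`.
#' @param bead_channels bead channel labels (default: panel role "bead").
#' @param threshold fixed transformed-scale threshold(s), or NULL to fit.
#' @param params logicle parameters.
#' @return logical mask of bead events with attribute `fraction`.
#' @export
identify_beads <- function(events, bead_channels = NULL, threshold = NULL,
                           params = logicle_params()) {
  if (is.null(bead_channels))
    bead_channels <- channels_by_role(events$panel, "bead")
  if (!length(bead_channels))
    ct_config_error("no bead channels available")
  tx <- transform_channels(events, bead_channels, params)
  if (is.null(threshold)) {
    threshold <- vapply(bead_channels, function(ch)
      fit_threshold(tx[, ch], method = "two_component_split"), numeric(1))
  } else {
    threshold <- rep_len(threshold, length(bead_channels))
  }
  mask <- rep(TRUE, nrow(tx))
  for (i in seq_along(bead_channels))
    mask <- mask & tx[, i] > threshold[i]
  attr(mask, "fraction") <- mean(mask)
  mask
}

#' Bead-based signal normalization
#'
#' Corrects acquisition drift using the spiked equilibration beads: bead
#' events are split into consecutive time windows of `window_size` beads;
#' per window and bead channel, gain = baseline bead median / window bead
#' median; gains are interpolated linearly between window centres and
#' applied to all events. Channels without bead signal receive the mean
#' gain curve across bead channels (the instrument drift modelled here is
#' channel-shared). Windows with fewer than 2 beads are merged into their
#' neighbour with a warning.
#'
#' @param events an `event_table`.
#' @param mask logical bead mask from [identify_beads()].
#' @param window_size bead events per window (default 500).
#' @param params logicle parameters (only used when refitting masks).
#' @return list with `events` (normalized) and `fit` (a
#'   `normalization_fit`: data.frame window_center x channel x gain plus
#'   baseline medians).
#' @export
normalize_beads <- function(events, mask = NULL, window_size = 500,
                            params = logicle_params()) {
  if (is.null(mask)) mask <- identify_beads(events, params = params)
  bead_ch <- channels_by_role(events$panel, "bead")
  bi <- which(mask)
  if (length(bi) < 2L) ct_data_error("need at least 2 bead events")
  bi <- bi[order(events$time[bi])]
  nw <- max(1L, length(bi) %/% as.integer(window_size))
  grp <- rep(seq_len(nw), each = ceiling(length(bi) / nw))[seq_along(bi)]
  sizes <- tabulate(grp, nw)
  if (any(sizes < 2L)) {
    warning("merging bead windows with < 2 beads into neighbours")
    keep <- sizes >= 2L
    grp <- cumsum(keep)[grp]
    grp[grp == 0L] <- 1L
    nw <- max(grp)
  }
  centers <- vapply(seq_len(nw), function(w) mean(events$time[bi[grp == w]]),
                    numeric(1))
  baseline <- vapply(bead_ch, function(ch)
    stats::median(events$exprs[bi, ch]), numeric(1))
  gains <- vapply(bead_ch, function(ch) {
    med <- vapply(seq_len(nw), function(w)
      stats::median(events$exprs[bi[grp == w], ch]), numeric(1))
    baseline[ch] / med
  }, numeric(nw))
  gains <- matrix(gains, nrow = nw,
                  dimnames = list(NULL, bead_ch))
  if (any(!is.finite(gains)) || any(gains <= 0))
    ct_data_error("bead medians yield non-positive gains; check bead mask")

  interp <- function(g) {
    if (nw == 1L) return(rep(g[1], n_events(events)))
    stats::approx(centers, g, xout = events$time, rule = 2)$y
  }
  mean_gain <- interp(rowMeans(gains))
  out <- events
  for (ch in colnames(out$exprs)) {
    g <- if (ch %in% bead_ch) interp(gains[, ch]) else mean_gain
    out$exprs[, ch] <- out$exprs[, ch] * g
  }
  fit <- structure(
    list(windows = data.frame(
           window = rep(seq_len(nw), length(bead_ch)),
           center = rep(centers, length(bead_ch)),
           channel = rep(bead_ch, each = nw),
           gain = as.numeric(gains)),
         baseline = baseline, window_size = window_size),
    class = "normalization_fit")
  list(events = out, fit = fit)
}

#' @export
print.normalization_fit <- function(x, ...) {
  cat(sprintf("bead normalization: %d windows x %d channels (window size %d)\n",
              max(x$windows$window), length(x$baseline), x$window_size))
  invisible(x)
}

#' Randomize exact-zero intensities
#'
#' Replaces every exactly-zero intensity by an independent draw from
#' Uniform(-1, 0), the standard CyTOF display convention; nonzero values
#' (and truth columns) are untouched. Deterministic under `seed`.
#'
#' @param events an `event_table`.
#' @param seed integer seed.
#' @return the `event_table` with zeros randomized.
#' @export
randomize_zeros <- function(events, seed = 1L) {
  z <- events$exprs == 0
  nz <- sum(z)
  if (nz > 0) {
    events$exprs[z] <- with_seed(seed, stats::runif(nz, -1, 0))
  }
  events
}

#' Automated sample-barcode deconvolution
#'
#' On the logicle scale, ranks each event's barcode channels; the event is
#' assigned to a sample iff its top-2 channel set is one of the scheme's
#' codes, the rank-2 minus rank-3 intensity gap is at least
#' `separation_cutoff`, and the rank-3 channel is below the positivity
#' threshold (rejecting doublet-like events with >= 3 active barcodes).
#'
#' @param events an `event_table`.
#' @param scheme a [barcode_scheme()].
#' @param separation_cutoff minimum rank-2 - rank-3 gap (transformed scale,
#'   default 0.3).
#' @param positivity transformed-scale threshold for "active"; NULL fits a
#'   pooled two-component split over all barcode channels.
#' @param params logicle parameters.
#' @return a `barcode_assignment`: data.frame with `sample_id` (NA when
#'   unassigned) and `separation` per event.
#' @export
debarcode <- function(events, scheme, separation_cutoff = 0.3,
                      positivity = NULL, params = logicle_params()) {
  if (!length(scheme$code_map)) ct_config_error("empty barcode scheme")
  miss <- setdiff(unique(unlist(scheme$code_map)), colnames(events$exprs))
  if (length(miss))
    ct_config_error("barcode scheme references missing channels: %s",
                    paste(miss, collapse = ", "))
  bc <- sort(scheme$channels)  # alphabetical so index order == key order
  tx <- transform_channels(events, bc, params)
  if (is.null(positivity))
    positivity <- fit_threshold(as.numeric(tx),
                                method = "two_component_split")
  n <- nrow(tx)
  ord <- t(apply(tx, 1L, order, decreasing = TRUE))
  r1 <- tx[cbind(seq_len(n), ord[, 1])]
  r2 <- tx[cbind(seq_len(n), ord[, 2])]
  r3 <- tx[cbind(seq_len(n), ord[, 3])]
  top2 <- paste(bc[pmin(ord[, 1], ord[, 2])],
                bc[pmax(ord[, 1], ord[, 2])], sep = "+")
  lookup <- decoding_table(scheme)
  sample_id <- unname(lookup[top2])
  gap <- r2 - r3
  ok <- !is.na(sample_id) & gap >= separation_cutoff &
    r2 > positivity & r3 <= positivity
  sample_id[!ok] <- NA_character_
  structure(
    data.frame(sample_id = sample_id, separation = gap,
               stringsAsFactors = FALSE),
    class = c("barcode_assignment", "data.frame"),
    positivity = positivity)
}
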