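# Automated combinatorial triple-tetramer gating and hit calling.
#
# Per CD8+ cell, the 9 logicle-transformed reporter intensities are ranked;
# the cell is assigned to the antigen whose code equals its top-3 channel
# set iff (a) the dimmest of the three is above the positivity threshold,
# (b) the gap between ranks 3 and 4 is at least the separation cutoff, and
# (c) the set is a code of the active scheme. Cells passing (a) and (b)
# whose set is an unused code are recorded as decoy positives for QC.

#' Decode parameters
#'
#' @param positivity transformed-scale positivity threshold(s); NULL fits a
#'   per-channel two-component split (guarded by `positivity_floor`).
#' @param positivity_floor lower bound on fitted per-channel thresholds:
#'   reporter channels used by no present antigen are unimodal background,
#'   where an unguarded split would land inside noise (default 1.0).
#' @param separation minimum rank-3 minus rank-4 gap (default 0.5).
#' @param hit_cutoff frequency cutoff for hit calling, strict greater-than
#'   (default 0.0015, i.e. >0.15% of CD8+ T cells).
#' @param require_dual_config when TRUE, [hit_concordance()] gates
#'   consistent hits on both staining configurations.
#' @return a `decode_params` list.
#' @export
decode_params <- function(positivity = NULL, positivity_floor = 1.0,
                          separation = 0.5, hit_cutoff = 0.0015,
                          require_dual_config = FALSE) {
  if (hit_cutoff <= 0 || hit_cutoff >= 1)
    ct_config_error("hit_cutoff must be in (0,1)")
  if (!is.finite(separation) && separation != Inf)
    ct_config_error("separation must be finite or Inf")
  structure(list(positivity = positivity,
                 positivity_floor = positivity_floor,
                 separation = separation, hit_cutoff = hit_cutoff,
                 require_dual_config = require_dual_config),
            class = "decode_params")
}

#' Decode antigen specificities of gated CD8+ T cells
#'
#' @param cd8_events an `event_table` already gated to CD8+ T cells.
#' @param scheme the active [assign_codes()] `coding_scheme`.
#' @param params a [decode_params()].
#' @param logicle logicle parameters.
#' @return a `decode_result` data.frame: per cell `antigen` (NA when
#'   unassigned), `top3` (canonical code key), `separation`, `decoy`
#'   (passed thresholds but matched an unused code). Attribute
#'   `thresholds` holds the per-channel positivity thresholds used.
#' @export
decode_cells <- function(cd8_events, scheme, params = decode_params(),
                         logicle = logicle_params()) {
  if (!length(scheme$code_map)) ct_config_error("empty coding scheme")
  rep_ch <- sort(scheme$channels)  # alphabetical: index order == key order
  miss <- setdiff(rep_ch, colnames(cd8_events$exprs))
  if (length(miss))
    ct_config_error("reporter channels missing from events: %s",
                    paste(miss, collapse = ", "))
  tx <- transform_channels(cd8_events, rep_ch, logicle)
  n <- nrow(tx)
  if (is.null(params$positivity)) {
    thr <- vapply(rep_ch, function(ch) {
      t0 <- tryCatch(fit_threshold(tx[, ch], channel = ch),
                     combitet_data_error = function(e) Inf)
      max(t0, params$positivity_floor)
    }, numeric(1))
  } else {
    thr <- stats::setNames(rep_len(params$positivity, length(rep_ch)), rep_ch)
  }
  ord <- t(apply(tx, 1L, order, decreasing = TRUE))
  idx3 <- cbind(seq_len(n), ord[, 3])
  idx4 <- cbind(seq_len(n), ord[, 4])
  r3 <- tx[idx3]
  gap <- r3 - tx[idx4]
  # min of the top 3 must clear each of its channels' thresholds
  pos3 <- tx[cbind(seq_len(n), ord[, 1])] > thr[ord[, 1]] &
          tx[cbind(seq_len(n), ord[, 2])] > thr[ord[, 2]] &
          r3 > thr[ord[, 3]]
  i1 <- ord[, 1]; i2 <- ord[, 2]; i3 <- ord[, 3]
  lo <- pmin(i1, i2, i3)
  hi <- pmax(i1, i2, i3)
  top3 <- paste(rep_ch[lo], rep_ch[i1 + i2 + i3 - lo - hi], rep_ch[hi],
                sep = "+")
  lookup <- decoding_table(scheme)
  antigen <- unname(lookup[top3])
  pass <- pos3 & gap >= params$separation
  antigen[!pass] <- NA_character_
  decoy <- pass & is.na(unname(lookup[top3])) &
    top3 %in% code_key(strsplit(scheme$unused, "+", fixed = TRUE))
  structure(
    data.frame(antigen = antigen, top3 = top3, separation = gap,
               decoy = decoy, stringsAsFactors = FALSE),
    class = c("decode_result", "data.frame"),
    thresholds = thr)
}

#' Per-antigen frequencies among CD8+ T cells
#'
#' @param result a `decode_result`.
#' @param n_cd8 total CD8+ T cells decoded (defaults to `nrow(result)`).
#' @param antigens antigens to report (default: those observed); absent
#'   antigens get frequency 0.
#' @return data.frame of `antigen`, `count`, `frequency`, plus one
#'   "unassigned" row; frequencies and the unassigned fraction sum to 1.
#' @export
compute_frequencies <- function(result, n_cd8 = nrow(result),
                                antigens = NULL) {
  if (n_cd8 <= 0) ct_data_error("n_cd8 must be positive")
  assigned <- result$antigen[!is.na(result$antigen)]
  if (is.null(antigens)) antigens <- sort(unique(assigned))
  cnt <- vapply(antigens, function(a) sum(assigned == a), integer(1))
  out <- data.frame(antigen = antigens, count = unname(cnt),
                    frequency = unname(cnt) / n_cd8,
                    stringsAsFactors = FALSE)
  rbind(out,
        data.frame(antigen = "unassigned",
                   count = n_cd8 - length(assigned),
                   frequency = (n_cd8 - length(assigned)) / n_cd8))
}

#' Call antigen hits across tissues
#'
#' A hit is strictly more frequent than `hit_cutoff` among CD8+ T cells;
#' an antigen is a "consistent hit" when it is a hit in at least
#' `min_tissues` of the supplied tissues (default: all of them).
#'
#' @param freqs data.frame with columns `antigen`, `tissue`, `frequency`
#'   (e.g. stacked [compute_frequencies()] outputs without the unassigned
#'   rows; an optional `arm` column is carried through).
#' @param params a [decode_params()].
#' @param min_tissues tissues required for a consistent hit (default: all
#'   tissues present in `freqs`).
#' @return a `hit_table` data.frame with `is_hit` and `consistent_hit`.
#' @export
call_hits <- function(freqs, params = decode_params(), min_tissues = NULL) {
  if (!nrow(freqs)) ct_data_error("empty frequency table")
  freqs <- freqs[freqs$antigen != "unassigned", , drop = FALSE]
  n_tissue <- length(unique(freqs$tissue))
  if (is.null(min_tissues)) min_tissues <- n_tissue
  freqs$is_hit <- freqs$frequency > params$hit_cutoff
  nh <- stats::aggregate(is_hit ~ antigen, data = freqs, FUN = sum)
  consistent <- nh$antigen[nh$is_hit >= min_tissues]
  freqs$consistent_hit <- freqs$antigen %in% consistent
  class(freqs) <- c("hit_table", "data.frame")
  freqs
}

#' Dual-configuration concordance
#'
#' @param hits_a,hits_b `hit_table`s from the two staining configurations
#'   covering the same antigens and tissues.
#' @return `hits_a` with `is_hit_b` and `concordant` (hit in both) columns.
#' @export
hit_concordance <- function(hits_a, hits_b) {
  ka <- paste(hits_a$antigen, hits_a$tissue)
  kb <- paste(hits_b$antigen, hits_b$tissue)
  if (!setequal(ka, kb))
    ct_data_error("configuration hit tables cover different antigen/tissue sets")
  hits_a$is_hit_b <- hits_b$is_hit[match(ka, kb)]
  hits_a$concordant <- hits_a$is_hit & hits_a$is_hit_b
  hits_a
}
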