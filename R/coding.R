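# Combinatorial code books: 3-of-9 tetramer codes and 2-of-6 sample barcodes.
#
# Every antigen's tetramer is assembled with an unordered set of 3 of the 9
# metal-labelled streptavidins, so C(9,3) = 84 specificities fit into 9
# channels; samples are barcoded with 2 of 6 Pd/In metals, C(6,2) = 15.

#' Enumerate all size-k subsets of n channels
#'
#' Subsets are returned sorted internally and in lexicographic order of the
#' channel vector supplied (or of 1..n when `channels` is NULL).
#'
#' @param n_channels number of channels (or a character vector of labels via
#'   `channels`).
#' @param code_size subset size.
#' @param channels optional channel labels of length `n_channels`.
#' @return list of character (or integer) vectors, each sorted, of length
#'   `choose(n_channels, code_size)`.
#' @examples
#' length(enumerate_codes(9, 3)) # 84
#' @export
enumerate_codes <- function(n_channels, code_size, channels = NULL) {
  if (!is.null(channels)) {
    n_channels <- length(channels)
  }
  n_channels <- as.integer(n_channels)
  code_size <- as.integer(code_size)
  if (code_size < 1L || code_size > n_channels)
    ct_config_error("code_size must be in [1, n_channels]; got %d of %d",
                    code_size, n_channels)
  idx <- utils::combn(n_channels, code_size, simplify = FALSE)
  if (is.null(channels)) return(idx)
  lapply(idx, function(i) sort(channels[i]))
}

#' Build an antigen panel from a candidate table
#'
#' @param candidates data.frame with columns `antigen_id`, `peptide`,
#'   `category` (one of "known", "predicted", "control").
#' @return an `antigen_panel` object; `$screened_count` counts known +
#'   predicted entries (controls such as SIINFEKL are excluded).
#' @export
antigen_panel <- function(candidates) {
  need <- c("antigen_id", "peptide", "category")
  if (!all(need %in% names(candidates)))
    ct_config_error("candidate table needs columns: %s",
                    paste(need, collapse = ", "))
  if (anyDuplicated(candidates$antigen_id))
    ct_config_error("duplicate antigen_id in candidate table: %s",
                    paste(unique(candidates$antigen_id[
                      duplicated(candidates$antigen_id)]), collapse = ", "))
  bad <- setdiff(unique(candidates$category),
                 c("known", "predicted", "control"))
  if (length(bad))
    ct_config_error("unknown category: %s", paste(bad, collapse = ", "))
  entries <- candidates[, need]
  rownames(entries) <- NULL
  structure(
    list(entries = entries,
         screened_count = sum(entries$category != "control")),
    class = "antigen_panel"
  )
}

#' @export
print.antigen_panel <- function(x, ...) {
  cat(sprintf("antigen panel: %d entries (%d screened, %d control)\n",
              nrow(x$entries), x$screened_count,
              sum(x$entries$category == "control")))
  invisible(x)
}

#' Screened (non-control) antigen ids of a panel
#' @param panel an `antigen_panel`.
#' @export
screened_antigens <- function(panel) {
  panel$entries$antigen_id[panel$entries$category != "control"]
}

#' Default 81-candidate panel
#'
#' Loads the candidate fixture shipped with the package: the two known
#' immunodominant sarcoma neoantigens (mLama4, mAlg8), 79 predicted
#' H-2Kb-restricted candidates, and the SIINFEKL control. The predicted
#' candidates' peptide sequences are synthetic placeholders (the study's
#' supplementary list is not redistributed); only the two known epitopes
#' carry their published sequences.
#'
#' @param file path to a candidate CSV; defaults to the shipped fixture.
#' @return an `antigen_panel` with `screened_count == 81`.
#' @export
build_default_panel <- function(file = system.file("extdata",
                                                   "panel_candidates_synthetic.csv",
                                                   package = "combitet")) {
  if (!nzchar(file) || !file.exists(file))
    ct_config_error("candidate fixture not found: %s", file)
  antigen_panel(utils::read.csv(file, stringsAsFactors = FALSE))
}

#' Assign tetramer codes to an antigen panel
#'
#' Draws a distinct random 3-of-9 code for every antigen, uniformly without
#' replacement from the 84 possible combinations, deterministically under
#' `seed`. Selected codes can be pinned via `pinned` (used for the two known
#' epitopes whose coding the source study prints: mLama4 =
#' Gd157/Tb159/Yb173, mAlg8 = Dy163/Tm169/Yb173).
#'
#' For a second staining configuration (`config_id = "B"`), supply the
#' configuration-A scheme via `avoid`: each antigen's B-code then shares at
#' most `max_shared` channels with its A-code (default 1), operationalizing
#' the study's "completely different combination" internal control.
#'
#' @param panel an `antigen_panel`.
#' @param channels a `channel_panel` (9 tetramer reporters required).
#' @param config_id "A" or "B".
#' @param seed integer RNG seed.
#' @param pinned named list antigen_id -> character(3) of reporter labels.
#' @param avoid a configuration-A `coding_scheme` to decorrelate against.
#' @param max_shared maximum channels a B-code may share with the A-code.
#' @param code_size code cardinality (default 3).
#' @return a `coding_scheme`: `$code_map` (named list antigen -> sorted
#'   labels), `$capacity`, `$config_id`, `$unused` (codes kept free as decoy
#'   negative controls).
#' @export
assign_codes <- function(panel, channels = default_channels(),
                         config_id = c("A", "B"), seed = 1L,
                         pinned = default_pinned_codes(), avoid = NULL,
                         max_shared = 1L, code_size = 3L) {
  config_id <- match.arg(config_id)
  reporters <- channels_by_role(channels, "tetramer_reporter")
  if (length(reporters) < code_size)
    ct_config_error("need at least %d tetramer reporter channels", code_size)
  antigens <- screened_antigens(panel)
  all_codes <- enumerate_codes(length(reporters), code_size,
                               channels = reporters)
  keys <- code_key(all_codes)
  if (length(antigens) > length(all_codes))
    ct_config_error("panel size %d exceeds code-book capacity %d",
                    length(antigens), length(all_codes))

  pinned <- pinned[names(pinned) %in% antigens]
  if (config_id == "B") pinned <- list()  # pins describe configuration A
  for (p in pinned) {
    if (!all(p %in% reporters))
      ct_config_error("pinned code uses unknown reporter channel")
  }

  a_map <- if (!is.null(avoid)) avoid$code_map else NULL
  code_map <- stats::setNames(vector("list", length(antigens)), antigens)
  with_seed(seed, {
    free <- keys
    # honour pins first
    for (id in names(pinned)) {
      k <- code_key(list(sort(pinned[[id]])))
      if (!k %in% free) ct_config_error("pinned code already taken: %s", k)
      code_map[[id]] <- sort(pinned[[id]])
      free <- setdiff(free, k)
    }
    todo <- setdiff(antigens, names(pinned))
    for (id in todo) {
      cand <- free
      if (!is.null(a_map) && !is.null(a_map[[id]])) {
        shared <- vapply(strsplit(cand, "+", fixed = TRUE),
                         function(s) length(intersect(s, a_map[[id]])),
                         integer(1))
        ok <- cand[shared <= max_shared]
        if (length(ok)) cand <- ok
        # fall back to least-overlapping codes if the book is exhausted
        else cand <- cand[shared == min(shared)]
      }
      pick <- cand[sample.int(length(cand), 1L)]
      code_map[[id]] <- strsplit(pick, "+", fixed = TRUE)[[1]]
      free <- setdiff(free, pick)
    }
    structure(
      list(config_id = config_id, code_map = code_map,
           capacity = length(all_codes), channels = reporters,
           unused = free),
      class = "coding_scheme"
    )
  })
}

#' Published example codes for the two known neoantigens
#' @return named list of reporter-label triples.
#' @export
default_pinned_codes <- function() {
  list(mLama4 = c("Gd157", "Tb159", "Yb173"),
       mAlg8  = c("Dy163", "Tm169", "Yb173"))
}

#' @export
print.coding_scheme <- function(x, ...) {
  cat(sprintf("coding scheme %s: %d antigens over %d channels (capacity %d, %d unused)\n",
              x$config_id, length(x$code_map), length(x$channels),
              x$capacity, length(x$unused)))
  invisible(x)
}

#' Invert a coding scheme (code key -> antigen id)
#' @param scheme a `coding_scheme` or `barcode_scheme`.
#' @return named character vector keyed by canonical code string.
#' @export
decoding_table <- function(scheme) {
  keys <- code_key(scheme$code_map)
  if (anyDuplicated(keys))
    ct_config_error("scheme codes are not distinct; cannot invert")
  stats::setNames(names(scheme$code_map), keys)
}

#' Sample barcode scheme (2-of-6 Pd/In codes)
#'
#' @param sample_ids sample identifiers (one per pooled sample/tissue).
#' @param channels a `channel_panel` with 6 barcode channels.
#' @return a `barcode_scheme` with `$code_map` sample -> sorted label pair.
#' @export
barcode_scheme <- function(sample_ids, channels = default_channels()) {
  bc <- channels_by_role(channels, "barcode")
  codes <- enumerate_codes(length(bc), 2L, channels = bc)
  if (length(sample_ids) > length(codes))
    ct_config_error("%d samples exceed barcode capacity %d",
                    length(sample_ids), length(codes))
  if (anyDuplicated(sample_ids))
    ct_config_error("duplicate sample ids")
  structure(
    list(code_map = stats::setNames(codes[seq_along(sample_ids)], sample_ids),
         channels = bc, capacity = length(codes)),
    class = "barcode_scheme"
  )
}

#' Serialize a panel + coding schemes as a structured text table
#'
#' One record per antigen: id, peptide, category, configuration-A code and
#' (optionally) configuration-B code, codes written as "+"-joined labels.
#'
#' @param panel an `antigen_panel`.
#' @param scheme_a,scheme_b `coding_scheme` objects (B optional).
#' @param file output path.
#' @export
write_coding_table <- function(panel, scheme_a, scheme_b = NULL, file) {
  e <- panel$entries
  tab <- data.frame(
    antigen_id = e$antigen_id, peptide = e$peptide, category = e$category,
    code_A = vapply(e$antigen_id, function(id) {
      cd <- scheme_a$code_map[[id]]
      if (is.null(cd)) "" else paste(cd, collapse = "+")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(scheme_b)) {
    tab$code_B <- vapply(e$antigen_id, function(id) {
      cd <- scheme_b$code_map[[id]]
      if (is.null(cd)) "" else paste(cd, collapse = "+")
    }, character(1))
  }
  utils::write.csv(tab, file, row.names = FALSE, quote = FALSE)
  invisible(tab)
}
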