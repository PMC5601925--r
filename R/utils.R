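# Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a class so that callers (and
#' the command-line driver) can distinguish configuration errors from data
#' errors from runtime failures.
#'
#' @param msg message string (sprintf-style with ...).
#' @param class condition class, one of "combitet_config_error",
#'   "combitet_data_error", "combitet_runtime_error" or a more specific
#'   subclass.
#' @param ... sprintf arguments.
#' @noRd
ct_stop <- function(msg, class = "combitet_runtime_error", ...) {
  if (length(list(...)) > 0L) msg <- sprintf(msg, ...)
  stop(structure(
    class = c(class, "combitet_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ct_config_error <- function(msg, ...) ct_stop(msg, "combitet_config_error", ...)
ct_data_error   <- function(msg, ...) ct_stop(msg, "combitet_data_error", ...)

#' Canonical string form of a channel-set code
#'
#' Codes (3-of-9 tetramer triples, 2-of-6 barcode pairs) are unordered sets of
#' channel labels; their canonical form is the sorted labels joined by "+".
#'
#' @noRd
code_key <- function(labels) {
  vapply(labels, function(x) paste(sort(x), collapse = "+"), character(1))
}

#' Scoped RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state, so
#' that seeded operations do not perturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Derive a stream seed below 2^31 from a base seed and a stage tag
#' @noRd
derive_seed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), as.character))
  h <- sum(utf8ToInt(paste(parts, collapse = "/")) *
             seq_along(utf8ToInt(paste(parts, collapse = "/")))) %% 99991L
  (as.integer(seed) %% 20000000L) * 100L + as.integer(h %% 100L) + h
}

`%||%` <- function(x, y) if (is.null(x)) y else x
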