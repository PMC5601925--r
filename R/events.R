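# Event-level container: intensities, acquisition time, hidden ground truth.
#
# Modelled on the cytometry frame idea: a numeric events x channels matrix
# plus channel metadata. Ground-truth annotations produced by the simulator
# live in a separate `truth` data.frame that inference operations never
# read; they only see `exprs` / `time` / `panel`.

#' Construct an event table
#'
#' @param exprs numeric matrix, events x channels, non-negative raw
#'   intensities (zero randomization may later introduce values in (-1, 0)).
#' @param panel a `channel_panel` whose labels match `colnames(exprs)`.
#' @param time acquisition time per event (seconds); defaults to event index.
#' @param truth optional data.frame of hidden ground-truth columns
#'   (population, antigen, cluster, sample_id, is_bead, is_dead).
#' @return an `event_table`.
#' @export
event_table <- function(exprs, panel, time = NULL, truth = NULL) {
  exprs <- as.matrix(exprs)
  storage.mode(exprs) <- "double"
  if (is.null(colnames(exprs)))
    ct_data_error("event intensities need channel column names")
  missing <- setdiff(panel$label, colnames(exprs))
  if (length(missing))
    ct_data_error("event table lacks panel channels: %s",
                  paste(missing, collapse = ", "))
  if (is.null(time)) time <- seq_len(nrow(exprs))
  if (length(time) != nrow(exprs))
    ct_data_error("time length != event count")
  if (!is.null(truth) && nrow(truth) != nrow(exprs))
    ct_data_error("truth rows != event count")
  structure(list(exprs = exprs, panel = panel, time = as.numeric(time),
                 truth = truth),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("event table: %d events x %d channels%s\n",
              nrow(x$exprs), ncol(x$exprs),
              if (!is.null(x$truth)) " (with ground truth)" else ""))
  invisible(x)
}

#' Number of events
#' @param events an `event_table`.
#' @export
n_events <- function(events) nrow(events$exprs)

#' Subset an event table by row index or logical mask
#' @param events an `event_table`.
#' @param i integer indices or logical mask.
#' @export
subset_events <- function(events, i) {
  event_table(events$exprs[i, , drop = FALSE], events$panel,
              time = events$time[i],
              truth = if (!is.null(events$truth))
                events$truth[i, , drop = FALSE] else NULL)
}

#' Drop hidden ground-truth annotations
#' @param events an `event_table`.
#' @export
strip_truth <- function(events) {
  events$truth <- NULL
  events
}

#' Bind event tables row-wise (shared panel)
#' @param ... `event_table` objects with identical panels.
#' @export
bind_events <- function(...) {
  lst <- list(...)
  if (length(lst) == 1L && is.list(lst[[1]]) &&
      !inherits(lst[[1]], "event_table")) lst <- lst[[1]]
  ex <- do.call(rbind, lapply(lst, function(e) e$exprs))
  tm <- unlist(lapply(lst, function(e) e$time))
  tr <- if (all(vapply(lst, function(e) !is.null(e$truth), logical(1)))) {
    do.call(rbind, lapply(lst, function(e) e$truth))
  }
  event_table(ex, lst[[1]]$panel, time = tm, truth = tr)
}

#' Write an event table (and optional truth sidecar) as CSV
#' @param events an `event_table`.
#' @param file output CSV path; truth goes to `truth_file` when given.
#' @param truth_file optional sidecar CSV for ground-truth columns.
#' @export
write_events_csv <- function(events, file, truth_file = NULL) {
  df <- data.frame(Time = events$time, events$exprs, check.names = FALSE)
  utils::write.csv(df, file, row.names = FALSE)
  if (!is.null(truth_file) && !is.null(events$truth))
    utils::write.csv(events$truth, truth_file, row.names = FALSE)
  invisible(file)
}

#' Read an event table from CSV
#' @param file CSV with a header of channel names (optional Time column).
#' @param panel a `channel_panel`; defaults to [default_channels()].
#' @param truth_file optional sidecar truth CSV.
#' @export
read_events_csv <- function(file, panel = default_channels(),
                            truth_file = NULL) {
  df <- utils::read.csv(file, check.names = FALSE)
  tm <- if ("Time" %in% names(df)) df$Time else NULL
  df <- df[, setdiff(names(df), "Time"), drop = FALSE]
  truth <- if (!is.null(truth_file)) utils::read.csv(truth_file) else NULL
  event_table(as.matrix(df), panel, time = tm, truth = truth)
}

#' Logicle-transform selected channels of an event table
#'
#' @param events an `event_table`.
#' @param channels channel labels (default: all panel channels).
#' @param params a [logicle_params()] object.
#' @return numeric matrix of transformed values (events x channels).
#' @export
transform_channels <- function(events, channels = events$panel$label,
                               params = logicle_params()) {
  missing <- setdiff(channels, colnames(events$exprs))
  if (length(missing))
    ct_config_error("unknown channels: %s", paste(missing, collapse = ", "))
  logicle_transform(events$exprs[, channels, drop = FALSE], params)
}
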