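# Minimal FCS 3.0/3.1 reader and FCS 3.1 writer (list-mode, numeric data).
#
# The writer emits FCS 3.1 with single-precision float data, little-endian
# ($BYTEORD 1,2,3,4), one parameter per channel plus a leading Time
# parameter; marker names go to $PnS. The reader accepts FCS 3.0/3.1 files
# with $DATATYPE F, D or I and either byte order. Offsets are taken from
# the header, falling back to $BEGINDATA/$ENDDATA.

.fcs_delim <- "/"

#' Write an event table to an FCS 3.1 file
#'
#' @param events an `event_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path) {
  ex <- cbind(Time = events$time, events$exprs)
  if (anyDuplicated(colnames(ex)))
    ct_data_error("channel name collision: %s",
                  paste(unique(colnames(ex)[duplicated(colnames(ex))]),
                        collapse = ", "))
  npar <- ncol(ex)
  ntot <- nrow(ex)
  marker <- c("Time",
              events$panel$marker[match(colnames(ex)[-1],
                                        events$panel$label)])
  kw <- c("$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0",
          "$BEGINDATA", "%BD%", "$ENDDATA", "%ED%",
          "$BYTEORD", "1,2,3,4", "$DATATYPE", "F", "$MODE", "L",
          "$NEXTDATA", "0", "$PAR", as.character(npar),
          "$TOT", as.character(ntot))
  for (i in seq_len(npar)) {
    kw <- c(kw,
            sprintf("$P%dB", i), "32",
            sprintf("$P%dE", i), "0,0",
            sprintf("$P%dN", i), colnames(ex)[i],
            sprintf("$P%dR", i),
            as.character(max(1024, 2^ceiling(log2(max(1, ex[, i]) + 1)))))
    if (!is.na(marker[i]))
      kw <- c(kw, sprintf("$P%dS", i), marker[i])
  }
  if (any(grepl(.fcs_delim, kw, fixed = TRUE)))
    ct_data_error("keyword values may not contain the delimiter '%s'",
                  .fcs_delim)
  text_of <- function(bd, ed) {
    vals <- kw
    vals[vals == "%BD%"] <- sprintf("%010d", bd)
    vals[vals == "%ED%"] <- sprintf("%010d", ed)
    paste0(.fcs_delim, paste(vals, collapse = .fcs_delim), .fcs_delim)
  }
  tlen <- nchar(text_of(0, 0), type = "bytes")
  text_begin <- 58L
  text_end <- text_begin + tlen - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + 4L * npar * ntot - 1L
  header <- sprintf("FCS3.1    %8d%8d%8d%8d%8d%8d",
                    text_begin, text_end,
                    if (data_end <= 99999999) data_begin else 0L,
                    if (data_end <= 99999999) data_end else 0L, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text_of(data_begin, data_end), con, eos = NULL)
  writeBin(as.numeric(t(ex)), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an FCS 3.0/3.1 file into an event table
#'
#' @param path FCS file path.
#' @param panel optional `channel_panel`; by default channel roles are
#'   looked up in [default_channels()] (unknown labels become phenotype
#'   channels).
#' @return an `event_table` (the Time parameter populates `$time`).
#' @export
read_fcs <- function(path, panel = NULL) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 58)
    ct_data_error("FCS parse error at byte 0: file truncated (%s)", path)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1"))
    ct_data_error("FCS parse error at byte 0: unsupported version '%s'",
                  version)
  offs <- suppressWarnings(
    as.integer(vapply(0:5, function(i)
      trimws(substr(header, 11 + 8 * i, 18 + 8 * i)), character(1))))
  if (any(is.na(offs[1:2])))
    ct_data_error("FCS parse error at byte 10: bad TEXT offsets")
  text_begin <- offs[1]; text_end <- offs[2]
  if (text_end <= text_begin || text_end >= sz)
    ct_data_error("FCS parse error at byte %d: TEXT segment out of range",
                  text_begin)
  seek(con, text_begin)
  txt <- readChar(con, text_end - text_begin + 1L, useBytes = TRUE)
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2L)
    ct_data_error("FCS parse error at byte %d: empty TEXT segment",
                  text_begin)
  keys <- parts[seq(1, length(parts) - 1, by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- stats::setNames(vals, toupper(trimws(keys)))

  npar <- as.integer(kw[["$PAR"]])
  ntot <- as.integer(kw[["$TOT"]])
  dtype <- toupper(kw[["$DATATYPE"]])
  byteord <- kw[["$BYTEORD"]]
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  bits <- as.integer(vapply(seq_len(npar), function(i)
    kw[[sprintf("$P%dB", i)]], character(1)))
  labels <- vapply(seq_len(npar), function(i)
    kw[[sprintf("$P%dN", i)]], character(1))
  if (anyDuplicated(labels))
    ct_data_error("FCS validation error: duplicate channel names: %s",
                  paste(unique(labels[duplicated(labels)]), collapse = ", "))

  data_begin <- offs[3]; data_end <- offs[4]
  if (is.na(data_begin) || data_begin == 0L) {
    data_begin <- as.integer(kw[["$BEGINDATA"]])
    data_end <- as.integer(kw[["$ENDDATA"]])
  }
  nbytes <- sum(bits / 8) * ntot
  if (is.na(data_begin) || data_begin + nbytes - 1 > sz)
    ct_data_error("FCS parse error at byte %d: DATA segment truncated",
                  data_begin)
  seek(con, data_begin)
  nvals <- npar * ntot
  raw <- switch(dtype,
    F = readBin(con, "double", n = nvals, size = 4L, endian = endian),
    D = readBin(con, "double", n = nvals, size = 8L, endian = endian),
    I = readBin(con, "integer", n = nvals, size = bits[1] / 8,
                signed = bits[1] / 8 > 2, endian = endian),
    ct_data_error("FCS parse error: unsupported $DATATYPE '%s'", dtype))
  if (length(raw) < nvals)
    ct_data_error("FCS parse error at byte %d: expected %d values, got %d",
                  data_begin, nvals, length(raw))
  mat <- matrix(as.numeric(raw), nrow = ntot, ncol = npar, byrow = TRUE,
                dimnames = list(NULL, labels))
  tm <- if ("Time" %in% labels) mat[, "Time"] else NULL
  mat <- mat[, setdiff(labels, "Time"), drop = FALSE]
  if (is.null(panel)) {
    ref <- default_channels()
    idx <- match(colnames(mat), ref$label)
    panel <- channel_panel(colnames(mat),
                           ifelse(is.na(idx), colnames(mat), ref$metal[idx]),
                           ifelse(is.na(idx), "phenotype", ref$role[idx]),
                           marker = ref$marker[idx])
  }
  event_table(mat, panel, time = tm)
}
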