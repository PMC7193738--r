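#' Multi-channel LFP recording
#'
#' Constructs a `Recording`, the package's container for a multi-channel
#' local field potential (LFP) session: a list of equal-length real-valued
#' channels sampled at `fs` Hz, together with the subject and condition
#' labels that downstream separation analyses key on.
#'
#' @param channels list of numeric vectors, one per channel; all the same
#'   length (at least 2 samples). A single numeric vector is accepted and
#'   treated as one channel.
#' @param fs sampling rate in Hz (positive scalar).
#' @param subject_id subject label (non-empty string).
#' @param condition condition label, e.g. `"saline"` or `"levodopa"`
#'   (non-empty string).
#' @param meta optional named list of free-form annotations (units, probe
#'   geometry, ...). Carried along but never interpreted.
#'
#' @return an object of class `"recording"`: a list with elements
#'   `channels`, `fs`, `subject_id`, `condition`, `meta`.
#' @examples
#' rec <- recording(list(sin(1:100), cos(1:100)), fs = 1000,
#'                  subject_id = "m1", condition = "saline")
#' n_samples(rec)
#' @export
recording <- function(channels, fs, subject_id = "unknown",
                      condition = "unlabelled", meta = list()) {
  if (is.numeric(channels)) channels <- list(channels)
  if (!is.list(channels) || length(channels) == 0L)
    stop("'channels' must be a non-empty list of numeric vectors")
  channels <- lapply(channels, function(ch) {
    if (!is.numeric(ch)) stop("every channel must be numeric")
    as.numeric(ch)
  })
  lens <- vapply(channels, length, integer(1))
  if (any(lens != lens[1]))
    stop("all channels must have identical length (got lengths ",
         paste(unique(lens), collapse = ", "), ")")
  if (lens[1] < 2L) stop("channels must contain at least 2 samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("'fs' must be a positive finite scalar (Hz)")
  if (!is.character(condition) || length(condition) != 1L || !nzchar(condition))
    stop("'condition' must be a non-empty string")
  if (!is.character(subject_id) || length(subject_id) != 1L ||
      !nzchar(subject_id))
    stop("'subject_id' must be a non-empty string")
  structure(
    list(channels = channels, fs = as.numeric(fs),
         subject_id = subject_id, condition = condition, meta = meta),
    class = "recording")
}

#' @rdname recording
#' @param x a `recording`.
#' @export
n_channels <- function(x) length(x$channels)

#' @rdname recording
#' @export
n_samples <- function(x) length(x$channels[[1]])

#' @rdname recording
#' @param ... ignored.
#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    n_channels(x), n_samples(x), x$fs, n_samples(x) / x$fs))
  cat(sprintf("  subject: %s   condition: %s\n", x$subject_id, x$condition))
  invisible(x)
}

# sidecar path convention: <data>.json next to <data>.csv
sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a recording from delimited text plus JSON sidecar
#'
#' Reads a comma-separated sample matrix (one column per channel, header
#' row, '.' decimal) and its JSON sidecar (same path with extension
#' `.json`) holding `fs_hz`, `subject_id` and `condition`. This pair is the
#' package's on-disk exchange format for raw LFP matrices.
#'
#' @param path path to the CSV file written by [write_recording()].
#' @param quiet suppress the one-line summary message.
#' @return a [recording()].
#' @export
read_recording <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("recording file not found: ", path)
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("missing JSON sidecar for ", path, " (expected ", side, ")")
  info <- jsonlite::fromJSON(side)
  for (key in c("fs_hz", "subject_id", "condition"))
    if (is.null(info[[key]]))
      stop("sidecar ", side, " lacks required key '", key, "'")
  if (!is.numeric(info$fs_hz) || info$fs_hz <= 0)
    stop("sidecar fs_hz must be a positive number, got: ", info$fs_hz)

  lines <- readLines(path)
  if (length(lines) < 2L) stop("recording file has no data rows: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  ncol_expect <- length(header)
  fields <- strsplit(lines[-1], ",", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != ncol_expect)) {
    bad <- which(nf != ncol_expect)[1]
    stop(sprintf(
      "ragged rows in %s: data row %d has %d field(s), header has %d",
      path, bad, nf[bad], ncol_expect))
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = ncol_expect, byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1, any))[1]
    stop(sprintf("non-numeric cell in %s at data row %d", path, bad))
  }
  drop_time <- header[1] %in% c("time_s", "t", "time")
  ch_cols <- if (drop_time) seq_len(ncol_expect)[-1] else seq_len(ncol_expect)
  channels <- lapply(ch_cols, function(j) mat[, j])
  rec <- recording(channels, fs = info$fs_hz,
                   subject_id = as.character(info$subject_id),
                   condition = as.character(info$condition),
                   meta = if (is.null(info$meta)) list() else as.list(info$meta))
  if (!quiet)
    message(sprintf("read %d channel(s) x %d samples @ %g Hz from %s",
                    n_channels(rec), n_samples(rec), rec$fs, path))
  rec
}

#' Write a recording to delimited text plus JSON sidecar
#'
#' Inverse of [read_recording()]. Samples are written with 9 significant
#' digits, enough to round-trip the unit-power scale used throughout.
#'
#' @param rec a [recording()].
#' @param path output CSV path; the sidecar goes to the same path with
#'   extension `.json`.
#' @param digits significant digits for the sample values.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 9L) {
  stopifnot(inherits(rec, "recording"))
  nch <- n_channels(rec)
  header <- paste0("ch", seq_len(nch), collapse = ",")
  mat <- do.call(cbind, rec$channels)
  body <- apply(mat, 1, function(row)
    paste(sprintf("%.*g", digits, row), collapse = ","))
  ok <- tryCatch({
    writeLines(c(header, body), path); TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write recording to ", path, ": ",
                        conditionMessage(ok))
  jsonlite::write_json(
    list(fs_hz = rec$fs, subject_id = rec$subject_id,
         condition = rec$condition, meta = rec$meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-epoch feature table
#'
#' A `feature_table` is a data frame with one row per
#' (subject, condition, epoch, method) cell and columns
#' `subject_id`, `condition`, `epoch_index`, `epoch_length_s`,
#' `method`, `value`. It is the carrier every feature-extraction
#' routine writes into and every separation analysis reads from.
#'
#' @param subject_id,condition,epoch_index,epoch_length_s,method,value
#'   column vectors, recycled to a common length.
#' @return a data frame of class `c("feature_table", "data.frame")`.
#' @export
feature_table <- function(subject_id = character(), condition = character(),
                          epoch_index = integer(), epoch_length_s = numeric(),
                          method = character(), value = numeric()) {
  tab <- data.frame(subject_id = as.character(subject_id),
                    condition = as.character(condition),
                    epoch_index = as.integer(epoch_index),
                    epoch_length_s = as.numeric(epoch_length_s),
                    method = as.character(method),
                    value = as.numeric(value),
                    stringsAsFactors = FALSE)
  validate_feature_table(tab)
}

validate_feature_table <- function(tab) {
  need <- c("subject_id", "condition", "epoch_index", "epoch_length_s",
            "method", "value")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("feature table lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(tab) > 0 && any(tab$epoch_length_s <= 0))
    stop("epoch_length_s must be positive")
  key <- paste(tab$subject_id, tab$condition, tab$epoch_index, tab$method,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf(
      "duplicate feature rows for (subject=%s, condition=%s, epoch=%d, method=%s)",
      d$subject_id, d$condition, d$epoch_index, d$method))
  }
  class(tab) <- unique(c("feature_table", class(tab)))
  tab
}

#' Read/write per-epoch feature tables
#'
#' CSV with header `subject_id,condition,epoch_index,epoch_length_s,method,value`.
#' The round trip is lossless at 9 significant digits; duplicate
#' (subject, condition, epoch, method) keys are rejected on read.
#'
#' @param tab a [feature_table()].
#' @param path CSV path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns a `feature_table`.
#' @export
write_features <- function(tab, path) {
  tab <- validate_feature_table(tab)
  out <- tab
  out$value <- sprintf("%.9g", out$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("feature file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0)
    return(feature_table())
  validate_feature_table(tab)
}
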