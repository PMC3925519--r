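# Record container and plain-text readers/writers.
#
# Time convention: annotation times are seconds from record start, 0-based,
# half-open intervals [start, end). Epoch k (1-based) covers [k-1, k) s.

#' Construct an EEG record
#'
#' The package's common container: a channels x time sample matrix with a
#' sampling rate, channel labels, a record id and optional seizure
#' annotations.
#'
#' @param samples Numeric matrix (channels x time) or vector (one channel).
#' @param sampling_rate_hz Positive sampling rate in Hz.
#' @param channel_labels Character vector, one per channel.
#' @param record_id Identifier string.
#' @param annotations `NULL` or a data frame with columns `start_s`, `end_s`:
#'   seizure intervals in seconds from record start, half-open
#'   `[start, end)`. Sorted on construction; overlapping or out-of-range
#'   intervals are an error.
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, sampling_rate_hz, channel_labels = NULL,
                       record_id = "record", annotations = NULL) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be positive")
  if (is.null(channel_labels))
    channel_labels <- paste0("ch", seq_len(nrow(samples)))
  if (length(channel_labels) != nrow(samples))
    stop("channel_labels length must equal the number of channels")
  duration <- ncol(samples) / sampling_rate_hz
  annotations <- validate_annotations(annotations, duration)
  structure(list(samples = samples, sampling_rate_hz = sampling_rate_hz,
                 channel_labels = as.character(channel_labels),
                 record_id = as.character(record_id),
                 annotations = annotations),
            class = "eeg_record")
}

validate_annotations <- function(annotations, duration = Inf) {
  if (is.null(annotations) || nrow(annotations) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  if (!all(c("start_s", "end_s") %in% names(annotations)))
    stop("annotations need columns start_s and end_s")
  a <- annotations[order(annotations$start_s), c("start_s", "end_s"), drop = FALSE]
  rownames(a) <- NULL
  if (any(a$end_s <= a$start_s))
    stop("annotation with end_s <= start_s")
  if (any(a$start_s < 0) || any(a$end_s > duration))
    stop("annotation outside [0, duration]")
  if (nrow(a) > 1L && any(a$start_s[-1L] < a$end_s[-nrow(a)]))
    stop("overlapping seizure annotations")
  a
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("EEG record '%s': %d channel(s) x %d samples @ %.2f Hz (%.1f s)\n",
              x$record_id, nrow(x$samples), ncol(x$samples),
              x$sampling_rate_hz, record_duration(x)))
  if (nrow(x$annotations))
    cat(sprintf("  %d seizure annotation(s): %s\n", nrow(x$annotations),
                paste(sprintf("[%g, %g)", x$annotations$start_s,
                              x$annotations$end_s), collapse = " ")))
  invisible(x)
}

#' Record duration in seconds
#' @param record An `eeg_record`.
#' @export
record_duration <- function(record) ncol(record$samples) / record$sampling_rate_hz

#' Read a single-column ASCII EEG record
#'
#' Reads Bonn-archive-style files: plain text, one sample per line, one
#' channel, 173.61 Hz by convention. Non-numeric lines are an error naming
#' the offending line.
#'
#' @param path File path.
#' @param sampling_rate_hz Sampling rate to attach (default 173.61 Hz).
#' @return A one-channel `eeg_record`; the id is the file name without
#'   extension.
#' @export
read_bonn_ascii <- function(path, sampling_rate_hz = 173.61) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty record file: ", path)
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x)) {
    bad <- which(is.na(x))[1L]
    stop(sprintf("non-numeric sample at line %d of %s: '%s'", bad, path, lines[bad]))
  }
  eeg_record(x, sampling_rate_hz,
             record_id = sub("\\.[^.]*$", "", basename(path)))
}

#' Write a single-column ASCII EEG record
#'
#' @param record An `eeg_record` with one channel, or a numeric vector.
#' @param path Output file.
#' @export
write_bonn_ascii <- function(record, path) {
  x <- if (inherits(record, "eeg_record")) {
    if (nrow(record$samples) != 1L) stop("ASCII format holds exactly one channel")
    record$samples[1L, ]
  } else as.numeric(record)
  writeLines(format(x, scientific = FALSE, trim = TRUE, digits = 15), path)
  invisible(path)
}

#' Read seizure annotations from CSV
#'
#' Expects a header `record_id,seizure_start_s,seizure_end_s`. Rows are
#' grouped by record and sorted by start time; an interval with
#' `end <= start` or overlapping intervals within a record are errors.
#'
#' @param path CSV file.
#' @return Named list (by record id) of data frames with columns `start_s`,
#'   `end_s`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("record_id", "seizure_start_s", "seizure_end_s")
  if (!all(need %in% names(df)))
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$record_id), function(g) {
    validate_annotations(data.frame(start_s = g$seizure_start_s,
                                    end_s = g$seizure_end_s))
  })
  out[order(names(out))]
}

#' Write seizure annotations to CSV
#'
#' @param annotations Named list of data frames as from [read_annotations()],
#'   or a single data frame plus `record_id`.
#' @param path Output file.
#' @param record_id Used when `annotations` is a single data frame.
#' @export
write_annotations <- function(annotations, path, record_id = NULL) {
  if (is.data.frame(annotations)) {
    annotations <- stats::setNames(list(annotations),
                                   record_id %||% "record")
  }
  rows <- do.call(rbind, lapply(names(annotations), function(id) {
    a <- annotations[[id]]
    if (nrow(a) == 0L) return(NULL)
    data.frame(record_id = id, seizure_start_s = a$start_s,
               seizure_end_s = a$end_s)
  }))
  if (is.null(rows))
    rows <- data.frame(record_id = character(0), seizure_start_s = numeric(0),
                       seizure_end_s = numeric(0))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a private, restored RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
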