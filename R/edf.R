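# Minimal EDF (European Data Format) reader and writer: ASCII header,
# per-signal subheaders, 16-bit little-endian samples in fixed-duration data
# records. Covers plain EDF with a uniform sampling rate across signals --
# the layout of scalp-EEG archives such as CHB-MIT -- not EDF+ annotations.

.edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write an EEG record as an EDF file
#'
#' Samples are scaled per channel to the full 16-bit digital range. The data
#' record duration is 1 second, so the sampling rate must be a whole number
#' of samples per second and the record a whole number of seconds.
#' Annotations are not embedded; write them separately with
#' [write_annotations()].
#'
#' @param record An `eeg_record`.
#' @param path Output file.
#' @export
write_edf <- function(record, path) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$sampling_rate_hz
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(fs)
  n <- ncol(record$samples)
  if (n %% fs != 0L) stop("EDF writer requires a whole number of seconds of data")
  n_rec <- n %/% fs
  ns <- nrow(record$samples)

  phys_min <- apply(record$samples, 1, min)
  phys_max <- apply(record$samples, 1, max)
  flat <- phys_max == phys_min
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8),
    .edf_pad(record$record_id, 80),
    .edf_pad("Startdate X X X X", 80),
    .edf_pad("01.01.00", 8),
    .edf_pad("00.00.00", 8),
    .edf_pad(256L + 256L * ns, 8),
    .edf_pad("", 44),
    .edf_pad(n_rec, 8),
    .edf_pad(1L, 8),
    .edf_pad(ns, 4))
  field <- function(vals, width)
    paste(vapply(vals, .edf_pad, "", width = width), collapse = "")
  hdr <- paste0(hdr,
    field(record$channel_labels, 16),
    field(rep("", ns), 80),
    field(rep("uV", ns), 8),
    field(formatC(phys_min, format = "g", digits = 7), 8),
    field(formatC(phys_max, format = "g", digits = 7), 8),
    field(rep(dig_min, ns), 8),
    field(rep(dig_max, ns), 8),
    field(rep("", ns), 80),
    field(rep(fs, ns), 8),
    field(rep("", ns), 32))
  writeChar(hdr, con, eos = NULL)

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  dig <- round(sweep(sweep(record$samples, 1, phys_min), 1, gain, "/")) + dig_min
  dig <- pmin(pmax(dig, dig_min), dig_max)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    block <- as.integer(t(dig[, cols, drop = FALSE]))  # signal-major
    writeBin(block, con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file into an EEG record
#'
#' All signals must share one sampling rate; mixed rates are refused (the
#' scalp-EEG data this package targets is uniformly sampled, and resampling
#' is out of scope). Channel labels are preserved (trailing padding
#' stripped).
#'
#' @param path EDF file.
#' @param annotations Optional seizure annotation data frame to attach
#'   (columns `start_s`, `end_s`), e.g. one element of [read_annotations()].
#' @return An `eeg_record`.
#' @export
read_edf <- function(path, annotations = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") stop("malformed EDF header (version field '", version, "')")
  patient <- rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop("malformed EDF header (signal count)")
  fields <- function(width) vapply(seq_len(ns), function(i) rd(width), "")
  labels <- fields(16); fields(80); fields(8)
  phys_min <- as.numeric(fields(8)); phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8)); dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr, n_rec, rec_dur)))
    stop("malformed EDF header (numeric fields)")
  if (length(unique(spr)) != 1L)
    stop("mixed sampling rates across EDF signals are not supported")
  if (seek(con) != hdr_bytes)
    stop("malformed EDF header (declared size ", hdr_bytes, ")")

  fs <- spr[1L] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  samples <- matrix(0, nrow = ns, ncol = n_rec * spr[1L])
  for (r in seq_len(n_rec)) {
    block <- readBin(con, "integer", n = ns * spr[1L], size = 2L,
                     endian = "little", signed = TRUE)
    if (length(block) < ns * spr[1L]) stop("truncated EDF data record ", r)
    cols <- ((r - 1L) * spr[1L] + 1L):(r * spr[1L])
    samples[, cols] <- t(matrix(block, ncol = ns))
  }
  samples <- sweep(sweep(samples, 1, dig_min), 1, gain, "*")
  samples <- sweep(samples, 1, phys_min, "+")
  id <- if (nzchar(patient)) patient else sub("\\.[^.]*$", "", basename(path))
  eeg_record(samples, fs, channel_labels = labels, record_id = id,
             annotations = annotations)
}
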