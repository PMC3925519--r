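# Subband and raw-epoch features.
#
# Six features per wavelet subband: maximum, minimum, mean, sample standard
# deviation (N-1 denominator), entropy sum(c^2 * log(c^2)) with natural log
# and the 0*log(0) = 0 convention, and energy sum(c^2). Two raw-epoch
# statistics: interquartile range (linear-interpolation quartiles) and mean
# absolute deviation from the mean.

.check_coeffs <- function(x, what = "coefficients") {
  if (length(x) == 0L) stop("empty ", what)
  if (!all(is.finite(x))) stop("non-finite values in ", what)
  invisible(x)
}

#' Subband energy
#'
#' Sum of squared coefficients, \eqn{\sum_j |c_j|^2}.
#'
#' @param coeffs Non-empty numeric vector.
#' @return Scalar energy.
#' @export
subband_energy <- function(coeffs) {
  .check_coeffs(coeffs)
  sum(coeffs^2)
}

#' Subband (log-energy weighted) entropy
#'
#' \eqn{\sum_j c_j^2 \log(c_j^2)} with natural logarithm and the convention
#' \eqn{0 \log 0 = 0}. Unlike Shannon entropy of a normalized distribution,
#' this is an unnormalized measure that grows with both spread and magnitude
#' of the coefficients.
#'
#' @param coeffs Non-empty numeric vector.
#' @return Scalar entropy.
#' @export
subband_entropy <- function(coeffs) {
  .check_coeffs(coeffs)
  s <- coeffs^2
  pos <- s > 0
  sum(s[pos] * log(s[pos]))
}

#' Subband order and moment statistics
#'
#' Maximum, minimum, mean and sample standard deviation (N-1 denominator) of
#' a coefficient vector. A length-one input has no dispersion estimate; its
#' standard deviation is reported as 0 with a warning.
#'
#' @param coeffs Non-empty numeric vector.
#' @return Named numeric vector `c(maximum, minimum, mean, std)`.
#' @export
subband_stats <- function(coeffs) {
  .check_coeffs(coeffs)
  std <- if (length(coeffs) < 2L) {
    warning("standard deviation of a length-1 vector reported as 0")
    0
  } else {
    stats::sd(coeffs)
  }
  c(maximum = max(coeffs), minimum = min(coeffs),
    mean = mean(coeffs), std = std)
}

#' Interquartile range of raw samples
#'
#' Q3 - Q1 with quartiles by linear interpolation of order statistics
#' (`stats::quantile()` type 7, the default of mainstream numeric
#' environments).
#'
#' @param samples Numeric vector, length >= 4.
#' @return Scalar IQR.
#' @export
iqr_range <- function(samples) {
  if (length(samples) < 4L) stop("need at least 4 samples for quartiles")
  .check_coeffs(samples, "samples")
  q <- stats::quantile(samples, c(0.25, 0.75), names = FALSE, type = 7)
  q[2] - q[1]
}

#' Mean absolute deviation from the mean
#'
#' \eqn{(1/N) \sum_j |x_j - \bar x|}. Note this is the mean absolute
#' deviation, not the median absolute deviation of [stats::mad()].
#'
#' @param samples Non-empty numeric vector.
#' @return Scalar MAD.
#' @export
mean_abs_dev <- function(samples) {
  .check_coeffs(samples, "samples")
  mean(abs(samples - mean(samples)))
}

.subband_feature_names <- c("max", "min", "mean", "std", "entropy", "energy")

subband_features <- function(coeffs) {
  st <- subband_stats(coeffs)
  stats::setNames(
    c(st[["maximum"]], st[["minimum"]], st[["mean"]], st[["std"]],
      subband_entropy(coeffs), subband_energy(coeffs)),
    .subband_feature_names)
}

#' Event-detection feature vector for one frame
#'
#' Decomposes a frame (256 samples by convention) to `levels` wavelet levels
#' and computes the six subband features on each of the selected subbands
#' (D3, D4, A4 by default: the bands covering the clinically interesting
#' frequency ranges at 173.61 Hz). Feature order is frozen as
#' `[max, min, mean, std, entropy, energy]` within each band, bands in the
#' order given by `bands`, so that serialized models remain portable.
#'
#' @param frame Numeric vector (one analysis window).
#' @param bands Character vector of subband names to use.
#' @param levels,filters,extension_mode Passed to [decompose()].
#' @return Named numeric vector of `6 * length(bands)` features, names like
#'   `"D3_max"`, `"A4_energy"`.
#' @export
event_feature_vector <- function(frame, bands = c("D3", "D4", "A4"),
                                 levels = 4L, filters = db2_filters(),
                                 extension_mode = "symmetric") {
  sb <- decompose(frame, levels = levels, filters = filters,
                  extension_mode = extension_mode)
  out <- lapply(bands, function(b) {
    v <- subband_features(subband(sb, b))
    stats::setNames(v, paste0(b, "_", names(v)))
  })
  unlist(out)
}

#' Onset-detection feature vector for one channel of one epoch
#'
#' The 18 wavelet features of [event_feature_vector()] followed by the
#' interquartile range and mean absolute deviation of the raw epoch samples
#' (no wavelet decomposition), for a total of 20 features per channel per
#' 1-second epoch.
#'
#' @param epoch_channel Numeric vector: one channel of one epoch
#'   (`sampling_rate * 1 s` samples).
#' @inheritParams event_feature_vector
#' @return Named numeric vector of 20 features.
#' @export
onset_channel_features <- function(epoch_channel, bands = c("D3", "D4", "A4"),
                                   levels = 4L, filters = db2_filters(),
                                   extension_mode = "symmetric") {
  c(event_feature_vector(epoch_channel, bands = bands, levels = levels,
                         filters = filters, extension_mode = extension_mode),
    IQR = iqr_range(epoch_channel),
    MAD = mean_abs_dev(epoch_channel))
}

#' Write a feature table as CSV
#'
#' Writes a matrix of feature vectors with provenance columns (record id,
#' channel, frame index) and a header of feature names.
#'
#' @param features Numeric matrix, one feature vector per row, named columns.
#' @param path Output file.
#' @param record_id,channel,frame Provenance vectors recycled to `nrow(features)`.
#' @export
write_feature_csv <- function(features, path, record_id = "", channel = 1L,
                              frame = seq_len(nrow(features))) {
  df <- data.frame(record_id = record_id, channel = channel, frame = frame,
                   features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
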