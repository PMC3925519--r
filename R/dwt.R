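# Filter-bank discrete wavelet decomposition with Daubechies order-2 filters.
#
# Conventions (frozen so downstream feature values are reproducible):
#   * symmetric / zero extension: pad (L-1) samples per side, downsampled
#     output length floor((n + L - 1) / 2)
#   * periodization: odd-length inputs repeat their last sample, pad L/2
#     samples per side periodically, output length ceiling(n / 2)
# These match the de-facto defaults of mainstream DWT implementations.

#' Daubechies order-2 analysis filter pair
#'
#' Returns the standard 4-tap db2 decomposition filters, hard-coded to full
#' double precision from the usual Daubechies tabulation. The highpass filter
#' is the quadrature mirror of the lowpass: `g == rev(h) * c(-1, 1, -1, 1)`.
#'
#' @return An object of class `wavelet_filter_pair` with elements `lowpass`,
#'   `highpass` (length-4 numeric) and `name` (`"db2"`).
#' @examples
#' f <- db2_filters()
#' sum(f$lowpass)   # sqrt(2)
#' sum(f$highpass)  # 0
#' @export
db2_filters <- function() {
  lowpass <- c(-0.1294095225512604, 0.2241438680420134,
                0.8365163037378079, 0.4829629131445341)
  highpass <- rev(lowpass) * c(-1, 1, -1, 1)
  structure(list(lowpass = lowpass, highpass = highpass, name = "db2"),
            class = "wavelet_filter_pair")
}

#' @export
print.wavelet_filter_pair <- function(x, ...) {
  cat("Wavelet analysis filter pair:", x$name, "\n")
  cat("  lowpass :", format(x$lowpass, digits = 6), "\n")
  cat("  highpass:", format(x$highpass, digits = 6), "\n")
  invisible(x)
}

# Index into x with half-point symmetric reflection (period 2n), valid for
# any integer position including <= 0 and > n.
sym_index <- function(n, pos) {
  p <- (pos - 1L) %% (2L * n)
  ifelse(p < n, p + 1L, 2L * n - p)
}

extend_signal <- function(x, k, mode) {
  n <- length(x)
  switch(mode,
    symmetric = x[sym_index(n, seq.int(1L - k, n + k))],
    zero = c(rep(0, k), x, rep(0, k)),
    periodization = x[((seq.int(1L - k, n + k) - 1L) %% n) + 1L],
    stop("unknown extension mode: ", mode))
}

# Convolve an already-extended signal with `f` and keep every second sample
# starting at the calibrated phase.
conv_down <- function(ext, f, out_len) {
  lf <- length(f)
  nv <- length(ext) - lf + 1L
  v <- numeric(nv)
  for (j in seq_len(lf)) {
    v <- v + f[j] * ext[seq.int(lf - j + 1L, length.out = nv)]
  }
  v[seq.int(2L, by = 2L, length.out = out_len)]
}

#' Single-level discrete wavelet transform
#'
#' Lowpass/highpass filtering followed by dyadic downsampling, with boundary
#' handling selected by `extension_mode`.
#'
#' @param signal Numeric vector, length >= 1.
#' @param filters A `wavelet_filter_pair`, by default [db2_filters()].
#' @param extension_mode One of `"symmetric"` (half-point reflection, the
#'   default), `"periodization"` (circular; the only mode with exact
#'   orthogonality and critical sampling) or `"zero"`.
#' @return A list with numeric components `approximation` and `detail`.
#' @export
dwt_single_level <- function(signal, filters = db2_filters(),
                             extension_mode = c("symmetric", "periodization", "zero")) {
  extension_mode <- match.arg(extension_mode)
  if (length(signal) == 0L) stop("empty signal: cannot take a wavelet transform")
  if (!all(is.finite(signal))) stop("signal contains non-finite values")
  lf <- length(filters$lowpass)
  x <- as.numeric(signal)
  if (extension_mode == "periodization") {
    if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
    out_len <- as.integer(ceiling(length(signal) / 2))
    ext <- extend_signal(x, lf %/% 2L, "periodization")
  } else {
    out_len <- (length(x) + lf - 1L) %/% 2L
    ext <- extend_signal(x, lf - 1L, extension_mode)
  }
  list(approximation = conv_down(ext, filters$lowpass, out_len),
       detail = conv_down(ext, filters$highpass, out_len))
}

#' Single-level inverse transform (periodization mode)
#'
#' Reconstructs a signal from one approximation/detail pair using the
#' time-reversed analysis filters as synthesis filters. Only periodization
#' mode is supported; it is the mode under which the transform is exactly
#' orthogonal, and the inverse exists without redundant coefficients.
#'
#' @param approximation,detail Equal-length numeric coefficient vectors.
#' @param filters A `wavelet_filter_pair`.
#' @param n_out Target signal length (defaults to `2 * length(approximation)`;
#'   pass the original odd length to drop the padding sample).
#' @return Numeric vector of length `n_out`.
#' @export
idwt_single_level <- function(approximation, detail, filters = db2_filters(),
                              n_out = 2L * length(approximation)) {
  if (length(approximation) != length(detail))
    stop("approximation and detail must have equal length")
  n <- 2L * length(approximation)
  up <- function(cf) {
    u <- numeric(n)
    u[seq.int(1L, by = 2L, length.out = length(cf))] <- cf
    u
  }
  rec_lo <- rev(filters$lowpass)
  rec_hi <- rev(filters$highpass)
  ua <- up(approximation)
  ud <- up(detail)
  y <- numeric(n)
  ks <- seq_len(n)
  for (j in seq_along(rec_lo)) {
    idx <- ((ks - j + 1L) %% n) + 1L
    y <- y + rec_lo[j] * ua[idx] + rec_hi[j] * ud[idx]
  }
  y[seq_len(n_out)]
}

#' Multilevel wavelet decomposition into detail and approximation subbands
#'
#' Iterates [dwt_single_level()] on the running approximation, producing the
#' detail subbands D1..Dl and the final approximation Al of the classic
#' filter-bank scheme. With four levels on EEG this yields D1-D4 and A4;
#' feature extraction downstream uses D3, D4 and A4, but all subbands are
#' retained here.
#'
#' @param signal Numeric vector.
#' @param levels Number of decomposition levels (default 4).
#' @param filters A `wavelet_filter_pair`.
#' @inheritParams dwt_single_level
#' @return An object of class `subband_set`: list with `details` (named list
#'   `D1`..`Dl`), `approximation` (`Al`), `levels`, `wavelet`,
#'   `extension_mode`.
#' @export
decompose <- function(signal, levels = 4L, filters = db2_filters(),
                      extension_mode = c("symmetric", "periodization", "zero")) {
  extension_mode <- match.arg(extension_mode)
  levels <- as.integer(levels)
  if (levels < 1L) stop("levels must be >= 1")
  details <- vector("list", levels)
  approx <- as.numeric(signal)
  lf <- length(filters$lowpass)
  for (lev in seq_len(levels)) {
    if (length(approx) < lf)
      stop(sprintf("signal too short: level %d input has %d samples (< filter length %d)",
                   lev, length(approx), lf))
    step <- dwt_single_level(approx, filters, extension_mode)
    details[[lev]] <- step$detail
    approx <- step$approximation
  }
  names(details) <- paste0("D", seq_len(levels))
  structure(list(details = details, approximation = approx, levels = levels,
                 wavelet = filters$name, extension_mode = extension_mode),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("Subband set: %s, %d levels, %s extension\n",
              x$wavelet, x$levels, x$extension_mode))
  lens <- c(vapply(x$details, length, integer(1)),
            stats::setNames(length(x$approximation), paste0("A", x$levels)))
  print(lens)
  invisible(x)
}

# Convenience accessor: subband by name ("D3", "A4", ...).
subband <- function(sb, name) {
  stopifnot(inherits(sb, "subband_set"))
  if (name == paste0("A", sb$levels)) return(sb$approximation)
  if (name %in% names(sb$details)) return(sb$details[[name]])
  stop("no such subband: ", name)
}
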