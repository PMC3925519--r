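# Independent brute-force oracles. Deliberately naive: explicit boundary
# extension, double-loop full convolution, then decimation -- no code shared
# with the package's transform path.

oracle_dwt_band <- function(x, f, mode) {
  L <- length(f)
  n <- length(x)
  if (mode == "periodization") {
    if (n %% 2 == 1) x <- c(x, x[n])
    m <- length(x)
    ext <- c(x[(m - 1):m], x, x[1:2])
    out_len <- ceiling(n / 2)
  } else {
    k <- L - 1
    left <- if (mode == "symmetric") x[k:1] else rep(0, k)
    right <- if (mode == "symmetric") x[n:(n - k + 1)] else rep(0, k)
    ext <- c(left, x, right)
    out_len <- floor((n + L - 1) / 2)
  }
  y <- numeric(length(ext) + L - 1)
  for (t in seq_along(y)) {
    acc <- 0
    for (j in 1:L) {
      i <- t - j + 1
      if (i >= 1 && i <= length(ext)) acc <- acc + f[j] * ext[i]
    }
    y[t] <- acc
  }
  y[seq(5, by = 2, length.out = out_len)]
}

oracle_dwt_single <- function(x, filters, mode) {
  list(approximation = oracle_dwt_band(x, filters$lowpass, mode),
       detail = oracle_dwt_band(x, filters$highpass, mode))
}

oracle_decompose <- function(x, levels, filters, mode) {
  details <- list()
  a <- x
  for (l in seq_len(levels)) {
    s <- oracle_dwt_single(a, filters, mode)
    details[[l]] <- s$detail
    a <- s$approximation
  }
  list(details = details, approximation = a)
}

oracle_energy <- function(x) {
  acc <- 0
  for (v in x) acc <- acc + v * v
  acc
}

oracle_entropy <- function(x) {
  acc <- 0
  for (v in x) if (v != 0) acc <- acc + v^2 * log(v^2)
  acc
}

oracle_mean_sd <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  m <- s / length(x)
  ss <- 0
  for (v in x) ss <- ss + (v - m)^2
  c(mean = m, sd = sqrt(ss / (length(x) - 1)))
}

oracle_mad <- function(x) {
  m <- sum(x) / length(x)
  acc <- 0
  for (v in x) acc <- acc + abs(v - m)
  acc / length(x)
}
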