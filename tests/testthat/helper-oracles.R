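# Independent brute-force evaluations of the defining formulas, kept
# deliberately loop-based and separate from the package implementations.

REP6 <- c("SI-L", "AP-L", "SI-R", "AP-R", "SI-W", "AP-W")

oracle_pearson <- function(x, y) {
  M <- length(x)
  sx <- sd(x); sy <- sd(y)
  s <- 0
  for (i in seq_len(M))
    s <- s + ((x[i] - mean(x)) / sx) * ((y[i] - mean(y)) / sy)
  s / (M - 1)
}

oracle_vr <- function(X) {
  n <- nrow(X); M <- ncol(X)
  num <- 0
  for (i in seq_len(M)) for (j in seq_len(n))
    num <- num + (X[j, i] - mean(X[, i]))^2
  num <- num / (M * (n - 1))
  gm <- mean(X)
  den <- 0
  for (i in seq_len(M)) for (j in seq_len(n))
    den <- den + (X[j, i] - gm)^2
  den <- den / (M * n - 1)
  if (den == 0) 0 else num / den
}

oracle_extremes <- function(x) {
  x <- x[c(TRUE, diff(x) != 0)]
  cnt <- 0L
  if (length(x) < 3) return(0L)
  for (i in 2:(length(x) - 1))
    if ((x[i] - x[i - 1]) * (x[i + 1] - x[i]) < 0) cnt <- cnt + 1L
  cnt
}

oracle_harmonic <- function(x, nh = 20, cap = 1e6) {
  x <- x - mean(x)
  M <- length(x)
  nh <- min(nh, (M - 1) %/% 2)
  Cn <- sapply(seq_len(nh), function(n)
    Mod(sum(x * exp(-2i * pi * n * (seq_len(M) - 1) / M))))
  even <- sum(Cn[seq(2, nh, 2)])
  odd <- sum(Cn[seq(1, nh, 2)])
  if (odd < 1e-12) cap else even / odd
}

oracle_symmetry <- function(x, band = c(0.3, 0.7)) {
  x <- x - mean(x)
  M <- length(x)
  y <- c(x, x)
  a0 <- sum(y^2) / (2 * M)
  if (a0 == 0) return(0)
  lags <- max(1, floor(band[1] * M)):min(M - 1, ceiling(band[2] * M))
  best <- -Inf
  for (l in lags) {
    s <- 0
    for (i in 1:(2 * M - l)) s <- s + y[i] * y[i + l]
    best <- max(best, s / (2 * M - l) / a0)
  }
  min(best, 1)
}

oracle_normalize_row <- function(x, xref) {
  sapply(seq_along(x), function(j)
    if (x[j] <= xref[j]) x[j] / xref[j] else 2 - x[j] / xref[j])
}

oracle_xi <- function(z, R, minAbs, maxAbs, gamma = 1) {
  sapply(seq_along(z), function(j) {
    dev <- abs(z[j] - R[j])
    raw <- (minAbs + gamma * maxAbs) / (dev + gamma * maxAbs)
    min(raw, 1)
  })
}

rand_channel_matrix <- function(M = 100, k = 6, chans = REP6) {
  m <- matrix(rnorm(M * k), M, k)
  colnames(m) <- chans[seq_len(k)]
  m
}

# wrap a plain matrix as an agg with its own source cycles attached
as_agg <- function(m, cycles = NULL) {
  if (is.null(cycles)) cycles <- list(m, m, m)
  structure(m, cycles = cycles, class = "agg")
}
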