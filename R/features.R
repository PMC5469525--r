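#' Pearson similarity of one channel between AGG and CGG
#'
#' Sample Pearson correlation (with M-1 normalization) between the
#' subject's averaged channel waveform and the healthy reference
#' waveform. Constant inputs yield 0 with a warning so the overall
#' similarity stays finite for pathological flat signals.
#'
#' @param x,y numeric vectors of equal length M.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_channel <- function(x, y) {
  if (length(x) != length(y)) stop("channels have unequal lengths")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant channel; correlation set to 0")
    return(0)
  }
  stats::cor(x, y)
}

#' Overall Pearson similarity P
#'
#' Sum of the per-channel correlations between an AGG and the CGG over
#' the K = 6 representative channels; its maximum value is K, attained
#' when every channel matches the reference exactly.
#'
#' @param agg M x 6 AGG matrix.
#' @param cgg M x 6 CGG matrix with the same channel set.
#' @return P in `[-6, 6]`.
#' @export
pearson_total <- function(agg, cgg) {
  if (!identical(colnames(agg), colnames(cgg)))
    stop("AGG and CGG channel sets differ")
  sum(vapply(colnames(agg), function(ch)
    pearson_channel(agg[, ch], cgg[, ch]), numeric(1L)))
}

#' Variance ratio of one channel across repeated cycles
#'
#' Hershler-Milner variance ratio: within-phase variance across the
#' repeated cycles over total variance about the grand mean,
#' \deqn{v = \frac{\sum_i \sum_j (X_{ij} - \bar X_i)^2 / (M(n-1))}
#'            {\sum_i \sum_j (X_{ij} - \bar X)^2 / (Mn - 1)}}
#' where \eqn{\bar X_i} is the across-cycle mean at phase i and
#' \eqn{\bar X} the grand mean. Identical cycles give v = 0; unrelated
#' cycles give v near 1.
#'
#' @param cycles n x M matrix, one row per cycle.
#' @return v >= 0 (0 by convention when all values are identical).
#' @export
variance_ratio_channel <- function(cycles) {
  n <- nrow(cycles)
  M <- ncol(cycles)
  if (n < 2) stop("need at least two cycles")
  phase_mean <- colMeans(cycles)
  grand_mean <- mean(cycles)
  denom <- sum((cycles - grand_mean)^2) / (M * n - 1)
  if (denom == 0) return(0)
  num <- sum(sweep(cycles, 2L, phase_mean)^2) / (M * (n - 1))
  num / denom
}

#' Overall variance ratio V
#'
#' Sum of per-channel variance ratios over the six representative
#' channels, computed on the same cycles that formed the AGG.
#'
#' @param cycle_stack list of the normalized cycles (each M x 6) behind
#'   one AGG, or an `agg` object carrying its `cycles` attribute.
#' @return V >= 0.
#' @export
variance_ratio_total <- function(cycle_stack) {
  if (inherits(cycle_stack, "agg"))
    cycle_stack <- attr(cycle_stack, "cycles")
  chans <- colnames(cycle_stack[[1L]])
  sum(vapply(chans, function(ch) {
    variance_ratio_channel(t(vapply(cycle_stack, function(cy) cy[, ch],
                                    numeric(nrow(cycle_stack[[1L]])))))
  }, numeric(1L)))
}

#' Count extreme points N of an AGG
#'
#' Counts, over all six channels, the interior points where the first
#' difference changes sign. Involuntary shaking superimposes ripple on
#' the averaged waveform and raises the count. Runs of exactly equal
#' adjacent samples are compressed first, so a plateau counts as at most
#' one extremum.
#'
#' @param agg M x 6 AGG matrix (or any channel matrix).
#' @return integer N >= 0.
#' @export
count_extreme_points <- function(agg) {
  sum(vapply(seq_len(ncol(agg)), function(j) {
    x <- agg[, j]
    x <- x[c(TRUE, diff(x) != 0)]      # compress plateaus
    if (length(x) < 3) return(0L)
    s <- sign(diff(x))
    sum(s[-1L] * s[-length(s)] < 0)
  }, integer(1L)))
}

#' Harmonic ratio of one stride-normalized channel
#'
#' A stride contains two steps, so a smooth symmetric gait concentrates
#' spectral energy in even multiples of the stride frequency. The
#' harmonic ratio is the sum of the magnitudes of the even harmonics
#' (2, 4, ..., 20) over the odd harmonics (1, 3, ..., 19) of the
#' discrete Fourier transform of one stride. When odd energy vanishes
#' the ratio is capped at a finite sentinel.
#'
#' @param channel numeric vector holding exactly one stride (M points).
#' @param n_harmonics highest harmonic used (default 20).
#' @param cap value returned when the odd-harmonic sum is below 1e-12
#'   (default 1e6).
#' @return h >= 0.
#' @export
harmonic_ratio <- function(channel, n_harmonics = 20, cap = 1e6) {
  x <- channel - mean(channel)
  M <- length(x)
  n_harmonics <- min(n_harmonics, (M - 1) %/% 2)
  Cn <- Mod(stats::fft(x))[2:(n_harmonics + 1L)]
  even <- sum(Cn[seq(2L, n_harmonics, by = 2L)])
  odd <- sum(Cn[seq(1L, n_harmonics, by = 2L)])
  if (odd < 1e-12) {
    warning("odd-harmonic energy vanishes; harmonic ratio capped")
    return(cap)
  }
  even / odd
}

#' Overall harmonic ratio H
#'
#' Sum of the harmonic ratios of the two waist channels (SI-W and AP-W)
#' of an AGG. Only the waist is used: trunk acceleration near the centre
#' of mass carries the rhythmic content the harmonic ratio measures.
#'
#' @param agg M x 6 AGG matrix containing `SI-W` and `AP-W`.
#' @inheritParams harmonic_ratio
#' @return H >= 0.
#' @export
harmonic_total <- function(agg, n_harmonics = 20, cap = 1e6) {
  if (!all(c("SI-W", "AP-W") %in% colnames(agg)))
    stop("waist channels SI-W and AP-W required")
  harmonic_ratio(agg[, "SI-W"], n_harmonics, cap) +
    harmonic_ratio(agg[, "AP-W"], n_harmonics, cap)
}

#' Step-regularity autocorrelation of one stride
#'
#' Step regularity is read off the unbiased autocorrelation of the gait
#' acceleration signal, which is periodic at the stride with a secondary
#' peak at the step lag. An AGG channel holds exactly one period of that
#' pattern, so the statistic is computed on the stride repeated twice:
#' \eqn{a(l) = \frac{1}{2M-l}\sum_i x_i x_{i+l}} over the doubled,
#' mean-centered stride, normalized by a(0). As is the maximum of the
#' normalized sequence over the step-lag search band (`band * M`,
#' default 0.3-0.7 of the stride), capped at 1: identical neighbouring
#' steps give exactly 1.
#'
#' @param channel numeric vector of one stride (M points); mean-centered
#'   internally.
#' @param band search band for the step lag as fractions of M
#'   (default `c(0.3, 0.7)`).
#' @return As, typically in `[-1, 1]` (0 with a warning for a null
#'   signal).
#' @export
symmetry_channel <- function(channel, band = c(0.3, 0.7)) {
  x <- channel - mean(channel)
  M <- length(x)
  y <- c(x, x)                         # one period, repeated twice
  a0 <- sum(y^2) / (2 * M)
  if (a0 == 0) {
    warning("null channel; symmetry set to 0")
    return(0)
  }
  lags <- max(1L, floor(band[1L] * M)):min(M - 1L, ceiling(band[2L] * M))
  ac <- vapply(lags, function(l)
    sum(y[1:(2 * M - l)] * y[(1 + l):(2 * M)]) / (2 * M - l) / a0,
    numeric(1L))
  min(max(ac), 1)
}

#' Overall symmetry S
#'
#' Sum of the step-regularity autocorrelation values of the two waist
#' channels (SI-W and AP-W) of an AGG; a perfectly step-symmetric gait
#' approaches S = 2.
#'
#' @param agg M x 6 AGG matrix containing `SI-W` and `AP-W`.
#' @inheritParams symmetry_channel
#' @return S in `[-2, 2]`.
#' @export
symmetry_total <- function(agg, band = c(0.3, 0.7)) {
  if (!all(c("SI-W", "AP-W") %in% colnames(agg)))
    stop("waist channels SI-W and AP-W required")
  symmetry_channel(agg[, "SI-W"], band) +
    symmetry_channel(agg[, "AP-W"], band)
}

#' Assemble the five-feature vector of one AGG
#'
#' Computes P (similarity to the reference), V (cycle-to-cycle variance
#' ratio), N (extreme-point count), H (harmonic ratio of the waist) and
#' S (step symmetry of the waist) for one Average Gait Graph.
#'
#' @param agg an `agg` object from [build_aggs()].
#' @param cgg the reference CGG matrix.
#' @param source_cycles list of the normalized cycles behind the AGG;
#'   defaults to the AGG's own `cycles` attribute.
#' @param config pipeline configuration from [gait_config()].
#' @return named numeric vector `(P, V, N, H, S)`.
#' @export
gait_features <- function(agg, cgg, source_cycles = attr(agg, "cycles"),
                          config = gait_config()) {
  if (is.null(source_cycles))
    stop("source cycles required for the variance ratio")
  c(P = pearson_total(agg, cgg),
    V = variance_ratio_total(source_cycles),
    N = as.numeric(count_extreme_points(agg)),
    H = harmonic_total(agg, config$n_harmonics, config$h_cap),
    S = symmetry_total(agg, config$symmetry_band))
}
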