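#' Time-normalize a gait cycle to a fixed length
#'
#' Resamples each channel of a stride to `M` phase points by linear
#' interpolation over normalized time, making cycles of different
#' durations comparable. Each channel is then mean-centered (optional)
#' so that gravity offsets on SI channels do not dominate averaged
#' waveforms; Pearson correlation and the variance ratio are unaffected
#' by centering.
#'
#' @param cycle a `gait_cycle` from [cut_strides()], or a duration x 6
#'   channel matrix.
#' @param M number of phase points (default 100).
#' @param center mean-center each channel (default TRUE).
#' @return an M x 6 matrix of class `normalized_cycle`, columns
#'   `SI-L, AP-L, SI-R, AP-R, SI-W, AP-W`.
#' @export
normalize_cycle <- function(cycle, M = 100, center = TRUE) {
  ch <- if (inherits(cycle, "gait_cycle")) cycle$channels else cycle
  L <- nrow(ch)
  if (is.null(L) || L < 4) stop("degenerate cycle duration")
  out <- apply(ch, 2L, function(col)
    stats::approx(x = seq(0, 1, length.out = L), y = col,
                  xout = seq(0, 1, length.out = M))$y)
  if (center) out <- scale(out, center = TRUE, scale = FALSE)
  out <- matrix(as.numeric(out), M, ncol(ch),
                dimnames = list(NULL, colnames(ch)))
  class(out) <- c("normalized_cycle", class(out))
  out
}

#' Build Average Gait Graphs from normalized cycles
#'
#' An Average Gait Graph (AGG) is the arithmetic mean of three
#' time-normalized gait cycles and represents one snapshot of a subject's
#' gait pattern. Cycles are consumed in consecutive non-overlapping
#' triples from the start of the pruned cycle list; by default four AGGs
#' are extracted per subject. If fewer than `3 * n_graphs` cycles are
#' available the number of graphs is reduced with a warning (minimum 1).
#'
#' @param cycles list of `normalized_cycle` matrices.
#' @param n_graphs number of AGGs requested (default 4).
#' @param cycles_per_graph cycles averaged per AGG (default 3).
#' @return list of `agg` objects: the M x 6 mean matrix with attributes
#'   `source_cycles` (indices) and per-channel source data for the
#'   variance ratio.
#' @export
build_aggs <- function(cycles, n_graphs = 4, cycles_per_graph = 3) {
  if (length(cycles) < cycles_per_graph)
    stop("need at least ", cycles_per_graph, " cycles to build an AGG")
  avail <- length(cycles) %/% cycles_per_graph
  if (avail < n_graphs) {
    warning("only ", avail, " AGG(s) can be formed from ",
            length(cycles), " cycles")
    n_graphs <- avail
  }
  lapply(seq_len(n_graphs), function(g) {
    idx <- ((g - 1L) * cycles_per_graph + 1L):(g * cycles_per_graph)
    stack <- cycles[idx]
    m <- Reduce(`+`, stack) / length(stack)
    m <- matrix(as.numeric(m), nrow(m), ncol(m),
                dimnames = dimnames(cycles[[1L]]))
    structure(m, source_cycles = idx, cycles = stack, class = "agg")
  })
}

#' Build the Characteristic Gait Graph
#'
#' The Characteristic Gait Graph (CGG) is the elementwise average of the
#' AGGs of several healthy adults and serves as the standard gait
#' acceleration pattern that test subjects are compared against.
#'
#' @param aggs list of AGG matrices (one or more per subject).
#' @return an M x 6 matrix of class `cgg`.
#' @export
build_cgg <- function(aggs) {
  if (length(aggs) < 1) stop("need at least one AGG")
  dims <- vapply(aggs, function(a) paste(dim(a), collapse = "x"),
                 character(1L))
  if (length(unique(dims)) != 1)
    stop("AGGs have mismatched dimensions")
  cols <- lapply(aggs, colnames)
  if (length(unique(vapply(cols, paste, character(1L), collapse = ","))) != 1)
    stop("AGGs have mismatched channel sets")
  m <- Reduce(`+`, lapply(aggs, unclass)) / length(aggs)
  m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(aggs[[1L]]))
  structure(m, n_aggs = length(aggs), class = "cgg")
}

#' Inter-subject channel stability
#'
#' For each of the nine acceleration channels, computes the Pearson
#' correlation of the per-subject average gait waveform over all
#' unordered subject pairs, and selects the channels whose mean
#' correlation reaches the threshold. In healthy adults the six SI and AP
#' channels are stable across subjects while the low-amplitude ML
#' channels are not; the selected set defines the representative
#' channels.
#'
#' @param mean_gaits list (one per subject) of M x 9 matrices with the
#'   full channel set as column names.
#' @param threshold minimum mean pairwise correlation (default 0.75).
#' @return list with `summary` (data.frame: channel, mean_r, sd_r) and
#'   `selected` (character vector of channel names).
#' @export
channel_stability <- function(mean_gaits, threshold = 0.75) {
  if (length(mean_gaits) < 2) stop("need at least two subjects")
  chans <- colnames(mean_gaits[[1L]])
  pairs <- utils::combn(length(mean_gaits), 2L)
  stats_per_chan <- lapply(chans, function(ch) {
    rs <- apply(pairs, 2L, function(pr) {
      x <- mean_gaits[[pr[1L]]][, ch]
      y <- mean_gaits[[pr[2L]]][, ch]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        warning("constant channel ", ch, "; pair correlation set to 0")
        return(0)
      }
      stats::cor(x, y)
    })
    c(mean_r = mean(rs), sd_r = stats::sd(rs))
  })
  summary <- data.frame(
    channel = chans,
    mean_r = vapply(stats_per_chan, `[[`, numeric(1L), "mean_r"),
    sd_r = vapply(stats_per_chan, `[[`, numeric(1L), "sd_r"))
  list(summary = summary,
       selected = select_channels(stats::setNames(summary$mean_r,
                                                  summary$channel),
                                  threshold))
}

#' Select representative channels by mean inter-subject correlation
#'
#' @param mean_r named numeric vector of per-channel mean pairwise
#'   correlations.
#' @param threshold selection threshold (default 0.75).
#' @return character vector of selected channel names, in input order.
#' @export
select_channels <- function(mean_r, threshold = 0.75) {
  names(mean_r)[mean_r >= threshold]
}

#' Reference inter-subject channel correlations in healthy adults
#'
#' Published per-channel mean and standard deviation of pairwise
#' correlation of gait acceleration waveforms across a healthy adult
#' cohort. The six SI/AP channels are stable (mean r of 0.77-0.89) while
#' the medio-lateral channels are not (0.02-0.05), which motivates the
#' six representative channels used by this package.
#'
#' @return data.frame with columns `channel`, `mean_r`, `sd_r`.
#' @export
adult_channel_reference <- function() {
  data.frame(
    channel = ALL_CHANNELS,
    mean_r = c(0.79, 0.03, 0.78, 0.78, 0.05, 0.77, 0.89, 0.02, 0.88),
    sd_r = c(0.12, 0.68, 0.10, 0.12, 0.70, 0.11, 0.05, 0.61, 0.06))
}
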