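#' Estimate the step period from waist AP acceleration
#'
#' Walking is quasi-periodic at the step: the waist anterior-posterior
#' acceleration repeats with every foot contact. The dominant period is
#' taken from the first prominent positive peak of the biased, normalized
#' autocorrelation within the lag band 0.4-2.0 s.
#'
#' @param ap_w waist AP acceleration series.
#' @param sample_rate sampling frequency in Hz.
#' @param min_peak minimum normalized autocorrelation for a peak to count
#'   as periodic gait (default 0.2).
#' @return estimated step period in samples.
#' @export
estimate_step_period <- function(ap_w, sample_rate, min_peak = 0.2) {
  x <- ap_w - mean(ap_w)
  n <- length(x)
  lo <- max(2L, round(0.4 * sample_rate))
  hi <- min(n - 2L, round(2.0 * sample_rate))
  if (hi <= lo) stop("series too short to estimate a step period")
  # biased autocorrelation, normalized by lag 0
  a0 <- sum(x^2) / n
  if (a0 == 0) stop("no periodic gait detected")
  lags <- lo:hi
  ac <- vapply(lags, function(l)
    sum(x[1:(n - l)] * x[(1 + l):n]) / n / a0, numeric(1L))
  # local maxima within the band
  isw <- which(diff(sign(diff(ac))) < 0) + 1L
  isw <- isw[ac[isw] >= min_peak]
  if (length(isw) == 0) stop("no periodic gait detected")
  lags[isw[1L]]
}

#' Detect heel strikes as positive peaks of waist AP acceleration
#'
#' A heel strike produces a positive peak in the waist AP acceleration
#' (inverted-pendulum behaviour of the body's centre of mass). Peaks are
#' found by a sliding-window maximum whose window length is 0.75 of the
#' estimated step period; maxima must exceed `mean + 0.2 sd` of the
#' series, and detections closer than 0.3 step periods keep only the
#' higher peak.
#'
#' @param ap_w waist AP acceleration series.
#' @param step_period estimated step period in samples
#'   (see [estimate_step_period()]).
#' @param threshold_sd threshold above the mean, in standard deviations
#'   (default 0.2).
#' @param refractory_frac minimum event spacing as a fraction of the step
#'   period (default 0.3).
#' @return a list of class `heel_strikes` with `events` (sample indices)
#'   and `step_period`.
#' @export
detect_heel_strikes <- function(ap_w, step_period, threshold_sd = 0.2,
                                refractory_frac = 0.3) {
  if (step_period <= 0) stop("step_period must be positive")
  n <- length(ap_w)
  thr <- mean(ap_w) + threshold_sd * stats::sd(ap_w)
  half <- max(1L, floor(0.75 * step_period / 2))
  # window maxima must be local maxima, so scan only those candidates
  d <- diff(ap_w)
  cand <- which(c(d, -1) <= 0 & c(1, d) > 0)
  cand <- cand[ap_w[cand] > thr]
  peaks <- cand[vapply(cand, function(i)
    ap_w[i] == max(ap_w[max(1L, i - half):min(n, i + half)]),
    logical(1L))]
  # refractory rule: enforce minimum spacing, dropping the lower peak
  min_gap <- refractory_frac * step_period
  keep <- integer(0)
  for (p in peaks) {
    if (length(keep) == 0 || p - keep[length(keep)] >= min_gap) {
      keep <- c(keep, p)
    } else if (ap_w[p] > ap_w[keep[length(keep)]]) {
      keep[length(keep)] <- p
    }
  }
  if (length(keep) < 4) stop("too few steps")
  structure(list(events = keep, step_period = step_period),
            class = "heel_strikes")
}

#' Cut strides between alternate heel strikes
#'
#' Consecutive peaks are contacts of alternating feet, so a full stride
#' runs from one peak to the second-next. Strides are paired
#' non-overlapping (events 1-3, 3-5, ...), anchored at the first detected
#' event, keeping cycles statistically independent for the variance
#' ratio. Each cycle carries the six representative channel slices.
#'
#' @param events a `heel_strikes` object or integer vector of event
#'   sample indices.
#' @param channels n x 9 global acceleration matrix from
#'   [preprocess_recording()] (or any matrix containing the six
#'   representative channels by name).
#' @return list of `gait_cycle` objects, each with `start`, `end`
#'   (half-open span), `duration` and a duration x 6 `channels` matrix.
#' @export
cut_strides <- function(events, channels) {
  ev <- if (inherits(events, "heel_strikes")) events$events else events
  if (length(ev) < 4) stop("too few steps")
  starts <- ev[seq(1L, length(ev) - 2L, by = 2L)]
  ends <- ev[seq(3L, length(ev), by = 2L)]
  m <- min(length(starts), length(ends))
  lapply(seq_len(m), function(i) {
    span <- starts[i]:(ends[i] - 1L)
    structure(list(start = starts[i], end = ends[i],
                   duration = length(span),
                   channels = channels[span, REP_CHANNELS, drop = FALSE]),
              class = "gait_cycle")
  })
}

#' Prune unusable gait cycles
#'
#' Removes gait-initiation and termination transients (the first two and
#' last two cycles), then iteratively drops any cycle whose duration is
#' more than twice or less than half the mean duration of the remaining
#' cycles, until stable.
#'
#' @param cycles list of `gait_cycle` objects from [cut_strides()].
#' @param end_trim cycles dropped at each end (default 2).
#' @return the pruned list of cycles.
#' @export
prune_cycles <- function(cycles, end_trim = 2) {
  if (length(cycles) < 3) stop("insufficient clean cycles")
  if (length(cycles) > 2 * end_trim + 2)
    cycles <- cycles[(end_trim + 1L):(length(cycles) - end_trim)]
  repeat {
    d <- vapply(cycles, `[[`, numeric(1L), "duration")
    if (length(d) < 3) stop("insufficient clean cycles")
    bad <- which(vapply(seq_along(d), function(i) {
      m <- mean(d[-i])
      d[i] > 2 * m || d[i] < 0.5 * m
    }, logical(1L)))
    if (length(bad) == 0) break
    # remove the single worst offender, then re-evaluate
    dev <- abs(log(d[bad] / vapply(bad, function(i) mean(d[-i]),
                                   numeric(1L))))
    cycles <- cycles[-bad[which.max(dev)]]
  }
  cycles
}

#' Score detected heel strikes against reference events
#'
#' Greedy one-to-one matching of detected to reference events within a
#' sample tolerance. Sensitivity is matched over reference count;
#' positive predictive value (PPV) is matched over detected count.
#'
#' @param detected a `heel_strikes` object or integer vector.
#' @param reference sorted integer vector of reference event indices
#'   (e.g. from foot-switch contacts or the synthetic ground truth).
#' @param tolerance matching tolerance in samples (default 10, i.e.
#'   100 ms at 100 Hz).
#' @return list with `sensitivity`, `ppv`, `matched`, `missed`,
#'   `spurious`.
#' @export
evaluate_segmentation <- function(detected, reference, tolerance = 10) {
  det <- if (inherits(detected, "heel_strikes")) detected$events
         else detected
  used <- rep(FALSE, length(det))
  matched <- 0L
  for (r in reference) {
    gaps <- abs(det - r)
    gaps[used] <- Inf
    j <- which.min(gaps)
    if (length(j) == 1 && is.finite(gaps[j]) && gaps[j] <= tolerance) {
      used[j] <- TRUE
      matched <- matched + 1L
    }
  }
  list(sensitivity = if (length(reference)) matched / length(reference)
                     else NA_real_,
       ppv = if (length(det)) matched / length(det) else NA_real_,
       matched = matched,
       missed = length(reference) - matched,
       spurious = length(det) - matched)
}
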