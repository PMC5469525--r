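#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults
#' follow the method's stated constants: M = 100 phase points, a 50th
#' order FIR filter with 20 Hz cutoff, channel-selection threshold
#' r >= 0.75, four AGGs of three cycles each, distinguishing coefficient
#' gamma = 1 and equal feature weights of 0.2.
#'
#' @param M phase points per normalized cycle.
#' @param filter_order FIR low-pass order.
#' @param filter_cutoff low-pass cutoff in Hz.
#' @param channel_threshold channel-selection correlation threshold.
#' @param end_trim cycles dropped at each end of a walk.
#' @param n_aggs AGGs extracted per subject.
#' @param cycles_per_agg cycles averaged per AGG.
#' @param gamma grey distinguishing coefficient.
#' @param weights feature weights (sum to 1).
#' @param symmetry_band step-lag search band as fractions of M.
#' @param n_harmonics highest harmonic for the harmonic ratio.
#' @param h_cap harmonic-ratio cap when odd energy vanishes.
#' @param peak_threshold_sd heel-strike threshold above the mean, in sd.
#' @param refractory_frac minimum peak spacing in step periods.
#' @param match_tolerance segmentation-evaluation tolerance in samples.
#' @param center_channels mean-center normalized cycles.
#' @return a list of class `gait_config`.
#' @export
gait_config <- function(M = 100, filter_order = 50, filter_cutoff = 20,
                        channel_threshold = 0.75, end_trim = 2,
                        n_aggs = 4, cycles_per_agg = 3, gamma = 1,
                        weights = rep(0.2, 5),
                        symmetry_band = c(0.3, 0.7), n_harmonics = 20,
                        h_cap = 1e6, peak_threshold_sd = 0.2,
                        refractory_frac = 0.3, match_tolerance = 10,
                        center_channels = TRUE) {
  if (channel_threshold <= 0 || channel_threshold > 1)
    stop("channel_threshold must be in (0, 1]")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  structure(as.list(environment()), class = "gait_config")
}

#' Segment a preprocessed recording and build AGGs
#'
#' Runs segmentation (step-period estimation, heel-strike detection,
#' stride cutting, pruning), time-normalization and AGG construction on
#' one recording.
#'
#' @param rec an [imu_recording()] object.
#' @param config a [gait_config()].
#' @return list with `aggs`, `cycles` (normalized), `raw_cycles`,
#'   `events` (`heel_strikes`), `global` (n x 9 matrix),
#'   `step_period`.
#' @export
extract_aggs <- function(rec, config = gait_config()) {
  global <- preprocess_recording(rec, config)
  fs <- attr(global, "sample_rate")
  period <- estimate_step_period(global[, "AP-W"], fs)
  events <- detect_heel_strikes(global[, "AP-W"], period,
                                threshold_sd = config$peak_threshold_sd,
                                refractory_frac = config$refractory_frac)
  raw_cycles <- cut_strides(events, global)
  pruned <- prune_cycles(raw_cycles, end_trim = config$end_trim)
  cycles <- lapply(pruned, normalize_cycle, M = config$M,
                   center = config$center_channels)
  aggs <- build_aggs(cycles, n_graphs = config$n_aggs,
                     cycles_per_graph = config$cycles_per_agg)
  list(aggs = aggs, cycles = cycles, raw_cycles = pruned,
       events = events, global = global, step_period = period)
}

#' Extract the feature table of one recording
#'
#' Full single-subject pipeline: preprocessing, segmentation, AGG
#' construction and the five-feature vector of every AGG against the
#' reference CGG.
#'
#' @param rec an [imu_recording()] object.
#' @param cgg reference CGG matrix from [build_cgg()].
#' @param config a [gait_config()].
#' @param subject_id optional label attached to the rows.
#' @return data.frame with columns `subject_id`, `agg_index`,
#'   `P`, `V`, `N`, `H`, `S`.
#' @export
run_extract <- function(rec, cgg, config = gait_config(),
                        subject_id = NA_character_) {
  ex <- extract_aggs(rec, config)
  rows <- t(vapply(ex$aggs, function(a)
    gait_features(a, cgg, config = config), numeric(5L)))
  data.frame(subject_id = subject_id,
             agg_index = seq_len(nrow(rows)), rows,
             check.names = FALSE)
}

#' Per-subject average gait over all nine channels
#'
#' The average of the first three pruned, time-normalized gait cycles
#' over the full 3 x 3 channel set; this is the waveform compared across
#' subjects by [channel_stability()].
#'
#' @param rec an [imu_recording()] object.
#' @param config a [gait_config()].
#' @return M x 9 matrix.
#' @export
subject_mean_gait <- function(rec, config = gait_config()) {
  global <- preprocess_recording(rec, config)
  fs <- attr(global, "sample_rate")
  period <- estimate_step_period(global[, "AP-W"], fs)
  events <- detect_heel_strikes(global[, "AP-W"], period,
                                threshold_sd = config$peak_threshold_sd,
                                refractory_frac = config$refractory_frac)
  ev <- events$events
  starts <- ev[seq(1L, length(ev) - 2L, by = 2L)]
  ends <- ev[seq(3L, length(ev), by = 2L)]
  m <- min(length(starts), length(ends))
  cycles9 <- lapply(seq_len(m), function(i)
    structure(list(start = starts[i], end = ends[i],
                   duration = ends[i] - starts[i],
                   channels = global[starts[i]:(ends[i] - 1L), ,
                                     drop = FALSE]),
              class = "gait_cycle"))
  pruned <- prune_cycles(cycles9, end_trim = config$end_trim)
  norm <- lapply(pruned[1:3], normalize_cycle, M = config$M,
                 center = config$center_channels)
  m <- Reduce(`+`, lapply(norm, unclass)) / 3
  matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(norm[[1L]]))
}

#' Fit an assessment model from a cohort of recordings
#'
#' Convenience wrapper for the training phase: extracts AGGs from every
#' healthy recording, builds the CGG as the average of all their AGGs,
#' computes the feature table (four rows per subject) and fits the grey
#' relational model.
#'
#' @param recordings list of [imu_recording()] objects (healthy
#'   subjects).
#' @param config a [gait_config()].
#' @return list with `model` (a `gait_grm`), `cgg`, and `features`
#'   (the training feature table).
#' @export
fit_cohort_model <- function(recordings, config = gait_config()) {
  extracts <- lapply(recordings, extract_aggs, config = config)
  cgg <- build_cgg(unlist(lapply(extracts, `[[`, "aggs"),
                   recursive = FALSE))
  feats <- do.call(rbind, lapply(seq_along(extracts), function(i)
    t(vapply(extracts[[i]]$aggs, function(a)
      gait_features(a, cgg, config = config), numeric(5L)))))
  ids <- rep(seq_along(extracts),
             vapply(extracts, function(e) length(e$aggs), integer(1L)))
  model <- fit_gait_model(feats, gamma = config$gamma,
                          weights = config$weights, subject_ids = ids)
  list(model = model, cgg = cgg, features = feats)
}

#' Score one recording with a fitted model
#'
#' @param rec an [imu_recording()] object.
#' @param model a fitted `gait_grm`.
#' @param cgg the CGG the model's features were computed against.
#' @param config a [gait_config()].
#' @return a `gait_assessment` (see [predict.gait_grm()]).
#' @export
assess_recording <- function(rec, model, cgg, config = gait_config()) {
  feats <- run_extract(rec, cgg, config)
  predict(model, feats[, FEATURE_ORDER])
}
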