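# Synthetic gait recordings with known heel-strike ground truth.
#
# The stride template is an analytic harmonic construction fit to the
# morphology of healthy waist/thigh gait acceleration: it is not derived
# from recorded data. Pathology is injected at the waveform level
# (left/right asymmetry, band-limited tremor, cycle-to-cycle jitter) and
# claims ordinal, not clinical, meaning.

# periodic Gaussian bump centered at phase c with width s (phase units)
periodic_bump <- function(t, c, s) {
  d <- abs((t - c) %% 1)
  d <- pmin(d, 1 - d)
  exp(-0.5 * (d / s)^2)
}

template_fun <- list(
  # heel-strike peaks at 0% and 50%, loading valleys after each contact,
  # small fundamental so left and right contacts are distinguishable
  "AP-W" = function(t) 1.6 * periodic_bump(t, 0.00, 0.045) +
    1.6 * periodic_bump(t, 0.50, 0.045) -
    0.9 * periodic_bump(t, 0.20, 0.090) -
    0.9 * periodic_bump(t, 0.70, 0.090) + 0.22 * cos(2 * pi * t),
  # dominant foot-flat peaks near 6% and 55%, slow regions 25-40%/75-90%
  "SI-W" = function(t) 2.0 * periodic_bump(t, 0.06, 0.050) +
    2.0 * periodic_bump(t, 0.55, 0.050) +
    0.7 * periodic_bump(t, 0.15, 0.040) +
    0.7 * periodic_bump(t, 0.64, 0.040) -
    0.8 * periodic_bump(t, 0.33, 0.060) -
    0.8 * periodic_bump(t, 0.83, 0.060),
  # left-thigh support burst over 0-15%, echoed at half stride on the right
  "SI-L" = function(t) 1.5 * periodic_bump(t, 0.07, 0.050) +
    0.6 * periodic_bump(t, 0.57, 0.060) +
    0.3 * periodic_bump(t, 0.30, 0.100),
  "SI-R" = function(t) 1.5 * periodic_bump(t, 0.57, 0.050) +
    0.6 * periodic_bump(t, 0.07, 0.060) +
    0.3 * periodic_bump(t, 0.80, 0.100),
  # thigh AP: stance leg decelerates then swings (falls, then rises);
  # the right leg mirrors at half stride
  "AP-L" = function(t) 0.9 * cos(2 * pi * t) +
    0.15 * cos(4 * pi * t + 0.4),
  "AP-R" = function(t) -0.9 * cos(2 * pi * t) +
    0.15 * cos(4 * pi * t + 0.4),
  # medio-lateral sway is low-amplitude and, in real cohorts,
  # subject-specific; the deterministic part is deliberately small
  "ML-W" = function(t) 0.12 * sin(2 * pi * t),
  "ML-L" = function(t) 0.12 * sin(2 * pi * t + 0.9),
  "ML-R" = function(t) 0.12 * sin(2 * pi * t - 0.9))

#' Healthy single-stride acceleration template
#'
#' Analytic 9-channel waveform of one stride (phase 0 = left heel
#' strike) honoring the landmark structure of healthy gait: waist AP
#' peaks at 0\% and ~50\% (the two heel strikes), waist SI foot-flat
#' peaks near 6\% and 55\% with slow regions at 25-40\% and 75-90\%,
#' left-thigh SI activity over 0-15\% mirrored by the right thigh at
#' half stride, and antisymmetric thigh AP trends. Units are m/s^2
#' about a zero baseline (gravity is added by [generate_recording()]).
#'
#' @param M samples per stride (default 100).
#' @return M x 9 matrix, columns `SI-L, ML-L, AP-L, SI-R, ML-R, AP-R,
#'   SI-W, ML-W, AP-W`.
#' @export
healthy_template <- function(M = 100) {
  if (M < 20) stop("M must be at least 20")
  t <- (seq_len(M) - 1) / M
  out <- vapply(ALL_CHANNELS, function(ch) template_fun[[ch]](t),
                numeric(M))
  colnames(out) <- ALL_CHANNELS
  out
}

#' Synthetic gait profile
#'
#' Parameter bundle for [generate_recording()]. The healthy default
#' stride frequency of 0.93 strides/s matches self-selected adult
#' walking; pathology parameters are relative magnitudes: `asymmetry`
#' scales a smooth left/right amplitude imbalance (factor 1 +/- a/2) and
#' delays the right heel strike by `0.1 * a` of the stride; `tremor_amp`
#' sets band-limited 6-15 Hz ripple relative to each channel's standard
#' deviation; `cycle_noise` sets both per-cycle duration jitter and
#' smooth per-cycle waveform perturbations.
#'
#' @param stride_frequency strides per second (default 0.93).
#' @param n_strides strides walked (default 30).
#' @param asymmetry left/right imbalance in `[0, 1]` (default 0).
#' @param tremor_amp relative tremor amplitude (default 0).
#' @param cycle_noise relative cycle-to-cycle variability (default 0).
#' @param seed integer RNG seed (default 1).
#' @param sample_rate sampling frequency in Hz (default 100).
#' @return a list of class `gait_profile`.
#' @export
gait_profile <- function(stride_frequency = 0.93, n_strides = 30,
                         asymmetry = 0, tremor_amp = 0, cycle_noise = 0,
                         seed = 1L, sample_rate = 100) {
  if (stride_frequency <= 0) stop("stride_frequency must be positive")
  if (any(c(asymmetry, tremor_amp, cycle_noise) < 0))
    stop("pathology parameters must be non-negative")
  structure(list(stride_frequency = stride_frequency,
                 n_strides = n_strides, asymmetry = asymmetry,
                 tremor_amp = tremor_amp, cycle_noise = cycle_noise,
                 seed = as.integer(seed), sample_rate = sample_rate),
            class = "gait_profile")
}

# fixed sensor mountings (sensor -> global quaternions); deliberately
# tilted so the preprocessing frame transform is exercised
sensor_orientations <- function() {
  tilt <- function(pitch_deg, roll_deg) {
    p <- pitch_deg * pi / 180
    r <- roll_deg * pi / 180
    qp <- c(cos(p / 2), 0, 0, sin(p / 2) * 1)   # about ML (z)
    qr <- c(cos(r / 2), sin(r / 2) * 1, 0, 0)   # about AP (x)
    quat_normalize(quat_multiply(qp, qr))
  }
  list(waist = tilt(8, 2), thigh_left = tilt(-12, -3),
       thigh_right = tilt(15, 4))
}

#' Generate a synthetic IMU gait recording
#'
#' Tiles the healthy stride template `n_strides` times with per-cycle
#' duration jitter and waveform perturbations, applies the profile's
#' asymmetry (amplitude modulation plus right-step timing shift) and
#' band-limited 6-15 Hz tremor, adds subject-specific medio-lateral
#' sway, gravity on the SI channels and a quiet-standing lead-in, and
#' finally rotates each sensor's signal into a tilted sensor frame with
#' known orientation, so that preprocessing recovers the global-frame
#' signal exactly. Half-stride amplitude ramps before the first and
#' after the last heel strike keep the walking segment continuous.
#'
#' @param profile a [gait_profile()].
#' @return list of class `synthetic_recording` with `recording` (an
#'   [imu_recording()]), `events` (data.frame `sample_index`, `foot`
#'   with `2 * n_strides` ground-truth heel strikes) and `profile`.
#' @export
generate_recording <- function(profile) {
  stopifnot(inherits(profile, "gait_profile"))
  set.seed(profile$seed)
  fs <- profile$sample_rate
  L0 <- round(fs / profile$stride_frequency)
  a <- profile$asymmetry
  delta <- 0.1 * a
  n_strides <- profile$n_strides

  # per-stride durations with truncated-normal jitter
  eps <- pmax(pmin(stats::rnorm(n_strides), 2), -2)
  L <- round(L0 * (1 + 0.3 * profile$cycle_noise * eps))

  # right heel strike occurs at warped phase 0.5 + delta; the template
  # is evaluated at the inverse warp so its own landmarks shift
  warp <- function(t) ifelse(t <= 0.5 + delta,
                             t * 0.5 / (0.5 + delta),
                             0.5 + (t - 0.5 - delta) * 0.5 / (0.5 - delta))
  tmpl_sd <- vapply(ALL_CHANNELS, function(ch)
    stats::sd(template_fun[[ch]]((0:999) / 1000)), numeric(1L))

  eval_stride <- function(Ls) {
    t <- (seq_len(Ls) - 1) / Ls
    tau <- warp(t)
    amp <- 1 + (a / 2) * cos(2 * pi * tau)
    block <- vapply(ALL_CHANNELS, function(ch)
      template_fun[[ch]](tau) * amp, numeric(Ls))
    # smooth per-cycle waveform jitter, relative to channel amplitude
    if (profile$cycle_noise > 0) {
      for (j in seq_along(ALL_CHANNELS)) {
        b <- stats::rnorm(2L)
        ph <- stats::runif(2L, 0, 2 * pi)
        block[, j] <- block[, j] + profile$cycle_noise *
          tmpl_sd[j] * (b[1L] * sin(2 * pi * t + ph[1L]) +
                          b[2L] * sin(4 * pi * t + ph[2L])) / sqrt(2)
      }
    }
    block
  }

  strides <- lapply(L, eval_stride)

  # half-stride lead-in/out with linear amplitude ramps for continuity
  lead_n <- ceiling(L0 / 2)
  t_lead <- 0.5 + (seq_len(lead_n) - 1) / L0
  lead <- vapply(ALL_CHANNELS, function(ch)
    template_fun[[ch]](warp(t_lead)) *
      seq(0, 1, length.out = lead_n + 1L)[-(lead_n + 1L)], numeric(lead_n))
  walk <- do.call(rbind, c(list(lead), strides))
  colnames(walk) <- ALL_CHANNELS

  # ground-truth heel strikes (walking-segment sample indices)
  starts <- lead_n + 1L + c(0L, cumsum(L[-n_strides]))
  left_hs <- starts
  right_hs <- starts + round((0.5 + delta) * L)

  # gait termination: the walk ends in deceleration right after the last
  # recorded contact, so no closing impact peak is generated. Cosine
  # taper to zero over a quarter stride after the final right strike.
  cut <- min(nrow(walk), right_hs[n_strides] + round(0.25 * L[n_strides]))
  walk <- walk[seq_len(cut), , drop = FALSE]
  tn <- cut - right_hs[n_strides]
  if (tn > 0) {
    taper <- (1 + cos(pi * seq_len(tn) / tn)) / 2
    idx <- (right_hs[n_strides] + 1L):cut
    walk[idx, ] <- walk[idx, ] * taper
  }
  n_walk <- nrow(walk)

  # band-limited tremor, coherent within the walk, per channel
  if (profile$tremor_amp > 0) {
    tt <- (seq_len(n_walk) - 1) / fs
    for (j in seq_along(ALL_CHANNELS)) {
      f <- stats::runif(6L, 6, 15)
      ph <- stats::runif(6L, 0, 2 * pi)
      cw <- stats::rnorm(6L)
      trem <- colSums(cw * t(sapply(seq_len(6L), function(k)
        sin(2 * pi * f[k] * tt + ph[k]))))
      trem <- trem / stats::sd(trem)
      walk[, j] <- walk[, j] + profile$tremor_amp * tmpl_sd[j] * trem
    }
  }

  # subject-specific medio-lateral sway dominates the ML channels
  tt <- (seq_len(n_walk) - 1) / fs
  for (ch in c("ML-L", "ML-R", "ML-W")) {
    f <- stats::runif(3L, 0.8, 3)
    ph <- stats::runif(3L, 0, 2 * pi)
    cw <- stats::rnorm(3L)
    sway <- colSums(cw * t(sapply(1:3, function(k)
      sin(2 * pi * f[k] * tt + ph[k]))))
    walk[, ch] <- walk[, ch] + 0.35 * sway / stats::sd(sway)
  }

  # assemble full recording: 6 s static, walk, 1 s trailing static
  n_static <- 6L * fs
  n_trail <- 1L * fs
  n <- n_static + n_walk + n_trail
  global <- matrix(0, n, 9L, dimnames = list(NULL, ALL_CHANNELS))
  global[(n_static + 1L):(n_static + n_walk), ] <- walk
  global[, c("SI-L", "SI-R", "SI-W")] <-
    global[, c("SI-L", "SI-R", "SI-W")] + GRAVITY

  # rotate into tilted sensor frames with zero angular velocity
  quats <- sensor_orientations()
  sensors <- list()
  for (p in names(quats)) {
    side <- GAIT_PLACEMENTS[[p]]
    glob_p <- global[, paste0(GAIT_AXES, "-", side)]
    Rm <- quat_to_matrix(quats[[p]])
    sensors[[p]] <- list(acc = glob_p %*% Rm,   # == t(R^T %*% t(glob))
                         gyro = matrix(0, n, 3L),
                         forward_axis = as.numeric(t(Rm) %*% c(1, 0, 0)))
  }

  rec <- imu_recording(sensors, sample_rate = fs,
                       static_window = c(round(0.5 * fs) + 1L, 5L * fs))
  events <- data.frame(
    sample_index = n_static + as.integer(rbind(left_hs, right_hs)),
    foot = rep(c("L", "R"), n_strides))
  structure(list(recording = rec, events = events, profile = profile),
            class = "synthetic_recording")
}

# severity ladder: ordinal parameter ranges, documented engineering
# choices (stride frequencies follow the healthy-to-severe slowing seen
# in clinical cohorts)
severity_ranges <- list(
  healthy = list(sf = c(0.85, 1.00), asym = c(0.00, 0.05),
                 tremor = c(0.00, 0.04), cn = c(0.01, 0.05)),
  mild = list(sf = c(0.80, 0.95), asym = c(0.08, 0.15),
              tremor = c(0.06, 0.12), cn = c(0.06, 0.10)),
  moderate = list(sf = c(0.70, 0.85), asym = c(0.18, 0.30),
                  tremor = c(0.15, 0.25), cn = c(0.12, 0.18)),
  severe = list(sf = c(0.60, 0.72), asym = c(0.35, 0.50),
                tremor = c(0.28, 0.40), cn = c(0.20, 0.28)))

#' Generate a cohort of synthetic subjects
#'
#' Draws per-subject profiles from severity-specific parameter ranges
#' (healthy, mild, moderate, severe) and generates one recording per
#' subject. The ladder claims only ordinal meaning: each level has more
#' asymmetry, tremor and cycle variability, and a lower stride
#' frequency, than the previous one.
#'
#' @param n_subjects subjects to generate.
#' @param severity one of `"healthy"`, `"mild"`, `"moderate"`,
#'   `"severe"`.
#' @param seed integer RNG seed.
#' @param n_strides strides per subject (default 30).
#' @return list of `synthetic_recording` objects.
#' @export
generate_cohort <- function(n_subjects, severity = "healthy", seed = 1L,
                            n_strides = 30) {
  rg <- severity_ranges[[match.arg(severity, names(severity_ranges))]]
  set.seed(seed)
  params <- data.frame(
    sf = stats::runif(n_subjects, rg$sf[1L], rg$sf[2L]),
    asym = stats::runif(n_subjects, rg$asym[1L], rg$asym[2L]),
    tremor = stats::runif(n_subjects, rg$tremor[1L], rg$tremor[2L]),
    cn = stats::runif(n_subjects, rg$cn[1L], rg$cn[2L]),
    seed = sample.int(.Machine$integer.max - 1L, n_subjects))
  lapply(seq_len(n_subjects), function(i)
    generate_recording(gait_profile(
      stride_frequency = params$sf[i], n_strides = n_strides,
      asymmetry = params$asym[i], tremor_amp = params$tremor[i],
      cycle_noise = params$cn[i], seed = params$seed[i])))
}

#' Write ground-truth heel-strike events to CSV
#'
#' @param events data.frame with `sample_index` and `foot` columns.
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Read heel-strike events from CSV
#'
#' @param path CSV with columns `sample_index`, `foot`.
#' @return data.frame.
#' @export
read_events <- function(path) {
  utils::read.csv(path, colClasses = c(sample_index = "integer",
                                       foot = "character"))
}
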