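## Synthetic single-lead ECG with semi-Markov class dynamics. Each class
## (stress level or sleep stage) has its own mean heart rate and R-wave
## amplitude; during a configurable window before every state switch the
## heart rate and amplitude drift linearly toward the next state's values,
## which makes future class labels partially predictable from current
## beats - the structure the multi-horizon forecaster assumes.

#' Configuration for the synthetic ECG generator
#'
#' Defaults emulate a three-class driving study. The `stress` profile uses
#' mean heart rates of 70/85/100 bpm for low/medium/high stress and a
#' 0.425/0.404/0.170 class mix; the `drowsiness` profile uses 72/62/55 bpm
#' for awake/stage-1/stage-2 and a 0.580/0.267/0.153 mix. Unless given
#' explicitly, the zero-diagonal transition matrix draws the next state
#' proportionally to the target mix (`P[i,j] = m_j / (1 - m_i)`), whose
#' embedded stationary distribution is `m_i (1 - m_i)` up to scale, and the
#' per-class mean dwell times are proportional to `1 / (1 - m_i)` (scaled
#' to average `dwell_mean_s`) so the stationary time fraction of class `i`
#' is exactly `m_i`.
#'
#' @param profile `"stress"` or `"drowsiness"` (sets per-class defaults).
#' @param duration_s Record length in seconds.
#' @param fs Sampling rate in Hz (> 60).
#' @param class_hr_bpm Length-3 mean heart rates per class.
#' @param hr_jitter_cv Coefficient of variation of beat-to-beat intervals.
#' @param class_amp Length-3 R-amplitude scalars per class.
#' @param dwell_mean_s Mean state dwell time in seconds (scalar, spread
#'   across classes as above) or an explicit length-3 vector.
#' @param transition_matrix Optional 3 x 3 row-stochastic matrix with a
#'   zero diagonal.
#' @param pre_transition_drift_s Seconds of linear HR/amplitude drift
#'   before each switch (0 disables predictive drift).
#' @param noise_sd White-noise standard deviation (signal units; the R
#'   template peaks near `class_amp`).
#' @param class_mix Target stationary label proportions (length 3, sums
#'   to 1).
#' @param dc_offset Constant offset added to the signal.
#' @param fixed_dwell Use deterministic dwell times equal to the means
#'   (for exactly reproducible layouts) instead of exponential ones.
#' @param seed Generator seed.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(profile = c("stress", "drowsiness"),
                             duration_s = 600, fs = 250,
                             class_hr_bpm = NULL, hr_jitter_cv = 0.03,
                             class_amp = NULL, dwell_mean_s = 40,
                             transition_matrix = NULL,
                             pre_transition_drift_s = 10, noise_sd = 0.05,
                             class_mix = NULL, dc_offset = 0.2,
                             fixed_dwell = FALSE, seed = 1L) {
  profile <- match.arg(profile)
  if (is.null(class_hr_bpm))
    class_hr_bpm <- if (profile == "stress") c(70, 85, 100) else c(72, 62, 55)
  if (is.null(class_amp))
    class_amp <- if (profile == "stress") c(1.0, 1.1, 1.25) else c(1.0, 0.9, 0.8)
  if (is.null(class_mix))
    class_mix <- if (profile == "stress") c(40, 38, 16) / 94 else
      c(76, 35, 20) / 131
  class_mix <- class_mix / sum(class_mix)
  if (fs <= 60) stop("fs must exceed 60 Hz")
  if (length(dwell_mean_s) == 1L) {
    raw <- 1 / (1 - class_mix)
    dwell_mean_s <- dwell_mean_s * raw / mean(raw)
  }
  if (any(dwell_mean_s <= 0)) stop("dwell means must be positive")
  if (is.null(transition_matrix)) {
    transition_matrix <- outer(1 - class_mix, class_mix,
                               function(d, m) m) / (1 - class_mix)
    diag(transition_matrix) <- 0
    transition_matrix <- transition_matrix / rowSums(transition_matrix)
  }
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-9) ||
      any(diag(transition_matrix) != 0))
    stop("transition_matrix must be row-stochastic with a zero diagonal")
  structure(list(profile = profile, duration_s = duration_s, fs = fs,
                 class_hr_bpm = class_hr_bpm, hr_jitter_cv = hr_jitter_cv,
                 class_amp = class_amp, dwell_mean_s = dwell_mean_s,
                 transition_matrix = transition_matrix,
                 pre_transition_drift_s = pre_transition_drift_s,
                 noise_sd = noise_sd, class_mix = class_mix,
                 dc_offset = dc_offset, fixed_dwell = fixed_dwell,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# Ricker (second-derivative-of-Gaussian) QRS template: sharp central
# maximum at the R time with symmetric negative side lobes, main lobe
# about 40 ms wide, spectral energy centered inside the 10-30 Hz band.
ricker <- function(t, sigma = 0.011) {
  u <- (t / sigma)^2
  (1 - u) * exp(-u / 2)
}

gaussian_bump <- function(t, sigma) exp(-(t / sigma)^2 / 2)

#' Generate one labeled synthetic ECG record
#'
#' Samples a semi-Markov class path (exponential or fixed dwell, jumps per
#' the transition matrix), places beats at intervals `60 / HR` with
#' multiplicative log-normal-free Gaussian jitter, renders each beat as a
#' class-scaled Ricker QRS plus small P and T bumps, adds the DC offset
#' and white noise, and attaches the state path as the label track.
#' During the `pre_transition_drift_s` window before each switch, heart
#' rate and amplitude interpolate linearly toward the next state.
#'
#' @param cfg A [generator_config()].
#' @param record_id Record identifier.
#' @return List with `record` (an [ecg_record()]) and `truth` (list:
#'   `r_peaks_s`, `beat_class`, `state_path` data frame).
#' @export
generate_record <- function(cfg, record_id = sprintf("sim%03d", cfg$seed)) {
  stopifnot(inherits(cfg, "generator_config"))
  old_seed <- sub_seed(cfg$seed, 601L)
  on.exit(restore_seed(old_seed))
  dur <- cfg$duration_s
  ## -- semi-Markov state path --
  st <- sample.int(3L, 1L, prob = cfg$class_mix) - 1L
  t0 <- 0
  path <- list()
  while (t0 < dur) {
    dwell <- if (cfg$fixed_dwell) cfg$dwell_mean_s[st + 1L] else
      stats::rexp(1L, rate = 1 / cfg$dwell_mean_s[st + 1L])
    dwell <- max(dwell, 1)
    nxt <- sample.int(3L, 1L, prob = cfg$transition_matrix[st + 1L, ]) - 1L
    path[[length(path) + 1L]] <- data.frame(
      start_s = t0, end_s = min(t0 + dwell, dur), cls = st, next_cls = nxt)
    t0 <- t0 + dwell
    st <- nxt
  }
  path <- do.call(rbind, path)
  ## per-time HR/amplitude with pre-transition drift
  state_param <- function(t) {
    i <- findInterval(t, path$start_s)
    row <- path[i, ]
    hr <- cfg$class_hr_bpm[row$cls + 1L]
    amp <- cfg$class_amp[row$cls + 1L]
    drift <- cfg$pre_transition_drift_s
    if (drift > 0 && row$end_s < dur && t > row$end_s - drift) {
      frac <- (t - (row$end_s - drift)) / drift
      hr <- hr + frac * (cfg$class_hr_bpm[row$next_cls + 1L] - hr)
      amp <- amp + frac * (cfg$class_amp[row$next_cls + 1L] - amp)
    }
    list(hr = unname(hr), amp = unname(amp), cls = row$cls)
  }
  ## -- beat placement --
  r_times <- numeric(0); r_amp <- numeric(0); r_cls <- integer(0)
  t <- 0.3
  while (t < dur - 0.3) {
    sp <- state_param(t)
    r_times <- c(r_times, t)
    r_amp <- c(r_amp, sp$amp)
    r_cls <- c(r_cls, as.integer(sp$cls))
    jit <- if (cfg$hr_jitter_cv > 0)
      max(1 + stats::rnorm(1L, 0, cfg$hr_jitter_cv), 0.5) else 1
    t <- t + (60 / sp$hr) * jit
  }
  ## -- signal synthesis --
  n <- as.integer(round(dur * cfg$fs))
  x <- rep(cfg$dc_offset, n)
  add_wave <- function(x, center_s, amp, sigma, shape) {
    half <- 4 * sigma
    lo <- max(1L, as.integer(floor((center_s - half) * cfg$fs)) + 1L)
    hi <- min(n, as.integer(ceiling((center_s + half) * cfg$fs)) + 1L)
    if (lo > hi) return(x)
    tt <- ((lo:hi) - 1L) / cfg$fs - center_s
    x[lo:hi] <- x[lo:hi] + amp * shape(tt, sigma)
    x
  }
  for (i in seq_along(r_times)) {
    x <- add_wave(x, r_times[i], r_amp[i], 0.011, ricker)
    x <- add_wave(x, r_times[i] - 0.16, 0.15 * r_amp[i], 0.025, gaussian_bump)
    x <- add_wave(x, r_times[i] + 0.25, 0.25 * r_amp[i], 0.04, gaussian_bump)
  }
  if (cfg$noise_sd > 0) x <- x + stats::rnorm(n, 0, cfg$noise_sd)
  labels <- path[c("start_s", "end_s", "cls")]
  rec <- ecg_record(record_id, cfg$fs, x, labels)
  list(record = rec,
       truth = list(r_peaks_s = r_times, beat_class = r_cls,
                    state_path = path))
}

#' Generate a feature-ready synthetic corpus
#'
#' Generates `n_records` records (seeds `cfg$seed, cfg$seed + 1, ...`),
#' runs R-peak detection, beat segmentation and featurization on each, and
#' returns the pooled [feature_set()] together with a manifest recording
#' the per-record seeds, ground-truth R counts and detector scores.
#'
#' @param cfg A [generator_config()] (its seed is the base seed).
#' @param n_records Number of records (>= 1).
#' @param horizons Look-ahead seconds for the labels.
#' @param L Standardized beat length.
#' @param use_truth_peaks Skip the detector and segment on the generator's
#'   true R times (isolates downstream stages from detector errors).
#' @return List with `features` (a [feature_set()]), `manifest` (data
#'   frame), `records` and `truths` (lists).
#' @export
generate_dataset <- function(cfg, n_records, horizons = 1:60, L = 100L,
                             use_truth_peaks = FALSE) {
  stopifnot(n_records >= 1L)
  sets <- list(); manifest <- list(); records <- list(); truths <- list()
  for (i in seq_len(n_records)) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i - 1L
    gen <- generate_record(cfg_i, record_id = sprintf("sim%03d", cfg_i$seed))
    peaks <- if (use_truth_peaks) {
      structure(list(record_id = gen$record$record_id,
                     peaks_s = gen$truth$r_peaks_s), class = "r_peak_list")
    } else detect_r_peaks(gen$record)
    score <- score_r_detection(peaks$peaks_s, gen$truth$r_peaks_s)
    fs_i <- if (length(peaks$peaks_s) >= 2L) {
      beats <- segment_beats(gen$record, peaks, L = L)
      build_samples(beats, gen$record, horizons = horizons, L = L)
    } else {
      feature_set(matrix(numeric(0), 0L, 2L * (2L * L - 1L)),
                  matrix(integer(0), 0L, length(horizons)), horizons, L,
                  character(0), numeric(0))
    }
    sets[[i]] <- fs_i
    records[[i]] <- gen$record
    truths[[i]] <- gen$truth
    manifest[[i]] <- data.frame(
      record_id = gen$record$record_id, seed = cfg_i$seed,
      n_true_peaks = length(gen$truth$r_peaks_s),
      n_detected = length(peaks$peaks_s),
      sensitivity = score$sensitivity, ppv = score$ppv,
      n_samples = nrow(fs_i$features))
  }
  features <- bind_feature_sets(sets)
  features$seed <- cfg$seed
  list(features = features, manifest = do.call(rbind, manifest),
       records = records, truths = truths)
}

#' Achieved class proportions of a label track
#'
#' Time-weighted fraction of the record spent in each class.
#'
#' @param record An [ecg_record()] (or label-interval data frame).
#' @return Length-3 numeric vector summing to 1.
#' @export
label_proportions <- function(record) {
  labels <- if (inherits(record, "ecg_record")) record$labels else record
  dur <- labels$end_s - labels$start_s
  vapply(0:2, function(cl) sum(dur[labels$cls == cl]), numeric(1)) / sum(dur)
}
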