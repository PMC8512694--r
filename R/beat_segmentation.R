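#' Remove the DC offset from a signal
#'
#' Subtracts the arithmetic mean so the output has zero mean.
#'
#' @param x Nonempty numeric vector.
#' @return Zero-mean vector of the same length.
#' @export
remove_dc <- function(x) {
  if (length(x) == 0L) stop("empty signal")
  x - mean(x)
}

#' Zero-phase QRS bandpass filter
#'
#' 4th-order Butterworth bandpass over the QRS energy band (10-30 Hz by
#' default), applied forward-backward (`signal::filtfilt`) so peaks are not
#' displaced. The sampling rate must place the upper band edge below
#' Nyquist (`fs > 60` Hz for the default band).
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param band_hz Length-2 passband in Hz.
#' @param order Butterworth order (applied twice by filtfilt).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_qrs <- function(x, fs, band_hz = c(10, 30), order = 4L) {
  if (fs <= 2 * max(band_hz))
    stop(sprintf("fs = %g Hz too low for a %g-%g Hz passband", fs,
                 band_hz[1], band_hz[2]))
  if (length(x) == 0L) return(numeric(0))
  bf <- signal::butter(order, band_hz / (fs / 2), type = "pass")
  # filtfilt needs a few filter lengths of signal; pad-reflect short inputs
  as.numeric(signal::filtfilt(bf, x))
}

#' Five-point derivative filter
#'
#' Pan-Tompkins-style slope amplifier: kernel `(fs/8) * [-1,-2,0,2,1]`
#' (centered), which approximates the first derivative and emphasizes the
#' steep Q-R and R-S limbs of the QRS complex. Edges are zero-padded.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz (scales the derivative to units/second).
#' @return Differentiated signal, same length.
#' @export
derivative_filter <- function(x, fs = 1) {
  n <- length(x)
  if (n == 0L) stop("empty signal")
  if (n < 5L) return(rep(0, n))
  xp <- c(0, 0, x, 0, 0)
  i <- seq_len(n) + 2L
  (fs / 8) * (-xp[i - 2L] - 2 * xp[i - 1L] + 2 * xp[i + 1L] + xp[i + 2L])
}

#' Pointwise squaring
#'
#' @param x Numeric signal.
#' @return `x^2`, elementwise nonnegative.
#' @export
squaring <- function(x) x^2

#' Centered moving-window integration
#'
#' Moving average over a window of `round(width_s * fs)` samples (at least
#' 1), centered on each sample; edges use zero padding outside the signal.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param width_s Window width in seconds (> 0).
#' @return Integrated signal, same length.
#' @export
moving_window_integrate <- function(x, fs, width_s = 0.15) {
  if (width_s <= 0) stop("width_s must be > 0")
  n <- length(x)
  w <- max(1L, as.integer(round(width_s * fs)))
  if (w > n) stop("integration window longer than signal")
  half_l <- (w - 1L) %/% 2L
  half_r <- w - 1L - half_l
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_l, 1L)
  hi <- pmin(seq_len(n) + half_r, n)
  (cs[hi + 1L] - cs[lo]) / w
}

#' Detect R-wave times in an ECG record
#'
#' Runs the fixed preprocessing chain - DC removal, 10-30 Hz zero-phase
#' bandpass, derivative, squaring, moving-window integration - then an
#' adaptive dual-threshold peak search on the integrated signal (running
#' signal/noise level estimates, threshold = noise + `threshold_frac` *
#' (signal - noise), refractory period). Each detection is refined to the
#' local maximum of the bandpassed signal within +/-50 ms, which localizes
#' the R wave itself rather than the integrator hump.
#'
#' @param record An [ecg_record()] of duration >= 2 s.
#' @param integration_window_s Integrator width (s).
#' @param refractory_s Minimum spacing between detections (s).
#' @param threshold_frac Fraction of the signal-noise gap added to the noise
#'   level to form the detection threshold.
#' @param band_hz,order Bandpass settings, see [bandpass_qrs()].
#' @return List of class `r_peak_list` with `record_id` and `peaks_s`
#'   (strictly increasing times in seconds; empty when nothing is found).
#' @export
detect_r_peaks <- function(record, integration_window_s = 0.15,
                           refractory_s = 0.2, threshold_frac = 0.25,
                           band_hz = c(10, 30), order = 4L) {
  stopifnot(inherits(record, "ecg_record"))
  fs <- record$fs
  if (duration(record) < 2) stop("record shorter than 2 s")
  x <- remove_dc(record$samples)
  if (stats::sd(x) < 1e-12) {   # flat line: nothing to detect
    return(structure(list(record_id = record$record_id, peaks_s = numeric(0)),
                     class = "r_peak_list"))
  }
  bp <- bandpass_qrs(x, fs, band_hz = band_hz, order = order)
  integ <- moving_window_integrate(squaring(derivative_filter(bp, fs)),
                                   fs, integration_window_s)
  # a second short average stabilizes the hump maxima against noise wiggle
  integ <- moving_window_integrate(integ, fs, integration_window_s / 2)
  n <- length(integ)
  refr <- as.integer(round(refractory_s * fs))
  # local maxima of the integrated signal
  is_pk <- c(FALSE, diff(sign(diff(integ))) < 0, FALSE)
  cand <- which(is_pk)
  if (!length(cand))
    return(structure(list(record_id = record$record_id, peaks_s = numeric(0)),
                     class = "r_peak_list"))
  # adaptive dual-threshold scan (Pan-Tompkins running estimates)
  init <- integ[seq_len(min(n, as.integer(2 * fs)))]
  spk <- max(init)
  npk <- mean(init)
  peaks <- integer(0)
  last <- -Inf
  for (i in cand) {
    thr <- npk + threshold_frac * (spk - npk)
    v <- integ[i]
    if (v >= thr && (i - last) > refr) {
      peaks <- c(peaks, i)
      spk <- 0.125 * v + 0.875 * spk
      last <- i
    } else {
      npk <- 0.125 * v + 0.875 * npk
    }
  }
  if (!length(peaks))
    return(structure(list(record_id = record$record_id, peaks_s = numeric(0)),
                     class = "r_peak_list"))
  # refine each detection to the bandpassed local maximum within +/-50 ms
  half <- as.integer(round(0.05 * fs))
  refined <- vapply(peaks, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(bp[lo:hi]) - 1L
  }, integer(1))
  refined <- sort(unique(refined))
  # enforce the refractory spacing after refinement
  keep <- logical(length(refined))
  last_t <- -Inf
  for (j in seq_along(refined)) {
    if ((refined[j] - last_t) > refr) {
      keep[j] <- TRUE
      last_t <- refined[j]
    }
  }
  structure(list(record_id = record$record_id,
                 peaks_s = (refined[keep] - 1L) / fs),
            class = "r_peak_list")
}

#' @export
print.r_peak_list <- function(x, ...) {
  cat(sprintf("<r_peak_list '%s': %d peak(s)>\n", x$record_id,
              length(x$peaks_s)))
  invisible(x)
}

#' Cut a record into standardized R-to-R beats
#'
#' A beat is the signal between two consecutive R waves, `[R_i, R_{i+1})`.
#' Each raw slice is standardized to length `L`: it is resampled onto a
#' fixed-rate grid (`grid_hz`, default 100 Hz) by linear interpolation,
#' then right-padded with zeros when shorter than `L` or tail-truncated
#' when longer. With the defaults a typical 0.6-1.0 s beat occupies 60-100
#' samples, so the zero-pad tail encodes the R-R interval. Optionally each
#' beat is amplitude z-scored (mean 0, unit variance, guard epsilon) so the
#' downstream convolution/cross-correlation features are scale-invariant
#' across recordings.
#'
#' @param record An [ecg_record()].
#' @param peaks An `r_peak_list` from [detect_r_peaks()] (>= 2 peaks).
#' @param L Standardized beat length (default 100).
#' @param grid_hz Resampling rate before padding/truncation.
#' @param zscore Z-score each beat's amplitudes (default `TRUE`).
#' @return List of `beat` objects (fields `record_id`, `r_start_s`,
#'   `r_end_s`, `samples` of length `L`); `length(peaks) - 1` beats.
#' @export
segment_beats <- function(record, peaks, L = 100L, grid_hz = 100,
                          zscore = TRUE) {
  stopifnot(inherits(record, "ecg_record"))
  pk <- peaks$peaks_s
  if (length(pk) < 2L) stop("need at least 2 R peaks to form a beat")
  fs <- record$fs
  t_all <- (seq_along(record$samples) - 1L) / fs
  lapply(seq_len(length(pk) - 1L), function(i) {
    t0 <- pk[i]; t1 <- pk[i + 1L]
    n_grid <- max(2L, as.integer(floor((t1 - t0) * grid_hz)))
    tg <- t0 + (seq_len(n_grid) - 1L) / grid_hz
    y <- stats::approx(t_all, record$samples, xout = tg, rule = 2)$y
    if (zscore) {
      y <- (y - mean(y)) / (stats::sd(y) + 1e-8)
    }
    s <- if (n_grid >= L) y[seq_len(L)] else c(y, rep(0, L - n_grid))
    structure(list(record_id = record$record_id, r_start_s = t0,
                   r_end_s = t1, samples = s),
              class = "beat")
  })
}

#' Score detected R peaks against ground truth
#'
#' Matches each detection to at most one true R time within `tol_s`
#' (greedy, nearest-first) and reports sensitivity (fraction of true peaks
#' found) and positive predictivity (fraction of detections that are true).
#'
#' @param detected_s,truth_s Numeric vectors of times in seconds.
#' @param tol_s Matching tolerance (default 50 ms).
#' @return List with `sensitivity`, `ppv`, `n_matched`.
#' @export
score_r_detection <- function(detected_s, truth_s, tol_s = 0.05) {
  if (length(truth_s) == 0L)
    return(list(sensitivity = NA_real_,
                ppv = if (length(detected_s)) 0 else NA_real_, n_matched = 0L))
  if (length(detected_s) == 0L)
    return(list(sensitivity = 0, ppv = NA_real_, n_matched = 0L))
  d <- abs(outer(detected_s, truth_s, "-"))
  pairs <- which(d <= tol_s, arr.ind = TRUE)
  n_matched <- 0L
  if (nrow(pairs)) {
    ord <- order(d[pairs])
    used_det <- logical(length(detected_s))
    used_tru <- logical(length(truth_s))
    for (k in ord) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      if (!used_det[i] && !used_tru[j]) {
        used_det[i] <- TRUE; used_tru[j] <- TRUE
        n_matched <- n_matched + 1L
      }
    }
  }
  list(sensitivity = n_matched / length(truth_s),
       ppv = n_matched / length(detected_s),
       n_matched = n_matched)
}
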