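#' Heart-rate series from R-peak times
#'
#' Builds the beat-interval representation used throughout the coupling
#' analysis: successive RR intervals and the instantaneous heart rate
#' `60 / RR` (bpm). Implausible intervals are cleaned at the peak level:
#' any peak closer than `rr_min` seconds to its accepted predecessor is
#' dropped (double detections), and a warning is raised if gaps longer than
#' `rr_max` seconds remain (missed beats are kept as gaps, not interpolated).
#'
#' @param peak_times Strictly increasing numeric vector of R-peak times (s).
#' @param fs_origin Sampling rate of the signal the peaks came from (Hz),
#'   kept as metadata.
#' @param rr_min,rr_max Plausibility bounds on RR intervals in seconds.
#' @param clean If `TRUE` (default), drop peaks violating `rr_min`.
#' @return An object of class `heart_rate_series` with fields `peak_times`,
#'   `rr` (s), `hr_series` (bpm, one value per interval) and `fs_origin`.
#' @export
heart_rate_series <- function(peak_times, fs_origin = NA_real_,
                              rr_min = 0.2, rr_max = 3, clean = TRUE) {
  if (length(peak_times) < 2L) {
    stop_invalid("insufficient peaks: need at least 2, got %d", length(peak_times))
  }
  if (any(diff(peak_times) <= 0)) stop_invalid("`peak_times` must be strictly increasing")
  pt <- as.numeric(peak_times)
  if (clean) {
    keep <- rep(TRUE, length(pt))
    last <- pt[1L]
    for (i in seq_along(pt)[-1L]) {
      if (pt[i] - last < rr_min) keep[i] <- FALSE else last <- pt[i]
    }
    pt <- pt[keep]
    if (length(pt) < 2L) stop_invalid("insufficient peaks after cleaning")
  }
  rr <- diff(pt)
  if (any(rr > rr_max)) {
    warning(sprintf("%d RR interval(s) exceed %.1f s; treated as gaps", sum(rr > rr_max), rr_max))
  }
  structure(
    list(peak_times = pt, rr = rr, hr_series = 60 / rr, fs_origin = fs_origin),
    class = "heart_rate_series"
  )
}

#' @export
print.heart_rate_series <- function(x, ...) {
  cat(sprintf("<heart_rate_series> %d beats over %.1f s | mean HR %.1f bpm\n",
              length(x$peak_times), diff(range(x$peak_times)), mean(x$hr_series)))
  invisible(x)
}

#' Detect R peaks in a single-channel ECG
#'
#' A Pan-Tompkins-style detector: zero-phase band-pass (5-30 Hz), squared
#' derivative, moving-window integration, adaptive amplitude threshold and a
#' refractory period of `refractory` seconds. Peak times are refined to the
#' maximum of the band-passed signal near each detection, so they land on the
#' R deflection rather than the energy envelope.
#'
#' @param ecg Numeric vector of ECG samples.
#' @param fs Sampling rate in Hz (>= 100).
#' @param refractory Minimum separation between accepted peaks (s). The
#'   default 0.2 s admits heart rates up to 300 bpm, covering fetal rates.
#' @return Numeric vector of peak times in seconds (0 = first sample).
#' @export
detect_rpeaks <- function(ecg, fs, refractory = 0.2) {
  if (!is_scalar_number(fs) || fs < 100) stop_invalid("`fs` must be >= 100 Hz")
  if (length(ecg) < 2 * fs) stop_invalid("signal must be at least 2 s long")
  if (!all(is.finite(ecg))) stop_invalid("`ecg` must be finite")
  if (diff(range(ecg)) < 1e-12) stop_invalid("no peaks: flat signal")

  ny <- fs / 2
  bf <- signal::butter(3, c(5, 30) / ny, type = "pass")
  bp <- signal::filtfilt(bf, ecg)

  energy <- c(0, diff(bp))^2
  w <- max(3L, round(0.12 * fs))
  kern <- rep(1 / w, w)
  env <- stats::filter(energy, kern, sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)

  thr <- 0.2 * stats::quantile(env, 0.99, names = FALSE)
  if (thr <= 0) stop_invalid("no peaks: signal energy below detection floor")

  above <- env > thr
  # local maxima of the envelope among supra-threshold samples
  n <- length(env)
  cand <- which(above &
                  env >= c(-Inf, env[-n]) &
                  env > c(env[-1], -Inf))
  if (length(cand) == 0L) stop_invalid("no peaks detected")

  # greedy refractory enforcement, strongest candidates first
  ord <- cand[order(env[cand], decreasing = TRUE)]
  min_gap <- round(refractory * fs)
  accepted <- integer(0)
  for (i in ord) {
    if (length(accepted) == 0L || all(abs(accepted - i) >= min_gap)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- sort(accepted)

  # refine to the R deflection: maximum of |bp| in a +/- 80 ms neighborhood
  half <- round(0.08 * fs)
  half <- as.integer(half)
  peaks <- vapply(accepted, function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    lo + which.max(abs(bp[lo:hi])) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refinement can merge neighbors; re-enforce refractory keeping first
  if (length(peaks) > 1L) {
    keep <- c(TRUE, diff(peaks) >= min_gap)
    peaks <- peaks[keep]
  }
  (peaks - 1) / fs
}

#' RR intervals and instantaneous heart rate from peak times
#'
#' @param peak_times Strictly increasing R-peak times in seconds.
#' @param fs_origin Optional source sampling rate (Hz), stored as metadata.
#' @return A [heart_rate_series()].
#' @export
rr_from_peaks <- function(peak_times, fs_origin = NA_real_) {
  heart_rate_series(peak_times, fs_origin = fs_origin)
}

#' Mean heart rate of a series
#'
#' Arithmetic mean of the instantaneous heart-rate values (bpm), the summary
#' used for reporting mean maternal and fetal heart rate. Intervals outside
#' the plausibility bounds of [heart_rate_series()] were already handled at
#' construction time.
#'
#' @param series A [heart_rate_series()].
#' @return Mean heart rate in bpm.
#' @export
mean_hr <- function(series) {
  stopifnot(inherits(series, "heart_rate_series"))
  if (length(series$hr_series) == 0L) stop_invalid("insufficient peaks: empty RR series")
  mean(series$hr_series)
}

#' Export / import RR series as two-column CSV
#'
#' Writes `time_s` (time of the interval-terminating beat) and `rr_s`
#' columns; [read_rr_csv()] reconstructs the [heart_rate_series()].
#'
#' @param series A [heart_rate_series()].
#' @param path File path.
#' @return `write_rr_csv` returns `path` invisibly; `read_rr_csv` returns a
#'   [heart_rate_series()].
#' @export
write_rr_csv <- function(series, path) {
  stopifnot(inherits(series, "heart_rate_series"))
  utils::write.csv(
    data.frame(time_s = series$peak_times[-1L], rr_s = series$rr),
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_rr_csv
#' @export
read_rr_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "rr_s") %in% names(df))) {
    stop_invalid("RR CSV must have columns time_s, rr_s")
  }
  first <- df$time_s[1L] - df$rr_s[1L]
  heart_rate_series(c(first, df$time_s), clean = FALSE)
}
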