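#' Configuration for bivariate phase-rectified signal averaging
#'
#' Defaults follow the clinical analysis this package reimplements: heart
#' rate interpolated at `fs = 900` Hz, averaging half-window `L = 9000`
#' samples (a 20-s total window), and quantification windows
#' `S1 = 1350`, `S2 = 2250` samples, i.e. 1.5 s and 2.5 s on either side of
#' the anchor.
#'
#' @param L Half-window length in samples; averaged segments have length `2L`.
#' @param S1,S2 Inner and outer bounds (samples) of the quantification
#'   windows on each side of the anchor; `0 < S1 < S2 <= L`.
#' @param fs Sampling rate (Hz) of the interpolated heart-rate series.
#' @param anchor_T Averaging half-window (samples) of the anchor decrease
#'   criterion; `1` compares single samples, larger values compare means of
#'   `anchor_T` samples before/after each candidate index.
#' @param mean_normalization If `TRUE`, [fsi()] divides each window sum by
#'   the number of summed points (`S2 - S1 + 1`) instead of the literal
#'   `S2 - S1` of the index definition. Default `FALSE` keeps the literal
#'   definition.
#' @return An object of class `bprsa_config`.
#' @export
bprsa_config <- function(L = 9000L, S1 = 1350L, S2 = 2250L, fs = 900,
                         anchor_T = 1L, mean_normalization = FALSE) {
  L <- as.integer(L); S1 <- as.integer(S1); S2 <- as.integer(S2)
  if (!(S1 > 0L && S1 < S2 && S2 <= L)) {
    stop_invalid("invalid config: need 0 < S1 < S2 <= L (got S1=%d, S2=%d, L=%d)", S1, S2, L)
  }
  if (!is_scalar_number(fs) || fs <= 0) stop_invalid("`fs` must be positive")
  if (anchor_T < 1L) stop_invalid("`anchor_T` must be >= 1")
  structure(list(L = L, S1 = S1, S2 = S2, fs = fs,
                 anchor_T = as.integer(anchor_T),
                 mean_normalization = isTRUE(mean_normalization)),
            class = "bprsa_config")
}

#' @export
print.bprsa_config <- function(x, ...) {
  cat(sprintf("<bprsa_config> L=%d S1=%d S2=%d fs=%g Hz | window %.3g s | quantification %.3g-%.3g s\n",
              x$L, x$S1, x$S2, x$fs, 2 * x$L / x$fs, x$S1 / x$fs, x$S2 / x$fs))
  invisible(x)
}

#' Interpolate a beat-wise heart-rate series onto a uniform grid
#'
#' Linear interpolation of the instantaneous heart rate, with each
#' interval's rate assigned to the time of its terminating beat and constant
#' extrapolation at the ends. This places the maternal and fetal heart-rate
#' series on a common high-rate grid so that anchor times in the trigger
#' series index directly into the target series.
#'
#' @param series A [heart_rate_series()].
#' @param fs Grid rate in Hz (default 900).
#' @param duration Grid length in seconds; defaults to the time of the last
#'   beat.
#' @return Numeric vector of length `round(duration * fs)`.
#' @export
interpolate_target <- function(series, fs = 900, duration = NULL) {
  stopifnot(inherits(series, "heart_rate_series"))
  if (length(series$peak_times) < 2L) stop_invalid("insufficient peaks: need >= 2 beats")
  if (is.null(duration)) duration <- max(series$peak_times)
  if (duration <= 0) stop_invalid("`duration` must be positive")
  n <- round(duration * fs)
  grid <- (seq_len(n) - 1) / fs
  stats::approx(x = series$peak_times[-1L], y = series$hr_series,
                xout = grid, method = "linear", rule = 2)$y
}

#' Find anchor points (heart-rate decreases) in a trigger series
#'
#' An index `i` is an anchor when the mean of the `anchor_T` samples
#' starting at `i` is strictly below the mean of the `anchor_T` samples
#' ending at `i - 1`; with the default `anchor_T = 1` this is the classical
#' single-sample decrease criterion `x[i] < x[i-1]`. Indices within `L` of
#' either edge are excluded so every anchor admits a full `2L` window.
#'
#' @param trigger Numeric vector (interpolated trigger heart rate).
#' @param config A [bprsa_config()].
#' @return Integer vector of 1-based anchor indices.
#' @export
find_anchors <- function(trigger, config = bprsa_config()) {
  L <- config$L; Tw <- config$anchor_T
  n <- length(trigger)
  if (n <= 2L * L) stop_invalid("trigger series must be longer than 2L = %d samples", 2L * L)
  cs <- cumsum(c(0, trigger))
  lo <- max(L + 1L, Tw + 1L)
  hi <- min(n - L, n - Tw + 1L)
  if (lo > hi) stop_invalid("no admissible anchor indices")
  i <- lo:hi
  after <- (cs[i + Tw] - cs[i]) / Tw
  before <- (cs[i] - cs[i - Tw]) / Tw
  anchors <- i[after < before]
  if (length(anchors) == 0L) stop_invalid("no anchors found: trigger has no decreases")
  anchors
}

#' Phase-rectified average around anchor points
#'
#' Aligns a window of `2L` target samples on each anchor (anchor at offset
#' `L`, 0-based) and averages across anchors:
#' `X[k] = mean over anchors a of target[a - L + k]` for offsets `k` from
#' 0 to `2L - 1`.
#'
#' Two computation paths give identical results: a direct accumulation over
#' anchors, and, for the large anchor sets produced by sample-wise decrease
#' criteria on interpolated series (where anchors form long consecutive
#' runs), a run-compressed path that sums each run of consecutive anchors
#' through a cumulative sum in O(runs * 2L) instead of O(anchors * 2L).
#'
#' @param target Numeric target series (interpolated fetal heart rate).
#' @param anchors Integer vector of anchor indices into `target`; every
#'   anchor must admit a full window (`a - L >= 1`, `a + L - 1 <= n`).
#' @param L Half-window length in samples.
#' @return Numeric vector `X` of length `2L`.
#' @export
bprsa_average <- function(target, anchors, L) {
  L <- as.integer(L)
  if (length(anchors) == 0L) stop_invalid("no anchors supplied")
  anchors <- as.integer(sort(anchors))
  n <- length(target)
  if (anchors[1L] - L < 1L || anchors[length(anchors)] + L - 1L > n) {
    stop_invalid("every anchor must admit a full 2L window inside the target")
  }
  na <- length(anchors)
  if (na <= 5000L) {
    X <- numeric(2L * L)
    for (a in anchors) {
      X <- X + target[(a - L):(a + L - 1L)]
    }
    return(X / na)
  }
  # run-compressed path: consecutive anchors a..a+m share shifted windows
  cs <- cumsum(c(0, target))
  run_end <- which(c(diff(anchors) != 1L, TRUE))
  run_start <- c(1L, head(run_end, -1L) + 1L)
  X <- numeric(2L * L)
  for (r in seq_along(run_start)) {
    s <- anchors[run_start[r]]
    e <- anchors[run_end[r]]
    # sum over a in s..e of target[(a-L):(a+L-1)] collapses to cumsum diffs
    X <- X + (cs[(e - L + 1L):(e + L)] - cs[(s - L):(s + L - 1L)])
  }
  X / na
}

#' Fetal Stress Index from a phase-rectified average
#'
#' The index contrasts the mean of the averaged curve in a window after the
#' anchor with a mirror window before it. With `X` indexed 0-based of length
#' `2L` and the anchor at index `L`:
#' \deqn{FSI = \frac{1}{S2-S1}\sum_{i=L+S1}^{L+S2} X(i)
#'       - \frac{1}{S2-S1}\sum_{i=L-S2}^{L-S1} X(i)}
#' Both sums are inclusive, so each covers `S2 - S1 + 1` points while the
#' normalization is `S2 - S1`; set `mean_normalization = TRUE` in the config
#' to divide by the point count instead. A positive value means the target
#' (fetal) heart rate is higher after trigger (maternal) decelerations than
#' before; entrainment of fetal by maternal decelerations yields negative
#' values.
#'
#' @param X Numeric vector of length `2L` from [bprsa_average()].
#' @param config A [bprsa_config()].
#' @return The FSI scalar (same units as the target series, bpm here).
#' @export
fsi <- function(X, config = bprsa_config()) {
  L <- config$L; S1 <- config$S1; S2 <- config$S2
  if (length(X) < L + S2 + 1L) {
    stop_invalid("X too short: need index L+S2 = %d (0-based), length %d", L + S2, length(X))
  }
  # 0-based index i maps to R index i + 1
  after <- sum(X[(L + S1 + 1L):(L + S2 + 1L)])
  before <- sum(X[(L - S2 + 1L):(L - S1 + 1L)])
  denom <- if (config$mean_normalization) (S2 - S1 + 1L) else (S2 - S1)
  (after - before) / denom
}

#' End-to-end FSI from maternal and fetal heart-rate series
#'
#' Interpolates both series to the configured rate over their common time
#' support, detects anchor points (decreases) on the maternal series,
#' averages fetal windows around the anchors and evaluates [fsi()].
#'
#' @param maternal,fetal [heart_rate_series()] objects for the trigger
#'   (maternal) and target (fetal) heart.
#' @param config A [bprsa_config()].
#' @return An object of class `bprsa_result` with fields `X` (length `2L`),
#'   `n_anchors`, `fsi`, `anchors` and `config`.
#' @export
compute_fsi <- function(maternal, fetal, config = bprsa_config()) {
  stopifnot(inherits(maternal, "heart_rate_series"),
            inherits(fetal, "heart_rate_series"))
  t0 <- max(min(maternal$peak_times), min(fetal$peak_times))
  t1 <- min(max(maternal$peak_times), max(fetal$peak_times))
  duration <- t1 - t0
  if (duration < 2 * config$L / config$fs) {
    stop_invalid("overlapping support (%.1f s) shorter than the 2L window (%.1f s)",
                 duration, 2 * config$L / config$fs)
  }
  shift <- function(s) heart_rate_series(s$peak_times - t0 + 1e-12,
                                         fs_origin = s$fs_origin, clean = FALSE)
  trig <- interpolate_target(shift(maternal), fs = config$fs, duration = duration)
  targ <- interpolate_target(shift(fetal), fs = config$fs, duration = duration)
  anchors <- find_anchors(trig, config)
  X <- bprsa_average(targ, anchors, config$L)
  structure(
    list(X = X, n_anchors = length(anchors), fsi = fsi(X, config),
         anchors = anchors, config = config),
    class = "bprsa_result"
  )
}

#' @export
print.bprsa_result <- function(x, ...) {
  cat(sprintf("<bprsa_result> FSI = %.5f | %d anchors | window %.3g s at %g Hz\n",
              x$fsi, x$n_anchors, 2 * x$config$L / x$config$fs, x$config$fs))
  invisible(x)
}
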