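#' Construct a uniformly sampled physiological signal recording
#'
#' A `signal_recording` bundles a 1-D sample vector with its sampling rate,
#' channel role and an aligned per-second signal-quality index (SQI). The SQI
#' carries one value in \[0, 1\] per full second of signal; seconds scoring
#' below 0.5 are conventionally treated as artifact and discarded by
#' [sqi_filter()].
#'
#' @param samples Numeric vector of samples.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param role Channel role: `"aECG"` (abdominal composite), `"mECG"`
#'   (maternal) or `"fECG"` (fetal).
#' @param subject_id Subject identifier string.
#' @param sqi Optional numeric vector of per-second quality values in
#'   \[0, 1\]; must have `floor(length(samples) / fs)` entries. Defaults to
#'   all-1 (clean).
#' @return An object of class `signal_recording`.
#' @seealso [simulate_sqi()], [sqi_filter()], [resample_signal()]
#' @export
signal_recording <- function(samples, fs, role = c("aECG", "mECG", "fECG"),
                             subject_id = "S1", sqi = NULL) {
  role <- match.arg(role)
  if (!is.numeric(samples)) stop_invalid("`samples` must be numeric")
  if (!is_scalar_number(fs) || fs <= 0) stop_invalid("`fs` must be a positive number")
  n_sec <- floor(length(samples) / fs)
  if (is.null(sqi)) sqi <- rep(1, n_sec)
  if (length(sqi) != n_sec) {
    stop_invalid("`sqi` must hold one value per full second (%d), got %d",
                 n_sec, length(sqi))
  }
  if (n_sec > 0 && (any(sqi < 0) || any(sqi > 1))) {
    stop_invalid("`sqi` values must lie in [0, 1]")
  }
  structure(
    list(samples = as.numeric(samples), fs = fs, role = role,
         subject_id = as.character(subject_id), sqi = as.numeric(sqi)),
    class = "signal_recording"
  )
}

#' @export
print.signal_recording <- function(x, ...) {
  cat(sprintf("<signal_recording> %s | subject %s | %.6g Hz | %.1f s | %d SQI seconds\n",
              x$role, x$subject_id, x$fs, length(x$samples) / x$fs, length(x$sqi)))
  if (length(x$sqi)) {
    cat(sprintf("  low-SQI (< 0.5) seconds: %d (%.1f%%)\n",
                sum(x$sqi < 0.5), 100 * mean(x$sqi < 0.5)))
  }
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording A [signal_recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording) {
  length(recording$samples) / recording$fs
}
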