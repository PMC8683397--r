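#' Discard low-quality seconds of a recording
#'
#' Keeps every 1-s block whose SQI is at or above `threshold` and
#' concatenates the survivors. The convention follows the quality rule the
#' pipeline assumes — seconds with SQI *lower than* 0.5 are discarded, so a
#' block scoring exactly 0.5 is kept. Segments later cut from the filtered
#' signal may straddle a splice point; the number of splices is recorded in
#' the `splices` attribute and the discarded fraction in `discarded`.
#'
#' @param recording A [signal_recording()] with an aligned per-second SQI.
#' @param threshold Quality threshold; blocks with `sqi >= threshold` are
#'   kept.
#' @return The filtered [signal_recording()] (attributes `discarded`,
#'   `splices` attached).
#' @export
sqi_filter <- function(recording, threshold = 0.5) {
  stopifnot(inherits(recording, "signal_recording"))
  fs <- recording$fs
  if (fs != round(fs)) stop_invalid("SQI filtering requires an integer sampling rate")
  n_sec <- length(recording$sqi)
  if (n_sec == 0L) stop_invalid("recording shorter than one second")
  keep <- recording$sqi >= threshold
  if (!any(keep)) stop_invalid("empty recording: all %d blocks below SQI threshold", n_sec)
  idx <- which(keep)
  block <- rep(idx, each = fs)
  offset <- rep(seq_len(fs), times = length(idx))
  samples <- recording$samples[(block - 1L) * fs + offset]
  out <- signal_recording(samples, fs, role = recording$role,
                          subject_id = recording$subject_id,
                          sqi = recording$sqi[keep])
  attr(out, "discarded") <- 1 - mean(keep)
  attr(out, "splices") <- sum(diff(idx) > 1L)
  out
}

#' Resample a recording to a target rate
#'
#' Deterministic FIR resampling: when downsampling, a zero-phase
#' linear-phase low-pass (cutoff at 90% of the target Nyquist, symmetric
#' 97-tap window FIR applied with edge padding) removes content that would
#' alias, then the signal is evaluated on the new uniform grid by cubic
#' spline interpolation. Upsampling skips the filter. The output has
#' exactly `round(n * target_fs / fs)` samples, so the duration is
#' preserved to within one sample. The per-second SQI channel is unchanged
#' (duration in seconds is invariant).
#'
#' @param recording A [signal_recording()].
#' @param target_fs Target sampling rate in Hz (default 256, the model
#'   rate of the representation-learning stage).
#' @return A [signal_recording()] at `target_fs`.
#' @export
resample_signal <- function(recording, target_fs = 256) {
  stopifnot(inherits(recording, "signal_recording"))
  if (!is_scalar_number(target_fs) || target_fs <= 0) {
    stop_invalid("`target_fs` must be positive")
  }
  if (target_fs == recording$fs) return(recording)
  x <- recording$samples
  n <- length(x)
  fs <- recording$fs
  if (target_fs < fs) {
    wc <- 0.9 * (target_fs / 2) / (fs / 2)
    ntaps <- 97L
    h <- signal::fir1(ntaps - 1L, wc)
    half <- (ntaps - 1L) %/% 2L
    xp <- c(rep(x[1L], half), x, rep(x[n], half))
    xf <- stats::filter(xp, h, sides = 2L)
    x <- as.numeric(xf[(half + 1L):(half + n)])
  }
  n_out <- round(n * target_fs / fs)
  t_new <- (seq_len(n_out) - 1) / target_fs
  y <- stats::spline(x = (seq_len(n) - 1) / fs, y = x, xout = t_new,
                     method = "fmm")$y
  signal_recording(y, target_fs, role = recording$role,
                   subject_id = recording$subject_id, sqi = recording$sqi)
}

#' Cut a recording into fixed-length non-overlapping windows
#'
#' @param recording A [signal_recording()] already at the model rate
#'   (`expected_fs`, enforced).
#' @param window_s Window length in seconds (default 10).
#' @param drop_partial Drop a trailing partial window (default `TRUE`; a
#'   `FALSE` value is not supported since downstream models need
#'   fixed-length inputs, and is reserved for future padding strategies).
#' @param expected_fs Sampling rate the windows must be cut at.
#' @return A `segment_set`: list with `samples` (matrix, one window per
#'   row), `subject_id`, `role`, `origin_index` (window position within the
#'   recording). Zero rows (with a warning) when the recording is shorter
#'   than one window.
#' @export
segment_signal <- function(recording, window_s = 10, drop_partial = TRUE,
                           expected_fs = 256) {
  stopifnot(inherits(recording, "signal_recording"))
  if (recording$fs != expected_fs) {
    stop_invalid("segmentation expects fs = %g Hz, got %g (resample first)",
                 expected_fs, recording$fs)
  }
  if (!isTRUE(drop_partial)) stop_invalid("only drop_partial = TRUE is supported")
  win <- round(window_s * recording$fs)
  n_win <- floor(length(recording$samples) / win)
  if (n_win == 0L) {
    warning("recording shorter than one window: returning empty segment set")
    return(segment_set(matrix(numeric(0), 0L, win), recording$subject_id,
                       recording$role, integer(0)))
  }
  m <- matrix(recording$samples[seq_len(n_win * win)], nrow = n_win, ncol = win,
              byrow = TRUE)
  segment_set(m, recording$subject_id, recording$role, seq_len(n_win))
}

segment_set <- function(samples, subject_id, role, origin_index) {
  structure(list(samples = samples,
                 subject_id = rep_len(as.character(subject_id), nrow(samples)),
                 role = role,
                 origin_index = origin_index),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d windows x %d samples | role %s | %d subject(s)\n",
              nrow(x$samples), ncol(x$samples), x$role,
              length(unique(x$subject_id))))
  invisible(x)
}

#' Z-normalize a segment
#'
#' Zero mean, unit standard deviation per window, so that the synthetic
#' amplitude knob and the scaling pretext transformation operate on a
#' defined scale. Constant windows carry no morphology and are rejected.
#'
#' @param segment Numeric vector (one window) or a `segment_set`.
#' @return The normalized vector / `segment_set`.
#' @export
normalize_segment <- function(segment) {
  if (inherits(segment, "segment_set")) {
    m <- segment$samples
    mu <- rowMeans(m)
    sd <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
    if (any(sd < 1e-12)) stop_invalid("constant segment cannot be normalized")
    segment$samples <- (m - mu) / sd
    return(segment)
  }
  s <- stats::sd(segment)
  if (!is.finite(s) || s < 1e-12) stop_invalid("constant segment cannot be normalized")
  (segment - mean(segment)) / s
}

#' Build a labeled segment dataset from cohort recordings
#'
#' Runs the full preprocessing chain for one channel role — SQI filtering,
#' resampling to the model rate, fixed-window segmentation, per-window
#' z-normalization — and attaches the per-subject label bundle (group,
#' PSS-10, PDQ, cortisol, FSI).
#'
#' @param cohort Output of [generate_cohort()], or a list with elements
#'   `recordings` (each holding `mecg`/`fecg`/`aecg`) and `truth`.
#' @param role Which channel to use: `"mECG"` or `"aECG"`.
#' @param sqi_threshold,target_fs,window_s Preprocessing parameters.
#' @return A `segment_dataset`: list with `segments` (matrix), `subject_id`
#'   (per row), `labels` (per-subject data frame with `subject_id, group,
#'   pss, pdq, cortisol, fsi`), and bookkeeping (`discarded` fraction per
#'   recording, `splices`).
#' @export
build_segment_dataset <- function(cohort, role = c("mECG", "aECG"),
                                  sqi_threshold = 0.5, target_fs = 256,
                                  window_s = 10) {
  role <- match.arg(role)
  field <- c(mECG = "mecg", aECG = "aecg")[[role]]
  seg_list <- list()
  sid_list <- list()
  discarded <- numeric(0)
  splices <- integer(0)
  for (rec in cohort$recordings) {
    r <- rec[[field]]
    filt <- sqi_filter(r, sqi_threshold)
    discarded[r$subject_id] <- attr(filt, "discarded")
    splices[r$subject_id] <- attr(filt, "splices")
    res <- resample_signal(filt, target_fs)
    segs <- suppressWarnings(segment_signal(res, window_s, expected_fs = target_fs))
    if (nrow(segs$samples) == 0L) next
    segs <- normalize_segment(segs)
    seg_list[[length(seg_list) + 1L]] <- segs$samples
    sid_list[[length(sid_list) + 1L]] <- segs$subject_id
  }
  if (length(seg_list) == 0L) stop_invalid("no usable segments in cohort")
  labels <- cohort$truth[, c("subject_id", "group", "pss", "pdq", "cortisol", "fsi_true")]
  names(labels)[names(labels) == "fsi_true"] <- "fsi"
  structure(
    list(segments = do.call(rbind, seg_list),
         subject_id = unlist(sid_list),
         role = role,
         labels = labels,
         discarded = discarded,
         splices = splices),
    class = "segment_dataset"
  )
}

#' @export
print.segment_dataset <- function(x, ...) {
  cat(sprintf("<segment_dataset> %s | %d segments x %d samples | %d subjects | mean discarded %.1f%%\n",
              x$role, nrow(x$segments), ncol(x$segments),
              length(unique(x$subject_id)), 100 * mean(x$discarded)))
  invisible(x)
}

# Per-segment label lookup used by the affect heads.
segment_labels <- function(dataset, task) {
  stopifnot(inherits(dataset, "segment_dataset"))
  lab <- dataset$labels
  idx <- match(dataset$subject_id, lab$subject_id)
  if (anyNA(idx)) stop_invalid("segment with no label bundle")
  switch(task,
         classify_stress = as.numeric(lab$group[idx] == "stressed"),
         regress_cortisol = lab$cortisol[idx],
         regress_fsi = lab$fsi[idx],
         regress_pdq = as.numeric(lab$pdq[idx]),
         regress_pss = as.numeric(lab$pss[idx]),
         stop_invalid("unknown task '%s'", task))
}
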