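#' Heart-rate variability parameters for the RR-interval generator
#'
#' The RR driver is deliberately minimal: two sinusoidal modulations of the
#' beat interval — a low-frequency (~0.1 Hz, baroreflex-band) and a
#' high-frequency (~0.25 Hz, respiratory-band) component — plus white
#' jitter. This is just enough structure for heart-rate decreases (anchor
#' points) to exist and for a stress effect to be encodable as a reduced
#' high-frequency amplitude.
#'
#' @param lf_amp,hf_amp Amplitudes of the LF/HF modulation, in seconds of RR.
#' @param lf_freq,hf_freq Modulation frequencies in Hz.
#' @param jitter_sd Standard deviation of white per-beat RR jitter (s).
#' @return A list of class `hrv_params`.
#' @export
hrv_params <- function(lf_amp = 0.03, hf_amp = 0.025,
                       lf_freq = 0.1, hf_freq = 0.25, jitter_sd = 0.01) {
  if (lf_amp < 0 || hf_amp < 0 || jitter_sd < 0) stop_invalid("HRV amplitudes must be >= 0")
  structure(list(lf_amp = lf_amp, hf_amp = hf_amp, lf_freq = lf_freq,
                 hf_freq = hf_freq, jitter_sd = jitter_sd),
            class = "hrv_params")
}

#' Generate beat event times with sinusoidal + white HRV
#'
#' Beats are laid down sequentially: each interval is the base RR
#' (`60 / mean_hr`) plus the LF/HF sinusoids evaluated at the current time
#' plus white jitter. Sinusoid phases are drawn from the session RNG, so
#' wrap calls in `set.seed()` for reproducibility. With all amplitudes zero
#' the output is the exact uniform beat grid.
#'
#' @param mean_hr Mean heart rate in bpm, in \[30, 250\].
#' @param hrv [hrv_params()] controlling variability.
#' @param duration Length of the series in seconds (> 0).
#' @return Strictly increasing beat times in `(0, duration]`.
#' @export
generate_rr_series <- function(mean_hr, hrv = hrv_params(), duration) {
  if (!is_scalar_number(duration) || duration <= 0) stop_invalid("`duration` must be positive")
  if (!is_scalar_number(mean_hr) || mean_hr < 30 || mean_hr > 250) {
    stop_invalid("`mean_hr` must lie in [30, 250] bpm")
  }
  rr_base <- 60 / mean_hr
  deterministic <- hrv$lf_amp == 0 && hrv$hf_amp == 0 && hrv$jitter_sd == 0
  ph <- if (deterministic) c(0, 0) else stats::runif(2, 0, 2 * pi)
  n_max <- ceiling(duration / (0.25 * rr_base)) + 8L
  times <- numeric(n_max)
  t <- 0
  k <- 0L
  repeat {
    rr <- rr_base +
      hrv$lf_amp * sin(2 * pi * hrv$lf_freq * t + ph[1L]) +
      hrv$hf_amp * sin(2 * pi * hrv$hf_freq * t + ph[2L])
    if (hrv$jitter_sd > 0) rr <- rr + stats::rnorm(1, 0, hrv$jitter_sd)
    rr <- max(rr, 0.25 * rr_base)
    t <- t + rr
    if (t > duration + 1e-9) break
    k <- k + 1L
    times[k] <- t
  }
  if (k < 2L) stop_invalid("duration too short to place two beats")
  times[seq_len(k)]
}

#' PQRST morphology for the Gaussian-kernel ECG synthesizer
#'
#' Each beat is a sum of five Gaussian deflections (P, Q, R, S, T) placed at
#' fixed fractions of the local RR interval around the R peak, with widths
#' that also scale with RR. Amplitudes are in arbitrary units with R = 1.
#'
#' @param p_amp,q_amp,r_amp,s_amp,t_amp Wave amplitudes.
#' @param offsets Named numeric vector of wave centers as fractions of the
#'   local RR interval (negative = before R).
#' @param widths Named numeric vector of Gaussian standard deviations as
#'   fractions of the local RR interval.
#' @return A list of class `ecg_morphology`.
#' @export
ecg_morphology <- function(p_amp = 0.15, q_amp = -0.12, r_amp = 1,
                           s_amp = -0.25, t_amp = 0.35,
                           offsets = c(P = -0.20, Q = -0.030, R = 0,
                                       S = 0.030, T = 0.30),
                           widths = c(P = 0.025, Q = 0.010, R = 0.012,
                                      S = 0.010, T = 0.055)) {
  structure(list(amps = c(P = p_amp, Q = q_amp, R = r_amp, S = s_amp, T = t_amp),
                 offsets = offsets, widths = widths),
            class = "ecg_morphology")
}

#' Synthesize an ECG trace from beat times
#'
#' @param rr_events Strictly increasing beat (R-peak) times in seconds.
#' @param fs Sampling rate in Hz.
#' @param duration Output duration in seconds; defaults to
#'   `ceiling(max(rr_events))`.
#' @param morphology An [ecg_morphology()].
#' @param amplitude_scale Global amplitude multiplier.
#' @return Numeric vector of length `round(duration * fs)`.
#' @export
synthesize_ecg <- function(rr_events, fs, duration = NULL,
                           morphology = ecg_morphology(), amplitude_scale = 1) {
  if (!is_scalar_number(fs) || fs <= 0) stop_invalid("`fs` must be positive")
  if (length(rr_events) == 0L) {
    warning("empty beat list: returning empty signal")
    return(numeric(0))
  }
  if (any(diff(rr_events) <= 0)) stop_invalid("`rr_events` must be strictly increasing")
  if (is.null(duration)) duration <- ceiling(max(rr_events))
  n <- round(duration * fs)
  x <- numeric(n)
  if (amplitude_scale == 0) return(x)
  rr_local <- if (length(rr_events) > 1L) {
    d <- diff(rr_events)
    c(d[1L], d)
  } else {
    rep(0.8, 1L)
  }
  amps <- morphology$amps * amplitude_scale
  for (b in seq_along(rr_events)) {
    tc <- rr_events[b]
    rr <- rr_local[b]
    lo <- max(1L, floor((tc - 0.45 * rr) * fs) + 1L)
    hi <- min(n, ceiling((tc + 0.55 * rr) * fs) + 1L)
    if (lo > hi) next
    tt <- ((lo:hi) - 1) / fs - tc
    beat <- numeric(hi - lo + 1L)
    for (w in seq_along(amps)) {
      mu <- morphology$offsets[w] * rr
      sd <- morphology$widths[w] * rr
      beat <- beat + amps[w] * exp(-0.5 * ((tt - mu) / sd)^2)
    }
    x[lo:hi] <- x[lo:hi] + beat
  }
  x
}

#' Generate fetal beats coupled to maternal heart-rate decelerations
#'
#' The fetal instantaneous heart rate is a baseline HRV process plus a
#' coupling term: `coupling_gain` times the lagged maternal deceleration
#' component, defined as the (non-positive) excursion of maternal HR below
#' its 0.9 quantile. With `coupling_gain = 0` the fetal series is
#' statistically independent of the maternal one; increasing the gain deepens
#' fetal decelerations that follow maternal ones, which is exactly the
#' coupling that the BPRSA-based FSI quantifies.
#'
#' @param maternal A maternal [heart_rate_series()].
#' @param coupling_gain Dimensionless gain (fetal bpm per maternal bpm of
#'   deceleration depth).
#' @param lag Latency of the fetal response in seconds (>= 0).
#' @param fetal_base_hr Fetal baseline heart rate in bpm, in \[80, 220\].
#' @param fetal_hrv [hrv_params()] for the fetal baseline process, with
#'   `lf_amp`/`hf_amp` interpreted in bpm of heart-rate modulation (not
#'   seconds of RR).
#' @param duration Length of the fetal series in seconds; defaults to the
#'   maternal support.
#' @return Strictly increasing fetal beat times.
#' @export
couple_fetal_rr <- function(maternal, coupling_gain, lag = 0.5,
                            fetal_base_hr = 140,
                            fetal_hrv = hrv_params(lf_amp = 2, hf_amp = 1.2,
                                                   lf_freq = 0.08, hf_freq = 0.25,
                                                   jitter_sd = 0.005),
                            duration = NULL) {
  stopifnot(inherits(maternal, "heart_rate_series"))
  if (lag < 0) stop_invalid("`lag` must be >= 0")
  if (fetal_base_hr < 80 || fetal_base_hr > 220) {
    stop_invalid("`fetal_base_hr` outside the fetal physiological range [80, 220] bpm")
  }
  if (is.null(duration)) duration <- max(maternal$peak_times)
  m_fun <- stats::approxfun(maternal$peak_times[-1L], maternal$hr_series, rule = 2)
  ref <- stats::quantile(maternal$hr_series, 0.9, names = FALSE)
  ph <- stats::runif(2, 0, 2 * pi)
  n_max <- ceiling(duration * 250 / 60) + 8L
  times <- numeric(n_max)
  t <- 0
  k <- 0L
  repeat {
    dec <- min(0, m_fun(max(0, t - lag)) - ref)
    hr <- fetal_base_hr +
      fetal_hrv$lf_amp * sin(2 * pi * fetal_hrv$lf_freq * t + ph[1L]) +
      fetal_hrv$hf_amp * sin(2 * pi * fetal_hrv$hf_freq * t + ph[2L]) +
      coupling_gain * dec
    hr <- min(max(hr, 60), 250)
    rr <- 60 / hr
    if (fetal_hrv$jitter_sd > 0) rr <- rr + stats::rnorm(1, 0, fetal_hrv$jitter_sd)
    rr <- max(rr, 0.22)
    t <- t + rr
    if (t > duration + 1e-9) break
    k <- k + 1L
    times[k] <- t
  }
  if (k < 2L) stop_invalid("duration too short to place two fetal beats")
  times[seq_len(k)]
}

#' Mix maternal and fetal ECG into an abdominal composite
#'
#' The abdominal channel is modeled as the maternal trace plus an attenuated
#' fetal trace plus white sensor noise; the SQI channel is left empty and is
#' filled by [simulate_sqi()].
#'
#' @param mecg,fecg [signal_recording()]s with equal `fs` and length.
#' @param fetal_attenuation Fraction multiplying the fetal trace (the fetal
#'   heart is farther from the abdominal electrodes).
#' @param noise_sd Standard deviation of additive Gaussian sensor noise.
#' @return A [signal_recording()] with `role = "aECG"`.
#' @export
mix_abdominal <- function(mecg, fecg, fetal_attenuation = 0.2, noise_sd = 0.05) {
  stopifnot(inherits(mecg, "signal_recording"), inherits(fecg, "signal_recording"))
  if (mecg$fs != fecg$fs) stop_invalid("sampling rates differ (%g vs %g Hz)", mecg$fs, fecg$fs)
  if (length(mecg$samples) != length(fecg$samples)) {
    stop_invalid("durations differ (%d vs %d samples)",
                 length(mecg$samples), length(fecg$samples))
  }
  x <- mecg$samples + fetal_attenuation * fecg$samples
  if (noise_sd > 0) x <- x + stats::rnorm(length(x), 0, noise_sd)
  signal_recording(x, mecg$fs, role = "aECG", subject_id = mecg$subject_id)
}

#' Fill the per-second SQI channel of a recording
#'
#' Each second is independently an artifact second with probability
#' `artifact_rate`; artifact seconds draw SQI uniformly in \[0, 0.5) and
#' clean seconds in \[0.5, 1\]. The default rate 0.041 reproduces the
#' typical ~4.1% of data discarded by quality control in transabdominal
#' recordings.
#'
#' @param recording A [signal_recording()].
#' @param artifact_rate Expected fraction of artifact seconds, in \[0, 1\].
#' @return The recording with its `sqi` field replaced.
#' @export
simulate_sqi <- function(recording, artifact_rate = 0.041) {
  stopifnot(inherits(recording, "signal_recording"))
  if (artifact_rate < 0 || artifact_rate > 1) stop_invalid("`artifact_rate` must be in [0, 1]")
  n_sec <- floor(length(recording$samples) / recording$fs)
  art <- stats::runif(n_sec) < artifact_rate
  sqi <- numeric(n_sec)
  sqi[art] <- stats::runif(sum(art), 0, 0.4999)
  sqi[!art] <- stats::runif(sum(!art), 0.5, 1)
  recording$sqi <- sqi
  recording
}

#' Synthetic cohort configuration
#'
#' Bundles every knob of the cohort generator. Defaults mirror the study
#' conditions the package emulates: ~46 minutes of usable signal per subject
#' at 900 Hz, an SQI artifact rate of 4.1%, and a stressed/control split
#' defined by the PSS-10 >= 19 rule. Stress is encoded in the signal as a
#' higher maternal heart rate, a reduced high-frequency HRV amplitude, a
#' flattened T wave and a larger maternal-to-fetal coupling gain; all four
#' effects scale continuously with a latent severity variable so that the
#' biomarkers are regressable, not merely classifiable.
#'
#' @param n_subjects Number of mother-fetus dyads (>= 2).
#' @param stress_prevalence Probability a subject is stressed, in \[0, 1\].
#' @param recording_minutes Recording duration per subject (minutes).
#' @param maternal_fs Sampling rate of all generated channels (Hz).
#' @param coupling_gain_stressed,coupling_gain_control Ground-truth coupling
#'   gains at the stressed/control severity centers.
#' @param label_noise_sd Noise scale added to the questionnaire biomarkers.
#' @param artifact_rate Expected low-SQI fraction per recording.
#' @param seed Integer RNG seed; same config + seed gives a bit-identical
#'   cohort.
#' @param maternal_hr,fetal_hr Baseline heart rates in bpm.
#' @param hr_stress_span Total bpm span of the stress-driven maternal HR
#'   shift (control-center to stressed-center).
#' @param hf_stress_factor Fractional HF-amplitude reduction at full stress.
#' @param twave_stress_factor Fractional T-wave-amplitude reduction at full
#'   stress.
#' @param fetal_attenuation,mix_noise_sd Abdominal mixing parameters, see
#'   [mix_abdominal()].
#' @param coupling_lag Fetal response latency in seconds.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, stress_prevalence = 0.5,
                          recording_minutes = 46, maternal_fs = 900,
                          coupling_gain_stressed = 1, coupling_gain_control = 0.25,
                          label_noise_sd = 1, artifact_rate = 0.041, seed = 1L,
                          maternal_hr = 80, fetal_hr = 140,
                          hr_stress_span = 10, hf_stress_factor = 0.6,
                          twave_stress_factor = 0.35,
                          fetal_attenuation = 0.2, mix_noise_sd = 0.05,
                          coupling_lag = 0.5) {
  if (!is_scalar_number(n_subjects) || n_subjects < 2) {
    stop_invalid("`n_subjects` must be >= 2")
  }
  if (stress_prevalence < 0 || stress_prevalence > 1) {
    stop_invalid("`stress_prevalence` must be in [0, 1]")
  }
  if (maternal_fs <= 0) stop_invalid("`maternal_fs` must be positive")
  if (artifact_rate < 0 || artifact_rate > 1) stop_invalid("`artifact_rate` must be in [0, 1]")
  if (recording_minutes <= 0) stop_invalid("`recording_minutes` must be positive")
  structure(as.list(environment()), class = "cohort_config")
}

# Map latent severity to a 0..1 stress-effect coordinate: 0 at the control
# center (severity -1), 1 at the stressed center (severity +1).
severity_to_unit <- function(severity) {
  z <- stats::plogis(1.5 * severity)
  lo <- stats::plogis(-1.5); hi <- stats::plogis(1.5)
  pmin(1.2, pmax(-0.2, (z - lo) / (hi - lo)))
}

#' Generate a synthetic mother-fetus cohort
#'
#' For each subject the generator draws a stress group and a latent
#' severity, derives the biomarkers (PSS-10, PDQ, hair cortisol) and the
#' ground-truth coupling gain from severity, simulates maternal and coupled
#' fetal beat series, synthesizes the mECG and fECG traces, mixes them into
#' the abdominal aECG and attaches simulated SQI channels. The ground-truth
#' `fsi_true` is computed by [compute_fsi()] on the noiseless beat series,
#' so the label is exactly the statistic the analysis pipeline estimates.
#'
#' Group and PSS-10 are kept mutually consistent: stressed subjects always
#' have PSS-10 >= 19 and controls < 19.
#'
#' @param config A [cohort_config()].
#' @return A list with `recordings` (per subject: `mecg`, `fecg`, `aecg`
#'   [signal_recording()]s plus the beat series) and `truth`, a data frame
#'   with columns `subject_id, group, latent_severity, pss, pdq, cortisol,
#'   coupling_gain, fsi_true`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- as.integer(config$n_subjects)
  duration <- config$recording_minutes * 60
  fs <- config$maternal_fs
  bcfg <- bprsa_config(fs = fs)

  with_seed(config$seed, {
    stressed <- stats::rbinom(n, 1L, config$stress_prevalence) == 1L
    severity <- stats::rnorm(n, mean = ifelse(stressed, 1, -1), sd = 0.3)
    u <- severity_to_unit(severity)

    pss <- round(12 + 14 * stats::plogis(2 * severity) +
                   stats::rnorm(n, 0, config$label_noise_sd))
    pss <- ifelse(stressed, pmax(pss, 19), pmin(pss, 18))
    pss <- pmin(40L, pmax(0L, as.integer(pss)))
    pdq <- pmax(0L, as.integer(round(12 + 5 * severity +
                                       stats::rnorm(n, 0, config$label_noise_sd))))
    cortisol <- exp(1.9 + 0.55 * severity + stats::rnorm(n, 0, 0.15))
    gain <- pmax(0, config$coupling_gain_control +
                   (config$coupling_gain_stressed - config$coupling_gain_control) * u)

    subject_seed <- vapply(seq_len(n), function(i) derive_seed(config$seed, i), integer(1))

    recordings <- vector("list", n)
    fsi_true <- numeric(n)
    for (i in seq_len(n)) {
      recordings[[i]] <- with_seed(subject_seed[i], {
        sid <- sprintf("S%03d", i)
        m_hr <- config$maternal_hr - config$hr_stress_span / 2 +
          config$hr_stress_span * u[i]
        m_hrv <- hrv_params(hf_amp = 0.025 * (1 - config$hf_stress_factor * min(1, max(0, u[i]))))
        m_events <- generate_rr_series(m_hr, m_hrv, duration)
        m_series <- heart_rate_series(m_events, fs_origin = fs, clean = FALSE)
        f_events <- couple_fetal_rr(m_series, gain[i], lag = config$coupling_lag,
                                    fetal_base_hr = config$fetal_hr,
                                    duration = duration)
        f_series <- heart_rate_series(f_events, fs_origin = fs, clean = FALSE)
        fsi_val <- compute_fsi(m_series, f_series, bcfg)$fsi

        morph_m <- ecg_morphology(t_amp = 0.35 * (1 - config$twave_stress_factor *
                                                    min(1, max(0, u[i]))))
        morph_f <- ecg_morphology()
        mecg <- signal_recording(
          synthesize_ecg(m_events, fs, duration, morph_m),
          fs, role = "mECG", subject_id = sid)
        fecg <- signal_recording(
          synthesize_ecg(f_events, fs, duration, morph_f),
          fs, role = "fECG", subject_id = sid)
        aecg <- mix_abdominal(mecg, fecg, config$fetal_attenuation, config$mix_noise_sd)
        mecg <- simulate_sqi(mecg, config$artifact_rate)
        fecg <- simulate_sqi(fecg, config$artifact_rate)
        aecg <- simulate_sqi(aecg, config$artifact_rate)
        list(subject_id = sid, mecg = mecg, fecg = fecg, aecg = aecg,
             maternal_beats = m_events, fetal_beats = f_events,
             fsi_true = fsi_val)
      })
      fsi_true[i] <- recordings[[i]]$fsi_true
    }

    truth <- data.frame(
      subject_id = vapply(recordings, `[[`, character(1), "subject_id"),
      group = ifelse(stressed, "stressed", "control"),
      latent_severity = severity,
      pss = pss, pdq = pdq, cortisol = cortisol,
      coupling_gain = gain, fsi_true = fsi_true,
      stringsAsFactors = FALSE
    )
    list(recordings = recordings, truth = truth, config = config)
  })
}
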