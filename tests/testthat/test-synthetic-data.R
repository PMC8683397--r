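test_that("RR generator honors the zero-variability and mean-rate contracts", {
  # zero HRV at 60 bpm: exact 1-s beat grid
  ev <- generate_rr_series(60, hrv_params(0, 0, jitter_sd = 0), 10)
  expect_identical(ev, as.numeric(1:10))

  # mean RR close to 60/mean_hr over long records
  ev <- with_seed_test(1, generate_rr_series(80, hrv_params(), 600))
  expect_true(all(diff(ev) > 0))
  expect_true(max(ev) <= 600 + 1e-9)
  expect_gt(mean(diff(ev)), 0.95 * 60 / 80)
  expect_lt(mean(diff(ev)), 1.05 * 60 / 80)

  expect_error(generate_rr_series(80, hrv_params(), 0), "positive")
  expect_error(generate_rr_series(20, hrv_params(), 10), "30")
})

test_that("ECG synthesis produces detectable beats with exact length arithmetic", {
  ev <- (1:10)
  x <- synthesize_ecg(ev, 900, 60)
  expect_length(x, 54000)

  pk <- detect_rpeaks(x, 900)
  expect_length(pk, 10)
  expect_true(all(vapply(ev, function(t) min(abs(pk - t)), numeric(1)) <= 0.02))

  expect_identical(synthesize_ecg(ev, 900, 12, amplitude_scale = 0),
                   numeric(12 * 900))
  expect_warning(out <- synthesize_ecg(numeric(0), 900), "empty")
  expect_length(out, 0)
})

test_that("fetal coupling: gain 0 decouples, deterministic step transfers with unit gain", {
  set.seed(7)
  m_ev <- generate_rr_series(80, hrv_params(), 600)
  m <- heart_rate_series(m_ev, clean = FALSE)
  f_ev <- couple_fetal_rr(m, 0, duration = 600)
  f <- heart_rate_series(f_ev, clean = FALSE)
  g <- seq(10, 590, by = 0.5)
  mh <- stats::approx(m$peak_times[-1], m$hr_series, g, rule = 2)$y
  fh <- stats::approx(f$peak_times[-1], f$hr_series, g, rule = 2)$y
  expect_lt(abs(stats::cor(mh, fh)), 0.1)

  # step drop of 10 bpm late in the record, no fetal HRV, zero lag:
  # the fetal HR drop equals gain * step within one beat of the step onset
  step_t <- 80
  mt <- cumsum(c(rep(60 / 90, 120), rep(60 / 80, 40)))
  mstep <- heart_rate_series(mt, clean = FALSE)
  quiet <- hrv_params(0, 0, jitter_sd = 0)
  for (gain in c(0.5, 1)) {
    fe <- couple_fetal_rr(mstep, gain, lag = 0, fetal_base_hr = 140,
                          fetal_hrv = quiet, duration = max(mt))
    fs_ <- heart_rate_series(fe, clean = FALSE)
    pre <- fs_$hr_series[fs_$peak_times[-1] < step_t - 2]
    post <- fs_$hr_series[fs_$peak_times[-1] > step_t + 2]
    expect_equal(mean(pre), 140, tolerance = 1e-6)
    expect_equal(mean(post), 140 - gain * 10, tolerance = 0.05)
  }

  expect_error(couple_fetal_rr(m, 1, fetal_base_hr = 60), "physiological")
  expect_error(couple_fetal_rr(m, 1, lag = -1), "lag")
})

test_that("abdominal mixing is linear, role-tagged and reproducible", {
  ev <- with_seed_test(2, generate_rr_series(80, hrv_params(), 30))
  fe <- with_seed_test(3, generate_rr_series(140, hrv_params(0.01, 0.01), 30))
  m <- signal_recording(synthesize_ecg(ev, 900, 30), 900, "mECG", "S1")
  f <- signal_recording(synthesize_ecg(fe, 900, 30), 900, "fECG", "S1")

  a0 <- mix_abdominal(m, f, fetal_attenuation = 0, noise_sd = 0)
  expect_identical(a0$samples, m$samples)
  expect_identical(a0$role, "aECG")

  a2 <- mix_abdominal(m, f, fetal_attenuation = 0.2, noise_sd = 0)
  expect_equal(a2$samples - m$samples, 0.2 * f$samples, tolerance = 1e-15)

  r1 <- with_seed_test(9, mix_abdominal(m, f, 0.2, 0.05))
  r2 <- with_seed_test(9, mix_abdominal(m, f, 0.2, 0.05))
  expect_identical(r1$samples, r2$samples)

  short <- signal_recording(f$samples[1:900], 900, "fECG", "S1")
  expect_error(mix_abdominal(m, short), "durations differ")
})

test_that("mixture residual variance matches the injected noise on 10-min records", {
  ev <- with_seed_test(4, generate_rr_series(80, hrv_params(), 600))
  fe <- with_seed_test(5, generate_rr_series(140, hrv_params(0.01, 0.01), 600))
  m <- signal_recording(synthesize_ecg(ev, 900, 600), 900, "mECG", "S1")
  f <- signal_recording(synthesize_ecg(fe, 900, 600), 900, "fECG", "S1")
  noise_sd <- 0.05
  a <- with_seed_test(6, mix_abdominal(m, f, 0.2, noise_sd))
  resid <- a$samples - m$samples - 0.2 * f$samples
  expect_lt(abs(stats::var(resid) - noise_sd^2) / noise_sd^2, 0.05)
})

test_that("SQI simulation hits the artifact rate and the band convention", {
  rec <- signal_recording(numeric(900 * 50), 900, "mECG")

  all_clean <- with_seed_test(1, simulate_sqi(rec, 0))
  expect_true(all(all_clean$sqi >= 0.5))
  all_bad <- with_seed_test(1, simulate_sqi(rec, 1))
  expect_true(all(all_bad$sqi < 0.5))

  long <- signal_recording(numeric(900 * 1000), 900, "mECG")
  s <- with_seed_test(3, simulate_sqi(long, 0.041))
  frac <- mean(s$sqi < 0.5)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.07)
})

test_that("cohort generation is deterministic and label-consistent", {
  cfg <- cohort_config(n_subjects = 10, stress_prevalence = 0.5,
                       recording_minutes = 1.5, seed = 11)
  ch <- generate_cohort(cfg)
  expect_length(ch$recordings, 10)
  expect_equal(nrow(ch$truth), 10)
  n_str <- sum(ch$truth$group == "stressed")
  expect_gte(n_str, 1); expect_lte(n_str, 9)  # Binomial(10, .5) plausible

  # PSS-10 >= 19 is exactly the stressed group
  expect_identical(ch$truth$group == "stressed", ch$truth$pss >= 19)
  expect_true(all(ch$truth$cortisol > 0))
  expect_true(all(ch$truth$pss >= 0 & ch$truth$pss <= 40))

  ch2 <- generate_cohort(cfg)
  expect_identical(ch$truth, ch2$truth)
  expect_identical(ch$recordings[[3]]$aecg$samples, ch2$recordings[[3]]$aecg$samples)
  expect_identical(ch$recordings[[3]]$aecg$sqi, ch2$recordings[[3]]$aecg$sqi)

  flat <- generate_cohort(cohort_config(n_subjects = 5, stress_prevalence = 0,
                                        recording_minutes = 1, seed = 2))
  expect_true(all(flat$truth$pss < 19))

  expect_error(cohort_config(n_subjects = 1), ">= 2")
  expect_error(cohort_config(n_subjects = 4, stress_prevalence = 1.5), "\\[0, 1\\]")
})
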