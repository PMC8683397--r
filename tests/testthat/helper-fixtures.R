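# Shared fixtures, all generated in code.

# Clean normalized 10-s / 256 Hz ECG windows with varied heart rate.
make_ecg_segments <- function(n, seed = 1) {
  with_seed_test(seed, {
    segs <- matrix(0, n, 2560)
    for (i in seq_len(n)) {
      hr <- stats::runif(1, 65, 95)
      ev <- generate_rr_series(hr, hrv_params(), 11)
      x <- synthesize_ecg(ev, 256, 11)
      segs[i, ] <- normalize_segment(x[1:2560])
    }
    segs
  })
}

# Matched-seed mother/fetus dyad FSI at a given coupling gain.
dyad_fsi <- function(gain, minutes, seed, config = bprsa_config()) {
  with_seed_test(seed, {
    m_ev <- generate_rr_series(80, hrv_params(), minutes * 60)
    m <- heart_rate_series(m_ev, clean = FALSE)
    f_ev <- couple_fetal_rr(m, gain, duration = minutes * 60)
    f <- heart_rate_series(f_ev, clean = FALSE)
    compute_fsi(m, f, config)
  })
}

# set.seed wrapper local to a test (restores RNG state afterwards).
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Tiny encoder configuration for fast network tests.
tiny_encoder_config <- function() {
  encoder_config(input_len = 2560L, widths = c(4L, 6L, 8L),
                 kernels = c(7L, 5L, 3L), pool = 8L, dropout = 0.5)
}

# Small experiment configuration used by orchestration tests.
tiny_experiment_config <- function(seed = 5, ...) {
  experiment_config(
    cohort = cohort_config(n_subjects = 4, recording_minutes = 3, seed = seed),
    approach = "from_scratch", sources = "mECG", tasks = "classify_stress",
    encoder = tiny_encoder_config(),
    pretext_epochs = 1L, pretext_max_segments = 30L,
    head_epochs = 3L, seed = seed, ...
  )
}
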