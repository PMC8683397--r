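# Brute-force oracles, independent of the implementation paths: the
# implementation accumulates whole windows per anchor (or run-compressed
# cumulative sums); the oracle walks offsets and gathers anchor samples.
oracle_prsa <- function(target, anchors, L) {
  X <- numeric(2 * L)
  for (k in seq_len(2 * L)) {
    X[k] <- mean(target[anchors - L + k - 1])
  }
  X
}

oracle_fsi <- function(X, L, S1, S2) {
  a <- 0; b <- 0
  for (i in (L + S1):(L + S2)) a <- a + X[i + 1]  # 0-based index i
  for (i in (L - S2):(L - S1)) b <- b + X[i + 1]
  (a - b) / (S2 - S1)
}

test_that("heart-rate interpolation is linear through the beat values", {
  const <- heart_rate_series(seq(0, 10, by = 60 / 140), clean = FALSE)
  v <- interpolate_target(const, fs = 100, duration = 10)
  expect_length(v, 1000)
  expect_true(all(abs(v - 140) < 1e-9))

  # two intervals: 120 bpm then 150 bpm; midpoint of the second is 135
  s <- heart_rate_series(c(0, 0.5, 0.9), clean = FALSE)
  expect_equal(s$hr_series, c(120, 150))
  v <- interpolate_target(s, fs = 1000, duration = 0.9)
  expect_equal(v[round(0.7 * 1000) + 1], 135, tolerance = 1e-3)

  # values at beat times equal the beat HR
  ev <- with_seed_test(1, generate_rr_series(80, hrv_params(), 60))
  hs <- heart_rate_series(ev, clean = FALSE)
  fs <- 900
  v <- interpolate_target(hs, fs = fs, duration = 60)
  on_grid <- round(hs$peak_times[-1] * fs) / fs  # beat times on the grid
  idx <- round(on_grid * fs) + 1
  ok <- idx <= length(v)
  hr_at_beats <- stats::approx(hs$peak_times[-1], hs$hr_series, on_grid[ok])$y
  expect_lt(max(abs(v[idx[ok]] - hr_at_beats)), 0.05)
})

test_that("anchor detection matches the brute-force decrease scan", {
  cfg <- bprsa_config(L = 50, S1 = 10, S2 = 20, fs = 10)
  expect_error(find_anchors(seq_len(200), cfg), "no anchors")

  dec <- seq(110, by = -0.5, length.out = 110)  # strictly decreasing, 2L+10
  a <- find_anchors(dec, cfg)
  expect_identical(a, 51:60)  # every interior admissible index

  with_seed_test(2, {
    walk <- cumsum(stats::rnorm(400))
    a <- find_anchors(walk, cfg)
    brute <- which(c(FALSE, diff(walk) < 0))
    brute <- brute[brute >= cfg$L + 1 & brute <= length(walk) - cfg$L]
    expect_identical(a, brute)
  })

  expect_error(find_anchors(seq_len(90), cfg), "longer than 2L")
})

test_that("phase-rectified averaging equals the brute-force windowed mean", {
  L <- 50
  with_seed_test(3, {
    target <- stats::rnorm(1000)
    anchors <- sort(sample(L:(1000 - L), 50))
    X <- bprsa_average(target, anchors, L)
    expect_lt(max(abs(X - oracle_prsa(target, anchors, L))), 1e-12)
  })

  # single anchor: exactly that window
  tgt <- sin(seq_len(400) / 10)
  X1 <- bprsa_average(tgt, 200, L)
  expect_identical(X1, tgt[150:249])

  # constant target: constant average
  expect_true(all(bprsa_average(rep(3.5, 400), c(60, 100, 300), L) == 3.5))

  expect_error(bprsa_average(tgt, integer(0), L), "no anchors")
  expect_error(bprsa_average(tgt, 10, L), "full 2L window")
})

test_that("the run-compressed averaging path agrees with direct accumulation", {
  L <- 30
  with_seed_test(4, {
    target <- stats::rnorm(20000)
    # long consecutive runs, > 5000 anchors total, to force the cumsum path
    starts <- sort(sample(seq(L + 1, 19000 - L, by = 400)))
    anchors <- unlist(lapply(starts, function(s) s:(s + 150)))
    anchors <- unique(pmin(anchors, 20000 - L))
    expect_gt(length(anchors), 5000)
    X_fast <- bprsa_average(target, anchors, L)
    X_direct <- oracle_prsa(target, anchors, L)
    expect_lt(max(abs(X_fast - X_direct)), 1e-9)
  })
})

test_that("FSI follows the printed index definition, including the step constant", {
  cfg <- bprsa_config()  # L = 9000, S1 = 1350, S2 = 2250

  expect_equal(fsi(rep(7.3, 18000), cfg), 0)

  step <- c(rep(0, 9000), rep(1, 9000))  # X(i) = 1 for i >= L (0-based)
  expect_equal(fsi(step, cfg), 901 / 900, tolerance = 1e-15)
  # conventional mean normalization available as a config switch
  cfg_mean <- bprsa_config(mean_normalization = TRUE)
  expect_equal(fsi(step, cfg_mean), 1, tolerance = 1e-15)

  with_seed_test(5, {
    X <- stats::rnorm(18000)
    expect_lt(abs(fsi(X, cfg) - oracle_fsi(X, 9000, 1350, 2250)), 1e-12)
  })

  expect_error(bprsa_config(S1 = 2250, S2 = 1350), "invalid config")
  expect_error(bprsa_config(S2 = 9500), "invalid config")
  expect_error(fsi(numeric(100), cfg), "too short")
})

test_that("FSI is linear in X with offset cancellation", {
  cfg <- bprsa_config(L = 100, S1 = 20, S2 = 40, fs = 10)
  with_seed_test(6, {
    X <- stats::rnorm(200)
    f0 <- fsi(X, cfg)
    expect_equal(fsi(3.2 * X + 17, cfg), 3.2 * f0, tolerance = 1e-10)
  })
})

test_that("end-to-end FSI responds to coupling and degenerates correctly", {
  r0 <- dyad_fsi(0, 8, 42)
  r2 <- dyad_fsi(2, 8, 42)
  expect_lt(abs(r0$fsi), abs(r2$fsi))
  expect_gt(r2$n_anchors, 100)
  expect_true(is.finite(r2$fsi))
  expect_length(r2$X, 18000)

  # constant fetal series: FSI exactly 0
  m_ev <- with_seed_test(9, generate_rr_series(80, hrv_params(), 120))
  m <- heart_rate_series(m_ev, clean = FALSE)
  f <- heart_rate_series(seq(0, 120, by = 60 / 140), clean = FALSE)
  expect_equal(compute_fsi(m, f)$fsi, 0)

  short <- heart_rate_series(c(0, 0.5, 1), clean = FALSE)
  expect_error(compute_fsi(short, short), "shorter than the 2L")
})

test_that("monovariate reduction: self-triggered averaging dips at the anchor", {
  # deceleration-triggered average of the trigger itself must step down
  cfg <- bprsa_config(L = 40, S1 = 5, S2 = 15, fs = 10)
  x <- seq(400, 1)  # pure downward trend: every interior index is an anchor
  a <- find_anchors(x, cfg)
  X <- bprsa_average(x, a, cfg$L)
  expect_true(all(diff(X) <= 1e-9))  # X non-increasing around the anchor
  expect_lt(fsi(X, cfg), 0)  # after-anchor mean below before-anchor mean
})
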