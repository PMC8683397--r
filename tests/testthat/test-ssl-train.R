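test_that("backpropagation matches finite-difference gradients", {
  # unit init gain: larger gains saturate the sigmoids, and the resulting
  # ~1e-9 gradients drown the central-difference quotient in cancellation
  cfg <- encoder_config(input_len = 64L, widths = c(3L, 4L, 5L),
                        kernels = c(5L, 3L, 3L), pool = 4L,
                        dropout = 0, n_heads = 2L, init_gain = 1)
  with_seed_test(1, {
    params <- fetalstress:::init_trunk(cfg)
    C3 <- cfg$widths[3]
    params$head.W <- matrix(stats::rnorm(C3 * 2, 0, 0.5), C3, 2)
    params$head.b <- stats::rnorm(2)
    X <- matrix(stats::rnorm(3 * 64), 3, 64)
    Y <- matrix(c(1, 0, 0, 1, 0, 0), 3, 2, byrow = TRUE)

    lossfn <- function(p) {
      f <- fetalstress:::trunk_forward(p, X, cfg, keep_cache = TRUE)
      Z <- sweep(f$features %*% p$head.W, 2, p$head.b, `+`)
      fetalstress:::bce_loss(Z, Y, pos_weight = 2)$loss
    }
    f <- fetalstress:::trunk_forward(params, X, cfg, keep_cache = TRUE)
    Z <- sweep(f$features %*% params$head.W, 2, params$head.b, `+`)
    ls <- fetalstress:::bce_loss(Z, Y, pos_weight = 2)
    grads <- list(head.W = crossprod(f$features, ls$dZ), head.b = colSums(ls$dZ))
    dF <- ls$dZ %*% t(params$head.W)
    grads <- c(grads, fetalstress:::trunk_backward(params, cfg, f$cache, dF))

    eps <- 1e-6
    for (nm in names(grads)) {
      g <- grads[[nm]]
      for (j in sample(seq_along(g), min(5, length(g)))) {
        p_hi <- params; p_hi[[nm]][j] <- p_hi[[nm]][j] + eps
        p_lo <- params; p_lo[[nm]][j] <- p_lo[[nm]][j] - eps
        num <- (lossfn(p_hi) - lossfn(p_lo)) / (2 * eps)
        expect_lt(abs(num - g[j]) / max(1e-8, abs(num) + abs(g[j])), 1e-4)
      }
    }
  })
})

test_that("softmax cross-entropy gradients match finite differences", {
  with_seed_test(2, {
    Z <- matrix(stats::rnorm(12, 0, 2), 3, 4)
    Y <- diag(4)[sample(1:4, 3, replace = TRUE), ]
    ls <- fetalstress:::softmax_ce_loss(Z, Y)
    eps <- 1e-6
    for (j in seq_along(Z)) {
      Zp <- Z; Zp[j] <- Zp[j] + eps
      Zm <- Z; Zm[j] <- Zm[j] - eps
      num <- (fetalstress:::softmax_ce_loss(Zp, Y)$loss -
                fetalstress:::softmax_ce_loss(Zm, Y)$loss) / (2 * eps)
      expect_lt(abs(num - ls$dZ[j]), 1e-6)
    }
    # rows of the implied probabilities sum to 1
    expect_equal(rowSums(ls$P), rep(1, 3), tolerance = 1e-12)
  })
})

test_that("pretext training reduces the loss and is seed-deterministic", {
  segs <- make_ecg_segments(40, seed = 20)
  pre <- build_pretext_dataset(segs, seed = 21)
  cfg <- tiny_encoder_config()

  enc1 <- train_pretext(cfg, pre, epochs = 2, batch_size = 64, seed = 22)
  enc2 <- train_pretext(cfg, pre, epochs = 2, batch_size = 64, seed = 22)
  expect_identical(enc1$loss_log$loss, enc2$loss_log$loss)
  expect_identical(enc1$params, enc2$params)

  ep_means <- tapply(enc1$loss_log$loss, enc1$loss_log$epoch, mean)
  expect_lt(ep_means[length(ep_means)], ep_means[1])
})

test_that("zero learning rate leaves the weights untouched", {
  segs <- make_ecg_segments(8, seed = 23)
  pre <- build_pretext_dataset(segs, seed = 24)
  cfg <- tiny_encoder_config()
  e1 <- train_pretext(cfg, pre, lr = 0, epochs = 1, seed = 25)
  e2 <- train_pretext(cfg, pre, lr = 0, epochs = 3, seed = 25)
  # weights never move from their (seed-determined) initialization
  expect_identical(e1$params, e2$params)
})

test_that("feature extraction is batch-size invariant", {
  segs <- make_ecg_segments(9, seed = 26)
  pre <- build_pretext_dataset(segs[1:4, ], seed = 27)
  enc <- train_pretext(tiny_encoder_config(), pre, epochs = 1, seed = 28)
  f_all <- encoder_features(enc, segs)
  f_split <- encoder_features(enc, segs, batch_size = 2L)
  expect_equal(f_all, f_split, tolerance = 1e-12)
  expect_equal(dim(f_all), c(9L, 8L))
})
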