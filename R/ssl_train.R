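#' Architecture of the transformation-recognition encoder
#'
#' Three convolutional blocks, each holding two same-padded 1-D
#' convolutions with leaky-ReLU activations followed by max pooling; a
#' global max pooling collapses the time axis, and parallel per-head
#' fully connected layers (one per transformation) sit on top during
#' pretext training. Channel widths and kernel sizes are configurable;
#' the defaults are sized for single-CPU training while keeping the
#' block structure fixed.
#'
#' @param input_len Window length in samples (10 s at 256 Hz by default).
#' @param widths Channel width of each of the three blocks.
#' @param kernels Kernel length (odd) of the convolutions in each block.
#' @param pool Max-pooling size applied after each block; `input_len` must
#'   be divisible by `pool^3`.
#' @param leaky Negative slope of the leaky ReLU.
#' @param dropout Dropout rate applied to the pooled feature vector during
#'   pretext head training. Defaults to 0: desk-scale pretext runs are far
#'   from overfitting and feature dropout adds gradient noise exactly where
#'   the short training must calibrate the heads (the affect stage keeps
#'   its own dropout).
#' @param n_heads Number of parallel binary heads (one per transformation).
#' @param init_gain Multiplier on the He initialization scale of the
#'   convolution weights. Values above 1 enlarge the pooled features and
#'   with them the logit growth per fixed-size Adam step, which is what
#'   makes very short pretext trainings converge reliably.
#' @param head_type Pretext objective: `"softmax"` (default) treats the
#'   seven variants (original + six transformations) as one multiclass
#'   problem — recognition then depends only on relative logits, which
#'   short trainings calibrate reliably; `"binary"` uses parallel
#'   per-transformation sigmoid heads with summed binary cross-entropy and
#'   a positive-class weight.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(input_len = 2560L, widths = c(16L, 32L, 64L),
                           kernels = c(11L, 7L, 5L), pool = 8L,
                           leaky = 0.1, dropout = 0, n_heads = 6L,
                           init_gain = 1.5,
                           head_type = c("softmax", "binary")) {
  head_type <- match.arg(head_type)
  if (length(widths) != 3L || length(kernels) != 3L) {
    stop_invalid("the trunk has exactly 3 blocks: `widths` and `kernels` need 3 entries")
  }
  if (any(widths < 1L)) stop_invalid("`widths` must be positive")
  if (any(kernels %% 2L == 0L)) stop_invalid("`kernels` must be odd (same-padding)")
  if (input_len %% pool^3 != 0L) {
    stop_invalid("`input_len` (%d) must be divisible by pool^3 = %d", input_len, pool^3)
  }
  if (!is_scalar_number(init_gain) || init_gain <= 0) {
    stop_invalid("`init_gain` must be positive")
  }
  structure(list(input_len = as.integer(input_len),
                 widths = as.integer(widths), kernels = as.integer(kernels),
                 pool = as.integer(pool), leaky = leaky, dropout = dropout,
                 n_heads = as.integer(n_heads), init_gain = init_gain,
                 head_type = head_type),
            class = "encoder_config")
}

#' Train the transformation-recognition network (pretext stage)
#'
#' Multi-task training of the transformation-recognition objective. With
#' the default `"softmax"` head the seven variants (original plus six
#' transformations) form one multiclass problem over a single linear layer
#' on the pooled features; recognition depends only on relative logits,
#' which even very short trainings calibrate reliably. With the
#' `"binary"` head type, `n_heads` parallel sigmoid heads are optimized
#' with summed binary cross-entropy, the positive class up-weighted by
#' `pos_weight` (default 6: one positive per seven stacked rows per head).
#'
#' @param config An [encoder_config()].
#' @param pretext A [build_pretext_dataset()] result (or any list with
#'   `inputs` and 0/1 `labels` of matching rows).
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 128).
#' @param epochs Number of passes over the pretext rows.
#' @param seed RNG seed for weight initialization, batch order and dropout.
#' @param pos_weight Positive-class weight in the per-head loss (binary
#'   head type only).
#' @param verbose Print the mean loss per epoch.
#' @return An object of class `encoder_state`: `config`, `params` (trunk
#'   weights), `head` (per-head weight matrix and bias), `loss_log` (one
#'   row per step), `seed`.
#' @export
train_pretext <- function(config, pretext, lr = 0.001, batch_size = 128L,
                          epochs = 2L, seed = 1L,
                          pos_weight = 6, verbose = FALSE) {
  stopifnot(inherits(config, "encoder_config"))
  X <- pretext$inputs
  Y <- pretext$labels
  if (is.null(X) || nrow(X) == 0L) stop_invalid("empty pretext dataset")
  if (ncol(X) != config$input_len) {
    stop_invalid("pretext windows have %d samples, config expects %d",
                 ncol(X), config$input_len)
  }
  if (ncol(Y) != config$n_heads) {
    stop_invalid("label matrix has %d heads, config expects %d", ncol(Y), config$n_heads)
  }
  C3 <- config$widths[3L]
  softmax_head <- identical(config$head_type, "softmax")
  n_out <- if (softmax_head) config$n_heads + 1L else config$n_heads
  if (softmax_head) {
    # class 1 is the untransformed original; classes 2..n follow head order
    Y <- cbind(1 - rowSums(Y), Y)
  }

  with_seed(seed, {
    params <- init_trunk(config)
    # near-zero head init: the max-pooled features are unnormalized, so a
    # generic init saturates the output nonlinearity and stalls short trainings
    params$head.W <- matrix(stats::rnorm(C3 * n_out, 0, 0.01), C3, n_out)
    params$head.b <- numeric(n_out)
    opt <- adam_init(params)
    steps <- list()
    step <- 0L

    for (ep in seq_len(epochs)) {
      ord <- sample.int(nrow(X))
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      ep_loss <- numeric(0)
      for (idx in batches) {
        step <- step + 1L
        xb <- X[idx, , drop = FALSE]
        yb <- Y[idx, , drop = FALSE]
        fwd <- trunk_forward(params, xb, config, keep_cache = TRUE)
        Fd <- fwd$features
        if (config$dropout > 0) {
          mask <- matrix(stats::runif(length(Fd)) >= config$dropout,
                         nrow(Fd), ncol(Fd)) / (1 - config$dropout)
          Fd <- Fd * mask
        } else {
          mask <- NULL
        }
        Z <- sweep(Fd %*% params$head.W, 2L, params$head.b, `+`)
        loss <- if (softmax_head) softmax_ce_loss(Z, yb) else
          bce_loss(Z, yb, pos_weight)
        if (!is.finite(loss$loss)) stop_invalid("training diverged: non-finite loss")
        ep_loss <- c(ep_loss, loss$loss)
        steps[[step]] <- c(epoch = ep, step = step, loss = loss$loss)

        grads <- list(head.W = crossprod(Fd, loss$dZ),
                      head.b = colSums(loss$dZ))
        dF <- loss$dZ %*% t(params$head.W)
        if (!is.null(mask)) dF <- dF * mask
        grads <- c(grads, trunk_backward(params, config, fwd$cache, dF))
        upd <- adam_step(params, grads, opt, lr)
        params <- upd$params
        opt <- upd$state
      }
      if (verbose) {
        message(sprintf("epoch %d/%d  mean loss %.4f", ep, epochs, mean(ep_loss)))
      }
    }

    structure(list(config = config, params = params,
                   loss_log = as.data.frame(do.call(rbind, steps)),
                   seed = seed, pos_weight = pos_weight),
              class = "encoder_state")
  })
}

#' @export
print.encoder_state <- function(x, ...) {
  cat(sprintf("<encoder_state> widths %s | %d training steps | final loss %.4f\n",
              paste(x$config$widths, collapse = "/"),
              nrow(x$loss_log),
              if (nrow(x$loss_log)) x$loss_log$loss[nrow(x$loss_log)] else NA_real_))
  invisible(x)
}

#' Frozen-trunk feature extraction
#'
#' Runs windows through the trained convolutional trunk (no dropout) and
#' returns the globally max-pooled feature vectors. This is the
#' representation transferred to the affect-recognition stage.
#'
#' @param encoder An [train_pretext()] result.
#' @param segments Numeric matrix, one window per row.
#' @param batch_size Windows per forward batch (memory control only).
#' @return Feature matrix, `nrow(segments)` x `widths[3]`.
#' @export
encoder_features <- function(encoder, segments, batch_size = 256L) {
  stopifnot(inherits(encoder, "encoder_state"))
  if (!is.matrix(segments)) segments <- matrix(segments, nrow = 1L)
  n <- nrow(segments)
  out <- matrix(0, n, encoder$config$widths[3L])
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    e <- min(n, s + batch_size - 1L)
    out[s:e, ] <- trunk_forward(encoder$params, segments[s:e, , drop = FALSE],
                                encoder$config)$features
  }
  out
}

#' Per-head predictions of the pretext network
#'
#' @param encoder An [train_pretext()] result.
#' @param segments Matrix of (transformed) windows.
#' @return Matrix of class probabilities: for the softmax head an
#'   `"original"` column followed by one column per transformation (rows
#'   sum to 1); for binary heads one independent sigmoid probability per
#'   transformation.
#' @export
predict_pretext <- function(encoder, segments) {
  Fd <- encoder_features(encoder, segments)
  Z <- sweep(Fd %*% encoder$params$head.W, 2L, encoder$params$head.b, `+`)
  if (identical(encoder$config$head_type, "binary")) {
    P <- sigmoid(Z)
    colnames(P) <- transform_kinds()[seq_len(ncol(P))]
  } else {
    P <- softmax_probs(Z)
    colnames(P) <- c("original", transform_kinds()[seq_len(ncol(P) - 1L)])
  }
  P
}

#' Held-out per-head recognition accuracy of a pretext encoder
#'
#' For the softmax head, a row's predicted variant is the argmax class and
#' head `k`'s accuracy is the agreement between "predicted as `k`" and the
#' 0/1 label of head `k`; for binary heads the per-head sigmoid is
#' thresholded at 0.5.
#'
#' @param encoder An [train_pretext()] result.
#' @param pretext A [build_pretext_dataset()] result (held-out windows).
#' @return Named numeric vector of per-transformation accuracies.
#' @export
pretext_accuracy <- function(encoder, pretext) {
  P <- predict_pretext(encoder, pretext$inputs)
  kinds <- colnames(pretext$labels)
  if (identical(encoder$config$head_type, "binary")) {
    acc <- vapply(kinds, function(k) {
      mean((P[, k] >= 0.5) == (pretext$labels[, k] == 1))
    }, numeric(1))
  } else {
    pred <- max.col(P)
    acc <- vapply(seq_along(kinds), function(k) {
      mean((pred == k + 1L) == (pretext$labels[, kinds[k]] == 1))
    }, numeric(1))
    names(acc) <- kinds
  }
  acc
}
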