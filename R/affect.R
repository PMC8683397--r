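#' Affect-recognition tasks
#' @return Character vector of supported task names.
#' @export
affect_tasks <- function() {
  c("classify_stress", "regress_cortisol", "regress_fsi", "regress_pdq", "regress_pss")
}

#' Build an affect model on top of a frozen encoder trunk
#'
#' The convolutional trunk of the transformation-recognition network is
#' transferred as-is and kept frozen; only a small fully connected head
#' (hidden layer + linear output, dropout on the hidden layer) is
#' trainable. Classification heads emit a probability through a sigmoid;
#' regression heads emit one real value on the standardized target scale
#' (inverse-transformed by [predict()]).
#'
#' @param encoder An [train_pretext()] result (trained `encoder_state`).
#' @param task One of [affect_tasks()].
#' @param hidden Width of the fully connected hidden layer.
#' @param dropout Dropout rate on the hidden layer during training.
#' @param seed RNG seed for head initialization.
#' @return An object of class `affect_model`.
#' @export
build_affect_model <- function(encoder, task = affect_tasks(), hidden = 128L,
                               dropout = 0.5, seed = 1L) {
  stopifnot(inherits(encoder, "encoder_state"))
  task <- match.arg(task)
  C3 <- encoder$config$widths[3L]
  head <- with_seed(seed, list(
    W1 = matrix(stats::rnorm(C3 * hidden, 0, sqrt(2 / C3)), C3, hidden),
    b1 = numeric(hidden),
    W2 = matrix(stats::rnorm(hidden, 0, sqrt(1 / hidden)), hidden, 1L),
    b2 = 0
  ))
  structure(list(trunk = encoder, head = head, task = task,
                 hidden = as.integer(hidden), dropout = dropout,
                 leaky = encoder$config$leaky,
                 target_center = 0, target_scale = 1, trained = FALSE),
            class = "affect_model")
}

#' @export
print.affect_model <- function(x, ...) {
  cat(sprintf("<affect_model> task %s | frozen trunk (%s) | head %d -> %d -> 1 | %s\n",
              x$task, paste(x$trunk$config$widths, collapse = "/"),
              x$trunk$config$widths[3L], x$hidden,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

head_forward <- function(model, Fd, dropout_mask = NULL) {
  H <- sweep(Fd %*% model$head$W1, 2L, model$head$b1, `+`)
  act <- leaky_forward(H, model$leaky)
  Hd <- act$Y
  if (!is.null(dropout_mask)) Hd <- Hd * dropout_mask
  z <- as.vector(Hd %*% model$head$W2) + model$head$b2
  list(z = z, H = Hd, neg = act$neg)
}

#' Train the affect head on a segment dataset
#'
#' The trunk stays frozen (bit-identical weights before and after);
#' only the fully connected head is optimized with Adam. Stress
#' classification minimizes binary cross-entropy on segment-level group
#' labels; biomarker regression minimizes mean absolute error on the
#' subject's value broadcast to its segments, with the target z-scored on
#' the training rows for conditioning and inverse-transformed at
#' prediction time.
#'
#' @param model An [build_affect_model()] result.
#' @param dataset A [build_segment_dataset()] result.
#' @param indices Optional row indices restricting training to a subset
#'   (e.g. the training folds).
#' @param features Optional precomputed [encoder_features()] matrix for
#'   all dataset rows (avoids recomputing the frozen trunk across folds).
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size Mini-batch size (default 128).
#' @param epochs Passes over the training rows; `0` returns the model
#'   unchanged.
#' @param seed RNG seed for batch order and dropout.
#' @return The trained `affect_model` (with `training_log`).
#' @export
train_affect <- function(model, dataset, indices = NULL, features = NULL,
                         lr = 0.001, batch_size = 128L, epochs = 30L,
                         seed = 1L) {
  stopifnot(inherits(model, "affect_model"), inherits(dataset, "segment_dataset"))
  if (is.null(indices)) indices <- seq_len(nrow(dataset$segments))
  y <- segment_labels(dataset, model$task)[indices]
  classify <- model$task == "classify_stress"
  if (classify && length(unique(y)) < 2L) {
    stop_invalid("degenerate labels: training set holds a single class")
  }
  if (!classify) {
    model$target_center <- mean(y)
    model$target_scale <- stats::sd(y)
    if (!is.finite(model$target_scale) || model$target_scale < 1e-12) {
      model$target_scale <- 1
    }
    y <- (y - model$target_center) / model$target_scale
  }
  if (epochs == 0L) {
    model$trained <- TRUE
    return(model)
  }
  Fd_all <- if (is.null(features)) {
    encoder_features(model$trunk, dataset$segments[indices, , drop = FALSE])
  } else {
    features[indices, , drop = FALSE]
  }

  with_seed(seed, {
    head <- model$head
    opt <- adam_init(head)
    log_rows <- list(); step <- 0L
    n <- nrow(Fd_all)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / batch_size))
      for (idx in batches) {
        step <- step + 1L
        Fd <- Fd_all[idx, , drop = FALSE]
        yb <- y[idx]
        mask <- if (model$dropout > 0) {
          matrix(stats::runif(length(idx) * model$hidden) >= model$dropout,
                 length(idx), model$hidden) / (1 - model$dropout)
        } else NULL
        tmp_model <- model; tmp_model$head <- head
        fw <- head_forward(tmp_model, Fd, mask)
        if (classify) {
          ls <- bce_loss(matrix(fw$z, ncol = 1L), matrix(yb, ncol = 1L))
          dz <- as.vector(ls$dZ)
        } else {
          ls <- mae_loss(fw$z, yb)
          dz <- ls$dpred
        }
        if (!is.finite(ls$loss)) stop_invalid("training diverged: non-finite loss")
        log_rows[[step]] <- c(epoch = ep, step = step, loss = ls$loss)
        dH <- outer(dz, as.vector(head$W2))
        if (!is.null(mask)) dH <- dH * mask
        dH <- leaky_backward(dH, fw$neg, model$leaky)
        grads <- list(
          W1 = crossprod(Fd, dH),
          b1 = colSums(dH),
          W2 = crossprod(fw$H, matrix(dz, ncol = 1L)),
          b2 = sum(dz)
        )
        upd <- adam_step(head, grads, opt, lr)
        head <- upd$params
        opt <- upd$state
      }
    }
    model$head <- head
    model$training_log <- as.data.frame(do.call(rbind, log_rows))
    model$trained <- TRUE
    model
  })
}

#' Per-segment predictions of an affect model
#'
#' @param object A trained `affect_model`.
#' @param segments Matrix of normalized windows, or `NULL` when
#'   `features` is given.
#' @param features Optional precomputed trunk features.
#' @param ... Unused.
#' @return Numeric vector: probabilities in \[0, 1\] for classification,
#'   original-scale values for regression.
#' @export
predict.affect_model <- function(object, segments = NULL, features = NULL, ...) {
  Fd <- if (is.null(features)) {
    if (is.null(segments)) stop_invalid("supply `segments` or `features`")
    encoder_features(object$trunk, segments)
  } else features
  z <- head_forward(object, Fd)$z
  if (object$task == "classify_stress") {
    sigmoid(z)
  } else {
    z * object$target_scale + object$target_center
  }
}

#' Aggregate segment predictions to one score per subject
#'
#' The subject score is the mean of its segment predictions; invariant to
#' segment order and to duplicating identical segments in equal
#' proportion.
#'
#' @param predictions Numeric vector of per-segment predictions.
#' @param subject_ids Character vector aligned with `predictions`.
#' @return Named numeric vector, one entry per subject (sorted by id).
#' @export
aggregate_subject <- function(predictions, subject_ids) {
  if (length(predictions) != length(subject_ids)) {
    stop_invalid("`predictions` and `subject_ids` lengths differ")
  }
  out <- tapply(predictions, subject_ids, mean)
  stats::setNames(as.numeric(out), dimnames(out)[[1L]])
}
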