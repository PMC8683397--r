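#' Within-subject k-fold split of a segment dataset
#'
#' Each subject's segments are partitioned into `k` near-equal parts
#' (sizes differing by at most one); fold `j`'s test set is the union of
#' part `j` across subjects. This is the split protocol of the analysis
#' the package reimplements: every subject contributes segments to both
#' the training and the test side of each fold, so fold metrics estimate
#' within-subject performance, not generalization to new subjects (see
#' `subject_wise` for the honest alternative).
#'
#' @param dataset A [build_segment_dataset()] result.
#' @param k Number of folds (default 5).
#' @param seed RNG seed for the random partition.
#' @param contiguous If `TRUE`, each subject's parts are contiguous blocks
#'   of its segment sequence instead of a random partition.
#' @param subject_wise If `TRUE`, whole subjects are assigned to folds
#'   (leakage-free split; not the published protocol).
#' @return An object of class `fold_split`: integer `fold` per segment row
#'   (`NA` for rows of dropped subjects) and a list `test_indices`.
#'   Subjects with fewer than `k` segments are dropped with a warning.
#' @export
make_within_subject_folds <- function(dataset, k = 5L, seed = 1L,
                                      contiguous = FALSE, subject_wise = FALSE) {
  stopifnot(inherits(dataset, "segment_dataset"))
  n <- nrow(dataset$segments)
  fold <- rep(NA_integer_, n)
  with_seed(seed, {
    if (subject_wise) {
      subj <- unique(dataset$subject_id)
      sfold <- sample(rep_len(seq_len(k), length(subj)))
      fold <- sfold[match(dataset$subject_id, subj)]
    } else {
      for (s in unique(dataset$subject_id)) {
        idx <- which(dataset$subject_id == s)
        m <- length(idx)
        if (m < k) {
          warning(sprintf("subject %s has %d < %d segments: dropped from folds", s, m, k))
          next
        }
        parts <- rep_len(seq_len(k), m)       # sizes differ by <= 1
        if (contiguous) {
          parts <- sort(parts)
        } else {
          parts <- sample(parts)
        }
        fold[idx] <- parts
      }
    }
  })
  if (all(is.na(fold))) stop_invalid("no subject has enough segments for %d folds", k)
  structure(list(fold = fold, k = k,
                 test_indices = lapply(seq_len(k), function(j) which(fold == j))),
            class = "fold_split")
}

#' Classification metric panel
#'
#' Confusion-matrix metrics at a fixed probability threshold plus AUROC
#' computed from the rank statistic (the Mann-Whitney U normalization,
#' tie-aware).
#'
#' @param y_true 0/1 vector of true labels.
#' @param y_score Probability (or score) vector.
#' @param threshold Decision threshold on the score (default 0.5).
#' @return Named list: `accuracy`, `f1`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `auroc`.
#' @export
classification_metrics <- function(y_true, y_score, threshold = 0.5) {
  if (length(y_true) != length(y_score)) stop_invalid("length mismatch")
  y_true <- as.numeric(y_true)
  if (!all(y_true %in% c(0, 1))) stop_invalid("`y_true` must be 0/1")
  np <- sum(y_true == 1); nn <- sum(y_true == 0)
  if (np == 0 || nn == 0) stop_invalid("AUROC undefined: single-class labels")
  pred <- as.numeric(y_score >= threshold)
  tp <- sum(pred == 1 & y_true == 1); fp <- sum(pred == 1 & y_true == 0)
  tn <- sum(pred == 0 & y_true == 0); fn <- sum(pred == 0 & y_true == 1)
  divz <- function(a, b) if (b == 0) NA_real_ else a / b
  r <- rank(y_score)
  auroc <- (sum(r[y_true == 1]) - np * (np + 1) / 2) / (np * nn)
  prec <- divz(tp, tp + fp)
  sens <- divz(tp, tp + fn)
  list(
    accuracy = (tp + tn) / length(y_true),
    f1 = if (is.na(prec) || is.na(sens) || (prec + sens) == 0) 0 else
      2 * prec * sens / (prec + sens),
    sensitivity = sens,
    specificity = divz(tn, tn + fp),
    ppv = prec,
    npv = divz(tn, tn + fn),
    auroc = auroc
  )
}

#' Regression metric panel
#'
#' @param y_true,y_pred Numeric vectors.
#' @return Named list: `r2` (1 - SS_res/SS_tot), `mae`, `rmse`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_invalid("length mismatch")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot < 1e-24) stop_invalid("R2 undefined: constant `y_true`")
  res <- y_true - y_pred
  list(r2 = 1 - sum(res^2) / ss_tot,
       mae = mean(abs(res)),
       rmse = sqrt(mean(res^2)))
}

#' Compare two fold-metric vectors (exact Mann-Whitney U, Holm-adjusted)
#'
#' Two-sided exact Mann-Whitney U test on the per-fold metric values of
#' two models, with the significance criterion adjusted for the stated
#' number of comparisons in the family: the Bonferroni-Holm first step,
#' i.e. significance requires `p < alpha / n_comparisons`. The exact
#' distribution is used because fold counts are tiny (the normal
#' approximation is poor at n = 5); if ties prevent an exact p-value the
#' tie-corrected normal approximation is used with a warning.
#'
#' @param metrics_a,metrics_b Equal-length numeric vectors of per-fold
#'   metric values.
#' @param n_comparisons Size of the comparison family (default 2).
#' @param alpha Family-wise significance level (default 0.05).
#' @return List with `U`, `p`, `significant`, `criterion`.
#' @export
compare_fold_metrics <- function(metrics_a, metrics_b, n_comparisons = 2L,
                                 alpha = 0.05) {
  if (length(metrics_a) != length(metrics_b)) stop_invalid("fold vectors differ in length")
  if (length(metrics_a) < 3L) stop_invalid("insufficient folds: need >= 3")
  if (identical(as.numeric(metrics_a), as.numeric(metrics_b))) {
    crit <- alpha / n_comparisons
    return(list(U = length(metrics_a)^2 / 2, p = 1, significant = FALSE,
                criterion = crit))
  }
  wt <- suppressWarnings(stats::wilcox.test(metrics_a, metrics_b,
                                            exact = TRUE, correct = FALSE))
  crit <- alpha / n_comparisons
  list(U = unname(wt$statistic), p = wt$p.value,
       significant = wt$p.value < crit, criterion = crit)
}

# Run one task (classification or one regression) through the fold split,
# training an affect head per fold on the training rows and scoring the
# test rows. Returns per-fold metric rows plus subject-level aggregates.
evaluate_task <- function(encoder, dataset, task, folds, features,
                          head_epochs = 30L, lr = 0.001, batch_size = 128L,
                          seed = 1L) {
  k <- folds$k
  seg_y <- segment_labels(dataset, task)
  per_fold <- vector("list", k)
  subj_rows <- vector("list", k)
  for (j in seq_len(k)) {
    test_idx <- folds$test_indices[[j]]
    train_idx <- which(!is.na(folds$fold) & folds$fold != j)
    model <- build_affect_model(encoder, task, seed = derive_seed(seed, j))
    model <- train_affect(model, dataset, indices = train_idx,
                          features = features, lr = lr,
                          batch_size = batch_size, epochs = head_epochs,
                          seed = derive_seed(seed, 100 + j))
    pred <- predict(model, features = features[test_idx, , drop = FALSE])
    if (task == "classify_stress") {
      per_fold[[j]] <- c(fold = j,
                         unlist(classification_metrics(seg_y[test_idx], pred)))
    } else {
      per_fold[[j]] <- c(fold = j,
                         unlist(regression_metrics(seg_y[test_idx], pred)))
    }
    agg_p <- aggregate_subject(pred, dataset$subject_id[test_idx])
    agg_y <- aggregate_subject(seg_y[test_idx], dataset$subject_id[test_idx])
    subj_rows[[j]] <- data.frame(fold = j, subject_id = names(agg_p),
                                 truth = as.numeric(agg_y),
                                 score = as.numeric(agg_p),
                                 stringsAsFactors = FALSE)
  }
  list(fold_metrics = as.data.frame(do.call(rbind, per_fold)),
       subject_scores = do.call(rbind, subj_rows))
}
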