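#' Write / read a cohort signal container
#'
#' Recordings are stored losslessly (samples, sampling rate, role, subject
#' id, SQI) in a single-file container holding the serialized object plus a
#' format version. CSV import/export of single recordings is provided for
#' interoperability with beat-level tooling.
#'
#' @param recordings A list of [signal_recording()]s (possibly nested, as
#'   produced by [generate_cohort()]).
#' @param path Container file path.
#' @return `write_signal_container` returns `path` invisibly;
#'   `read_signal_container` returns the recordings.
#' @export
write_signal_container <- function(recordings, path) {
  saveRDS(list(format = "fetalstress-container", version = 1L,
               recordings = recordings), path)
  invisible(path)
}

#' @rdname write_signal_container
#' @export
read_signal_container <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || !identical(obj$format, "fetalstress-container")) {
    stop_invalid("not a fetalstress signal container: %s", path)
  }
  obj$recordings
}

#' Export / import a single recording as plain-text CSV
#'
#' One `sample` column; sampling rate, role and subject id are carried in
#' `#key=value` header comment lines. A file without an `fs` header is
#' rejected.
#'
#' @param recording A [signal_recording()].
#' @param path CSV file path.
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns a [signal_recording()] (SQI defaults to
#'   clean).
#' @export
write_recording_csv <- function(recording, path) {
  stopifnot(inherits(recording, "signal_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#fs=%.10g", recording$fs),
               sprintf("#role=%s", recording$role),
               sprintf("#subject=%s", recording$subject_id),
               "sample"), con)
  writeLines(format(recording$samples, digits = 17, trim = TRUE, scientific = FALSE), con)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path) {
  lines <- readLines(path, n = 10L)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(sprintf("^#%s=", key), hdr, value = TRUE)
    if (length(m) == 0L) return(NULL)
    sub(sprintf("^#%s=", key), "", m[1L])
  }
  fs <- get_field("fs")
  if (is.null(fs)) stop_invalid("format error: missing #fs= header in %s", path)
  fs <- as.numeric(fs)
  if (!is.finite(fs) || fs <= 0) stop_invalid("format error: invalid fs in %s", path)
  role <- get_field("role"); if (is.null(role)) role <- "mECG"
  subject <- get_field("subject"); if (is.null(subject)) subject <- "S1"
  df <- utils::read.csv(path, comment.char = "#")
  signal_recording(df$sample, fs, role = role, subject_id = subject)
}

#' Full experiment configuration
#'
#' Bundles every stage's parameters with the defaults of the analysis the
#' package reimplements: SQI threshold 0.5, model rate 256 Hz, 10-s
#' windows, Adam with learning rate 0.001 and batch size 128, and
#' within-subject 5-fold evaluation. Two training approaches are
#' supported: `"from_scratch"` pretext-trains on the evaluation cohort's
#' own segments; `"transfer"` pretext-trains on an independent synthetic
#' corpus (standing in for public ECG corpora) and transfers the frozen
#' trunk.
#'
#' @param cohort A [cohort_config()] for the evaluation cohort.
#' @param approach `"from_scratch"`, `"transfer"`, or both.
#' @param sources Channels to analyze: subset of `c("mECG", "aECG")`.
#' @param tasks Subset of [affect_tasks()].
#' @param sqi_threshold,target_fs,window_s Preprocessing parameters.
#' @param encoder An [encoder_config()].
#' @param transforms A [transform_specs()].
#' @param pretext_lr,pretext_batch,pretext_epochs Pretext-stage training
#'   hyper-parameters.
#' @param pretext_max_segments Cap on the number of evaluation-cohort
#'   windows entering pretext training (each yields 7 pretext rows).
#' @param head_lr,head_batch,head_epochs Affect-head training
#'   hyper-parameters.
#' @param k Number of evaluation folds.
#' @param transfer_cohort Optional [cohort_config()] for the independent
#'   pretraining corpus; defaults to a copy of `cohort` with a different
#'   seed.
#' @param seed Master seed; all stage seeds are derived from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(cohort,
                              approach = c("from_scratch", "transfer"),
                              sources = c("mECG", "aECG"),
                              tasks = affect_tasks(),
                              sqi_threshold = 0.5, target_fs = 256, window_s = 10,
                              encoder = encoder_config(),
                              transforms = transform_specs(),
                              pretext_lr = 0.001, pretext_batch = 128L,
                              pretext_epochs = 4L, pretext_max_segments = 320L,
                              head_lr = 0.001, head_batch = 128L,
                              head_epochs = 80L,
                              k = 5L, transfer_cohort = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"))
  approach <- match.arg(approach, several.ok = TRUE)
  sources <- match.arg(sources, c("mECG", "aECG"), several.ok = TRUE)
  tasks <- match.arg(tasks, affect_tasks(), several.ok = TRUE)
  if (is.null(transfer_cohort) && "transfer" %in% approach) {
    transfer_cohort <- cohort
    transfer_cohort$seed <- derive_seed(cohort$seed, 7919)
  }
  structure(as.list(environment()), class = "experiment_config")
}

#' Run the end-to-end stress-detection experiment
#'
#' Generates (or accepts) a synthetic cohort, preprocesses the requested
#' channels, trains the transformation-recognition encoder per approach,
#' then trains and evaluates the affect heads under the within-subject
#' k-fold protocol, producing the classification and regression metric
#' panels.
#'
#' @param config An [experiment_config()].
#' @param cohort Optional pre-generated [generate_cohort()] result
#'   (matching `config$cohort`); generated when `NULL`.
#' @param verbose Print stage progress.
#' @return An object of class `experiment_report`: `classification` and
#'   `regression` summary data frames (mean and sd over folds),
#'   `fold_metrics` (full per-fold rows), `subject_scores`,
#'   `pretext_loss`, `encoder_checksums`, `discarded_sqi`, and `config`.
#' @export
run_experiment <- function(config, cohort = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating cohort (%d subjects, %.1f min)...",
      config$cohort$n_subjects, config$cohort$recording_minutes)
  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)

  datasets <- lapply(config$sources, function(src) {
    say("preprocessing %s...", src)
    build_segment_dataset(cohort, role = src,
                          sqi_threshold = config$sqi_threshold,
                          target_fs = config$target_fs,
                          window_s = config$window_s)
  })
  names(datasets) <- config$sources

  pick_pretext_rows <- function(segments, seed) {
    n <- nrow(segments)
    m <- min(n, config$pretext_max_segments)
    idx <- with_seed(seed, sample.int(n, m))
    segments[idx, , drop = FALSE]
  }

  train_encoder <- function(segments, seed, label) {
    say("pretext training (%s, %d windows x 7 variants)...", label, nrow(segments))
    pre <- build_pretext_dataset(segments, config$transforms,
                                 seed = derive_seed(seed, 1))
    train_pretext(config$encoder, pre, lr = config$pretext_lr,
                  batch_size = config$pretext_batch,
                  epochs = config$pretext_epochs,
                  seed = derive_seed(seed, 2))
  }

  encoders <- list()
  if ("from_scratch" %in% config$approach) {
    encoders$from_scratch <- lapply(config$sources, function(src) {
      train_encoder(pick_pretext_rows(datasets[[src]]$segments,
                                      derive_seed(config$seed, 11)),
                    derive_seed(config$seed, 20 + match(src, config$sources)),
                    paste("from_scratch", src))
    })
    names(encoders$from_scratch) <- config$sources
  }
  if ("transfer" %in% config$approach) {
    say("generating independent pretraining corpus...")
    tc <- generate_cohort(config$transfer_cohort)
    tds <- build_segment_dataset(tc, role = "mECG",
                                 sqi_threshold = config$sqi_threshold,
                                 target_fs = config$target_fs,
                                 window_s = config$window_s)
    enc <- train_encoder(pick_pretext_rows(tds$segments,
                                           derive_seed(config$seed, 12)),
                         derive_seed(config$seed, 30), "transfer")
    encoders$transfer <- stats::setNames(
      rep(list(enc), length(config$sources)), config$sources)
  }

  fold_rows <- list(); subj_rows <- list()
  for (app in names(encoders)) {
    for (src in config$sources) {
      enc <- encoders[[app]][[src]]
      ds <- datasets[[src]]
      say("evaluating %s / %s...", app, src)
      features <- encoder_features(enc, ds$segments)
      folds <- make_within_subject_folds(ds, k = config$k,
                                         seed = derive_seed(config$seed, 40))
      for (task in config$tasks) {
        res <- evaluate_task(enc, ds, task, folds, features,
                             head_epochs = config$head_epochs,
                             lr = config$head_lr,
                             batch_size = config$head_batch,
                             seed = derive_seed(config$seed,
                                                50 + match(task, affect_tasks())))
        fm <- res$fold_metrics
        fm$approach <- app; fm$source <- src; fm$task <- task
        fold_rows[[length(fold_rows) + 1L]] <- fm
        ss <- res$subject_scores
        ss$approach <- app; ss$source <- src; ss$task <- task
        subj_rows[[length(subj_rows) + 1L]] <- ss
      }
    }
  }

  fold_metrics <- do.call(rbind_fill, fold_rows)
  summarize <- function(task_filter, cols) {
    rows <- fold_metrics[fold_metrics$task %in% task_filter, , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    out <- list()
    for (app in unique(rows$approach)) for (src in unique(rows$source)) {
      for (task in unique(rows$task)) {
        sel <- rows$approach == app & rows$source == src & rows$task == task
        if (!any(sel)) next
        stats_row <- c(list(approach = app, source = src, task = task),
                       as.list(unlist(lapply(cols, function(cl) {
                         v <- rows[[cl]][sel]
                         stats::setNames(c(mean(v), stats::sd(v)),
                                         paste0(cl, c("_mean", "_sd")))
                       }))))
        out[[length(out) + 1L]] <- as.data.frame(stats_row, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  }

  cls_cols <- c("accuracy", "f1", "sensitivity", "specificity", "ppv", "npv", "auroc")
  reg_cols <- c("r2", "mae", "rmse")
  report <- structure(list(
    classification = summarize("classify_stress", cls_cols),
    regression = summarize(setdiff(config$tasks, "classify_stress"), reg_cols),
    fold_metrics = fold_metrics,
    subject_scores = do.call(rbind, subj_rows),
    pretext_loss = lapply(encoders, function(e) lapply(e, function(x) x$loss_log)),
    encoder_checksums = lapply(encoders, function(e)
      vapply(e, function(x) weight_checksum(x$params), numeric(1))),
    discarded_sqi = vapply(datasets, function(d) mean(d$discarded), numeric(1)),
    config = config
  ), class = "experiment_report")
  report
}

# rbind data frames whose column sets differ (classification vs regression).
rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[cols]
  }))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  if (!is.null(x$classification)) {
    cat("\nStress classification (mean +/- sd over folds):\n")
    df <- x$classification
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %-12s %-5s acc %.3f+/-%.3f  F1 %.3f+/-%.3f  AUROC %.3f+/-%.3f\n",
                  df$approach[i], df$source[i],
                  df$accuracy_mean[i], df$accuracy_sd[i],
                  df$f1_mean[i], df$f1_sd[i],
                  df$auroc_mean[i], df$auroc_sd[i]))
    }
  }
  if (!is.null(x$regression)) {
    cat("\nBiomarker regression (mean +/- sd over folds):\n")
    df <- x$regression
    for (i in seq_len(nrow(df))) {
      cat(sprintf("  %-12s %-5s %-16s R2 %.3f+/-%.3f  MAE %.3f  RMSE %.3f\n",
                  df$approach[i], df$source[i], df$task[i],
                  df$r2_mean[i], df$r2_sd[i], df$mae_mean[i], df$rmse_mean[i]))
    }
  }
  cat(sprintf("\nDiscarded low-SQI fraction: %s\n",
              paste(sprintf("%s %.1f%%", names(x$discarded_sqi),
                            100 * x$discarded_sqi), collapse = ", ")))
  invisible(x)
}

#' Write an experiment report to CSV files
#'
#' @param report An [run_experiment()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "experiment_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$classification)) {
    utils::write.csv(report$classification,
                     file.path(dir, "classification.csv"), row.names = FALSE)
  }
  if (!is.null(report$regression)) {
    utils::write.csv(report$regression,
                     file.path(dir, "regression.csv"), row.names = FALSE)
  }
  utils::write.csv(report$fold_metrics, file.path(dir, "fold_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$subject_scores, file.path(dir, "subject_scores.csv"),
                   row.names = FALSE)
  invisible(dir)
}
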