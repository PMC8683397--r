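make_small_cohort_dataset <- function(seed = 31) {
  ch <- generate_cohort(cohort_config(n_subjects = 6, recording_minutes = 3,
                                      seed = seed))
  list(cohort = ch, dataset = build_segment_dataset(ch, "mECG"))
}

make_small_encoder <- function(dataset, seed = 31, epochs = 1) {
  idx <- with_seed_test(seed, sample.int(nrow(dataset$segments),
                                         min(40, nrow(dataset$segments))))
  pre <- build_pretext_dataset(dataset$segments[idx, , drop = FALSE], seed = seed)
  train_pretext(tiny_encoder_config(), pre, epochs = epochs, seed = seed)
}

test_that("the frozen-trunk contract holds bit-exactly through head training", {
  sc <- make_small_cohort_dataset()
  enc <- make_small_encoder(sc$dataset)
  trunk_before <- enc$params[grep("^conv", names(enc$params))]

  model <- build_affect_model(enc, "classify_stress", seed = 1)
  trained <- train_affect(model, sc$dataset, epochs = 2, seed = 2)
  trunk_after <- trained$trunk$params[grep("^conv", names(trained$trunk$params))]
  expect_identical(trunk_before, trunk_after)

  # but the head did move
  expect_false(identical(model$head, trained$head))
})

test_that("affect model construction is deterministic and outputs are well-formed", {
  sc <- make_small_cohort_dataset()
  enc <- make_small_encoder(sc$dataset)

  m1 <- build_affect_model(enc, "classify_stress", seed = 7)
  m2 <- build_affect_model(enc, "classify_stress", seed = 7)
  expect_identical(m1$head, m2$head)

  p <- predict(m1, segments = sc$dataset$segments[1:5, ])
  expect_true(all(p >= 0 & p <= 1))

  reg <- build_affect_model(enc, "regress_fsi", seed = 7)
  reg <- train_affect(reg, sc$dataset, epochs = 1, seed = 8)
  pr <- predict(reg, segments = sc$dataset$segments[1:5, ])
  expect_true(all(is.finite(pr)))
})

test_that("zero-epoch training changes nothing but records target scaling", {
  sc <- make_small_cohort_dataset()
  enc <- make_small_encoder(sc$dataset)
  model <- build_affect_model(enc, "regress_pss", seed = 3)
  out <- train_affect(model, sc$dataset, epochs = 0)
  expect_identical(out$head, model$head)
  expect_true(out$trained)
})

test_that("single-class training sets are rejected for classification", {
  ch <- generate_cohort(cohort_config(n_subjects = 4, stress_prevalence = 0,
                                      recording_minutes = 3, seed = 33))
  ds <- build_segment_dataset(ch, "mECG")
  enc <- make_small_encoder(ds, seed = 34)
  model <- build_affect_model(enc, "classify_stress")
  expect_error(train_affect(model, ds, epochs = 1), "single class")
})

test_that("subject aggregation is a mean: order- and duplication-invariant", {
  p <- c(0.2, 0.4, 0.9, 0.8)
  ids <- c("A", "A", "B", "B")
  agg <- aggregate_subject(p, ids)
  expect_equal(unname(agg), c(0.3, 0.85))
  expect_equal(names(agg), c("A", "B"))

  # one segment per subject: score equals the prediction
  expect_equal(unname(aggregate_subject(0.7, "C")), 0.7)

  # permuting segments leaves scores unchanged
  perm <- c(3, 1, 4, 2)
  expect_equal(aggregate_subject(p[perm], ids[perm]), agg)

  # duplicating all segments leaves scores unchanged
  expect_equal(aggregate_subject(c(p, p), c(ids, ids)), agg)

  expect_error(aggregate_subject(p, ids[1:2]), "differ")
})

test_that("pretext-trained features beat a random frozen trunk on a separable cohort", {
  ch <- generate_cohort(cohort_config(n_subjects = 8, recording_minutes = 3,
                                      seed = 40))
  ds <- build_segment_dataset(ch, "mECG")
  enc_trained <- make_small_encoder(ds, seed = 41, epochs = 3)
  # random frozen trunk: same architecture, zero training steps
  pre0 <- build_pretext_dataset(ds$segments[1:2, , drop = FALSE], seed = 42)
  enc_random <- train_pretext(tiny_encoder_config(), pre0, lr = 0, epochs = 1,
                              seed = 41)

  auroc_for <- function(enc, seed) {
    feats <- encoder_features(enc, ds$segments)
    y <- fetalstress:::segment_labels(ds, "classify_stress")
    folds <- make_within_subject_folds(ds, k = 5, seed = seed)
    test_idx <- folds$test_indices[[1]]
    train_idx <- which(!is.na(folds$fold) & folds$fold != 1)
    m <- build_affect_model(enc, "classify_stress", seed = seed)
    m <- train_affect(m, ds, indices = train_idx, features = feats,
                      epochs = 20, seed = seed)
    p <- predict(m, features = feats[test_idx, , drop = FALSE])
    classification_metrics(y[test_idx], p)$auroc
  }

  wins <- vapply(1:3, function(s) {
    auroc_for(enc_trained, s) >= auroc_for(enc_random, s)
  }, logical(1))
  expect_gte(sum(wins), 2)  # 3-seed majority
})
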