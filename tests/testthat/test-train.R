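# Training-protocol tests run at deliberately tiny scale (8^3 grids, a few
# epochs) so the whole file stays in the seconds range; the full-size
# property experiment lives in test-acceptance.R.

tiny_train_cfg <- function(...) {
  train_config(scale = "test", epochs = 2, perturb = FALSE, ...)
}

test_that("LOOCV holds each participant out exactly once", {
  co <- tiny_cohort(n_per_group = 2, grid = 8, seed = 51)
  res <- run_loocv(co, model_config(), tiny_train_cfg(seed = 1))
  expect_length(res, 4)
  ids <- vapply(res, `[[`, "", "held_out_id")
  expect_setequal(ids, names(cohort_labels(co)))
  df <- fold_table(res)
  expect_identical(sum(confusion_counts(df)), 4L)
  expect_identical(df$pred, as.numeric(df$prob >= 0.5))
})

test_that("training is bit-reproducible under a fixed master seed", {
  co <- tiny_cohort(n_per_group = 2, grid = 8, seed = 52)
  cfg <- train_config(scale = "test", epochs = 2, n_repeats = 2, seed = 77)
  a <- train_fold(co, "S001", model_config(), cfg, fold_index = 1)
  b <- train_fold(co, "S001", model_config(), cfg, fold_index = 1)
  expect_identical(a$predicted_prob, b$predicted_prob)
  expect_identical(a$train_loss, b$train_loss)
  expect_identical(a$perturbation_errors, b$perturbation_errors)
  # a different fold index draws a different stream
  c2 <- train_fold(co, "S001", model_config(), cfg, fold_index = 2)
  expect_false(identical(a$predicted_prob, c2$predicted_prob))
})

test_that("degenerate cohorts and unknown ids are rejected", {
  co <- tiny_cohort(n_per_group = 2, grid = 8, seed = 53)
  expect_error(train_fold(co, "nope", model_config(), tiny_train_cfg()),
               class = "dmnfuse_invalid_spec")
  single <- co
  labs <- cohort_labels(co)
  single$participants <- co$participants[labs == "AD"]
  expect_error(run_loocv(single, model_config(), tiny_train_cfg()),
               class = "dmnfuse_invalid_spec")
})

test_that("per-fold normalization refit uses training participants only", {
  co <- tiny_cohort(n_per_group = 3, grid = 8, seed = 54)
  ids <- names(cohort_labels(co))
  # make the held-out participant the unique maximum of one measure: with
  # refit, the remaining cohort's maximum must come from the others
  co$participants[[1]]$clinical_raw["FAQ"] <- 29.5
  sub <- co
  sub$participants <- co$participants[-1]
  np_ref <- fit_normalization(sub)
  np_all <- fit_normalization(co)
  expect_lt(np_ref$max[["FAQ"]], np_all$max[["FAQ"]])
  oc <- train_fold(co, ids[1], model_config(),
                   tiny_train_cfg(seed = 3, refit_normalization = TRUE))
  expect_s3_class(oc, "dmn_fold_outcome")
})

test_that("confusion counts tally a hand-enumerated outcome list", {
  df <- data.frame(true = c(1, 1, 0, 0, 1, 0),
                   pred = c(1, 0, 0, 1, 1, 0))
  expect_identical(confusion_counts(df), c(TP = 2L, FN = 1L, TN = 2L, FP = 1L))
})

test_that("metric suite reproduces the reference worked examples", {
  m <- compute_metrics(22, 4, 25, 1)
  expect_equal(round(m$accuracy, 2), 90.38)
  expect_equal(round(m$f1, 2), 0.90)
  expect_equal(round(m$mcc, 2), 0.81)
  expect_equal(round(m$sensitivity, 2), 0.85)  # 22/26
  expect_equal(round(m$specificity, 2), 0.96)

  u <- compute_metrics(18, 8, 12, 14)
  expect_equal(round(u$accuracy, 2), 57.69)
  expect_equal(round(u$f1, 2), 0.62)
  expect_equal(round(u$mcc, 2), 0.16)

  perf <- compute_metrics(26, 0, 26, 0)
  expect_equal(perf$accuracy, 100)
  expect_equal(c(perf$sensitivity, perf$specificity, perf$precision,
                 perf$f1, perf$mcc), rep(1, 5))
})

test_that("metric identities and degenerate guards hold", {
  for (cm in list(c(5, 2, 6, 1), c(3, 3, 3, 3), c(10, 0, 1, 9))) {
    m <- compute_metrics(cm[1], cm[2], cm[3], cm[4])
    n_pos <- cm[1] + cm[2]; n_neg <- cm[3] + cm[4]
    expect_equal(m$accuracy,
                 100 * (m$sensitivity * n_pos + m$specificity * n_neg) /
                   (n_pos + n_neg))
    expect_true(m$mcc >= -1 && m$mcc <= 1)
    # swapping the positive class swaps sensitivity and specificity but
    # leaves accuracy unchanged
    sw <- compute_metrics(cm[3], cm[4], cm[1], cm[2])
    expect_equal(sw$accuracy, m$accuracy)
    expect_equal(sw$sensitivity, m$specificity)
    expect_equal(sw$specificity, m$sensitivity)
  }
  # no positive predictions: precision and F1 defined as 0, MCC as 0 guard
  z <- compute_metrics(0, 5, 5, 0)
  expect_identical(z$precision, 0)
  expect_identical(z$mcc, 0)
  expect_error(compute_metrics(0, 0, 5, 1), class = "dmnfuse_invalid_spec")
})

test_that("printed rates invert to consistent confusion counts", {
  expect_identical(recover_confusion_from_rates(0.84, 0.96, 26, 26),
                   c(TP = 22L, FN = 4L, TN = 25L, FP = 1L))
  expect_identical(recover_confusion_from_rates(0.69, 0.46, 26, 26),
                   c(TP = 18L, FN = 8L, TN = 12L, FP = 14L))
  expect_identical(recover_confusion_from_rates(1, 1, 7, 9),
                   c(TP = 7L, FN = 0L, TN = 9L, FP = 0L))
})
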