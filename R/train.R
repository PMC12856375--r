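#' Training configuration
#'
#' Defaults follow the reference protocol: 80 epochs, batch size 64
#' (effectively full-batch under leave-one-out with 51 training
#' participants), Adam at learning rate 1e-4, flip/rotate augmentation each
#' with probability 0.5. `scale = "test"` switches to a desk-scale preset
#' (10 epochs, learning rate 1e-2) for property tests and small synthetic
#' experiments; the higher rate is the standard full-batch Adam choice when
#' only ~10 optimization steps are taken (see the methods vignette).
#'
#' @param epochs training epochs per fold.
#' @param batch_size maximum batch size; the effective size is
#'   `min(batch_size, n_train)`.
#' @param learning_rate Adam learning rate.
#' @param p_flip,p_rotate augmentation probabilities.
#' @param seed master seed; every RNG stream in a run derives from it.
#' @param mode `"multimodal"` or `"unimodal"`.
#' @param scale `"paper"` or `"test"` preset; explicit arguments override
#'   the preset.
#' @param refit_normalization if `TRUE`, min-max clinical normalization is
#'   refitted inside each fold on the training participants only (leakage-
#'   free variant); default `FALSE` fits once on the full cohort, matching
#'   the reference description order.
#' @param perturb if `TRUE`, per-feature perturbation errors are computed on
#'   each fold's held-out participant with `n_repeats` draws per feature.
#' @param n_repeats perturbation draws per feature per fold.
#' @param resize optional length-3 grid to resize inputs to (e.g.
#'   `c(91, 91, 91)`); `NULL` keeps the native grid.
#' @param verbose print per-fold progress.
#' @return Object of class `dmn_train_config`.
#' @export
train_config <- function(epochs = NULL, batch_size = 64L,
                         learning_rate = NULL, p_flip = 0.5, p_rotate = 0.5,
                         seed = 1L, mode = c("multimodal", "unimodal"),
                         scale = c("paper", "test"),
                         refit_normalization = FALSE,
                         perturb = TRUE, n_repeats = 20L,
                         resize = NULL, verbose = FALSE) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  if (is.null(epochs)) epochs <- if (scale == "paper") 80L else 10L
  if (is.null(learning_rate)) {
    learning_rate <- if (scale == "paper") 1e-4 else 1e-2
  }
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            p_flip >= 0, p_flip <= 1, p_rotate >= 0, p_rotate <= 1,
            n_repeats >= 1)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 p_flip = p_flip, p_rotate = p_rotate,
                 seed = as.integer(seed), mode = mode, scale = scale,
                 refit_normalization = refit_normalization,
                 perturb = perturb, n_repeats = as.integer(n_repeats),
                 resize = resize, verbose = verbose),
            class = "dmn_train_config")
}

.cohort_bundles <- function(cohort, params, resize = NULL) {
  bundles <- lapply(cohort$participants, assemble_bundle, params = params)
  if (!is.null(resize)) {
    bundles <- lapply(bundles, function(b) {
      b$image_stack <- resize_stack(b$image_stack, resize)
      b
    })
  }
  names(bundles) <- vapply(bundles, `[[`, character(1), "id")
  bundles
}

#' Train one leave-one-out fold
#'
#' Trains a freshly initialized model on every participant except
#' `held_out_id` and evaluates the final-epoch model once on the held-out
#' participant (no augmentation, no gradients). Augmentation is applied to
#' training images only, redrawn each epoch. All randomness (weights,
#' shuffling, augmentation, perturbation) derives from
#' `train_cfg$seed` via named substreams, so a fold is bit-reproducible.
#'
#' @param cohort a `dmn_cohort`.
#' @param held_out_id participant id to hold out.
#' @param model_cfg a [model_config()]; its mode is overridden by
#'   `train_cfg$mode`.
#' @param train_cfg a [train_config()].
#' @param fold_index integer used to derive this fold's seed substream.
#' @param norm_params optional pre-fitted `dmn_norm_params` (cohort-level
#'   normalization); ignored when `train_cfg$refit_normalization`.
#' @return Object of class `dmn_fold_outcome`: `held_out_id`, `true_label`,
#'   `predicted_prob`, `predicted_label`, `baseline_error`, `group`,
#'   `perturbation_errors` (named vector or `NULL`), `train_loss`
#'   (per-epoch).
#' @export
train_fold <- function(cohort, held_out_id, model_cfg = model_config(),
                       train_cfg = train_config(), fold_index = 0L,
                       norm_params = NULL) {
  ids <- vapply(cohort$participants, `[[`, character(1), "id")
  if (!held_out_id %in% ids) {
    .err("dmnfuse_invalid_spec", "unknown participant id ", held_out_id)
  }
  if (model_cfg$mode != train_cfg$mode) {
    model_cfg$mode <- train_cfg$mode
  }
  train_ids <- setdiff(ids, held_out_id)
  if (train_cfg$refit_normalization) {
    sub <- cohort
    sub$participants <- cohort$participants[match(train_ids, ids)]
    norm_params <- fit_normalization(sub)
  } else if (is.null(norm_params)) {
    norm_params <- fit_normalization(cohort)
  }
  bundles <- .cohort_bundles(cohort, norm_params, train_cfg$resize)
  train_bundles <- bundles[train_ids]
  held_bundle <- bundles[[held_out_id]]

  fold_seed <- derive_seed(train_cfg$seed, "fold", fold_index)
  model <- build_model(model_cfg, seed = derive_seed(fold_seed, "init"))
  opt <- adam_state(collect_learnable(c(model$extractor, model$head)),
                    lr = train_cfg$learning_rate)

  n_train <- length(train_bundles)
  eff_batch <- min(train_cfg$batch_size, n_train)
  if (eff_batch < train_cfg$batch_size && train_cfg$verbose) {
    message("effective batch size reduced to training-set size ", eff_batch)
  }
  losses <- numeric(train_cfg$epochs)
  for (ep in seq_len(train_cfg$epochs)) {
    ep_seed <- derive_seed(fold_seed, "epoch", ep)
    losses[ep] <- with_seed(ep_seed, {
      order_idx <- sample(n_train)
      aug <- lapply(train_bundles[order_idx], function(b) {
        b$image_stack <- augment_stack(b$image_stack, train_cfg$p_flip,
                                       train_cfg$p_rotate)
        b
      })
      tot <- 0
      starts <- seq(1L, n_train, by = eff_batch)
      for (s in starts) {
        e <- min(s + eff_batch - 1L, n_train)
        bt <- batch_images(aug[s:e])
        st <- train_step(model, opt, bt$x, bt$clinical, bt$y)
        opt <- st$opt
        tot <- tot + st$loss * (e - s + 1L)
      }
      tot / n_train
    })
  }

  # evaluation-mode batch norm should normalize with training-set moments,
  # which the short exponential average has not yet reached
  full <- batch_images(train_bundles)
  calibrate_batchnorm(model, full$x, full$clinical)

  prob <- predict_bundle(model, held_bundle)
  truth <- held_bundle$label
  outcome <- structure(list(
    held_out_id = held_out_id,
    true_label = truth,
    predicted_prob = prob,
    predicted_label = as.integer(prob >= 0.5),
    baseline_error = bce_loss(prob, truth),
    group = if (truth == 1L) "AD" else "CN",
    perturbation_errors = NULL,
    train_loss = losses), class = "dmn_fold_outcome")

  if (train_cfg$perturb) {
    outcome$perturbation_errors <- with_seed(
      derive_seed(fold_seed, "perturb"),
      fold_perturbation_errors(model, held_bundle,
                               feature_ids(cohort),
                               n_repeats = train_cfg$n_repeats))
  }
  outcome
}

#' Run full leave-one-out cross-validation
#'
#' Each participant is held out exactly once; per-fold seeds derive
#' deterministically from the master seed and the fold index.
#'
#' @param cohort a `dmn_cohort` with both classes present.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()].
#' @return Object of class `dmn_loocv`: list of `dmn_fold_outcome`, one per
#'   participant, in cohort order.
#' @export
run_loocv <- function(cohort, model_cfg = model_config(),
                      train_cfg = train_config()) {
  labs <- cohort_labels(cohort)
  if (length(labs) < 2L || length(unique(labs)) < 2L) {
    .err("dmnfuse_invalid_spec",
         "LOOCV needs at least two participants and both diagnosis groups")
  }
  norm_params <- if (train_cfg$refit_normalization) NULL else
    fit_normalization(cohort)
  ids <- names(labs)
  outcomes <- lapply(seq_along(ids), function(i) {
    if (train_cfg$verbose) {
      message(sprintf("fold %d/%d: holding out %s", i, length(ids), ids[i]))
    }
    train_fold(cohort, ids[i], model_cfg, train_cfg, fold_index = i,
               norm_params = norm_params)
  })
  structure(outcomes, class = "dmn_loocv")
}

#' Fold outcomes as a data frame
#'
#' @param outcomes a `dmn_loocv` or list of `dmn_fold_outcome`.
#' @return data.frame with one row per fold: `held_out_id`, `group`,
#'   `true`, `prob`, `pred`, `baseline_error`.
#' @export
fold_table <- function(outcomes) {
  data.frame(
    held_out_id = vapply(outcomes, `[[`, character(1), "held_out_id"),
    group = vapply(outcomes, `[[`, character(1), "group"),
    true = vapply(outcomes, `[[`, numeric(1), "true_label"),
    prob = vapply(outcomes, `[[`, numeric(1), "predicted_prob"),
    pred = vapply(outcomes, `[[`, numeric(1), "predicted_label"),
    baseline_error = vapply(outcomes, `[[`, numeric(1), "baseline_error"),
    stringsAsFactors = FALSE)
}

#' Confusion matrix of LOOCV outcomes
#'
#' AD is the positive class (label 1).
#'
#' @param outcomes a `dmn_loocv`, list of fold outcomes, or a data.frame
#'   with `true` and `pred` columns.
#' @return Named integer vector `c(TP, FN, TN, FP)`.
#' @export
confusion_counts <- function(outcomes) {
  df <- if (is.data.frame(outcomes)) outcomes else fold_table(outcomes)
  if (nrow(df) == 0L) .err("dmnfuse_invalid_spec", "no outcomes")
  c(TP = sum(df$true == 1 & df$pred == 1),
    FN = sum(df$true == 1 & df$pred == 0),
    TN = sum(df$true == 0 & df$pred == 0),
    FP = sum(df$true == 0 & df$pred == 1))
}

#' Classification metric suite
#'
#' Computes the standard binary suite from confusion counts with AD
#' positive: accuracy (as a percentage), sensitivity, specificity,
#' precision, F1 and the Matthews correlation coefficient. Precision and F1
#' are defined as 0 when no positive predictions exist; MCC is 0 when any
#' marginal is empty.
#'
#' @param TP,FN,TN,FP confusion counts; `TP` may also be a named vector as
#'   returned by [confusion_counts()].
#' @return Object of class `dmn_metrics` (a list): counts plus `accuracy`
#'   (percent), `sensitivity`, `specificity`, `precision`, `f1`, `mcc`.
#' @examples
#' m <- compute_metrics(22, 4, 25, 1)
#' round(m$accuracy, 2)  # 90.38
#' @export
compute_metrics <- function(TP, FN = NULL, TN = NULL, FP = NULL) {
  if (is.null(FN) && length(TP) == 4L) {
    FN <- TP[["FN"]]; TN <- TP[["TN"]]; FP <- TP[["FP"]]; TP <- TP[["TP"]]
  }
  n <- TP + FN + TN + FP
  if (n == 0) .err("dmnfuse_invalid_spec", "empty confusion matrix")
  if (TP + FN == 0 || TN + FP == 0) {
    .err("dmnfuse_invalid_spec",
         "metrics need at least one positive and one negative")
  }
  prec <- if (TP + FP == 0) 0 else TP / (TP + FP)
  denom <- prod(sqrt(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  mcc <- if (denom == 0) 0 else (TP * TN - FP * FN) / denom
  structure(list(TP = TP, FN = FN, TN = TN, FP = FP,
                 accuracy = 100 * (TP + TN) / n,
                 sensitivity = TP / (TP + FN),
                 specificity = TN / (TN + FP),
                 precision = prec,
                 f1 = if (2 * TP + FP + FN == 0) 0 else
                   2 * TP / (2 * TP + FP + FN),
                 mcc = mcc),
            class = "dmn_metrics")
}

#' @export
print.dmn_metrics <- function(x, ...) {
  cat(sprintf("confusion (AD positive): TP %d  FN %d  TN %d  FP %d\n",
              x$TP, x$FN, x$TN, x$FP))
  cat(sprintf("accuracy %.2f%%  sensitivity %.2f  specificity %.2f\n",
              x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("precision %.2f  F1 %.2f  MCC %.2f\n",
              x$precision, x$f1, x$mcc))
  invisible(x)
}

#' Recover confusion counts from printed rates
#'
#' Inverts rounded sensitivity/specificity back to integer counts
#' (`TP = round(sens * n_pos)` etc., rounding half away from zero), which
#' lets printed rate pairs be checked for internal consistency against
#' printed accuracies.
#'
#' @param sensitivity,specificity rates in `[0, 1]`.
#' @param n_pos,n_neg group sizes.
#' @return Named integer vector `c(TP, FN, TN, FP)`.
#' @examples
#' recover_confusion_from_rates(0.84, 0.96, 26, 26)  # 22 4 25 1
#' @export
recover_confusion_from_rates <- function(sensitivity, specificity,
                                         n_pos, n_neg) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1, n_pos >= 1, n_neg >= 1)
  half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
  TP <- half_away(sensitivity * n_pos)
  TN <- half_away(specificity * n_neg)
  c(TP = as.integer(TP), FN = as.integer(n_pos - TP),
    TN = as.integer(TN), FP = as.integer(n_neg - TN))
}
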