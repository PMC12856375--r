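#' Pipeline configuration
#'
#' One structured object tying the stages together, serializable to JSON
#' (the package's fixed configuration dialect) via [write_pipeline_config()].
#'
#' @param cohort_dir directory holding a BIDS-like cohort (see
#'   [write_cohort()]); `NULL` to generate a synthetic cohort from
#'   `synthetic`.
#' @param synthetic list with optional `n_per_group`, `grid_size`, `null`
#'   (logical) controlling the synthetic cohort when `cohort_dir` is `NULL`.
#' @param mode `"multimodal"`, `"unimodal"` or `"both"`.
#' @param scale `"paper"` or `"test"` preset for [train_config()].
#' @param output_dir where results are written.
#' @param seed master seed.
#' @param train extra arguments forwarded to [train_config()].
#' @return Object of class `dmn_pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir = NULL,
                            synthetic = list(n_per_group = 26,
                                             grid_size = c(16, 16, 16),
                                             null = FALSE),
                            mode = c("multimodal", "unimodal", "both"),
                            scale = c("paper", "test"),
                            output_dir = "dmnfuse-results",
                            seed = 1L,
                            train = list()) {
  mode <- match.arg(mode)
  scale <- match.arg(scale)
  structure(list(cohort_dir = cohort_dir, synthetic = synthetic, mode = mode,
                 scale = scale, output_dir = output_dir,
                 seed = as.integer(seed), train = train),
            class = "dmn_pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `dmn_pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[intersect(names(raw), names(formals(pipeline_config)))])
}

.config_cohort <- function(config) {
  if (!is.null(config$cohort_dir)) return(load_cohort(config$cohort_dir))
  syn <- config$synthetic
  spec <- cohort_spec(n_per_group = syn$n_per_group %||% 26,
                      grid_size = syn$grid_size %||% c(16, 16, 16),
                      seed = derive_seed(config$seed, "cohort"))
  eff <- if (isTRUE(syn$null)) null_effect_config() else effect_config()
  generate_cohort(spec, eff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate and persist a synthetic cohort
#'
#' Wraps [generate_cohort()] + [write_cohort()], logging participant and
#' image counts (the default full-shape cohort yields 52 participants and
#' 208 images).
#'
#' @param config a [pipeline_config()]; the cohort lands in
#'   `file.path(config$output_dir, "cohort")` unless `directory` is given.
#' @param directory optional explicit output directory.
#' @return Invisibly, the manifest of written files.
#' @export
cmd_simulate <- function(config = pipeline_config(), directory = NULL) {
  cohort <- .config_cohort(config)
  directory <- directory %||% file.path(config$output_dir, "cohort")
  manifest <- write_cohort(cohort, directory)
  n_img <- sum(grepl("\\.nii\\.gz$", manifest))
  message(sprintf(
    "simulated cohort: %d participants, %d images, %d datapoints -> %s",
    length(cohort$participants), n_img,
    length(cohort$participants) *
      (length(cohort$roi_names) + length(cohort$clinical_names)),
    directory))
  invisible(manifest)
}

.mode_dir <- function(output_dir, mode) file.path(output_dir, mode)

# run LOOCV for one mode with per-fold flushing; resumes from an existing
# fold table if present
.run_mode <- function(cohort, mode, config) {
  out_dir <- .mode_dir(config$output_dir, mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tcfg <- do.call(train_config,
                  c(list(mode = mode, scale = config$scale, seed = config$seed,
                         perturb = mode == "multimodal"),
                    config$train))
  mcfg <- model_config(mode = mode)
  fold_path <- file.path(out_dir, "fold_table.tsv")
  perr_path <- file.path(out_dir, "perturbation_errors.tsv")
  done <- if (file.exists(fold_path)) {
    utils::read.table(fold_path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)$held_out_id
  } else character(0)
  labs <- cohort_labels(cohort)
  norm_params <- if (tcfg$refit_normalization) NULL else fit_normalization(cohort)
  ids <- names(labs)
  for (i in seq_along(ids)) {
    if (ids[i] %in% done) next
    oc <- train_fold(cohort, ids[i], mcfg, tcfg, fold_index = i,
                     norm_params = norm_params)
    row <- fold_table(list(oc))
    utils::write.table(row, fold_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = !file.exists(fold_path),
                       append = file.exists(fold_path))
    if (!is.null(oc$perturbation_errors)) {
      pe <- data.frame(held_out_id = oc$held_out_id, group = oc$group,
                       t(oc$perturbation_errors), check.names = FALSE)
      utils::write.table(pe, perr_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = !file.exists(perr_path),
                         append = file.exists(perr_path))
    }
    if (tcfg$verbose) message(sprintf("[%s] fold %d/%d done", mode, i, length(ids)))
  }
  df <- utils::read.table(fold_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  cm <- confusion_counts(df)
  metrics <- compute_metrics(cm)
  utils::write.table(data.frame(metric = c("TP", "FN", "TN", "FP", "accuracy",
                                           "sensitivity", "specificity",
                                           "precision", "f1", "mcc"),
                                value = c(cm, metrics$accuracy,
                                          metrics$sensitivity, metrics$specificity,
                                          metrics$precision, metrics$f1,
                                          metrics$mcc)),
                     file.path(out_dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  imp <- NULL
  if (file.exists(perr_path)) {
    pdf <- utils::read.table(perr_path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, check.names = FALSE)
    outs <- lapply(seq_len(nrow(pdf)), function(i) {
      list(group = pdf$group[i],
           perturbation_errors = unlist(pdf[i, -(1:2)]))
    })
    imp <- aggregate_importance(outs)
    utils::write.table(as.data.frame(imp),
                       file.path(out_dir, "importance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rank_change(imp),
                       file.path(out_dir, "rank_change.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(mode = mode, metrics = metrics, importance = imp, fold_table = df)
}

#' Run the full pipeline
#'
#' Loads (or generates) the cohort, runs leave-one-out cross-validation for
#' the configured mode(s), and writes per-mode fold tables, confusion/metric
#' reports, and — for the multimodal model — the perturbation importance
#' and rank-change tables. Fold results are flushed to disk as each fold
#' completes, so an interrupted run resumes where it stopped. With
#' `mode = "both"` a `summary.json` records the multimodal-minus-unimodal
#' accuracy difference in percentage points.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list of per-mode results (and `accuracy_difference`
#'   when both modes ran).
#' @export
cmd_run <- function(config = pipeline_config()) {
  cohort <- .config_cohort(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  modes <- if (config$mode == "both") c("multimodal", "unimodal") else config$mode
  results <- lapply(modes, function(m) .run_mode(cohort, m, config))
  names(results) <- modes
  summary <- list(seed = config$seed, scale = config$scale,
                  n_participants = length(cohort$participants))
  for (m in modes) summary[[paste0(m, "_accuracy")]] <- results[[m]]$metrics$accuracy
  if (length(modes) == 2L) {
    summary$accuracy_difference <-
      results$multimodal$metrics$accuracy - results$unimodal$metrics$accuracy
    results$accuracy_difference <- summary$accuracy_difference
  }
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Render human-readable reports from a results directory
#'
#' Re-derives every displayed number from the persisted fold and
#' perturbation tables (the report layer does no statistics of its own
#' beyond rounding: percentages and rates to 2 decimals, importances to 3).
#'
#' @param results_dir directory written by [cmd_run()].
#' @return Invisibly, a named list of the rendered tables; the text is also
#'   printed.
#' @export
cmd_report <- function(results_dir) {
  modes <- intersect(c("multimodal", "unimodal"), list.dirs(results_dir,
                                                            recursive = FALSE,
                                                            full.names = FALSE))
  if (!length(modes)) {
    .err("dmnfuse_io_error", "no results under ", results_dir)
  }
  out <- list()
  for (m in modes) {
    df <- utils::read.table(file.path(results_dir, m, "fold_table.tsv"),
                            sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    metrics <- compute_metrics(confusion_counts(df))
    cat(sprintf("== %s model (%d folds) ==\n", m, nrow(df)))
    print(metrics)
    out[[m]]$metrics <- metrics
    imp_path <- file.path(results_dir, m, "importance.tsv")
    if (file.exists(imp_path)) {
      imp <- utils::read.table(imp_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
      imp$mean_error <- round(imp$mean_error, 3)
      imp$importance <- sprintf("%.3f", imp$importance)
      cat("feature importance by diagnosis group:\n")
      print(imp, row.names = FALSE)
      rc <- utils::read.table(file.path(results_dir, m, "rank_change.tsv"),
                              sep = "\t", header = TRUE, stringsAsFactors = FALSE)
      cat("rank change (CN rank - AD rank):\n")
      print(rc, row.names = FALSE)
      out[[m]]$importance <- imp
      out[[m]]$rank_change <- rc
    }
  }
  if (length(modes) == 2L) {
    d <- out$multimodal$metrics$accuracy - out$unimodal$metrics$accuracy
    cat(sprintf("accuracy difference (multimodal - unimodal): %.2f%%\n", d))
    out$accuracy_difference <- d
  }
  invisible(out)
}
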