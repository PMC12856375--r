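#' Feature identifiers for perturbation ranking
#'
#' The model consumes 10 features per participant in the default
#' configuration: 4 ROI image channels followed by 6 clinical scores, in the
#' frozen package order, so perturbation indices are stable across runs.
#'
#' @param cohort optional `dmn_cohort`; defaults to the canonical orderings.
#' @return data.frame with columns `kind` (`"roi"`/`"clinical"`), `name`,
#'   `index` (position within its modality).
#' @export
feature_ids <- function(cohort = NULL) {
  rois <- if (is.null(cohort)) dmn_roi_names() else cohort$roi_names
  clin <- if (is.null(cohort)) dmn_clinical_names() else cohort$clinical_names
  data.frame(kind = c(rep("roi", length(rois)), rep("clinical", length(clin))),
             name = c(rois, clin),
             index = c(seq_along(rois), seq_along(clin)),
             stringsAsFactors = FALSE)
}

#' Perturb one feature of an input bundle
#'
#' Returns a copy of the bundle in which exactly the named feature has been
#' randomized; every other feature is bit-identical. Default strategies:
#' a clinical score is replaced by a uniform draw on `[0, 1]` (its
#' normalized range); an ROI channel has its voxels randomly permuted, which
#' destroys spatial structure while preserving the voxel multiset.
#' Alternatives: `"gaussian"` replaces the ROI channel with Gaussian noise
#' matched to the channel's mean and SD; `"reference"` draws the clinical
#' value from `reference_values`.
#'
#' @param bundle a `dmn_bundle`.
#' @param feature one row of [feature_ids()] (or a list with `kind` and
#'   `index`).
#' @param roi_strategy `"permute"` or `"gaussian"`.
#' @param clinical_strategy `"uniform"` or `"reference"`.
#' @param reference_values numeric pool of normalized scores for the
#'   `"reference"` strategy.
#' @return A perturbed `dmn_bundle`.
#' @export
perturb_feature <- function(bundle, feature,
                            roi_strategy = c("permute", "gaussian"),
                            clinical_strategy = c("uniform", "reference"),
                            reference_values = NULL) {
  roi_strategy <- match.arg(roi_strategy)
  clinical_strategy <- match.arg(clinical_strategy)
  kind <- as.character(feature$kind)
  idx <- as.integer(feature$index)
  if (kind == "clinical") {
    if (idx < 1L || idx > length(bundle$clinical)) {
      .err("dmnfuse_invalid_spec", "unknown clinical feature index ", idx)
    }
    bundle$clinical[idx] <- if (clinical_strategy == "uniform") runif(1) else {
      if (is.null(reference_values) || !length(reference_values)) {
        .err("dmnfuse_invalid_spec",
             "reference strategy needs reference_values")
      }
      reference_values[sample.int(length(reference_values), 1L)]
    }
  } else if (kind == "roi") {
    if (idx < 1L || idx > dim(bundle$image_stack)[1]) {
      .err("dmnfuse_invalid_spec", "unknown ROI feature index ", idx)
    }
    v <- bundle$image_stack[idx, , , ]
    bundle$image_stack[idx, , , ] <- if (roi_strategy == "permute") {
      array(as.vector(v)[sample.int(length(v))], dim(v))
    } else {
      array(rnorm(length(v), mean(v), stats::sd(as.vector(v))), dim(v))
    }
  } else {
    .err("dmnfuse_invalid_spec", "unknown feature kind '", kind, "'")
  }
  bundle
}

#' Per-feature perturbation errors on one held-out participant
#'
#' For each feature, perturbs the held-out bundle `n_repeats` times with
#' independent draws, evaluates the final-epoch model on each perturbed copy
#' and averages the BCE loss (or misclassification indicator with
#' `error = "misclass"`). Higher mean error means the model relied more on
#' that feature.
#'
#' @param model a trained `dmn_model` (evaluation mode is used throughout).
#' @param bundle the held-out `dmn_bundle`.
#' @param features data.frame as from [feature_ids()].
#' @param n_repeats independent perturbation draws per feature.
#' @param error `"bce"` (default) or `"misclass"`.
#' @param ... passed to [perturb_feature()] (strategies, reference pool).
#' @return Named numeric vector of mean errors, one per feature.
#' @export
fold_perturbation_errors <- function(model, bundle, features = feature_ids(),
                                     n_repeats = 20L, error = c("bce", "misclass"),
                                     ...) {
  error <- match.arg(error)
  stopifnot(n_repeats >= 1)
  errs <- vapply(seq_len(nrow(features)), function(i) {
    mean(vapply(seq_len(n_repeats), function(r) {
      pb <- perturb_feature(bundle, features[i, ], ...)
      p <- predict_bundle(model, pb)
      if (error == "bce") bce_loss(p, bundle$label)
      else as.numeric(as.integer(p >= 0.5) != bundle$label)
    }, numeric(1)))
  }, numeric(1))
  stats::setNames(errs, features$name)
}

#' Aggregate perturbation errors into a per-group importance table
#'
#' Averages each feature's perturbation error over the folds whose held-out
#' participant belongs to each diagnosis group, ranks features within group
#' by descending mean error (rank 1 = most important; ties broken by the
#' frozen feature order) and normalizes importances by the within-group
#' maximum, so each group's top feature scores exactly 1.
#'
#' @param outcomes a `dmn_loocv` whose folds carry `perturbation_errors`,
#'   or a pre-averaged named list `list(CN = ..., AD = ...)` of per-feature
#'   mean-error vectors.
#' @param features optional character vector restricting and ordering the
#'   reported features (e.g. only the clinical measures).
#' @return Object of class `dmn_importance`: data.frame with `group`,
#'   `feature`, `mean_error`, `rank`, `importance`.
#' @export
aggregate_importance <- function(outcomes, features = NULL) {
  if (is.list(outcomes) && !is.null(names(outcomes)) &&
      all(c("CN", "AD") %in% names(outcomes)) &&
      all(vapply(outcomes, is.numeric, logical(1)))) {
    group_means <- outcomes[c("CN", "AD")]
  } else {
    groups <- vapply(outcomes, `[[`, character(1), "group")
    perr <- lapply(outcomes, `[[`, "perturbation_errors")
    if (any(vapply(perr, is.null, logical(1)))) {
      .err("dmnfuse_invalid_spec",
           "all fold outcomes must carry perturbation_errors")
    }
    feat_names <- names(perr[[1]])
    if (!all(vapply(perr, function(e) identical(names(e), feat_names),
                    logical(1)))) {
      .err("dmnfuse_invalid_spec", "folds disagree on the feature set")
    }
    group_means <- lapply(c(CN = "CN", AD = "AD"), function(g) {
      sel <- groups == g
      if (!any(sel)) {
        .err("dmnfuse_invalid_spec", "no folds with held-out group ", g)
      }
      colMeans(do.call(rbind, perr[sel]))
    })
  }
  rows <- lapply(names(group_means), function(g) {
    e <- group_means[[g]]
    if (!is.null(features)) {
      missing <- setdiff(features, names(e))
      if (length(missing)) {
        .err("dmnfuse_invalid_spec", "unknown feature(s): ",
             paste(missing, collapse = ", "))
      }
      e <- e[features]
    }
    # rank 1 = largest mean error; ties keep the frozen feature order
    ord <- order(-e, seq_along(e))
    rk <- integer(length(e)); rk[ord] <- seq_along(e)
    data.frame(group = g, feature = names(e), mean_error = unname(e),
               rank = rk, importance = unname(e / max(e)),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("dmn_importance", "data.frame"))
}

#' Rank change between diagnosis groups
#'
#' For every feature, `change = CN rank - AD rank`: a large positive value
#' means the feature matters far more for classifying AD participants than
#' CN participants (its rank number is smaller in AD), and vice versa.
#'
#' @param table a `dmn_importance` covering both groups over one feature
#'   set.
#' @return data.frame with `feature`, `cn_rank`, `ad_rank`, `change`,
#'   ordered by CN rank.
#' @export
rank_change <- function(table) {
  cn <- table[table$group == "CN", ]
  ad <- table[table$group == "AD", ]
  if (!setequal(cn$feature, ad$feature) || nrow(cn) == 0L) {
    .err("dmnfuse_invalid_spec",
         "rank_change needs both groups ranked over identical features")
  }
  ad_rank <- ad$rank[match(cn$feature, ad$feature)]
  out <- data.frame(feature = cn$feature, cn_rank = cn$rank,
                    ad_rank = ad_rank, change = cn$rank - ad_rank,
                    stringsAsFactors = FALSE)
  out[order(out$cn_rank), ]
}
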