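#' Load a cohort from a BIDS-like directory
#'
#' Counterpart of [write_cohort()]. Participants listed in
#' `participants.tsv` must have every ROI volume present and every clinical
#' value non-missing; incomplete participants abort the load with an error
#' naming them, mirroring the exclusion of incomplete records from the
#' source cohort.
#'
#' @param directory directory containing `participants.tsv` and
#'   `sub-<id>/` folders of `.nii.gz` ROI volumes.
#' @param roi_names ordered ROI identifiers expected per participant.
#' @return A `dmn_cohort`.
#' @export
load_cohort <- function(directory, roi_names = dmn_roi_names()) {
  tsv <- file.path(directory, "participants.tsv")
  if (!dir.exists(directory) || !file.exists(tsv)) {
    .err("dmnfuse_empty_cohort", "no participants.tsv under ", directory)
  }
  df <- utils::read.table(tsv, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) {
    .err("dmnfuse_empty_cohort", "participants.tsv is empty: ", tsv)
  }
  need <- c("participant_id", "diagnosis")
  if (!all(need %in% names(df))) {
    .err("dmnfuse_io_error", "participants.tsv lacks required columns")
  }
  clinical_names <- setdiff(names(df), need)
  grid <- NULL
  participants <- lapply(seq_len(nrow(df)), function(i) {
    id <- as.character(df$participant_id[i])
    dx <- as.character(df$diagnosis[i])
    if (!dx %in% c("AD", "CN")) {
      .err("dmnfuse_io_error", "participant ", id,
           ": diagnosis must be AD or CN, got '", dx, "'")
    }
    cl <- suppressWarnings(as.numeric(unlist(df[i, clinical_names])))
    if (anyNA(cl)) {
      .err("dmnfuse_incomplete_participant", "participant ", id,
           " is missing clinical values (",
           paste(clinical_names[is.na(cl)], collapse = ", "), ")")
    }
    names(cl) <- clinical_names
    vols <- lapply(roi_names, function(r) {
      path <- file.path(directory, paste0("sub-", id),
                        sprintf("sub-%s_roi-%s.nii.gz", id, r))
      if (!file.exists(path)) {
        .err("dmnfuse_incomplete_participant", "participant ", id,
             " is missing ROI volume ", r, " (", path, ")")
      }
      v <- read_nifti(path)
      attr(v, "voxel_size") <- NULL
      v
    })
    names(vols) <- roi_names
    shapes <- vapply(vols, function(v) paste(dim(v), collapse = "x"), character(1))
    if (length(unique(shapes)) != 1L) {
      .err("dmnfuse_shape_error", "participant ", id, " has mismatched ROI shapes")
    }
    list(id = id, diagnosis = dx, volumes = vols, clinical_raw = cl)
  })
  grid <- dim(participants[[1]]$volumes[[1]])
  structure(list(participants = participants, roi_names = roi_names,
                 clinical_names = clinical_names, grid_size = grid,
                 signal_region = NULL),
            class = "dmn_cohort")
}

#' Min-max normalization of the clinical measures
#'
#' All six clinical instruments are scored on different scales, so before
#' entering the model each measure X is rescaled to `[0, 1]` by
#' `(X - X_min) / (X_max - X_min)` with the extrema taken over the cohort.
#' `fit_normalization()` learns the per-measure extrema;
#' `normalize_clinical()` applies them, clipping out-of-range values at
#' inference time so the head's inputs stay bounded.
#'
#' By default the extrema are fitted on the full cohort before
#' cross-validation (the reference procedure describes normalization ahead of
#' modelling); this leaks the held-out participant's marginal extrema into
#' training folds, so [train_config()] offers `refit_normalization = TRUE`
#' to refit within each fold instead.
#'
#' @param cohort a `dmn_cohort` with at least 2 distinct values per measure.
#' @param raw named numeric vector of raw scores in the fitted measure order.
#' @param params a `dmn_norm_params` from `fit_normalization()`.
#' @return `fit_normalization()`: object of class `dmn_norm_params` with
#'   `min` and `max` vectors; `normalize_clinical()`: numeric vector in
#'   `[0, 1]`.
#' @export
fit_normalization <- function(cohort) {
  stopifnot(inherits(cohort, "dmn_cohort"))
  if (length(cohort$participants) == 0L) {
    .err("dmnfuse_empty_cohort", "cannot fit normalization on an empty cohort")
  }
  cl <- do.call(rbind, lapply(cohort$participants, `[[`, "clinical_raw"))
  mins <- apply(cl, 2, min)
  maxs <- apply(cl, 2, max)
  flat <- names(mins)[maxs <= mins]
  if (length(flat)) {
    .err("dmnfuse_degenerate_measure",
         "measure(s) with no spread (max = min): ", paste(flat, collapse = ", "))
  }
  structure(list(min = mins, max = maxs, measures = colnames(cl)),
            class = "dmn_norm_params")
}

#' @rdname fit_normalization
#' @export
normalize_clinical <- function(raw, params) {
  stopifnot(inherits(params, "dmn_norm_params"))
  if (length(raw) != length(params$min)) {
    .err("dmnfuse_shape_error", "expected ", length(params$min),
         " clinical values, got ", length(raw))
  }
  if (!is.null(names(raw)) && !identical(names(raw), params$measures)) {
    raw <- raw[params$measures]
  }
  z <- (raw - params$min) / (params$max - params$min)
  stats::setNames(pmin(pmax(z, 0), 1), params$measures)
}

#' Assemble one participant's multimodal input bundle
#'
#' Stacks the participant's ROI volumes into a single channel-first 4-D
#' array, normalizes the clinical scores and attaches the binary label
#' (AD = 1, the positive class; CN = 0). A bundle is atomic: all of one
#' participant's data travel together, which is what makes leave-one-out
#' evaluation leakage-safe.
#'
#' @param record one participant record from a `dmn_cohort`.
#' @param params a `dmn_norm_params`.
#' @return Object of class `dmn_bundle`: `image_stack` (array, channels x
#'   D x H x W), `clinical` (normalized vector), `label` (0/1), `id`.
#' @export
assemble_bundle <- function(record, params) {
  shapes <- vapply(record$volumes, function(v) paste(dim(v), collapse = "x"),
                   character(1))
  if (length(unique(shapes)) != 1L) {
    .err("dmnfuse_shape_error", "ROI volumes of participant ", record$id,
         " differ in shape")
  }
  d <- dim(record$volumes[[1]])
  stack <- array(0, c(length(record$volumes), d))
  for (k in seq_along(record$volumes)) {
    stack[k, , , ] <- record$volumes[[k]]
  }
  structure(list(image_stack = stack,
                 clinical = normalize_clinical(record$clinical_raw, params),
                 label = if (record$diagnosis == "AD") 1L else 0L,
                 id = record$id),
            class = "dmn_bundle")
}

#' Spatial augmentation of an image stack
#'
#' With probability `p_flip` reverses one randomly chosen spatial axis and
#' with probability `p_rotate` applies a random quarter-turn (90/180/270
#' degrees) in a randomly chosen spatial plane; the same transform is applied
#' to every channel, and clinical values are never touched. Quarter-turns
#' keep the voxel multiset intact (no interpolation), so augmentation is
#' measure-preserving.
#'
#' @param stack channel-first 4-D array (channels x D x H x W).
#' @param p_flip,p_rotate transform probabilities in `[0, 1]`.
#' @return Augmented stack of identical shape.
#' @seealso [flip_stack()], [rotate_stack()] for the deterministic pieces.
#' @export
augment_stack <- function(stack, p_flip = 0.5, p_rotate = 0.5) {
  stopifnot(length(dim(stack)) == 4L, p_flip >= 0, p_flip <= 1,
            p_rotate >= 0, p_rotate <= 1)
  d <- dim(stack)[2:4]
  if (p_rotate > 0 && length(unique(d)) != 1L) {
    .err("dmnfuse_shape_error",
         "90-degree rotation requires a cubic grid; got ",
         paste(d, collapse = "x"))
  }
  if (runif(1) < p_flip) {
    stack <- flip_stack(stack, sample(3L, 1L))
  }
  if (runif(1) < p_rotate) {
    plane <- sample(list(c(1L, 2L), c(1L, 3L), c(2L, 3L)), 1L)[[1]]
    stack <- rotate_stack(stack, plane, sample(3L, 1L))
  }
  stack
}

#' @rdname augment_stack
#' @param axis spatial axis to reverse (1..3).
#' @export
flip_stack <- function(stack, axis) {
  idx <- rep(list(quote(expr = )), 4L)
  idx[[axis + 1L]] <- rev(seq_len(dim(stack)[axis + 1L]))
  do.call(`[`, c(list(stack), idx, list(drop = FALSE)))
}

#' @rdname augment_stack
#' @param plane integer pair of spatial axes (1..3) spanning the rotation
#'   plane.
#' @param k number of quarter turns (1..3).
#' @export
rotate_stack <- function(stack, plane, k = 1L) {
  # one quarter turn in plane (a, b): transpose a<->b then reverse b
  a <- plane[1] + 1L; b <- plane[2] + 1L
  for (i in seq_len(k %% 4L)) {
    perm <- seq_len(4L); perm[c(a, b)] <- c(b, a)
    stack <- aperm(stack, perm)
    stack <- flip_stack(stack, plane[2])
  }
  stack
}

# axis interpolation matrix, endpoints aligned (identity when n_to == n_from)
.interp_matrix <- function(n_to, n_from) {
  if (n_from == 1L) return(matrix(1, n_to, 1))
  pos <- if (n_to == 1L) (n_from + 1) / 2 else
    1 + (seq_len(n_to) - 1) * (n_from - 1) / (n_to - 1)
  lo <- pmin(floor(pos), n_from - 1)
  w <- pos - lo
  M <- matrix(0, n_to, n_from)
  M[cbind(seq_len(n_to), lo)] <- 1 - w
  M[cbind(seq_len(n_to), lo + 1)] <- M[cbind(seq_len(n_to), lo + 1)] + w
  M
}

#' Trilinear resize of an image stack
#'
#' Resamples every channel to `target` via separable linear interpolation
#' with aligned endpoints (an input already at the target shape is returned
#' unchanged up to float arithmetic). Used to bring volumes to the model's
#' working resolution, e.g. the full-scale 91^3 target.
#'
#' @param stack channel-first 4-D array.
#' @param target integer length-3 output spatial shape.
#' @return Resized stack, channels preserved.
#' @export
resize_stack <- function(stack, target) {
  stopifnot(length(dim(stack)) == 4L, length(target) == 3L, all(target >= 1))
  d <- dim(stack)
  M1 <- .interp_matrix(target[1], d[2])
  M2 <- .interp_matrix(target[2], d[3])
  M3 <- .interp_matrix(target[3], d[4])
  out <- array(0, c(d[1], target))
  for (c_i in seq_len(d[1])) {
    v <- stack[c_i, , , ]
    if (is.null(dim(v))) v <- array(v, d[2:4])
    x <- M1 %*% matrix(v, d[2], d[3] * d[4])              # (t1, d2*d3)
    x <- array(x, c(target[1], d[3], d[4]))
    x <- aperm(x, c(2, 1, 3))
    x <- M2 %*% matrix(x, d[3], target[1] * d[4])
    x <- array(x, c(target[2], target[1], d[4]))
    x <- aperm(x, c(3, 2, 1))                             # (d4, t1, t2)
    x <- M3 %*% matrix(x, d[4], target[1] * target[2])
    out[c_i, , , ] <- aperm(array(x, c(target[3], target[1], target[2])),
                            c(2, 3, 1))
  }
  out
}
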