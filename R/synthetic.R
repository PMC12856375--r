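#' @importFrom stats qnorm pnorm runif rnorm sd
NULL

.err <- function(class, ..., call. = FALSE) {
  stop(errorCondition(paste0(...), class = c(class, "dmnfuse_error")))
}

# default stated world for the synthetic cohort: group means/SDs chosen once
# as clinically plausible raw-scale values for mild AD vs controls (see the
# methods vignette); they are placeholders for the unpublished source
# distributions, not a calibration target.
.default_clinical_means <- list(
  ADAS13               = c(cn = 9,    ad = 30),
  EcogPtTotal          = c(cn = 1.4,  ad = 2.6),
  FAQ                  = c(cn = 1,    ad = 16),
  MoCA                 = c(cn = 26,   ad = 17),
  RAVLT_immediate      = c(cn = 45,   ad = 22),
  RAVLT_pct_forgetting = c(cn = 35,   ad = 85)
)
.default_clinical_sd <- c(
  ADAS13 = 5, EcogPtTotal = 0.4, FAQ = 5, MoCA = 3,
  RAVLT_immediate = 9, RAVLT_pct_forgetting = 18
)

#' Effect configuration for the synthetic cohort
#'
#' Describes how the AD and CN groups differ in the generated data: per-measure
#' clinical group means and standard deviations (raw scale, truncated-normal
#' draws within each instrument's plausible range), a per-ROI mean shift in
#' correlation units applied to AD volumes inside `signal_region`, and the
#' voxel noise level. A null configuration (no group differences anywhere) is
#' available via [null_effect_config()].
#'
#' @param clinical_means named list, one entry per clinical measure, each a
#'   numeric `c(cn, ad)` pair of raw-scale group means.
#' @param clinical_sd named numeric vector of per-measure standard deviations
#'   (shared by both groups); all must be `> 0`.
#' @param clinical_ranges named list of `c(min, max)` truncation bounds per
#'   measure; defaults to the instruments' native score ranges.
#' @param roi_effect numeric mean shift (correlation units) added to AD
#'   volumes inside `signal_region`; either a scalar recycled over ROIs or a
#'   named per-ROI vector.
#' @param roi_noise_sd voxel noise standard deviation before smoothing; `> 0`.
#' @param roi_baseline mean correlation level of all volumes.
#' @param smooth_sigma Gaussian smoothing width (voxels) applied to the noise
#'   field to mimic the spatial correlation of connectivity maps.
#' @param signal_region list with integer vectors `lo` and `hi`: an
#'   axis-aligned subvolume in 0-based, half-open voxel coordinates carrying
#'   the imaging group effect. `NULL` selects the central half-cube of the
#'   grid at generation time.
#' @return An object of class `dmn_effect_config`.
#' @seealso [generate_cohort()]
#' @export
effect_config <- function(clinical_means = .default_clinical_means,
                          clinical_sd = .default_clinical_sd,
                          clinical_ranges = clinical_score_ranges(),
                          roi_effect = -0.15,
                          roi_noise_sd = 0.3,
                          roi_baseline = 0.2,
                          smooth_sigma = 1,
                          signal_region = NULL) {
  if (any(unlist(clinical_sd) <= 0)) {
    .err("dmnfuse_invalid_spec", "all clinical standard deviations must be > 0")
  }
  if (roi_noise_sd <= 0) {
    .err("dmnfuse_invalid_spec", "roi_noise_sd must be > 0")
  }
  for (m in names(clinical_means)) {
    rng <- clinical_ranges[[m]]
    if (is.null(rng) || diff(rng) <= 0) {
      .err("dmnfuse_invalid_spec", "missing or degenerate range for measure ", m)
    }
  }
  structure(list(clinical_means = clinical_means,
                 clinical_sd = clinical_sd,
                 clinical_ranges = clinical_ranges,
                 roi_effect = roi_effect,
                 roi_noise_sd = roi_noise_sd,
                 roi_baseline = roi_baseline,
                 smooth_sigma = smooth_sigma,
                 signal_region = signal_region),
            class = "dmn_effect_config")
}

#' @rdname effect_config
#' @details `null_effect_config()` keeps the CN means for both groups and
#'   zeroes the imaging effect, so the two diagnosis groups are statistically
#'   identical — the negative control for every downstream stage.
#' @export
null_effect_config <- function(clinical_sd = .default_clinical_sd,
                               roi_noise_sd = 0.3, ...) {
  means <- lapply(.default_clinical_means, function(p) c(cn = p[["cn"]], ad = p[["cn"]]))
  effect_config(clinical_means = means, clinical_sd = clinical_sd,
                roi_effect = 0, roi_noise_sd = roi_noise_sd, ...)
}

#' Cohort shape specification
#'
#' @param n_per_group participants per diagnosis group (`>= 1`). The default
#'   26 per group reproduces the reference cohort shape (52 participants,
#'   208 images, 520 datapoints).
#' @param grid_size integer length-3 voxel dimensions of each ROI volume.
#'   16^3 by default for test speed; set `c(91, 91, 91)` for the full-scale
#'   resize target.
#' @param roi_names ordered ROI identifiers (default the four DMN regions).
#' @param clinical_names ordered clinical measure identifiers.
#' @param seed integer seed; the same spec and seed give a bit-identical
#'   cohort.
#' @return An object of class `dmn_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 26,
                        grid_size = c(16, 16, 16),
                        roi_names = dmn_roi_names(),
                        clinical_names = dmn_clinical_names(),
                        seed = 1L) {
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L ||
      n_per_group < 1 || n_per_group != round(n_per_group)) {
    .err("dmnfuse_invalid_spec", "n_per_group must be a positive integer")
  }
  if (length(grid_size) != 3L || any(grid_size < 1)) {
    .err("dmnfuse_invalid_spec", "grid_size must be three positive integers")
  }
  if (anyDuplicated(roi_names) || anyDuplicated(clinical_names)) {
    .err("dmnfuse_invalid_spec", "ROI and clinical names must be unique")
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 grid_size = as.integer(grid_size),
                 roi_names = roi_names,
                 clinical_names = clinical_names,
                 seed = as.integer(seed)),
            class = "dmn_cohort_spec")
}

# inverse-CDF truncated normal draw
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  a <- pnorm(lo, mean, sd)
  b <- pnorm(hi, mean, sd)
  u <- runif(n, a, b)
  pmin(pmax(qnorm(u, mean, sd), lo), hi)
}

# separable Gaussian smoothing of a 3-D field via banded interpolation
# matrices; rows renormalized so constant fields stay constant at edges
smooth3d <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  mats <- lapply(d, function(g) {
    K <- outer(seq_len(g), seq_len(g),
               function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
    K[abs(row(K) - col(K)) > ceiling(3 * sigma)] <- 0
    K / rowSums(K)
  })
  x <- matrix(vol, d[1], d[2] * d[3])
  x <- mats[[1]] %*% x
  x <- array(x, d)
  x <- aperm(x, c(2, 1, 3))
  x <- array(mats[[2]] %*% matrix(x, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
  x <- aperm(x, c(2, 1, 3))
  x <- aperm(x, c(3, 1, 2))
  x <- array(mats[[3]] %*% matrix(x, d[3], d[1] * d[2]), c(d[3], d[1], d[2]))
  aperm(x, c(2, 3, 1))
}

.default_signal_region <- function(grid) {
  list(lo = as.integer(floor(grid / 4)), hi = as.integer(floor(3 * grid / 4)))
}

.check_signal_region <- function(region, grid) {
  lo <- region$lo; hi <- region$hi
  if (length(lo) != 3L || length(hi) != 3L ||
      any(lo < 0) || any(hi > grid) || any(lo >= hi)) {
    .err("dmnfuse_invalid_spec",
         "signal_region must be a non-empty 0-based half-open box inside the grid")
  }
  region
}

#' Generate a synthetic AD/CN cohort
#'
#' Emulates the statistical end product of a seed-based connectivity study:
#' each participant carries one smoothed correlation-like volume per DMN ROI
#' (voxels clipped to `[-1, 1]`) and one raw score per clinical measure.
#' AD participants receive the configured mean shift inside the signal
#' subregion and clinical scores drawn from the AD group means; groups are
#' exactly balanced.
#'
#' @param spec a [cohort_spec()].
#' @param effect an [effect_config()].
#' @return An object of class `dmn_cohort`: a list of participant records
#'   (each with `id`, `diagnosis` (`"AD"`/`"CN"`), `volumes` — a named list
#'   of 3-D arrays — and `clinical_raw`), plus the orderings and grid shape.
#' @examples
#' co <- generate_cohort(cohort_spec(n_per_group = 2, grid_size = c(8, 8, 8)))
#' length(co$participants)  # 4
#' @export
generate_cohort <- function(spec = cohort_spec(), effect = effect_config()) {
  stopifnot(inherits(spec, "dmn_cohort_spec"), inherits(effect, "dmn_effect_config"))
  grid <- spec$grid_size
  region <- effect$signal_region
  if (is.null(region)) region <- .default_signal_region(grid)
  region <- .check_signal_region(region, grid)

  for (m in spec$clinical_names) {
    if (is.null(effect$clinical_means[[m]]) || is.na(effect$clinical_sd[[m]])) {
      .err("dmnfuse_invalid_spec", "effect config lacks parameters for measure ", m)
    }
  }
  roi_eff <- effect$roi_effect
  if (length(roi_eff) == 1L) {
    roi_eff <- stats::setNames(rep(roi_eff, length(spec$roi_names)), spec$roi_names)
  }
  if (!all(spec$roi_names %in% names(roi_eff))) {
    .err("dmnfuse_invalid_spec", "roi_effect must cover every ROI in the spec")
  }

  n <- spec$n_per_group
  ids <- sprintf("S%03d", seq_len(2L * n))
  dx <- rep(c("CN", "AD"), each = n)
  # mask of the effect-carrying subvolume (0-based half-open -> 1-based)
  in_region <- array(FALSE, grid)
  in_region[(region$lo[1] + 1):region$hi[1],
            (region$lo[2] + 1):region$hi[2],
            (region$lo[3] + 1):region$hi[3]] <- TRUE

  participants <- with_seed(spec$seed, lapply(seq_along(ids), function(i) {
    is_ad <- dx[i] == "AD"
    vols <- lapply(spec$roi_names, function(r) {
      v <- array(rnorm(prod(grid), 0, effect$roi_noise_sd), grid)
      v <- smooth3d(v, effect$smooth_sigma) + effect$roi_baseline
      if (is_ad) v[in_region] <- v[in_region] + roi_eff[[r]]
      pmin(pmax(v, -1), 1)
    })
    names(vols) <- spec$roi_names
    cl <- vapply(spec$clinical_names, function(m) {
      mu <- effect$clinical_means[[m]][[if (is_ad) "ad" else "cn"]]
      rng <- effect$clinical_ranges[[m]]
      rtrunc_norm(1L, mu, effect$clinical_sd[[m]], rng[1], rng[2])
    }, numeric(1))
    list(id = ids[i], diagnosis = dx[i], volumes = vols, clinical_raw = cl)
  }))

  structure(list(participants = participants,
                 roi_names = spec$roi_names,
                 clinical_names = spec$clinical_names,
                 grid_size = grid,
                 signal_region = region),
            class = "dmn_cohort")
}

#' @export
print.dmn_cohort <- function(x, ...) {
  labs <- vapply(x$participants, `[[`, character(1), "diagnosis")
  cat(sprintf("dmn_cohort: %d participants (%d AD / %d CN), %d ROI volumes of %s, %d clinical measures\n",
              length(x$participants), sum(labs == "AD"), sum(labs == "CN"),
              length(x$roi_names), paste(x$grid_size, collapse = "x"),
              length(x$clinical_names)))
  invisible(x)
}

#' Cohort diagnosis labels
#'
#' @param cohort a `dmn_cohort`.
#' @return Named character vector of `"AD"`/`"CN"` labels, one per participant.
#' @export
cohort_labels <- function(cohort) {
  stats::setNames(vapply(cohort$participants, `[[`, character(1), "diagnosis"),
                  vapply(cohort$participants, `[[`, character(1), "id"))
}

#' Clinical scores of a cohort as a data frame
#'
#' @param cohort a `dmn_cohort`.
#' @return data.frame with `participant_id`, `diagnosis` and one raw-scale
#'   column per clinical measure.
#' @export
clinical_table <- function(cohort) {
  cl <- do.call(rbind, lapply(cohort$participants, function(p) p$clinical_raw))
  df <- data.frame(participant_id = vapply(cohort$participants, `[[`, character(1), "id"),
                   diagnosis = vapply(cohort$participants, `[[`, character(1), "diagnosis"),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(cl))
}

#' Write a cohort to a BIDS-like directory
#'
#' Lays the cohort out as one NIfTI file per ROI volume
#' (`sub-<id>/sub-<id>_roi-<name>.nii.gz`) plus a tab-separated
#' `participants.tsv` holding `participant_id`, `diagnosis` and the raw
#' clinical scores. [load_cohort()] round-trips this layout.
#'
#' @param cohort a `dmn_cohort`.
#' @param directory output directory (created if absent).
#' @return Invisibly, a character vector manifest of every file written.
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "dmn_cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    .err("dmnfuse_io_error", "cannot create directory ", directory)
  }
  manifest <- character(0)
  for (p in cohort$participants) {
    sub_dir <- file.path(directory, paste0("sub-", p$id))
    dir.create(sub_dir, showWarnings = FALSE)
    for (r in names(p$volumes)) {
      path <- file.path(sub_dir, sprintf("sub-%s_roi-%s.nii.gz", p$id, r))
      write_nifti(p$volumes[[r]], path)
      manifest <- c(manifest, path)
    }
  }
  tsv <- file.path(directory, "participants.tsv")
  df <- if (length(cohort$participants)) {
    clinical_table(cohort)
  } else {
    stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = 2 + length(cohort$clinical_names))),
      c("participant_id", "diagnosis", cohort$clinical_names))
  }
  utils::write.table(format(df, digits = 10, trim = TRUE, scientific = FALSE),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(manifest, tsv)
  invisible(manifest)
}
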