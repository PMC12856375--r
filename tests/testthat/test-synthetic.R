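test_that("cohort at full shape has the reference counts", {
  co <- generate_cohort(cohort_spec(n_per_group = 26, seed = 5))
  expect_length(co$participants, 52)
  n_vol <- sum(vapply(co$participants, function(p) length(p$volumes), 0L))
  expect_identical(n_vol, 208L)
  n_data <- sum(vapply(co$participants, function(p)
    length(p$volumes) + length(p$clinical_raw), 0L))
  expect_identical(n_data, 520L)
  labs <- cohort_labels(co)
  expect_identical(as.integer(table(labs)[c("AD", "CN")]), c(26L, 26L))
  expect_false(anyDuplicated(names(labs)) > 0)
})

test_that("same spec and seed give a bit-identical cohort", {
  spec <- cohort_spec(n_per_group = 2, grid_size = c(8, 8, 8), seed = 99)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
})

test_that("volumes are correlation-like and AD shift lands in the signal region", {
  eff <- effect_config(roi_effect = -0.3, signal_region = list(lo = c(2, 2, 2),
                                                               hi = c(6, 6, 6)))
  co <- generate_cohort(cohort_spec(n_per_group = 12, grid_size = c(8, 8, 8),
                                    seed = 3), eff)
  vals <- unlist(lapply(co$participants, function(p) p$volumes[[1]]))
  expect_true(all(vals >= -1 & vals <= 1))
  labs <- cohort_labels(co)
  region_mean <- function(p) mean(p$volumes[[1]][3:6, 3:6, 3:6])
  ad <- mean(vapply(co$participants[labs == "AD"], region_mean, 0))
  cn <- mean(vapply(co$participants[labs == "CN"], region_mean, 0))
  expect_lt(ad, cn)  # negative connectivity shift in AD
})

test_that("null configuration produces no clinical group separation", {
  # Monte-Carlo: under the null, group mean differences should stay within
  # 4 SE; with 20 seeds x 6 measures, P(any |z| > 4) is ~1e-2, allow 1
  violations <- 0L
  for (s in 1:20) {
    co <- generate_cohort(cohort_spec(n_per_group = 15, grid_size = c(4, 4, 4),
                                      seed = 1000 + s), null_effect_config())
    df <- clinical_table(co)
    for (m in dmn_clinical_names()) {
      x <- df[[m]][df$diagnosis == "AD"]
      y <- df[[m]][df$diagnosis == "CN"]
      se <- sqrt(var(x) / length(x) + var(y) / length(y))
      if (abs(mean(x) - mean(y)) > 4 * se) violations <- violations + 1L
    }
  }
  expect_lte(violations, 1L)
})

test_that("configured clinical separation is recovered within 3 SE", {
  # pool many participants at one seed; truncation can only shrink the
  # separation for measures whose means sit far from the bounds, so test a
  # mid-range measure (ADAS13 config: 21 points apart, sd 5)
  co <- generate_cohort(cohort_spec(n_per_group = 200, grid_size = c(2, 2, 2),
                                    seed = 7), clinical_only_effect())
  df <- clinical_table(co)
  x <- df$ADAS13[df$diagnosis == "AD"]; y <- df$ADAS13[df$diagnosis == "CN"]
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  expect_lt(abs((mean(x) - mean(y)) - 21), 3 * se)
})

test_that("voxels outside the signal region are distribution-identical across groups", {
  # two-sample t-test on pooled out-of-region voxel means, per ROI,
  # Bonferroni at alpha 0.01
  eff <- effect_config(roi_effect = -0.5, signal_region = list(lo = c(0, 0, 0),
                                                               hi = c(4, 8, 8)))
  pool_ad <- vector("list", 4); pool_cn <- vector("list", 4)
  for (s in 1:6) {
    co <- generate_cohort(cohort_spec(n_per_group = 10, grid_size = c(8, 8, 8),
                                      seed = 300 + s), eff)
    labs <- cohort_labels(co)
    for (r in 1:4) {
      out_mean <- function(p) mean(p$volumes[[r]][5:8, , ])
      pool_ad[[r]] <- c(pool_ad[[r]],
                        vapply(co$participants[labs == "AD"], out_mean, 0))
      pool_cn[[r]] <- c(pool_cn[[r]],
                        vapply(co$participants[labs == "CN"], out_mean, 0))
    }
  }
  pvals <- vapply(1:4, function(r)
    t.test(pool_ad[[r]], pool_cn[[r]])$p.value, numeric(1))
  expect_true(all(pvals > 0.01 / 4))
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(n_per_group = 0), class = "dmnfuse_invalid_spec")
  expect_error(effect_config(roi_noise_sd = 0), class = "dmnfuse_invalid_spec")
  expect_error(
    generate_cohort(cohort_spec(n_per_group = 1, grid_size = c(4, 4, 4)),
                    effect_config(signal_region = list(lo = c(0, 0, 0),
                                                       hi = c(5, 4, 4)))),
    class = "dmnfuse_invalid_spec")
})

test_that("write_cohort lays out BIDS-like files and round-trips", {
  co <- tiny_cohort(n_per_group = 2, grid = 8, seed = 21)
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_identical(sum(grepl("\\.nii\\.gz$", manifest)), 16L)  # 4 subj x 4 ROI
  expect_true(file.exists(file.path(dir, "participants.tsv")))
  back <- load_cohort(dir)
  expect_identical(vapply(back$participants, `[[`, "", "id"),
                   vapply(co$participants, `[[`, "", "id"))
  for (i in seq_along(co$participants)) {
    expect_equal(back$participants[[i]]$clinical_raw,
                 co$participants[[i]]$clinical_raw, tolerance = 1e-6)
    expect_equal(back$participants[[i]]$volumes[[1]],
                 co$participants[[i]]$volumes[[1]], tolerance = 1e-6)
  }
})

test_that("empty cohort writes a header-only participants table", {
  co <- tiny_cohort(n_per_group = 2, grid = 8, seed = 21)
  co$participants <- list()
  dir <- withr::local_tempdir()
  manifest <- write_cohort(co, dir)
  expect_identical(sum(grepl("\\.nii\\.gz$", manifest)), 0L)
  tsv <- read.table(file.path(dir, "participants.tsv"), sep = "\t",
                    header = TRUE)
  expect_identical(nrow(tsv), 0L)
  expect_true(all(c("participant_id", "diagnosis", "MoCA") %in% names(tsv)))
})
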