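test_that("feature set covers 4 ROIs plus 6 clinical measures in frozen order", {
  f <- feature_ids()
  expect_identical(nrow(f), 10L)
  expect_identical(f$name[1:4], dmn_roi_names())
  expect_identical(f$name[5:10], dmn_clinical_names())
  expect_false(anyDuplicated(f$name) > 0)
})

make_bundle <- function(seed = 1, grid = 8) {
  co <- tiny_cohort(n_per_group = 2, grid = grid, seed = seed)
  assemble_bundle(co$participants[[1]], fit_normalization(co))
}

test_that("perturbation is local: only the named feature changes", {
  b <- make_bundle()
  f <- feature_ids()
  set.seed(1)
  for (i in c(2, 7)) {
    pb <- perturb_feature(b, f[i, ])
    for (j in seq_len(4)) {
      if (f$kind[i] == "roi" && f$index[i] == j) next
      expect_identical(pb$image_stack[j, , , ], b$image_stack[j, , , ])
    }
    for (j in seq_len(6)) {
      if (f$kind[i] == "clinical" && f$index[i] == j) next
      expect_identical(pb$clinical[[j]], b$clinical[[j]])
    }
    expect_identical(pb$label, b$label)
  }
})

test_that("perturbation strategies respect their contracts", {
  b <- make_bundle(seed = 2)
  f <- feature_ids()
  set.seed(9)
  # ROI permutation preserves the voxel multiset
  pb <- perturb_feature(b, f[3, ])
  expect_equal(sort(as.vector(pb$image_stack[3, , , ])),
               sort(as.vector(b$image_stack[3, , , ])))
  # clinical replacement stays in the normalized range
  for (r in 1:20) {
    pc <- perturb_feature(b, f[6, ])
    expect_true(pc$clinical[[2]] >= 0 && pc$clinical[[2]] <= 1)
  }
  # gaussian ROI strategy matches channel moments loosely
  pg <- perturb_feature(b, f[1, ], roi_strategy = "gaussian")
  expect_equal(mean(pg$image_stack[1, , , ]), mean(b$image_stack[1, , , ]),
               tolerance = 0.2)
  # reference strategy draws from the supplied pool
  pr <- perturb_feature(b, f[5, ], clinical_strategy = "reference",
                        reference_values = c(0.25))
  expect_identical(pr$clinical[[1]], 0.25)
  expect_error(perturb_feature(b, list(kind = "clinical", index = 99)),
               class = "dmnfuse_invalid_spec")
})

test_that("clinical perturbations cannot move a unimodal model", {
  b <- make_bundle(seed = 3)
  um <- build_model(model_config(mode = "unimodal"), seed = 4)
  base <- bce_loss(predict_bundle(um, b), b$label)
  set.seed(2)
  errs <- fold_perturbation_errors(um, b, feature_ids(), n_repeats = 2)
  for (m in dmn_clinical_names()) expect_identical(errs[[m]], base)
})

test_that("an analytically informative feature ranks first", {
  # hand-built probe: zero the last conv layer so image features are
  # constant, and wire the head to pass only the MoCA score through
  b <- make_bundle(seed = 5)
  m <- build_model(model_config(dropout = 0), seed = 6)
  conv6 <- m$extractor[[16]]
  expect_identical(conv6$type, "conv3d")
  conv6$set_params(list(W = conv6$W * 0, b = conv6$b * 0))
  lin1 <- m$head[[1]]
  W1 <- lin1$W * 0
  moca_col <- 64 + match("MoCA", dmn_clinical_names())
  W1[, moca_col] <- 1
  lin1$set_params(list(W = W1, b = lin1$b * 0))
  lin2 <- m$head[[5]]
  lin2$set_params(list(W = matrix(1, 1, 32), b = 0))

  # baseline sits at the decision boundary (MoCA = 0 -> p = 0.5); only a
  # MoCA perturbation can push the output off it
  b$clinical[["MoCA"]] <- 0
  set.seed(11)
  errs <- fold_perturbation_errors(m, b, feature_ids(), n_repeats = 30)
  expect_identical(names(which.max(errs)), "MoCA")
  expect_true(all(errs[setdiff(names(errs), "MoCA")] < errs[["MoCA"]]))
})

test_that("fold_perturbation_errors is reproducible under seeding", {
  b <- make_bundle(seed = 6)
  m <- build_model(model_config(), seed = 8)
  a1 <- dmnfuse:::with_seed(33, fold_perturbation_errors(m, b, n_repeats = 3))
  a2 <- dmnfuse:::with_seed(33, fold_perturbation_errors(m, b, n_repeats = 3))
  expect_identical(a1, a2)
})

test_that("importance aggregation reproduces the reference worked example", {
  ref <- reference_errors()
  imp <- aggregate_importance(ref)
  cn <- imp[imp$group == "CN", ]
  ad <- imp[imp$group == "AD", ]
  expect_equal(cn$importance[cn$feature == "FAQ"], 0.595, tolerance = 5e-4)
  expect_equal(ad$importance[ad$feature == "EcogPtTotal"], 0.670,
               tolerance = 5e-4)
  # each group's top-ranked feature has importance exactly 1
  expect_identical(cn$importance[cn$rank == 1], 1)
  expect_identical(ad$importance[ad$rank == 1], 1)
  expect_identical(cn$feature[cn$rank == 1], "MoCA")
  expect_identical(ad$feature[ad$rank == 1], "RAVLT_pct_forgetting")
  # recomputed importances match the printed ones within rounding slack
  printed_cn <- c(MoCA = 1.000, RAVLT_immediate = 0.753, FAQ = 0.595,
                  EcogPtTotal = 0.590, ADAS13 = 0.553,
                  RAVLT_pct_forgetting = 0.512)
  expect_equal(setNames(cn$importance, cn$feature)[names(printed_cn)],
               printed_cn, tolerance = 3e-3)
  # ranks are permutations of 1..K
  expect_setequal(cn$rank, 1:6)
  expect_setequal(ad$rank, 1:6)
})

test_that("ties in mean error break by the frozen feature order", {
  flat <- list(CN = setNames(rep(0.2, 6), dmn_clinical_names()),
               AD = setNames(rep(0.2, 6), dmn_clinical_names()))
  imp <- aggregate_importance(flat)
  cn <- imp[imp$group == "CN", ]
  expect_identical(cn$rank, 1:6)
  expect_identical(cn$feature, dmn_clinical_names())
  expect_true(all(imp$importance == 1))
})

test_that("aggregation over fold outcomes averages within diagnosis group", {
  feats <- c("a", "b")
  mk <- function(g, e) list(group = g,
                            perturbation_errors = setNames(e, feats))
  outs <- list(mk("CN", c(0.1, 0.3)), mk("CN", c(0.3, 0.5)),
               mk("AD", c(0.6, 0.2)))
  imp <- aggregate_importance(outs)
  cn <- imp[imp$group == "CN", ]
  expect_equal(cn$mean_error, c(0.2, 0.4))
  expect_identical(cn$rank, c(2L, 1L))
  expect_equal(cn$importance, c(0.5, 1))
  expect_error(aggregate_importance(outs[1:2]),
               class = "dmnfuse_invalid_spec")  # no AD folds
})

test_that("rank change follows the CN-minus-AD convention", {
  imp <- aggregate_importance(reference_errors())
  rc <- rank_change(imp)
  expect_identical(rc$change[rc$feature == "MoCA"], 1L - 6L)
  expect_identical(rc$change[rc$feature == "FAQ"], 0L)
  expect_identical(sum(rc$change), 0L)
  # identical rankings give all-zero changes
  same <- aggregate_importance(list(CN = reference_errors()$CN,
                                    AD = reference_errors()$CN))
  expect_true(all(rank_change(same)$change == 0L))
  # mismatched feature sets are rejected
  broken <- imp[!(imp$group == "AD" & imp$feature == "MoCA"), ]
  expect_error(rank_change(broken), class = "dmnfuse_invalid_spec")
})
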