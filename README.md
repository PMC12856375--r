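# dmnfuse

Multimodal 3-D convolutional classification of Alzheimer's disease (AD)
versus cognitively normal (CN) participants from default-mode-network (DMN)
connectivity maps fused with neuropsychological scores — with built-in
explainability and a synthetic cohort generator, so the full pipeline is
testable without access to any clinical dataset.

**Who it is for.** Researchers studying small-sample multimodal fusion in
neuroimaging: the package packages the whole protocol — data layout,
normalization, leakage-safe leave-one-out cross-validation (LOOCV),
training, metrics, and perturbation-based feature ranking — as composable,
seeded, unit-tested R functions.

## The method

Each participant contributes four co-registered 3-D seed-correlation maps
(posterior cingulate, left/right lateral parietal, medial prefrontal) and
six clinical scores (ADAS13, ECog patient total, FAQ, MoCA, RAVLT immediate,
RAVLT % forgetting), min-max normalized:

    x_norm = (x − x_min) / (x_max − x_min)

A convolutional extractor (4→8→16→24→24→32→64 channels; first kernel 6³,
then 3³; 3³/stride-2 max-pools; global max-pool) compresses the 4-channel
volume to 64 features; the multimodal head concatenates the 6 clinical
scores (70 inputs) before a 32-unit linear layer and a sigmoid output
(unimodal variant: images only, 64 inputs). Training: BCE loss, Adam,
random flip/90°-rotation augmentation, LOOCV with the final-epoch model
evaluating each held-out participant. From the pooled held-out predictions
(AD positive):

    accuracy% = 100·(TP+TN)/n        sensitivity = TP/(TP+FN)
    specificity = TN/(TN+FP)         precision = TP/(TP+FP)
    F1 = 2TP/(2TP+FP+FN)             MCC = (TP·TN − FP·FN)/√(…)

**Perturbation ranking**: each of the 10 features (4 ROI channels + 6
scores) is randomized on every fold's held-out participant; per-feature
errors are averaged within diagnosis group, ranked (1 = most important),
and normalized by the group maximum so each group's top feature has
importance exactly 1.0. Rank change = CN rank − AD rank.

The network and optimizer are implemented natively (R + Rcpp/Armadillo
GEMM convolutions); no deep-learning framework is required. Backprop is
verified against finite differences and independent direct-loop oracles in
the test suite.

## Worked example

Metric arithmetic on the published confusion structure (26 AD / 26 CN;
sensitivity 0.84, specificity 0.96):

```r
library(dmnfuse)
cm <- recover_confusion_from_rates(0.84, 0.96, 26, 26)
cm
#> TP FN TN FP
#> 22  4 25  1
compute_metrics(cm)
#> confusion (AD positive): TP 22  FN 4  TN 25  FP 1
#> accuracy 90.38%  sensitivity 0.85  specificity 0.96
#> precision 0.96  F1 0.90  MCC 0.81
```

An end-to-end synthetic run — generate a cohort with clinical-only group
signal, train both model variants under LOOCV, and rank features:

```r
co <- generate_cohort(cohort_spec(n_per_group = 4, grid_size = c(12, 12, 12),
                                  seed = 42))
res <- run_loocv(co, model_config(),
                 train_config(scale = "test", epochs = 3, n_repeats = 5,
                              seed = 42))
compute_metrics(confusion_counts(res))$accuracy
#> [1] 100
imp <- aggregate_importance(res)
head(imp[imp$group == "CN", ], 3)
#>   group feature mean_error rank importance
#> 1    CN     PCC  0.3546318    8  0.7249417
#> 2    CN    LP_L  0.3546489    5  0.7249766
#> 3    CN    LP_R  0.3546354    7  0.7249490
```

(The default synthetic world separates groups on all six clinical measures
and shifts DMN connectivity downward in AD, so even this minimal
configuration classifies perfectly; importances quantify which inputs the
trained network actually used.)

The same pipeline is scriptable from the command line via the installed
CLI (`system.file("cli", "dmnfuse", package = "dmnfuse")`):
`simulate`, `run`, `rank`, `report`, `compare` subcommands with `--seed`,
`--mode {multimodal,unimodal,both}` and `--scale {paper,test}` flags.

## Documentation

The methods vignette
(`vignettes/multimodal-dmn-classification.Rmd`) documents the model and its
assumptions, the synthetic world and what green tests do/don't establish,
numerical choices (batch-norm calibration, tie-breaking, seeding), and
known limitations.
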