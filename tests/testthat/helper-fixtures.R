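# Shared fixtures, generated in code (no binary files ship with the package).

# small cohort for structural tests; memoised per (n, grid, seed, null)
.fixture_env <- new.env(parent = emptyenv())

tiny_cohort <- function(n_per_group = 3, grid = 8, seed = 11, null = FALSE) {
  key <- paste(n_per_group, grid, seed, null, sep = "_")
  if (is.null(.fixture_env[[key]])) {
    eff <- if (null) null_effect_config() else effect_config()
    .fixture_env[[key]] <- generate_cohort(
      cohort_spec(n_per_group = n_per_group, grid_size = rep(grid, 3),
                  seed = seed), eff)
  }
  .fixture_env[[key]]
}

# effect configuration with group signal in exactly two clinical measures
# (ADAS13: 21/5 = 4.2 SD; MoCA: 9/3 = 3 SD) and a null imaging effect —
# the stated world for the multimodal-vs-unimodal property experiments
clinical_only_effect <- function() {
  means <- list(
    ADAS13               = c(cn = 9,   ad = 30),
    EcogPtTotal          = c(cn = 1.4, ad = 1.4),
    FAQ                  = c(cn = 1,   ad = 1),
    MoCA                 = c(cn = 26,  ad = 17),
    RAVLT_immediate      = c(cn = 45,  ad = 45),
    RAVLT_pct_forgetting = c(cn = 35,  ad = 35))
  effect_config(clinical_means = means, roi_effect = 0)
}

# worked-example per-group mean perturbation errors over the six clinical
# measures (reference values shipped as plain text)
reference_errors <- function() {
  path <- system.file("extdata", "reference_group_errors.tsv",
                      package = "dmnfuse")
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  list(CN = setNames(df$CN_error, df$feature),
       AD = setNames(df$AD_error, df$feature))
}

random_stack <- function(channels = 2, grid = 6, seed = 1) {
  set.seed(seed)
  array(rnorm(channels * grid^3), c(channels, grid, grid, grid))
}
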