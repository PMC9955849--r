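# Shared fixtures. The posture model is expensive to train, so tests that
# only need *a* trained model share one, built lazily and cached for the
# whole test run.

.fixture_env <- new.env(parent = emptyenv())

cached_posture_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    cohort <- simulate_cohort(3, seed = 401)
    .fixture_env$fit <- fit_posture_model(
      cohort,
      K = 3, config = svi_config(steps = 1200), seed = 402
    )
  }
  .fixture_env$fit
}

cached_model_dir <- function() {
  if (is.null(.fixture_env$model_dir)) {
    dir <- file.path(tempdir(), "fallgmm-model")
    dir.create(dir, showWarnings = FALSE)
    write_model_json(cached_posture_fit(), file.path(dir, "model.json"))
    .fixture_env$model_dir <- dir
  }
  .fixture_env$model_dir
}

# small, fast mixture-fit configuration for tests that exercise mechanics
fast_config <- function(steps = 400L, ...) svi_config(steps = steps, ...)

# Mclust resolves mclustBIC in the search path, so the oracle package must be
# attached, not just loaded
if (requireNamespace("mclust", quietly = TRUE)) {
  suppressPackageStartupMessages(library(mclust))
}
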