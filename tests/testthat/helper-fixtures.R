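# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

ref_model <- function(seed = 1L) {
  key <- paste0("model", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_reference(seed = seed)
  .fixture_env[[key]]
}

iran20_results <- function() {
  if (is.null(.fixture_env$iran20)) {
    model <- ref_model()
    cohort <- generate_cohort(model, load_fixture("iran20"))
    .fixture_env$iran20 <- list(
      model = model, cohort = cohort,
      res = run_pipeline(cohort$sequences, model))
  }
  .fixture_env$iran20
}
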