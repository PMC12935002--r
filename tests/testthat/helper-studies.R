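# The full-scale synthetic studies used by the acceptance checks are
# expensive; build each once per test run and reuse across test blocks.
.study_cache <- new.env(parent = emptyenv())

full_study <- function(condition) {
  key <- paste0("study_", condition)
  if (is.null(.study_cache[[key]])) {
    cfg <- study_config(
      co2_schedule = data.frame(frame = 1, condition = condition),
      seed = if (condition == "air") 1L else 2L)
    .study_cache[[key]] <- run_timelapse_study(cfg)
  }
  .study_cache[[key]]
}
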