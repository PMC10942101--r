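# Shared setup for the analysis drivers: one deterministic study session
# (coupling deficit + onset lag phenotypes on) and one matched null session.
# Sessions are regenerated from the config on demand -- cheaper and exactly
# reproducible, so no multi-megabyte trace files need to live on disk.

library(spinefate)

RESULTS <- file.path("results")
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

STUDY_SEED <- 20240315L

study_config <- function(deficit = 0.5, lag = 0.05, seed = STUDY_SEED) {
  sim_config(seed = seed,
             eliminated_coupling_deficit = deficit,
             eliminated_lag = lag)
}

get_session <- function(kind = c("effect", "null")) {
  kind <- match.arg(kind)
  if (kind == "effect") {
    generate_session(study_config())
  } else {
    generate_session(study_config(deficit = 0, lag = 0, seed = STUDY_SEED + 1L))
  }
}
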