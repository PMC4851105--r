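# Study-scale fixture: 15 subjects x 5 shots under the default generator,
# with segments and feature tables. Only seed 1 is cached (reused across
# tests); other seeds are built on demand by the caller.

study_fixture <- function(seed) {
  build <- function() {
    sim <- simulate_shots(default_study_config(seed = seed))
    segments <- lapply(sim$dataset$recordings, extract_segment)
    tables <- build_feature_tables(sim$dataset, segments)
    list(sim = sim, segments = segments, tables = tables)
  }
  if (seed == 1) memo("study_fixture_1", build()) else build()
}

# base-learner score sets for every feature set of a fixture
base_scoresets <- function(fx, task, target = "speed", B = 500,
                           q_search = FALSE) {
  out <- list()
  for (nm in names(fx$tables)) {
    cfg <- forest_config(B = B, task = task,
                         seed = 7 + match(nm, names(fx$tables)))
    out[[nm]] <- if (q_search) {
      q_grid_search(fx$tables[[nm]], cfg, target = target)$scores
    } else {
      oob_scores(fit_forest(fx$tables[[nm]], cfg, target = target))
    }
  }
  out
}
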