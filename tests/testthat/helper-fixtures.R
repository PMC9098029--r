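# Shared small-scale fixtures, built once per test run.

small_design <- function(n_studies = 3L, n_participants = 12L, n_trials = 24L) {
  st <- default_study_table()[seq_len(n_studies), , drop = FALSE]
  st$n_participants <- rep(as.integer(n_participants), n_studies)
  st$n_trials <- rep(as.integer(n_trials), n_studies)
  st
}

small_cfg <- function(..., n_voxels = 600L, n_regions = 12L, n_frsn = 4L,
                      n_crsn = 2L, studies = small_design()) {
  generator_config(studies = studies, n_voxels = n_voxels,
                   n_regions = n_regions, n_frsn = n_frsn, n_crsn = n_crsn, ...)
}

fast_analysis_cfg <- function(...) {
  analysis_config(inner_folds = 5L, innermost_folds = 3L,
                  opt = opt_config("grid"), ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, build) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- build()
  .fixture_cache[[key]]
}

# A small MULTISYSTEM world: parcellation, simulation, quartile data, spaces.
small_world <- function(seed = 1L, scenario = "MULTISYSTEM") {
  cached_fixture(paste0("world_", scenario, "_", seed), function() {
    cfg <- small_cfg(scenario = scenario)
    parc <- make_nested_parcellation(cfg, seed = seed)
    sim <- simulate_multistudy(cfg, parc, seed = seed)
    qd <- preprocess_datasets(sim$datasets)
    list(cfg = cfg, parc = parc, sim = sim, qd = qd,
         spaces = build_model_spaces(parc))
  })
}

# Direct quartile-style dataset with a planted linear signal, for decoder
# unit tests that do not need the full generator.
toy_qdata <- function(n_participants = 20L, V = 60L, seed = 1L,
                      signal_voxels = 1:5, snr = 1) {
  set.seed(seed)
  pid <- rep(sprintf("p%02d", seq_len(n_participants)), each = 4L)
  n <- length(pid)
  y <- as.vector(scale(rnorm(n)))
  X <- matrix(rnorm(n * V), n, V)
  for (v in signal_voxels) X[, v] <- X[, v] + snr * y
  meta <- data.frame(study = "S1", participant_id = pid,
                     quartile = rep(1:4, n_participants), rating = y,
                     n_trials = 5L, stringsAsFactors = FALSE)
  quartile_dataset(X, meta, mask_geometry(c(V, 1L, 1L), seq_len(V)),
                   factor_schema = list(S1 = character(0)))
}
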