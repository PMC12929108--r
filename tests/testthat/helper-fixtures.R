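# Small shared fixtures, built in code at test time.

# a tiny, fast two-state model for end-to-end smoke tests
tiny_model <- function(n_rois = 8) {
  covs <- make_state_covariances(n_rois, list(
    list(list(nodes = 1:(n_rois / 2), level = 0.7),
         list(nodes = (n_rois / 2 + 1):n_rois, level = 0.7)),
    list(list(nodes = 1:n_rois, level = 0.05))
  ))
  p <- matrix(c(0.95, 0.05,
                0.05, 0.95), 2, 2, byrow = TRUE)
  latent_state_model(covs, p)
}

tiny_cohort <- function(seed = 1, n_timepoints = 80) {
  simulate_cohort(model = tiny_model(),
                  groups = list(group_spec("A", 3), group_spec("B", 3)),
                  n_timepoints = n_timepoints, seed = seed)
}

# the desk-scale default cohort run used by several acceptance checks;
# computed once per test session
default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_dfc_pipeline(dfc_config(n_perm = 200,
                                            run_graph_stats = FALSE,
                                            seed = 20240401))
    }
    cache
  }
})
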