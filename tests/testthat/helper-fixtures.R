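# The standard synthetic benchmark: three well-separated Gaussian blobs in
# a 10-dimensional embedding, swept over five resolutions.
standard_fixture_sweep <- function(seed, reps = 50, fraction = 0.8,
                                   n_cells = 600) {
  sim <- simulate_reduced(k = 3, n_cells = n_cells, d = 10,
                          separation = 10, seed = seed)
  sw <- cluster_sweep(sim$reduced, grid = c(0.1, 0.3, 0.6, 1.0, 2.0),
                      reps = reps, fraction = fraction,
                      config = backend_config(knn_k = 20),
                      n_boot = 25000, seed = seed)
  list(sweep = sw, truth = sim$labels)
}
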