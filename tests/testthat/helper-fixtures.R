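# Small cohorts used across tests; built in code, sized for speed.

tiny_spec <- function(seed = 11L, noise_sigma = 0.2, kappa = 8,
                      n_frames = 80L, n_areas = 20L, n_conditions = 1L,
                      n_group_a = 4L, n_group_b = 3L) {
  synthetic_spec(n_group_a = n_group_a, n_group_b = n_group_b,
                 n_conditions = n_conditions, n_areas = n_areas,
                 n_frames = n_frames, tr = 2, n_states = 3,
                 occupancy_a = c(0.5, 0.3, 0.2),
                 occupancy_b = c(0.5, 0.3, 0.2),
                 noise_sigma = noise_sigma, phase_jitter_kappa = kappa,
                 seed = seed)
}

# a filtered eigen sample from a tiny cohort (memoised per session)
tiny_sample <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- generate_cohort(tiny_spec())
      f <- lapply(co$scans, bandpass_filter)
      cache <<- list(sample = pool_eigenvectors(f), truth = co$truth,
                     manifest = co$manifest)
    }
    cache
  }
})

# noiseless single-scan builder with a fixed constant state
constant_state_scan <- function(state, n_areas = 12L, n_frames = 100L,
                                minority_sets = list(7:12, 1:4)) {
  spec <- synthetic_spec(n_group_a = 1, n_group_b = 1, n_conditions = 1,
                         n_areas = n_areas, n_frames = n_frames, tr = 2,
                         n_states = 3, minority_sets = minority_sets,
                         occupancy_a = c(0.5, 0.3, 0.2),
                         occupancy_b = c(0.5, 0.3, 0.2),
                         noise_sigma = 0, phase_jitter_kappa = Inf, seed = 5L)
  cen <- make_planted_centroids(3, n_areas, minority_sets)
  synthesize_scan(cen, rep(state, n_frames), spec, seed = 7L)
}
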