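test_that("planted centroids are unit norm with the stated community signs", {
  C <- make_planted_centroids(2, 4, list(c(3, 4)))
  expect_equal(sqrt(rowSums(C^2)), c(state1 = 1, state2 = 1), tolerance = 1e-12)
  expect_true(all(C[1, ] < 0))                     # global mode: one sign
  expect_equal(sign(C[2, ]), c(-1, -1, 1, 1))      # minority positive
  C90 <- make_planted_centroids(4, 90, list(1:18, 31:50, 61:78))
  expect_true(all(abs(sqrt(rowSums(C90^2)) - 1) < 1e-12))
  expect_true(all(C90[1, ] < 0))
  # majority of elements negative in every centroid
  expect_true(all(rowSums(C90 < 0) > 45))
})

test_that("degenerate community definitions are rejected", {
  expect_error(make_planted_centroids(2, 4, list(integer(0))), "empty")
  expect_error(make_planted_centroids(2, 4, list(1:4)), "full area set")
  expect_error(synthetic_spec(n_states = 2, n_areas = 10,
                              minority_sets = list(integer(0)),
                              occupancy_a = c(0.5, 0.5),
                              occupancy_b = c(0.5, 0.5)),
               "empty")
  expect_error(synthetic_spec(carrier_freq = 0.15), "band")
})

test_that("markov sequences honour the transition structure", {
  # absorbing chain: identity matrix keeps the initial state forever
  s <- sample_state_sequence(diag(3), 50, seed = 1)
  expect_length(unique(s), 1L)
  # determinism
  P <- occupancy_transition_matrix(c(0.3, 0.7), 0.6)
  expect_identical(sample_state_sequence(P, 200, seed = 42),
                   sample_state_sequence(P, 200, seed = 42))
  # invalid matrix
  expect_error(sample_state_sequence(matrix(c(0.5, 0.2, 0.5, 0.2), 2), 10),
               "sum to 1")
})

test_that("long-run occupancy matches the stationary distribution", {
  # symmetric 2-state chain with p(stay) = 0.9 has stationary (0.5, 0.5)
  P <- matrix(c(0.9, 0.1, 0.1, 0.9), 2, byrow = TRUE)
  s <- sample_state_sequence(P, 1e5, seed = 3)
  occ <- tabulate(s, 2) / length(s)
  expect_equal(occ, c(0.5, 0.5), tolerance = 0.01)
  # and the constructed matrix reproduces a requested asymmetric target
  pi_t <- c(0.47, 0.25, 0.2, 0.08)
  P4 <- occupancy_transition_matrix(pi_t, 0.5)
  s4 <- sample_state_sequence(P4, 1e5, seed = 4)
  expect_equal(tabulate(s4, 4) / length(s4), pi_t, tolerance = 0.01)
})

test_that("noiseless constant-state scans give the exact coherence pattern", {
  # global state: all areas identical -> dFC all ones
  ts <- constant_state_scan(1)
  ph <- instantaneous_phase(bandpass_filter(ts))
  mid <- nrow(ph$theta) %/% 2
  C <- phase_coherence(ph$theta[mid, ])
  expect_true(all(abs(C - 1) < 1e-6))
  # two-community state: +1 within, -1 between communities
  ts2 <- constant_state_scan(2)
  ph2 <- instantaneous_phase(bandpass_filter(ts2))
  C2 <- phase_coherence(ph2$theta[mid, ])
  inside <- 7:12
  outside <- 1:6
  expect_true(all(abs(C2[inside, inside] - 1) < 1e-3))
  expect_true(all(abs(C2[outside, outside] - 1) < 1e-3))
  expect_true(all(abs(C2[inside, outside] + 1) < 1e-3))
})

test_that("cohort generation matches the requested shape and is deterministic", {
  spec <- tiny_spec(seed = 21L)
  co <- generate_cohort(spec)
  expect_length(co$scans, 7L)
  expect_equal(nrow(co$manifest), 7L)
  expect_equal(sort(unique(co$manifest$group)), c("A", "B"))
  # planted occupancy rows sum to 1 exactly
  expect_true(all(abs(rowSums(co$truth$planted_occupancy) - 1) < 1e-12))
  # state sequences in range
  expect_true(all(vapply(co$truth$state_sequences,
                         function(s) all(s >= 1 & s <= spec$n_states),
                         logical(1))))
  # bit-identical regeneration
  co2 <- generate_cohort(tiny_spec(seed = 21L))
  expect_identical(co$scans[[3]]$data, co2$scans[[3]]$data)
  expect_identical(co$truth$state_sequences, co2$truth$state_sequences)
  # different seed -> different data, same shape
  co3 <- generate_cohort(tiny_spec(seed = 22L))
  expect_false(identical(co$scans[[1]]$data, co3$scans[[1]]$data))
  expect_identical(dim(co$scans[[1]]$data), dim(co3$scans[[1]]$data))
})

test_that("identical transition matrices plant a zero group difference", {
  spec <- tiny_spec(seed = 8L)   # occupancy_a == occupancy_b
  co <- generate_cohort(spec)
  occ <- co$truth$planted_occupancy
  grp <- co$manifest$group
  diff <- colMeans(occ[grp == "A", , drop = FALSE]) -
    colMeans(occ[grp == "B", , drop = FALSE])
  # no systematic difference beyond sampling noise at these sizes
  expect_true(all(abs(diff) < 0.15))
})

test_that("cohort round-trips through disk (TSV + manifest + truth JSON)", {
  dir <- withr::local_tempdir()
  spec <- tiny_spec(seed = 31L, n_group_a = 2L, n_group_b = 1L,
                    n_frames = 40L, n_areas = 6L)
  co <- generate_cohort(spec)
  manifest <- simulate_cohort(spec, dir)
  expect_true(file.exists(manifest))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  scans <- read_cohort(manifest)
  expect_length(scans, 3L)
  expect_equal(scans[[2]]$data, co$scans[[2]]$data, tolerance = 1e-12)
  expect_identical(scans[[2]]$scan_id, co$manifest$scan_id[2])
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_equal(unname(as.matrix(truth$planted_centroids)),
               unname(co$truth$planted_centroids), tolerance = 1e-12)
})
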