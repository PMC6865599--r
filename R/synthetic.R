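#' Build a transition matrix with a prescribed stationary distribution
#'
#' Constructs `P = (1 - s) * I + s * 1 %o% pi`, a convex combination of staying
#' put and resampling from `pi`. Its stationary distribution is exactly `pi`,
#' and `s` ("stickiness" of the complementary jump process) controls dwell
#' times: the mean dwell of state `i` is `1 / (s * (1 - pi_i))` frames.
#'
#' @param pi stationary probability vector (sums to 1)
#' @param stickiness jump probability `s` in (0, 1]
#' @return row-stochastic matrix
#' @export
occupancy_transition_matrix <- function(pi, stickiness = 0.5) {
  stopifnot(all(pi >= 0), abs(sum(pi) - 1) < 1e-12,
            stickiness > 0, stickiness <= 1)
  k <- length(pi)
  P <- (1 - stickiness) * diag(k) + stickiness * matrix(pi, k, k, byrow = TRUE)
  check_row_stochastic(P)
  P
}

#' Specification of a synthetic phase-coupled cohort
#'
#' Defines a cohort of narrowband oscillatory "BOLD-like" signals whose
#' pairwise phase relations follow a hidden first-order Markov sequence over
#' planted phase-community patterns. Defaults mirror a two-group resting-state
#' study: 51 + 35 subjects, 2 conditions, 210 frames of 90 areas at TR = 2 s,
#' signals in the 0.02-0.1 Hz band, and 4 planted states whose stationary
#' occupancies differ between groups in one target state (0.08 vs 0.05).
#'
#' @param n_group_a,n_group_b subjects per group
#' @param n_conditions scans (conditions) per subject
#' @param n_areas parcels per scan
#' @param n_frames frames per scan
#' @param tr repetition time, seconds
#' @param n_states number of planted states (state 1 is the global mode)
#' @param minority_sets list of integer vectors, one per non-global state:
#'   the areas forming the minority phase community of that state
#' @param carrier_freq carrier frequency in Hz, strictly inside (0.02, 0.1)
#' @param phase_jitter_kappa von Mises concentration of per-area phase jitter
#'   (`Inf` = no jitter)
#' @param noise_sigma SD of additive Gaussian noise, relative to unit amplitude
#' @param occupancy_a,occupancy_b per-state stationary occupancies per group
#'   (used when transition matrices are not supplied directly)
#' @param stickiness jump probability of the planted Markov chain
#' @param transition_matrix_a,transition_matrix_b optional explicit
#'   row-stochastic transition matrices (override the occupancy construction)
#' @param seed RNG seed for the cohort
#' @return object of class `leida_synth_spec`
#' @export
synthetic_spec <- function(n_group_a = 51, n_group_b = 35, n_conditions = 2,
                           n_areas = 90, n_frames = 210, tr = 2,
                           n_states = 4,
                           minority_sets = NULL,
                           carrier_freq = 0.05,
                           phase_jitter_kappa = 8,
                           noise_sigma = 0.2,
                           occupancy_a = c(0.47, 0.25, 0.20, 0.08),
                           occupancy_b = c(0.50, 0.25, 0.20, 0.05),
                           stickiness = 0.5,
                           transition_matrix_a = NULL,
                           transition_matrix_b = NULL,
                           seed = 1L) {
  stopifnot(n_group_a >= 1, n_group_b >= 1, n_conditions >= 1,
            n_areas >= 2, n_frames >= 20, tr > 0, n_states >= 2)
  if (carrier_freq <= 0.02 || carrier_freq >= 0.1) {
    stop("carrier_freq must lie strictly inside the 0.02-0.1 Hz analysis band",
         call. = FALSE)
  }
  if (carrier_freq >= 1 / (2 * tr)) {
    stop("carrier_freq at or above Nyquist for tr = ", tr, call. = FALSE)
  }
  if (is.null(minority_sets)) {
    # evenly spread, non-overlapping communities of ~n_areas/5 areas each
    sz <- max(2L, floor(n_areas / 5))
    minority_sets <- lapply(seq_len(n_states - 1L), function(i) {
      start <- (i - 1L) * sz + 1L
      seq.int(start, min(start + sz - 1L, n_areas))
    })
  }
  if (length(minority_sets) != n_states - 1L) {
    stop("need one minority set per non-global state (", n_states - 1L, ")",
         call. = FALSE)
  }
  for (s in minority_sets) {
    if (length(s) == 0L) stop("minority community is empty", call. = FALSE)
    if (length(s) >= n_areas) {
      stop("minority community equals the full area set", call. = FALSE)
    }
    if (any(s < 1L | s > n_areas)) {
      stop("minority community indexes outside 1..n_areas", call. = FALSE)
    }
  }
  if (is.null(transition_matrix_a)) {
    stopifnot(length(occupancy_a) == n_states)
    transition_matrix_a <- occupancy_transition_matrix(occupancy_a, stickiness)
  }
  if (is.null(transition_matrix_b)) {
    stopifnot(length(occupancy_b) == n_states)
    transition_matrix_b <- occupancy_transition_matrix(occupancy_b, stickiness)
  }
  check_row_stochastic(transition_matrix_a)
  check_row_stochastic(transition_matrix_b)
  if (nrow(transition_matrix_a) != n_states ||
      nrow(transition_matrix_b) != n_states) {
    stop("transition matrices must be n_states x n_states", call. = FALSE)
  }
  structure(list(
    n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
    n_conditions = as.integer(n_conditions), n_areas = as.integer(n_areas),
    n_frames = as.integer(n_frames), tr = tr, n_states = as.integer(n_states),
    minority_sets = minority_sets, carrier_freq = carrier_freq,
    phase_jitter_kappa = phase_jitter_kappa, noise_sigma = noise_sigma,
    transition_matrix_a = transition_matrix_a,
    transition_matrix_b = transition_matrix_b,
    seed = as.integer(seed)
  ), class = "leida_synth_spec")
}

#' Planted centroid patterns
#'
#' State 1 is the global mode: all areas in one phase community (all elements
#' one sign). Each further state splits the areas into a minority community
#' (positive elements) phase-shifted against the majority (negative elements),
#' imitating the two-community structure read off leading-eigenvector signs.
#' All centroids are unit-norm with a majority of negative elements.
#'
#' @param n_states number of states (>= 2)
#' @param n_areas number of areas
#' @param minority_sets list of minority-area index vectors, one per
#'   non-global state
#' @return `n_states x n_areas` matrix of unit-norm rows
#' @export
make_planted_centroids <- function(n_states, n_areas, minority_sets) {
  stopifnot(n_states >= 2, length(minority_sets) == n_states - 1L)
  C <- matrix(-1, n_states, n_areas)
  for (i in seq_along(minority_sets)) {
    s <- minority_sets[[i]]
    if (length(s) == 0L) stop("minority community is empty", call. = FALSE)
    if (length(s) >= n_areas) {
      stop("minority community equals the full area set", call. = FALSE)
    }
    C[i + 1L, s] <- 1
  }
  C <- C / sqrt(rowSums(C^2))
  rownames(C) <- paste0("state", seq_len(n_states))
  C
}

#' Sample a first-order Markov state sequence
#'
#' The initial state is drawn from the stationary distribution of the chain so
#' planted occupancies carry no burn-in bias.
#'
#' @param transition_matrix row-stochastic `k x k` matrix
#' @param n_frames sequence length
#' @param seed RNG seed
#' @return integer vector of states in `1..k`
#' @export
sample_state_sequence <- function(transition_matrix, n_frames, seed = 1L) {
  check_row_stochastic(transition_matrix)
  stopifnot(n_frames >= 1)
  k <- nrow(transition_matrix)
  pi0 <- stationary_distribution(transition_matrix)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  s <- integer(n_frames)
  s[1L] <- sample.int(k, 1L, prob = pi0)
  if (n_frames > 1L) {
    u <- stats::runif(n_frames - 1L)
    cum <- t(apply(transition_matrix, 1L, cumsum))
    for (t in 2L:n_frames) {
      s[t] <- findInterval(u[t - 1L], cum[s[t - 1L], ]) + 1L
    }
  }
  s
}

# Best & Fisher (1979) rejection sampler for the von Mises distribution,
# mean 0, concentration kappa. kappa = Inf degenerates to 0; kappa = 0 is
# uniform on (-pi, pi].
rvonmises <- function(n, kappa) {
  if (n == 0L) return(numeric(0))
  if (!is.finite(kappa)) return(rep(0, n))
  if (kappa <= 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- stats::runif(1); u2 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(stats::runif(1) - 0.5) * acos(max(-1, min(1, f)))
      i <- i + 1L
    }
  }
  out
}

#' Synthesize one scan of phase-coupled signals
#'
#' Each area's signal is `cos(2*pi*f*t + phi_community(state(t)) + jitter) +
#' noise`, where areas in the active state's minority community carry a pi
#' phase offset against the majority. Offsets and per-area jitter change only
#' at state switches (constant within each state run), so the ground-truth
#' label of every frame is exact.
#'
#' @param planted_centroids matrix from [make_planted_centroids()]; signs
#'   define the communities (positive = minority)
#' @param state_sequence integer state labels, one per frame
#' @param spec a `leida_synth_spec`
#' @param seed RNG seed
#' @param scan_id,subject_id,group,condition metadata attached to the scan
#' @return a `parcel_ts` object (frames x parcels)
#' @export
synthesize_scan <- function(planted_centroids, state_sequence, spec, seed = 1L,
                            scan_id = "scan1", subject_id = "sub1",
                            group = "A", condition = "cond1") {
  stopifnot(length(state_sequence) == spec$n_frames,
            ncol(planted_centroids) == spec$n_areas)
  n <- spec$n_frames
  N <- spec$n_areas
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  tvec <- (seq_len(n) - 1L) * spec$tr
  base <- 2 * pi * spec$carrier_freq * tvec
  offset <- matrix(0, n, N)
  runs <- rle(state_sequence)
  pos <- 1L
  for (j in seq_along(runs$lengths)) {
    idx <- pos:(pos + runs$lengths[j] - 1L)
    st <- runs$values[j]
    minority <- which(planted_centroids[st, ] > 0)
    jit <- rvonmises(N, spec$phase_jitter_kappa)
    row_off <- jit
    row_off[minority] <- row_off[minority] + pi
    offset[idx, ] <- matrix(row_off, length(idx), N, byrow = TRUE)
    pos <- pos + runs$lengths[j]
  }
  X <- cos(base + offset)  # base recycles down columns
  if (spec$noise_sigma > 0) {
    X <- X + matrix(stats::rnorm(n * N, sd = spec$noise_sigma), n, N)
  }
  parcel_ts(X, tr = spec$tr, scan_id = scan_id, subject_id = subject_id,
            group = group, condition = condition,
            area_labels = paste0("area", seq_len(N)))
}

#' Generate a full synthetic cohort with ground truth
#'
#' Produces `n_group_a + n_group_b` subjects x `n_conditions` scans. Group B
#' uses `transition_matrix_b`, so a between-group difference in one state's
#' occupancy can be planted through the stationary distributions. Ground truth
#' (planted centroids, per-scan state sequences and their empirical
#' occupancies) is returned alongside, never re-derivable from internals.
#'
#' @param spec a `leida_synth_spec`
#' @return list with `scans` (list of `parcel_ts` in manifest order),
#'   `manifest` (data.frame: scan_id, subject_id, group, condition, tr) and
#'   `truth` (planted_centroids, state_sequences, planted_occupancy)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "leida_synth_spec"))
  centroids <- make_planted_centroids(spec$n_states, spec$n_areas,
                                      spec$minority_sets)
  n_sub <- spec$n_group_a + spec$n_group_b
  n_scan <- n_sub * spec$n_conditions
  seeds <- derive_seeds(spec$seed, 2L * n_scan)
  scans <- vector("list", n_scan)
  seqs <- vector("list", n_scan)
  occ <- matrix(NA_real_, n_scan, spec$n_states)
  man <- data.frame(scan_id = character(n_scan), subject_id = character(n_scan),
                    group = character(n_scan), condition = character(n_scan),
                    tr = spec$tr, stringsAsFactors = FALSE)
  i <- 0L
  for (sub in seq_len(n_sub)) {
    grp <- if (sub <= spec$n_group_a) "A" else "B"
    P <- if (grp == "A") spec$transition_matrix_a else spec$transition_matrix_b
    sid <- sprintf("sub%03d", sub)
    for (cond in seq_len(spec$n_conditions)) {
      i <- i + 1L
      cid <- paste0("cond", cond)
      scid <- paste0(sid, "_", cid)
      ss <- sample_state_sequence(P, spec$n_frames, seed = seeds[2L * i - 1L])
      scans[[i]] <- synthesize_scan(centroids, ss, spec, seed = seeds[2L * i],
                                    scan_id = scid, subject_id = sid,
                                    group = grp, condition = cid)
      seqs[[i]] <- ss
      occ[i, ] <- tabulate(ss, spec$n_states) / spec$n_frames
      man[i, c("scan_id", "subject_id", "group", "condition")] <-
        c(scid, sid, grp, cid)
    }
  }
  names(seqs) <- man$scan_id
  rownames(occ) <- man$scan_id
  colnames(occ) <- rownames(centroids)
  list(scans = scans, manifest = man,
       truth = list(planted_centroids = centroids, state_sequences = seqs,
                    planted_occupancy = occ))
}

#' Write a cohort to disk (TSV scans + manifest CSV + ground-truth JSON)
#'
#' One tab-delimited frames x parcels file per scan with a header row of area
#' labels, a manifest CSV (scan_id, subject_id, group, condition, tr, path)
#' and a sidecar `ground_truth.json`.
#'
#' @param cohort result of [generate_cohort()]
#' @param dir output directory (created if missing)
#' @return path of the manifest CSV, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$path <- file.path(dir, paste0(man$scan_id, ".tsv"))
  for (i in seq_along(cohort$scans)) {
    ts <- cohort$scans[[i]]
    dt <- data.table::as.data.table(ts$data)
    data.table::setnames(dt, ts$area_labels)
    data.table::fwrite(dt, man$path[i], sep = "\t")
  }
  manifest_path <- file.path(dir, "manifest.csv")
  data.table::fwrite(man, manifest_path)
  truth <- cohort$truth
  jsonlite::write_json(
    list(planted_centroids = truth$planted_centroids,
         state_sequences = truth$state_sequences,
         planted_occupancy = truth$planted_occupancy),
    file.path(dir, "ground_truth.json"), digits = NA)
  invisible(manifest_path)
}
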