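# One Lloyd run from a given initialization. Cosine distance treats the
# (already unit-norm) eigenvectors as directions; Euclidean is the classical
# variant. Empty clusters are reseeded to the currently worst-fit point.
kmeans_once <- function(X, k, init_idx, distance, max_iter = 100L) {
  C <- X[init_idx, , drop = FALSE]
  n <- nrow(X)
  lab_old <- integer(n)
  for (iter in seq_len(max_iter)) {
    if (distance == "cosine") {
      Cn <- C / sqrt(rowSums(C^2))
      S <- X %*% t(Cn)
      lab <- max.col(S, ties.method = "first")
      d <- 1 - S[cbind(seq_len(n), lab)]
    } else {
      D2 <- outer(rowSums(X^2), rep(1, k)) - 2 * (X %*% t(C)) +
        outer(rep(1, n), rowSums(C^2))
      lab <- max.col(-D2, ties.method = "first")
      d <- pmax(D2[cbind(seq_len(n), lab)], 0)
    }
    counts <- tabulate(lab, k)
    if (any(counts == 0L)) {
      for (j in which(counts == 0L)) {
        w <- which.max(d)
        C[j, ] <- X[w, ]
        d[w] <- 0
      }
      next
    }
    if (identical(lab, lab_old)) break
    lab_old <- lab
    C <- rowsum(X, lab) / counts
  }
  inertia <- sum(d)
  list(centroids = C, labels = lab, inertia = inertia, iterations = iter)
}

#' Partition pooled eigenvectors into k FC states
#'
#' k-means over the pooled leading eigenvectors with `n_replicates` restarts
#' (distinct sub-seeds derived from `seed`); the replicate with the lowest
#' inertia is kept. States are relabelled in decreasing overall occupancy
#' (state 1 = most frequent, typically the global mode) and final centroids
#' are re-oriented to the majority-negative sign convention.
#'
#' @param sample a `leida_eigen_sample` (or plain matrix, rows = frames)
#' @param k number of states (>= 2)
#' @param seed master seed for the restarts
#' @param n_replicates restarts per k
#' @param distance "cosine" (default) or "euclidean"
#' @param max_iter Lloyd iteration cap per restart
#' @return object of class `leida_partition`: k, centroids (k x parcels),
#'   frame_labels, inertia, replicate inertias and metadata
#' @export
cluster_eigenvectors <- function(sample, k, seed = 1L, n_replicates = 20L,
                                 distance = c("cosine", "euclidean"),
                                 max_iter = 100L) {
  distance <- match.arg(distance)
  X <- if (inherits(sample, "leida_eigen_sample")) sample$matrix else
    as.matrix(sample)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > nrow(X)) {
    stop("k (", k, ") exceeds the number of pooled frames (", nrow(X), ")",
         call. = FALSE)
  }
  rep_seeds <- derive_seeds(seed, n_replicates)
  distinct <- which(!duplicated(X))
  best <- NULL
  rep_inertia <- numeric(n_replicates)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  for (r in seq_len(n_replicates)) {
    set.seed(rep_seeds[r])
    init <- if (length(distinct) >= k) sample(distinct, k) else
      sample.int(nrow(X), k)
    fit <- kmeans_once(X, k, init, distance, max_iter)
    rep_inertia[r] <- fit$inertia
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  # stable state order: decreasing occupancy, ties by first occurrence
  occ <- tabulate(best$labels, k)
  ord <- order(-occ, seq_len(k))
  relabel <- integer(k)
  relabel[ord] <- seq_len(k)
  labels <- relabel[best$labels]
  centroids <- best$centroids[ord, , drop = FALSE]
  centroids <- t(apply(centroids, 1L, enforce_sign_convention))
  rownames(centroids) <- paste0("state", seq_len(k))
  structure(list(k = as.integer(k), centroids = centroids,
                 frame_labels = labels, seed = as.integer(seed),
                 n_replicates = as.integer(n_replicates),
                 distance = distance, inertia = best$inertia,
                 replicate_inertias = rep_inertia,
                 iterations = best$iterations),
            class = "leida_partition")
}

#' @export
print.leida_partition <- function(x, ...) {
  cat("<leida_partition> k = ", x$k, ", ", length(x$frame_labels),
      " frames, ", x$distance, " distance, inertia ",
      format(x$inertia, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Independent partitions over a sweep of k
#'
#' One k-means model per k; models are mutually independent (no nesting).
#' Per-k sub-seeds are derived deterministically from the master seed.
#'
#' @inheritParams cluster_eigenvectors
#' @param k_min,k_max sweep range (default 2..20)
#' @return named list of `leida_partition` ("k2", "k3", ...)
#' @export
sweep_k <- function(sample, k_min = 2L, k_max = 20L, seed = 1L,
                    n_replicates = 20L,
                    distance = c("cosine", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(k_min >= 2L, k_max >= k_min)
  ks <- seq.int(k_min, k_max)
  seeds <- derive_seeds(seed, length(ks))
  models <- lapply(seq_along(ks), function(i) {
    cluster_eigenvectors(sample, ks[i], seed = seeds[i],
                         n_replicates = n_replicates, distance = distance)
  })
  names(models) <- paste0("k", ks)
  models
}

#' Per-scan FC-state time courses from a partition
#'
#' Splits the pooled frame labels back into per-scan sequences using the
#' provenance index; concatenating the outputs in manifest order reproduces
#' `frame_labels` exactly.
#'
#' @param model a `leida_partition`
#' @param index provenance data.frame from a `leida_eigen_sample`
#' @return list of `leida_timecourse` (scan_id, labels, tr, k) in scan order
#' @export
extract_timecourses <- function(model, index) {
  if (length(model$frame_labels) != nrow(index)) {
    stop("partition labels (", length(model$frame_labels), ") and provenance ",
         "index (", nrow(index), " rows) are misaligned", call. = FALSE)
  }
  sids <- unique(index$scan_id)
  lapply(sids, function(sid) {
    rows <- which(index$scan_id == sid)
    structure(list(scan_id = sid, labels = model$frame_labels[rows],
                   tr = index$tr[rows[1L]], k = model$k,
                   subject_id = index$subject_id[rows[1L]],
                   group = index$group[rows[1L]],
                   condition = index$condition[rows[1L]]),
              class = "leida_timecourse")
  })
}

#' Pearson correlation between two state centroids
#'
#' @param c1,c2 equal-length numeric vectors
#' @return Pearson r
#' @export
centroid_similarity <- function(c1, c2) {
  stopifnot(length(c1) == length(c2))
  if (stats::sd(c1) == 0 || stats::sd(c2) == 0) {
    stop("undefined correlation: zero-variance centroid", call. = FALSE)
  }
  stats::cor(c1, c2)
}

#' Represent a state centroid as its outer-product matrix
#'
#' The rank-1 parcels x parcels matrix `v v^T`; entries are positive exactly
#' when the two areas' eigenvector elements share sign.
#'
#' @param centroid numeric vector
#' @return symmetric rank-1 matrix
#' @export
state_to_matrix <- function(centroid) {
  stopifnot(all(is.finite(centroid)))
  tcrossprod(centroid)
}

#' Match states across two partitions by centroid correlation
#'
#' For each state of `model_a`, the `model_b` state with maximum `|r|`
#' (sign-aligned); ties broken by the higher-occupancy candidate.
#'
#' @param model_a,model_b `leida_partition` objects (or centroid matrices)
#' @return data.frame: state_a, state_b, r
#' @export
match_states <- function(model_a, model_b) {
  Ca <- if (inherits(model_a, "leida_partition")) model_a$centroids else model_a
  Cb <- if (inherits(model_b, "leida_partition")) model_b$centroids else model_b
  occ_b <- if (inherits(model_b, "leida_partition")) {
    tabulate(model_b$frame_labels, nrow(Cb))
  } else {
    rep(0L, nrow(Cb))
  }
  out <- data.frame(state_a = seq_len(nrow(Ca)), state_b = NA_integer_,
                    r = NA_real_)
  for (i in seq_len(nrow(Ca))) {
    rs <- apply(Cb, 1L, function(b) centroid_similarity(Ca[i, ], b))
    top <- which(abs(rs) > max(abs(rs)) - 1e-12)
    j <- top[which.max(occ_b[top])]
    out$state_b[i] <- j
    out$r[i] <- rs[j]
  }
  out
}
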