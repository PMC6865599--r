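#' Deterministic sub-seed fan-out
#'
#' A single master seed reproduces every stochastic stage (generator, k-means
#' restarts, permutation tests). Sub-seeds are drawn from the master seed so
#' stages stay independent of each other's RNG consumption.
#'
#' @param seed master integer seed
#' @param n number of sub-seeds
#' @return integer vector of length `n`, each in \[1, 2^31 - 2\]
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 0)
  if (n == 0L) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Eigenvector sign convention
#'
#' `v` and `-v` span the same direction; orientation is fixed so that most
#' elements are negative. When exactly half the elements are positive, the
#' vector is flipped so its largest-magnitude element is negative.
#'
#' @param v numeric vector
#' @return `v` or `-v`
#' @export
enforce_sign_convention <- function(v) {
  n_pos <- sum(v > 0)
  n_neg <- sum(v < 0)
  if (n_pos > length(v) / 2) return(-v)
  if (n_pos == n_neg && n_pos == length(v) / 2) {
    if (v[which.max(abs(v))] > 0) return(-v)
  }
  v
}

#' Check that a matrix is row-stochastic
#' @param m square numeric matrix
#' @param tol tolerance on row sums
#' @keywords internal
check_row_stochastic <- function(m, tol = 1e-12) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop("transition matrix must be square", call. = FALSE)
  }
  if (any(m < 0)) stop("transition matrix entries must be >= 0", call. = FALSE)
  rs <- rowSums(m)
  if (any(abs(rs - 1) > tol)) {
    stop("transition matrix rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Stationary distribution of a row-stochastic matrix
#' @param m row-stochastic matrix
#' @return probability vector
#' @keywords internal
stationary_distribution <- function(m) {
  check_row_stochastic(m)
  e <- eigen(t(m))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# standard error of the mean, NA-dropping
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
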