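# FFT-based analytic signal: zero the negative frequencies, double the
# positive ones, keep DC (and Nyquist for even length) untouched.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1
    h[2L:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase and amplitude via the Hilbert transform
#'
#' Expresses each parcel's filtered signal as `X(t) = A(t) * cos(theta(t))`
#' using the analytic signal: `theta` is its argument (wrapped to (-pi, pi])
#' and `A` its modulus. Taken over the full series per scan, no tapering, so
#' one phase is produced per acquired frame.
#'
#' @param ts band-pass filtered `parcel_ts`
#' @return object of class `leida_phase` with `theta` and `amplitude`
#'   (frames x parcels) plus the scan metadata
#' @export
instantaneous_phase <- function(ts) {
  stopifnot(inherits(ts, "parcel_ts"))
  X <- ts$data
  zero_cols <- which(apply(X, 2L, function(x) all(x == 0)))
  if (length(zero_cols)) {
    stop("degenerate (all-zero) signal in parcel ",
         ts$area_labels[zero_cols[1L]], call. = FALSE)
  }
  A <- apply(X, 2L, analytic_signal)
  structure(list(theta = Arg(A), amplitude = Mod(A), tr = ts$tr,
                 scan_id = ts$scan_id, subject_id = ts$subject_id,
                 group = ts$group, condition = ts$condition,
                 area_labels = ts$area_labels),
            class = "leida_phase")
}

#' Per-frame phase-coherence matrix
#'
#' `dFC[n, p] = cos(theta_n - theta_p)`: 1 for synchronized areas, 0 for a
#' 90-degree phase difference, -1 for antiphase. Symmetric with unit diagonal.
#'
#' @param theta_row numeric vector of parcel phases at one frame (radians)
#' @return parcels x parcels matrix in \[-1, 1\]
#' @export
phase_coherence <- function(theta_row) {
  if (any(!is.finite(theta_row))) stop("non-finite phase", call. = FALSE)
  C <- cos(outer(theta_row, theta_row, "-"))
  C <- (C + t(C)) / 2
  diag(C) <- 1
  C
}

#' Leading eigenvector of a phase-coherence matrix
#'
#' The unit eigenvector of the largest-magnitude eigenvalue, sign-oriented so
#' most elements are negative. Selection is literally by `|lambda|`; a
#' selected negative eigenvalue and a degenerate leading eigenvalue
#' (multiplicity > 1 within 1e-10) are both flagged, never masked.
#'
#' @param C symmetric coherence matrix
#' @return list with `v` (unit vector), `eigenvalue`, `degenerate` flag and
#'   `negative_lambda` flag
#' @export
leading_eigenvector <- function(C) {
  if (!isSymmetric(unname(C), tol = 1e-8)) {
    stop("coherence matrix is not symmetric", call. = FALSE)
  }
  e <- eigen(C, symmetric = TRUE)
  i <- which.max(abs(e$values))
  lambda <- e$values[i]
  v <- enforce_sign_convention(e$vectors[, i])
  degenerate <- sum(abs(abs(e$values) - abs(lambda)) < 1e-10) > 1L
  list(v = v, eigenvalue = lambda, degenerate = degenerate,
       negative_lambda = lambda < 0)
}

#' Leading eigenvectors for every frame of one scan
#'
#' @param ph a `leida_phase`
#' @return list with `V` (frames x parcels matrix of unit eigenvectors),
#'   `eigenvalues`, and per-frame QC flags `degenerate`, `negative_lambda`
#' @export
scan_eigenvectors <- function(ph) {
  stopifnot(inherits(ph, "leida_phase"))
  n <- nrow(ph$theta)
  N <- ncol(ph$theta)
  V <- matrix(NA_real_, n, N)
  lam <- numeric(n)
  degen <- logical(n)
  neg <- logical(n)
  for (t in seq_len(n)) {
    le <- leading_eigenvector(phase_coherence(ph$theta[t, ]))
    V[t, ] <- le$v
    lam[t] <- le$eigenvalue
    degen[t] <- le$degenerate
    neg[t] <- le$negative_lambda
  }
  list(V = V, eigenvalues = lam, degenerate = degen, negative_lambda = neg)
}

#' Pool leading eigenvectors across a cohort
#'
#' Filters nothing and discards nothing: one eigenvector per acquired frame
#' per scan, concatenated in the given (manifest) order with a full
#' provenance index. All scans must share parcel count and area ordering.
#'
#' @param scans list of band-pass filtered `parcel_ts` in manifest order
#' @return object of class `leida_eigen_sample`: `matrix`
#'   (total_frames x parcels), `index` (data.frame: scan_id, subject_id,
#'   group, condition, frame, tr), `area_labels`, and per-scan `qc` counts of
#'   degenerate / negative-eigenvalue frames
#' @export
pool_eigenvectors <- function(scans) {
  stopifnot(length(scans) >= 1L)
  labels <- scans[[1L]]$area_labels
  for (s in scans) {
    if (!identical(s$area_labels, labels)) {
      stop("scan ", s$scan_id, ": area labels differ from the first scan ",
           "(parcel count or ordering mismatch)", call. = FALSE)
    }
  }
  Vs <- vector("list", length(scans))
  idx <- vector("list", length(scans))
  qc <- data.frame(scan_id = vapply(scans, `[[`, "", "scan_id"),
                   n_degenerate = 0L, n_negative_lambda = 0L,
                   stringsAsFactors = FALSE)
  for (i in seq_along(scans)) {
    ph <- instantaneous_phase(scans[[i]])
    sv <- scan_eigenvectors(ph)
    Vs[[i]] <- sv$V
    qc$n_degenerate[i] <- sum(sv$degenerate)
    qc$n_negative_lambda[i] <- sum(sv$negative_lambda)
    idx[[i]] <- data.frame(scan_id = scans[[i]]$scan_id,
                           subject_id = scans[[i]]$subject_id,
                           group = scans[[i]]$group,
                           condition = scans[[i]]$condition,
                           frame = seq_len(nrow(sv$V)),
                           tr = scans[[i]]$tr,
                           stringsAsFactors = FALSE)
  }
  structure(list(matrix = do.call(rbind, Vs),
                 index = do.call(rbind, idx),
                 area_labels = labels, qc = qc),
            class = "leida_eigen_sample")
}

#' @export
print.leida_eigen_sample <- function(x, ...) {
  cat("<leida_eigen_sample> ", nrow(x$matrix), " eigenvectors x ",
      ncol(x$matrix), " parcels from ", length(unique(x$index$scan_id)),
      " scans\n", sep = "")
  invisible(x)
}
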