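as_labels <- function(tc) {
  if (inherits(tc, "leida_timecourse")) tc$labels else as.integer(tc)
}

check_labels <- function(labels, k) {
  if (any(labels < 1L | labels > k)) {
    stop("state label outside 1..", k, call. = FALSE)
  }
  invisible(TRUE)
}

#' Occupancy probability of each FC state in a scan
#'
#' Fraction of the scan's frames assigned to each state. Always sums to 1.
#'
#' @param tc a `leida_timecourse` or integer label vector
#' @param k number of states
#' @return numeric vector of length k
#' @export
occupancy_probability <- function(tc, k) {
  labels <- as_labels(tc)
  check_labels(labels, k)
  tabulate(labels, k) / length(labels)
}

#' Mean lifetime (dwell time) of each FC state, in seconds
#'
#' Mean length of the maximal runs of consecutive frames in each state,
#' multiplied by TR. States never visited are `NA`. Runs truncated by scan
#' boundaries are included by default (set `include_truncated = FALSE` to
#' drop the first and last run).
#'
#' @param tc a `leida_timecourse` (or labels, with `tr` supplied)
#' @param k number of states
#' @param tr repetition time in seconds (taken from `tc` when available)
#' @param include_truncated count boundary-truncated runs?
#' @return numeric vector of length k (seconds; NA where never visited)
#' @export
mean_lifetime <- function(tc, k, tr = NULL, include_truncated = TRUE) {
  labels <- as_labels(tc)
  check_labels(labels, k)
  if (is.null(tr)) tr <- tc$tr
  stopifnot(is.numeric(tr), tr > 0)
  r <- rle(labels)
  keep <- rep(TRUE, length(r$lengths))
  if (!include_truncated && length(r$lengths) > 2L) {
    keep[c(1L, length(keep))] <- FALSE
  }
  vapply(seq_len(k), function(s) {
    lens <- r$lengths[keep & r$values == s]
    if (length(lens) == 0L) NA_real_ else mean(lens) * tr
  }, numeric(1))
}

#' Switching frequency of a scan, in Hz
#'
#' Number of state transitions divided by scan duration:
#' `#\{label changes\} / ((n_frames - 1) * tr)`.
#'
#' @inheritParams mean_lifetime
#' @return scalar Hz
#' @export
switching_frequency <- function(tc, tr = NULL) {
  labels <- as_labels(tc)
  if (length(labels) < 2L) {
    stop("switching frequency undefined for a single-frame scan",
         call. = FALSE)
  }
  if (is.null(tr)) tr <- tc$tr
  sum(diff(labels) != 0) / ((length(labels) - 1L) * tr)
}

#' Switching-profile matrix of a scan
#'
#' Row s is the empirical distribution of the next state given the current
#' state s. With `conditional_on_switch = TRUE` (default) self-transitions
#' are excluded from numerator and denominator, so rows sum to 1 over the
#' other k - 1 states; rows for states never exited are NA.
#'
#' @inheritParams occupancy_probability
#' @param conditional_on_switch condition on a switch occurring?
#' @return k x k matrix of probabilities (rows may be NA)
#' @export
switching_profile <- function(tc, k, conditional_on_switch = TRUE) {
  labels <- as_labels(tc)
  check_labels(labels, k)
  n <- length(labels)
  counts <- matrix(0, k, k)
  if (n >= 2L) {
    from <- labels[-n]
    to <- labels[-1L]
    counts <- unname(as.matrix(table(factor(from, seq_len(k)),
                                     factor(to, seq_len(k)))))
    counts <- matrix(as.numeric(counts), k, k)
  }
  if (conditional_on_switch) diag(counts) <- 0
  rs <- rowSums(counts)
  out <- counts / rs  # rows with rs == 0 become NaN
  out[rs == 0, ] <- NA_real_
  dimnames(out) <- list(paste0("from", seq_len(k)), paste0("to", seq_len(k)))
  out
}

#' Shannon entropy of a scan's state-occupancy distribution
#'
#' `entropy_full` is the Shannon entropy (bits) of the full occupancy
#' distribution over k states; `entropy_state[s]` is the binary entropy of
#' "in state s vs not", also in bits. Both are reported because the
#' per-state reading and the full-distribution reading are distinct
#' operationalizations.
#'
#' @inheritParams occupancy_probability
#' @return list with `entropy_full` (scalar) and `entropy_state` (length k)
#' @export
state_entropy <- function(tc, k) {
  p <- occupancy_probability(tc, k)
  plog <- function(q) ifelse(q > 0, q * log2(q), 0)
  list(entropy_full = -sum(plog(p)),
       entropy_state = -(plog(p) + plog(1 - p)))
}

#' All dynamical metrics for one scan
#'
#' @inheritParams mean_lifetime
#' @param conditional_on_switch see [switching_profile()]
#' @return list: scan metadata, `probability`, `mean_lifetime` (s),
#'   `switching_frequency` (Hz), `switching_matrix` (conditional-on-switch),
#'   `switching_matrix_full` (persistence included), `entropy_full`,
#'   `entropy_state`
#' @export
scan_metrics <- function(tc, k, tr = NULL, include_truncated = TRUE,
                         conditional_on_switch = TRUE) {
  if (is.null(tr)) tr <- tc$tr
  ent <- state_entropy(tc, k)
  list(scan_id = tc$scan_id, subject_id = tc$subject_id, group = tc$group,
       condition = tc$condition, k = k,
       probability = occupancy_probability(tc, k),
       mean_lifetime = mean_lifetime(tc, k, tr = tr,
                                     include_truncated = include_truncated),
       switching_frequency = switching_frequency(tc, tr = tr),
       switching_matrix = switching_profile(tc, k, conditional_on_switch),
       switching_matrix_full = switching_profile(tc, k, FALSE),
       entropy_full = ent$entropy_full,
       entropy_state = ent$entropy_state)
}

#' Tidy metric tables for a list of time courses
#'
#' @param tcs list of `leida_timecourse` (from [extract_timecourses()])
#' @param k number of states
#' @param include_truncated,conditional_on_switch see [scan_metrics()]
#' @return list of data.frames: `by_state` (scan x state rows: probability,
#'   lifetime, entropy_state), `by_scan` (switching_frequency, entropy_full),
#'   `switching` (scan x from x to rows, conditional-on-switch)
#' @export
cohort_metrics <- function(tcs, k, include_truncated = TRUE,
                           conditional_on_switch = TRUE) {
  ms <- lapply(tcs, scan_metrics, k = k,
               include_truncated = include_truncated,
               conditional_on_switch = conditional_on_switch)
  by_state <- do.call(rbind, lapply(ms, function(m) {
    data.frame(scan_id = m$scan_id, subject_id = m$subject_id,
               group = m$group, condition = m$condition, k = k,
               state = seq_len(k), probability = m$probability,
               lifetime = m$mean_lifetime, entropy_state = m$entropy_state,
               stringsAsFactors = FALSE)
  }))
  by_scan <- do.call(rbind, lapply(ms, function(m) {
    data.frame(scan_id = m$scan_id, subject_id = m$subject_id,
               group = m$group, condition = m$condition, k = k,
               switching_frequency = m$switching_frequency,
               entropy_full = m$entropy_full, stringsAsFactors = FALSE)
  }))
  switching <- do.call(rbind, lapply(ms, function(m) {
    g <- expand.grid(from = seq_len(k), to = seq_len(k))
    data.frame(scan_id = m$scan_id, subject_id = m$subject_id,
               group = m$group, condition = m$condition, k = k,
               from = g$from, to = g$to,
               p = m$switching_matrix[cbind(g$from, g$to)],
               stringsAsFactors = FALSE)
  }))
  rownames(by_state) <- rownames(by_scan) <- rownames(switching) <- NULL
  list(by_state = by_state, by_scan = by_scan, switching = switching)
}
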