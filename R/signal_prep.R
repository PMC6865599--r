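#' Parcellated BOLD time series for one scan
#'
#' @param data frames x parcels numeric matrix (rows = frames)
#' @param tr repetition time, seconds
#' @param scan_id,subject_id,group,condition metadata strings
#' @param area_labels parcel names (defaults to V1..Vn)
#' @return object of class `parcel_ts`
#' @export
parcel_ts <- function(data, tr, scan_id = "scan1", subject_id = "sub1",
                      group = NA_character_, condition = NA_character_,
                      area_labels = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (anyNA(data) || any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    stop("non-finite value at frame ", bad[1L], ", parcel ", bad[2L],
         call. = FALSE)
  }
  if (nrow(data) < 20L) stop("need at least 20 frames", call. = FALSE)
  if (ncol(data) < 2L) stop("need at least 2 parcels", call. = FALSE)
  if (!is.numeric(tr) || tr <= 0) stop("tr must be > 0", call. = FALSE)
  if (is.null(area_labels)) area_labels <- paste0("V", seq_len(ncol(data)))
  stopifnot(length(area_labels) == ncol(data))
  dimnames(data) <- NULL
  structure(list(data = data, tr = tr, scan_id = scan_id,
                 subject_id = subject_id, group = group, condition = condition,
                 area_labels = as.character(area_labels), filtered = FALSE),
            class = "parcel_ts")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat("<parcel_ts> ", x$scan_id, ": ", nrow(x$data), " frames x ",
      ncol(x$data), " parcels, TR = ", x$tr, " s",
      if (isTRUE(x$filtered)) " (band-pass filtered)", "\n", sep = "")
  invisible(x)
}

#' Read one parcellated time series from a TSV/CSV file
#'
#' Rows are frames, columns parcels (header row of area labels). A square
#' table without an explicit `frames_in_rows` is rejected rather than
#' guessed at.
#'
#' @param path file path
#' @param scan_id,subject_id,group,condition,tr metadata (typically a
#'   manifest row)
#' @param frames_in_rows set explicitly to TRUE/FALSE for square tables
#' @return a `parcel_ts`
#' @export
read_parcel_timeseries <- function(path, scan_id = basename(path),
                                   subject_id = NA_character_,
                                   group = NA_character_,
                                   condition = NA_character_,
                                   tr, frames_in_rows = NA) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty file: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = TRUE)
  if (nrow(dt) == 0L) stop("empty table: ", path, call. = FALSE)
  not_num <- names(dt)[!vapply(dt, is.numeric, logical(1))]
  if (length(not_num)) {
    stop("non-numeric column(s) in ", path, ": ",
         paste(not_num, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(dt)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    stop("missing value in ", path, " at row ", bad[1L], ", column ",
         colnames(dt)[bad[2L]], call. = FALSE)
  }
  labels <- colnames(m)
  if (nrow(m) == ncol(m) && is.na(frames_in_rows)) {
    stop("square table (", nrow(m), " x ", ncol(m), "): frame/parcel ",
         "orientation is ambiguous; pass frames_in_rows explicitly",
         call. = FALSE)
  }
  if (isFALSE(frames_in_rows)) {
    m <- t(m)
    labels <- paste0("V", seq_len(ncol(m)))
  }
  parcel_ts(m, tr = tr, scan_id = scan_id, subject_id = subject_id,
            group = group, condition = condition, area_labels = labels)
}

#' Read a cohort manifest and all its scans
#'
#' @param manifest_path CSV with columns scan_id, subject_id, group,
#'   condition, tr, path (relative paths resolved against the manifest's
#'   directory)
#' @return list of `parcel_ts` in manifest order
#' @export
read_cohort <- function(manifest_path) {
  man <- data.table::fread(manifest_path)
  need <- c("scan_id", "subject_id", "group", "condition", "tr", "path")
  miss <- setdiff(need, names(man))
  if (length(miss)) {
    stop("manifest missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, basename(p))
    if (!file.exists(p)) {
      stop("scan ", man$scan_id[i], ": file not found (", man$path[i], ")",
           call. = FALSE)
    }
    read_parcel_timeseries(p, scan_id = man$scan_id[i],
                           subject_id = man$subject_id[i],
                           group = man$group[i], condition = man$condition[i],
                           tr = man$tr[i])
  })
}

# direct-form II transposed IIR filter with explicit initial state;
# only used on short zero vectors to build the observability matrix.
lfilter_zi_state <- function(b, a, n, zi) {
  ord <- length(zi)
  y <- numeric(n)
  z <- zi
  for (i in seq_len(n)) {
    y[i] <- z[1L]
    if (ord > 1L) {
      for (j in seq_len(ord - 1L)) {
        z[j] <- z[j + 1L] - a[j + 1L] * y[i]
      }
    }
    z[ord] <- -a[ord + 1L] * y[i]
  }
  y
}

# Forward-backward filtering with Gustafsson's initial conditions: the
# initial states of the forward and backward passes are chosen by least
# squares so that filtering forward-then-backward equals
# backward-then-forward, which suppresses the edge transients that plague
# padding-based zero-phase filtering at the long 0.02 Hz time constant.
# The per-length operator pieces depend only on (b, a, n).
gust_prepare <- function(bf, n) {
  b <- bf$b / bf$a[1L]
  a <- bf$a / bf$a[1L]
  ord <- max(length(a), length(b)) - 1L
  b <- c(b, numeric(ord + 1L - length(b)))
  a <- c(a, numeric(ord + 1L - length(a)))
  Obs <- matrix(0, n, ord)
  Obs[, 1L] <- lfilter_zi_state(b, a, n, c(1, numeric(ord - 1L)))
  if (ord > 1L) {
    for (k in seq_len(ord - 1L)) {
      Obs[(k + 1L):n, k + 1L] <- Obs[1L:(n - k), 1L]
    }
  }
  Obsr <- Obs[n:1L, , drop = FALSE]
  S <- apply(Obsr, 2L, function(col) as.numeric(signal::filter(bf, col)))
  Sr <- S[n:1L, , drop = FALSE]
  M <- cbind(Sr - Obs, Obsr - S)
  W <- cbind(Sr, Obsr)
  list(bf = bf, qr_M = qr(M), W = W, n = n)
}

filtfilt_gust <- function(prep, x) {
  bf <- prep$bf
  y_f <- as.numeric(signal::filter(bf, x))
  y_fb <- rev(as.numeric(signal::filter(bf, rev(y_f))))
  y_b <- rev(as.numeric(signal::filter(bf, rev(x))))
  y_bf <- as.numeric(signal::filter(bf, y_b))
  ic <- qr.coef(prep$qr_M, y_bf - y_fb)
  as.numeric(y_fb + prep$W %*% ic)
}

#' Temporal band-pass filter (zero-phase Butterworth)
#'
#' Applies a second-order Butterworth band-pass (default 0.02-0.1 Hz)
#' forward and backward to every parcel, removing phase distortion -- the
#' downstream analysis is phase-based. Edge transients are controlled with
#' Gustafsson's initial-condition method rather than signal padding. Column
#' means are removed before and after filtering. All frames are retained.
#'
#' @param ts a `parcel_ts`
#' @param low_hz,high_hz band edges in Hz
#' @param order Butterworth order of a single pass
#' @return filtered `parcel_ts` of the same shape
#' @export
bandpass_filter <- function(ts, low_hz = 0.02, high_hz = 0.1, order = 2) {
  stopifnot(inherits(ts, "parcel_ts"))
  fs <- 1 / ts$tr
  nyq <- fs / 2
  if (low_hz <= 0 || high_hz <= low_hz || high_hz >= nyq) {
    stop("band (", low_hz, ", ", high_hz, ") Hz must satisfy 0 < low < high ",
         "< Nyquist (", nyq, " Hz)", call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  prep <- gust_prepare(bf, nrow(ts$data))
  X <- sweep(ts$data, 2L, colMeans(ts$data))
  out <- apply(X, 2L, function(x) filtfilt_gust(prep, x))
  out <- sweep(out, 2L, colMeans(out))
  ts$data <- out
  ts$filtered <- TRUE
  ts
}
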