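#' Sliding-window specification
#'
#' Width and step are in repetition-time (TR) units. Defaults follow the
#' common resting-state convention of a 30-TR window advanced 1 TR at a
#' time.
#'
#' @param width Window width in time points (>= 2).
#' @param step Step between consecutive window starts (>= 1).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width = 30, step = 1) {
  stopifnot(width >= 2, step >= 1)
  structure(list(width = as.integer(width), step = as.integer(step)),
            class = "window_spec")
}

#' Extract sliding windows from a time-series matrix
#'
#' Windows are 0-based half-open segments: window i covers rows
#' `[i*step, i*step + width)`, and the number of windows is
#' `floor((T - width) / step) + 1`.
#'
#' @param data T x N numeric matrix (rows = time points).
#' @param spec A [window_spec()].
#' @return A list with `segments` (list of width x N matrices) and
#'   `starts` (0-based start indices).
#' @export
extract_windows <- function(data, spec = window_spec()) {
  stopifnot(is.matrix(data))
  t_len <- nrow(data)
  if (spec$width > t_len) {
    stop("window width (", spec$width, ") exceeds series length (", t_len,
         ")", call. = FALSE)
  }
  n_win <- (t_len - spec$width) %/% spec$step + 1L
  starts <- (seq_len(n_win) - 1L) * spec$step
  segments <- lapply(starts, function(s) {
    data[(s + 1L):(s + spec$width), , drop = FALSE]
  })
  list(segments = segments, starts = starts)
}

#' Pearson correlation of one window
#'
#' Columns with zero variance within the window would produce undefined
#' correlations; their entries are set to 0 (self-correlation stays 1) and
#' a warning identifies the ROIs, so degenerate windows cannot inject
#' non-finite values into downstream clustering.
#'
#' @param segment T' x N matrix, T' >= 2.
#' @return N x N symmetric correlation matrix with unit diagonal.
#' @export
window_correlation <- function(segment) {
  stopifnot(is.matrix(segment), nrow(segment) >= 2)
  sds <- apply(segment, 2, sd)
  degenerate <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(cor(segment))
  if (any(degenerate)) {
    warning("zero-variance ROI(s) in window: ",
            paste(which(degenerate), collapse = ", "),
            "; correlations set to 0", call. = FALSE)
    r[degenerate, ] <- 0
    r[, degenerate] <- 0
  }
  diag(r) <- 1
  r
}

#' Fisher z transformation of a correlation matrix
#'
#' Applies `atanh` off-diagonal after clipping |r| to `1 - 1e-7` so that
#' perfect correlations map to a large finite value; the diagonal is set
#' to 0 by convention.
#'
#' @param r_matrix Correlation matrix with entries in \[-1, 1\].
#' @return Matrix of z values, zero diagonal, finite everywhere.
#' @export
fisher_z <- function(r_matrix) {
  r <- pmin(pmax(r_matrix, -1 + 1e-7), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Windowed Fisher-z connectivity series for one subject
#'
#' The per-subject core of the dFC pipeline: slide windows, correlate,
#' Fisher-z.
#'
#' @param data T x N matrix of ROI time courses.
#' @param spec A [window_spec()].
#' @param detrend If TRUE, remove a per-ROI linear trend before
#'   windowing (default FALSE; bandpass filtering and nuisance regression
#'   are assumed to have happened upstream).
#' @return A list of class `dfc_zseries`: `z` (list of N x N z-matrices),
#'   `starts` (0-based), `spec`.
#' @export
windowed_z <- function(data, spec = window_spec(), detrend = FALSE) {
  if (detrend) {
    t_idx <- seq_len(nrow(data))
    data <- apply(data, 2, function(y) stats::resid(stats::lm.fit(
      cbind(1, t_idx), y)))
  }
  w <- extract_windows(data, spec)
  z <- lapply(w$segments, function(s) fisher_z(window_correlation(s)))
  structure(list(z = z, starts = w$starts, spec = spec),
            class = "dfc_zseries")
}

#' dFC variability map
#'
#' Entrywise sample standard deviation (denominator W - 1) of the Fisher-z
#' connectivity values across windows: the classical "variability of dFC"
#' summary.
#'
#' @param z_series A `dfc_zseries` (or plain list of z matrices).
#' @return N x N matrix of standard deviations, zero diagonal.
#' @export
dfc_variability <- function(z_series) {
  z <- if (inherits(z_series, "dfc_zseries")) z_series$z else z_series
  w <- length(z)
  if (w < 2) stop("need at least 2 windows for a variability map",
                  call. = FALSE)
  n <- nrow(z[[1]])
  stacked <- vapply(z, as.vector, numeric(n * n))
  v <- matrix(apply(stacked, 1, sd), n, n)
  diag(v) <- 0
  dimnames(v) <- dimnames(z[[1]])
  v
}
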