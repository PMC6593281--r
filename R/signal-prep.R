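#' Regional time-series container
#'
#' A light wrapper around a T x N numeric matrix (time points x regions)
#' carrying the repetition time, a subject identifier and the number of
#' initial volumes already discarded.
#'
#' @param values T x N numeric matrix.
#' @param tr repetition time in seconds.
#' @param subject_id identifier.
#' @param n_dropped initial volumes already removed upstream.
#' @return object of class `subject_ts`.
#' @export
subject_ts <- function(values, tr = 2, subject_id = NA, n_dropped = 0L) {
  values <- as.matrix(values)
  stopifnot(nrow(values) >= 2, is.numeric(values), tr > 0)
  if (anyNA(values)) stop("time series contains missing values")
  structure(list(values = values, tr = tr, subject_id = subject_id,
                 n_dropped = as.integer(n_dropped)),
            class = "subject_ts")
}

as_subject_ts <- function(x, tr = 2) {
  if (inherits(x, "subject_ts")) x else subject_ts(x, tr = tr)
}

#' @export
print.subject_ts <- function(x, ...) {
  cat(sprintf("subject_ts: %d volumes x %d regions, TR = %g s (%d dropped)\n",
              nrow(x$values), ncol(x$values), x$tr, x$n_dropped))
  invisible(x)
}

#' @export
dim.subject_ts <- function(x) dim(x$values)

#' Write / read a subject time series as TSV
#'
#' Plain tab-separated text, one row per volume, header line of region
#' labels.
#'
#' @param ts a [subject_ts].
#' @param path file path.
#' @param labels region labels used as the header.
#' @export
write_subject_ts <- function(ts, path, labels = NULL) {
  ts <- as_subject_ts(ts)
  m <- ts$values
  colnames(m) <- labels %||% colnames(m) %||% sprintf("R%03d", seq_len(ncol(m)))
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_subject_ts
#' @param tr repetition time to attach.
#' @param subject_id identifier to attach.
#' @export
read_subject_ts <- function(path, tr = 2, subject_id = NA) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  subject_ts(m, tr = tr, subject_id = subject_id)
}

#' Discard initial volumes
#'
#' Removes the first `k` time points (default 10), the standard guard
#' against unsaturated longitudinal magnetization at scan start; 185
#' acquired volumes thus become 175 retained ones.
#'
#' @param ts a [subject_ts] or matrix.
#' @param k number of leading volumes to drop; must be smaller than T.
#' @return the shortened [subject_ts] with `n_dropped` incremented.
#' @export
drop_initial_volumes <- function(ts, k = 10L) {
  ts <- as_subject_ts(ts)
  if (k < 0) stop("k must be non-negative")
  if (k >= nrow(ts$values)) stop("cannot drop k >= number of volumes")
  if (k == 0) return(ts)
  subject_ts(ts$values[-seq_len(k), , drop = FALSE], tr = ts$tr,
             subject_id = ts$subject_id, n_dropped = ts$n_dropped + as.integer(k))
}

#' Remove per-region linear trends
#'
#' Subtracts the least-squares line (intercept + slope on the time index)
#' from every column, leaving zero-mean, trend-free signals.
#'
#' @param ts a [subject_ts] or matrix.
#' @return detrended [subject_ts].
#' @export
detrend_linear <- function(ts) {
  ts <- as_subject_ts(ts)
  v <- ts$values
  if (nrow(v) < 3) stop("need at least 3 time points to detrend")
  x <- cbind(1, seq_len(nrow(v)))
  resid <- v - x %*% qr.solve(x, v)
  subject_ts(resid, tr = ts$tr, subject_id = ts$subject_id,
             n_dropped = ts$n_dropped)
}

#' Band-pass filter regional signals
#'
#' Zero-phase (forward-backward) Butterworth filter of the given order
#' applied to every column; defaults to the canonical resting-state band
#' 0.01-0.08 Hz. Forward-backward application squares the magnitude
#' response, so an order-2 design attenuates a 0.2 Hz component by more
#' than a factor of 10 at TR = 2 s while passing mid-band components
#' essentially unchanged, and introduces no phase distortion that could
#' bias Pearson correlations.
#'
#' @param ts a [subject_ts] or matrix.
#' @param low,high pass-band edges in Hz; require `0 < low < high` and
#'   `high` below the Nyquist frequency `1/(2*tr)`.
#' @param order Butterworth order of the one-way design.
#' @return filtered [subject_ts] (column means removed).
#' @export
bandpass <- function(ts, low = 0.01, high = 0.08, order = 2) {
  ts <- as_subject_ts(ts)
  nyq <- 1 / (2 * ts$tr)
  if (low <= 0 || high <= low) stop("need 0 < low < high")
  if (high >= nyq) {
    stop(sprintf("high edge %.3f Hz must be below Nyquist %.3f Hz", high, nyq))
  }
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  v <- scale(ts$values, center = TRUE, scale = FALSE)
  filtered <- apply(v, 2, function(col) signal::filtfilt(bf, col))
  subject_ts(filtered, tr = ts$tr, subject_id = ts$subject_id,
             n_dropped = ts$n_dropped)
}

#' Regress nuisance confounds out of every region
#'
#' Least-squares residuals of each regional signal on an intercept plus the
#' confound columns (typically white-matter and CSF signals and the
#' 24-parameter motion expansion). Residuals are exactly orthogonal to
#' every confound.
#'
#' @param ts a [subject_ts] or matrix.
#' @param confounds numeric matrix with one row per time point, or `NULL` /
#'   zero columns for mean-centering only.
#' @return residual [subject_ts].
#' @export
regress_confounds <- function(ts, confounds = NULL) {
  ts <- as_subject_ts(ts)
  v <- ts$values
  if (is.null(confounds) || NCOL(confounds) == 0) {
    out <- scale(v, center = TRUE, scale = FALSE)
  } else {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nrow(v)) {
      stop("confounds must have one row per time point")
    }
    x <- cbind(1, confounds)
    qx <- qr(x)
    if (qx$rank < ncol(x)) stop("confound design matrix is rank deficient")
    out <- v - x %*% qr.coef(qx, v)
  }
  subject_ts(out, tr = ts$tr, subject_id = ts$subject_id,
             n_dropped = ts$n_dropped)
}

#' Friston 24-parameter motion expansion
#'
#' Expands 6 rigid-body realignment parameters into the 24-regressor set
#' `[p, p^2, p(t-1), p(t-1)^2]` (lagged rows zero-padded at t = 1).
#'
#' @param motion6 T x 6 matrix: 3 translations (mm), 3 rotations (degrees).
#' @return T x 24 matrix.
#' @export
friston24 <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6) stop("expected 6 motion parameters")
  lag1 <- rbind(0, motion6[-nrow(motion6), , drop = FALSE])
  out <- cbind(motion6, motion6^2, lag1, lag1^2)
  colnames(out) <- c(paste0("p", 1:6), paste0("p", 1:6, "_sq"),
                     paste0("p", 1:6, "_lag"), paste0("p", 1:6, "_lagsq"))
  out
}

#' Motion-based subject exclusion
#'
#' Flags a subject for exclusion when any translation exceeds `trans_mm`
#' millimetres or any rotation exceeds `rot_deg` degrees. The comparison is
#' a strict inequality: a value exactly at the threshold is retained.
#'
#' @param params T x 6 matrix: 3 translations (mm), 3 rotations (degrees).
#' @param trans_mm translation threshold in mm.
#' @param rot_deg rotation threshold in degrees.
#' @return list with per-axis maxima (`max_translation`, `max_rotation`)
#'   and the logical `excluded`.
#' @export
assess_motion <- function(params, trans_mm = 1.5, rot_deg = 1.5) {
  params <- as.matrix(params)
  if (ncol(params) != 6) stop("expected a 6-column motion-parameter table")
  if (anyNA(params)) stop("motion parameters contain missing values")
  max_t <- apply(abs(params[, 1:3, drop = FALSE]), 2, max)
  max_r <- apply(abs(params[, 4:6, drop = FALSE]), 2, max)
  list(max_translation = max_t, max_rotation = max_r,
       excluded = any(max_t > trans_mm) || any(max_r > rot_deg))
}

#' Full time-series cleaning chain
#'
#' Applies, in fixed order: initial-volume dropping, linear detrending,
#' band-pass filtering and confound regression.
#'
#' @param ts a [subject_ts] or matrix.
#' @param drop_volumes leading volumes to discard.
#' @param band length-2 pass band in Hz or `NULL` to skip filtering.
#' @param confounds optional confound matrix (rows must match the series
#'   length *after* dropping).
#' @return cleaned [subject_ts].
#' @export
preprocess_subject <- function(ts, drop_volumes = 10L, band = c(0.01, 0.08),
                               confounds = NULL) {
  ts <- drop_initial_volumes(as_subject_ts(ts), drop_volumes)
  ts <- detrend_linear(ts)
  if (!is.null(band)) ts <- bandpass(ts, band[1], band[2])
  if (!is.null(confounds)) ts <- regress_confounds(ts, confounds)
  ts
}
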