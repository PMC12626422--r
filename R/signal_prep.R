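# Timecourse-level signal conditioning: initial-volume discard, motion
# exclusion, framewise displacement, outlier scrubbing with spline
# interpolation, linear detrending, confound regression, and zero-phase
# band-pass filtering. Volume-level steps (realignment, normalization,
# smoothing) are assumed done upstream by standard tools.

#' Discard initial volumes
#'
#' Removes the first `n_discard` TRs (scanner signal stabilization period)
#' from a timecourse matrix or vector.
#'
#' @param x numeric vector or ROI-by-time matrix.
#' @param n_discard nonnegative integer; default 5.
#' @return `x` without its first `n_discard` time points; attribute
#'   `"discarded"` records the offset.
#' @export
discard_initial <- function(x, n_discard = 5) {
  .check(n_discard >= 0 && n_discard == round(n_discard),
         "n_discard must be a nonnegative integer")
  n_t <- if (is.matrix(x)) ncol(x) else length(x)
  .check(n_t > n_discard, "series length %d must exceed n_discard = %d",
         n_t, n_discard)
  out <- if (n_discard == 0) x
         else if (is.matrix(x)) x[, -seq_len(n_discard), drop = FALSE]
         else x[-seq_len(n_discard)]
  attr(out, "discarded") <- as.integer(n_discard)
  out
}

#' Motion exclusion flag
#'
#' A subject is excluded when any absolute translation exceeds `trans_mm`
#' millimetres or any absolute rotation exceeds `rot_deg` degrees (strict
#' inequalities). Rotations in the motion trace are stored in radians and
#' converted at this boundary.
#'
#' @param motion numeric matrix with 6 columns: translations x, y, z (mm)
#'   then rotations about x, y, z (radians); one row per TR.
#' @param trans_mm translation threshold in mm (default 3.0).
#' @param rot_deg rotation threshold in degrees (default 3.0).
#' @return `TRUE` if the subject should be excluded.
#' @export
motion_exclusion_flag <- function(motion, trans_mm = 3.0, rot_deg = 3.0) {
  .check(is.matrix(motion) && ncol(motion) == 6L,
         "motion must be a TR x 6 matrix (3 translations mm, 3 rotations rad)")
  trans <- abs(motion[, 1:3, drop = FALSE])
  rot_degrees <- abs(motion[, 4:6, drop = FALSE]) * 180 / pi
  any(trans > trans_mm) || any(rot_degrees > rot_deg)
}

#' Framewise displacement (Power formulation)
#'
#' FD at TR t is the sum of absolute backward differences of the six
#' rigid-body parameters, with rotations converted to arc displacement on a
#' sphere of radius `head_radius_mm`. FD of the first TR is 0 by convention.
#'
#' @param motion TR x 6 matrix (translations mm, rotations radians).
#' @param head_radius_mm assumed head radius (default 50 mm).
#' @return numeric FD vector, one value per TR.
#' @export
compute_fd <- function(motion, head_radius_mm = 50) {
  .check(is.matrix(motion) && ncol(motion) == 6L,
         "motion must be a TR x 6 matrix")
  .check(nrow(motion) >= 2L, "need at least 2 TRs to compute FD")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Scrub high-motion TRs by cubic-spline interpolation
#'
#' TRs with `fd > threshold_mm` are flagged, the flag set is dilated by
#' `extend_before` preceding and `extend_after` following TRs (clipped to
#' the series bounds), and the flagged samples are replaced by evaluating a
#' cubic interpolating spline fitted to the clean samples. Clean samples are
#' returned bit-identical.
#'
#' @param series numeric vector.
#' @param fd FD vector of the same length.
#' @param threshold_mm FD threshold (default 0.5 mm).
#' @param extend_before,extend_after dilation in TRs (defaults 1 and 2).
#' @param spline_order spline order; only 3 (cubic) is supported.
#' @return the series with outlier TRs replaced; attribute `"scrubbed"`
#'   lists the replaced TR indices (1-based).
#' @export
scrub_interpolate <- function(series, fd, threshold_mm = 0.5,
                              extend_before = 1, extend_after = 2,
                              spline_order = 3) {
  .check(spline_order == 3, "only a third-order (cubic) spline is supported")
  .check(length(series) == length(fd), "series and fd lengths differ")
  n <- length(series)
  flagged <- which(fd > threshold_mm)
  if (length(flagged) == 0) {
    attr(series, "scrubbed") <- integer(0)
    return(series)
  }
  dil <- sort(unique(unlist(lapply(
    flagged, function(t) seq(t - extend_before, t + extend_after)))))
  dil <- dil[dil >= 1 & dil <= n]
  clean <- setdiff(seq_len(n), dil)
  .check(length(clean) >= spline_order + 1,
         "only %d clean TRs remain; need at least %d for a cubic spline",
         length(clean), spline_order + 1)
  out <- series
  # method "fmm": end cubics through the outer points, reproduces a global
  # cubic polynomial exactly and extrapolates sanely at the series edges
  out[dil] <- stats::spline(clean, series[clean], xout = dil,
                            method = "fmm")$y
  attr(out, "scrubbed") <- dil
  out
}

#' Remove a linear trend
#'
#' Ordinary least-squares fit of `intercept + slope * t`, returning the
#' residual, which is orthogonal to both the constant and the ramp.
#'
#' @param series numeric vector, length >= 3.
#' @return detrended series.
#' @export
detrend_linear <- function(series) {
  n <- length(series)
  .check(n >= 3, "need at least 3 time points to detrend")
  t_idx <- seq_len(n)
  stats::lm.fit(cbind(1, t_idx), series)$residuals
}

#' Regress nuisance confounds out of a series
#'
#' OLS residual of the series on `[intercept | confounds]`. Typical
#' confounds: 24 head-motion regressors (6 rigid-body parameters, their
#' one-TR-back copies, and the squares of both sets), mean white-matter and
#' mean CSF signal.
#'
#' @param series numeric vector.
#' @param confounds numeric matrix or data frame, one row per TR.
#' @return residual series, numerically orthogonal to every confound column.
#' @export
regress_confounds <- function(series, confounds) {
  confounds <- as.matrix(confounds)
  .check(nrow(confounds) == length(series),
         "confounds have %d rows but series has %d time points",
         nrow(confounds), length(series))
  .check(all(is.finite(confounds)), "confounds contain non-finite values")
  X <- cbind(`(intercept)` = 1, confounds)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    if (is.null(dropped)) dropped <- paste("column", qx$pivot[(qx$rank + 1):ncol(X)])
    stop(sprintf("confound design is rank deficient; collinear columns: %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  as.numeric(qr.resid(qx, series))
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth band-pass applied forward and backward
#' ([signal::filtfilt()]) for zero phase shift. Defaults isolate the
#' 0.01-0.15 Hz band conventionally associated with stimulus-driven BOLD
#' fluctuations.
#'
#' @param series numeric vector, length >= 32.
#' @param low_hz,high_hz band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < 1 / (2 * tr_seconds)`.
#' @param tr_seconds sampling interval (TR) in seconds.
#' @param order Butterworth order (default 4).
#' @return the filtered series.
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.15, tr_seconds,
                     order = 4) {
  .check(length(series) >= 32, "series too short to filter (length >= 32)")
  nyquist <- 1 / (2 * tr_seconds)
  .check(low_hz > 0 && low_hz < high_hz && high_hz < nyquist,
         "band (%g, %g) Hz must satisfy 0 < low < high < Nyquist = %g Hz",
         low_hz, high_hz, nyquist)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  as.numeric(signal::filtfilt(bf, series))
}

#' Full timecourse conditioning pipeline
#'
#' Applies, in order: initial-volume discard, linear detrend, confound
#' regression, band-pass filter, FD scrubbing with spline interpolation, and
#' z-normalization, to every ROI row of a subject timecourse. Each step is
#' optional (skipped when its inputs are `NULL`). The order (filter before
#' scrub) follows the conventional listing and is recorded in the output.
#'
#' @param tc a `subject_timecourse` (raw).
#' @param n_discard initial volumes to drop (default 5; 0 disables).
#' @param confounds optional confound matrix (rows matching the series
#'   length *after* discarding).
#' @param motion optional TR x 6 motion matrix (after discarding) used for
#'   FD scrubbing.
#' @param band optional `c(low_hz, high_hz)`; default `c(0.01, 0.15)`;
#'   `NULL` disables filtering.
#' @param fd_threshold_mm scrubbing threshold (default 0.5).
#' @return a z-scored `subject_timecourse`; attribute `"prep_steps"` lists
#'   the steps applied.
#' @export
prep_timecourse <- function(tc, n_discard = 5, confounds = NULL,
                            motion = NULL, band = c(0.01, 0.15),
                            fd_threshold_mm = 0.5) {
  steps <- character(0)
  if (n_discard > 0) {
    tc$data <- discard_initial(tc$data, n_discard)
    steps <- c(steps, sprintf("discard_initial(%d)", n_discard))
  }
  tc$data <- t(apply(tc$data, 1L, detrend_linear))
  steps <- c(steps, "detrend_linear")
  if (!is.null(confounds)) {
    tc$data <- t(apply(tc$data, 1L, regress_confounds, confounds = confounds))
    steps <- c(steps, "regress_confounds")
  }
  if (!is.null(band)) {
    tc$data <- t(apply(tc$data, 1L, bandpass, low_hz = band[1],
                       high_hz = band[2], tr_seconds = tc$tr_seconds))
    steps <- c(steps, sprintf("bandpass(%g, %g)", band[1], band[2]))
  }
  if (!is.null(motion)) {
    fd <- compute_fd(motion)
    tc$data <- t(apply(tc$data, 1L, scrub_interpolate, fd = fd,
                       threshold_mm = fd_threshold_mm))
    steps <- c(steps, sprintf("scrub_interpolate(fd > %g)", fd_threshold_mm))
  }
  tc <- znormalize(tc)
  attr(tc, "prep_steps") <- c(steps, "znormalize")
  tc
}
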