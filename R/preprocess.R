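# Resting-state cleaning: nuisance regression, zero-phase band-pass,
# FD-based censoring with interpolation and refiltering.

#' Framewise displacement from a realignment trace
#'
#' `FD_t = |d trans_x| + |d trans_y| + |d trans_z| +
#'  radius * (|d rot_x| + |d rot_y| + |d rot_z|)`, i.e. the sum of absolute
#' values of the frame-to-frame differentials of the six rigid-body
#' parameters, with rotations converted to arc displacement on a sphere
#' (default radius 50 mm, the convention of the motion-scrubbing literature).
#' FD of the first frame is defined as 0.
#'
#' @param motion frames x 6 matrix: three translations (mm) then three
#'   rotations (radians).
#' @param rotation_radius_mm sphere radius for the rotation-to-mm conversion.
#' @return Numeric vector of per-frame FD (mm).
#' @export
compute_fd <- function(motion, rotation_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (nrow(motion) < 2) stop("need at least 2 frames to compute FD")
  if (ncol(motion) != 6) stop("motion trace must have 6 columns")
  if (!all(is.finite(motion))) {
    bad <- which(!apply(is.finite(motion), 1, all))[1]
    stop(sprintf("non-finite realignment parameter at frame %d", bad))
  }
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Friston 24-parameter motion regressor set
#'
#' Expands a six-parameter realignment trace into the 24-column motion design:
#' the parameters at frame t, at frame t-1, and the squares of both. The
#' lagged value at the first frame is defined as 0 (no preceding frame).
#'
#' @param motion frames x 6 realignment matrix.
#' @return frames x 24 numeric matrix.
#' @export
friston24 <- function(motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion trace must have 6 columns")
  lag1 <- rbind(0, motion[-nrow(motion), , drop = FALSE])
  out <- cbind(motion, lag1, motion^2, lag1^2)
  colnames(out) <- c(paste0(colnames(motion), "_t"),
                     paste0(colnames(motion), "_tm1"),
                     paste0(colnames(motion), "_t_sq"),
                     paste0(colnames(motion), "_tm1_sq"))
  out
}

#' Nuisance regression
#'
#' Regresses every node's time course on the supplied regressors plus an
#' intercept and returns the residuals, which are orthogonal to the regressor
#' column space.
#'
#' @param ts frames x nodes matrix.
#' @param regressors frames x k matrix (an intercept is added internally).
#' @return Residual matrix, same shape as `ts`.
#' @export
nuisance_regress <- function(ts, regressors) {
  ts <- as.matrix(ts); X <- cbind(intercept = 1, as.matrix(regressors))
  if (nrow(ts) != nrow(X)) stop("ts and regressors must be frame-aligned")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient nuisance design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  res <- ts - X %*% qr.coef(qrX, ts)
  dimnames(res) <- dimnames(ts)
  res
}

#' Zero-phase band-pass filter
#'
#' Order-2 Butterworth band-pass applied forward and backward
#' (zero phase) to every column. Pass-band sinusoids are preserved and
#' stop-band sinusoids strongly attenuated.
#'
#' @param ts frames x nodes matrix (or a vector).
#' @param tr_seconds sampling interval (s).
#' @param low_hz,high_hz band edges; default 0.009-0.08 Hz.
#' @return Filtered matrix of the same shape.
#' @export
bandpass <- function(ts, tr_seconds, low_hz = 0.009, high_hz = 0.08) {
  vec <- is.null(dim(ts))
  ts <- as.matrix(ts)
  nyq <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("need 0 < low_hz < high_hz < Nyquist (", nyq, " Hz)")
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  # filtfilt pads by 3 * (filter order); order-2 band-pass has 5 coefficients
  minlen <- 3 * (length(bf$a) - 1) + 1
  if (nrow(ts) < minlen)
    stop("series too short for filtering; need at least ", minlen, " frames")
  out <- apply(ts, 2L, function(x) signal::filtfilt(bf, x))
  dimnames(out) <- dimnames(ts)
  if (vec) drop(out) else out
}

# Linear interpolation of flagged frames from the nearest kept frames,
# per column; flagged runs at either end are held at the nearest kept value.
interpolate_frames <- function(ts, flagged) {
  if (!any(flagged)) return(ts)
  if (all(flagged)) stop("cannot interpolate: every frame is flagged")
  kept <- which(!flagged)
  apply(ts, 2L, function(x)
    stats::approx(kept, x[kept], xout = seq_along(x), rule = 2)$y)
}

#' Clean a resting-state run (nuisance regression, filtering, scrubbing)
#'
#' Executes the standard cleaning sequence: (1) nuisance regression,
#' (2) band-pass filtering, (3) flagging of frames with FD above threshold,
#' (4) linear interpolation of flagged frames in the raw series,
#' (5) re-regression and re-filtering of the interpolated series (so that
#' artifacts from censored frames do not blur into kept frames), and
#' (6) removal of the flagged frames. If fewer than `min_frames` frames
#' survive, a `netsel_exclusion` error is raised: the participant is to be
#' discarded from further analyses.
#'
#' Discarding initial scanner-stabilization frames (if any) is the caller's
#' responsibility; synthetic runs have none.
#'
#' @param ts frames x nodes matrix.
#' @param regressors frames x k nuisance design (e.g. [friston24()] output).
#' @param fd per-frame framewise displacement, e.g. from [compute_fd()].
#' @param fd_threshold censoring threshold in mm (default 0.3).
#' @param min_frames minimum surviving frames (default 75).
#' @param tr_seconds sampling interval (s).
#' @param low_hz,high_hz band-pass edges.
#' @return A `netsel_clean_ts` list: `series` (kept frames x nodes),
#'   `keep_mask` (logical per original frame), `n_kept`, `fd_threshold`.
#' @export
clean_rsfc <- function(ts, regressors, fd,
                       fd_threshold = 0.3, min_frames = 75,
                       tr_seconds = 2, low_hz = 0.009, high_hz = 0.08) {
  ts <- as.matrix(ts)
  if (length(fd) != nrow(ts)) stop("fd and ts must be frame-aligned")
  flagged <- fd > fd_threshold
  n_kept <- sum(!flagged)
  if (n_kept < min_frames) {
    cond <- structure(
      class = c("netsel_exclusion", "error", "condition"),
      list(message = sprintf(
        "participant excluded: %d frames survive scrubbing (< %d required)",
        n_kept, min_frames),
        call = sys.call(-1), n_kept = n_kept))
    stop(cond)
  }
  # first pass establishes the residual band-limited series
  pass1 <- bandpass(nuisance_regress(ts, regressors), tr_seconds,
                    low_hz, high_hz)
  if (any(flagged)) {
    interp <- interpolate_frames(ts, flagged)
    pass2 <- bandpass(nuisance_regress(interp, regressors), tr_seconds,
                      low_hz, high_hz)
  } else {
    pass2 <- pass1
  }
  structure(list(series = pass2[!flagged, , drop = FALSE],
                 keep_mask = !flagged, n_kept = n_kept,
                 fd_threshold = fd_threshold),
            class = "netsel_clean_ts")
}
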