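# Signal conditioning and stance segmentation: zero-lag Butterworth
# filtering (10 Hz markers / 50 Hz forces), 50 N threshold gait events on
# the force clock, resampling of force channels onto the marker clock, and
# percent-stance time normalization.

#' Zero-lag low-pass Butterworth filter
#'
#' Applies an `order`-th order low-pass Butterworth filter forward and
#' backward (zero phase lag), after reflective (odd) padding of one warm-up
#' length at each end to suppress edge transients. The dual pass squares the
#' magnitude response, so the half-power point of the single pass becomes a
#' quarter-power point.
#'
#' @param x numeric vector or time x d matrix, gap-free.
#' @param fs sampling rate, Hz.
#' @param fc cutoff frequency, Hz; must be below Nyquist. Defaults used in
#'   the pipeline are 10 Hz for markers and 50 Hz for forces.
#' @param order single-pass filter order (default 2, i.e. 4th-order
#'   effective after the dual pass).
#' @return filtered array of the same shape.
#' @export
lowpass_filter <- function(x, fs, fc, order = 2) {
  if (fc >= fs / 2) stop("cutoff fc must be below the Nyquist frequency fs/2")
  if (fc <= 0 || order < 1) stop("fc and order must be positive")
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  if (anyNA(xm)) stop("signal contains NA/NaN over the filtered span")
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  # warm-up length: long enough for the zero-state transient to decay below
  # double precision noise, from the slowest pole of the designed filter
  r <- max(Mod(polyroot(rev(bf$a))))
  pad <- as.integer(min(max(ceiling(log(1e-13) / log(min(r, 0.999))), 24L), 2000L))
  if (nrow(xm) <= pad + 1L)
    stop("signal shorter than the filter warm-up length (", pad + 2, " samples)")
  out <- xm
  n <- nrow(xm)
  for (j in seq_len(ncol(xm))) {
    s <- xm[, j]
    # odd reflection about the end points
    head_pad <- 2 * s[1] - s[(pad + 1):2]
    tail_pad <- 2 * s[n] - s[(n - 1):(n - pad)]
    ext <- c(head_pad, s, tail_pad)
    f1 <- signal::filter(bf, ext)
    f2 <- rev(signal::filter(bf, rev(f1)))
    out[, j] <- f2[(pad + 1):(pad + n)]
  }
  if (vec) drop(out) else out
}

#' Detect heel strike and toe off from the vertical ground reaction force
#'
#' Heel strike is the first sample at or above `threshold`; toe off is the
#' first subsequent sample below it. Exactly one supra-threshold contact of
#' plausible duration must be present; shorter bursts are ignored as noise.
#'
#' @param vertical_force vertical GRF time series, N.
#' @param fs sampling rate, Hz.
#' @param threshold contact threshold, N (default 50).
#' @param min_stance,max_stance plausible stance duration bounds, s.
#' @return a `gait_events` list: `heel_strike`/`toe_off` sample indices (on
#'   the input clock), their times `t_heel_strike`/`t_toe_off` (s, sample
#'   `i` at time `(i-1)/fs`), `stance_time`, and `threshold`.
#' @export
detect_gait_events <- function(vertical_force, fs, threshold = 50,
                               min_stance = 0.3, max_stance = 1.5) {
  fz <- as.numeric(vertical_force)
  n <- length(fz)
  above <- fz >= threshold
  if (!any(above)) stop("no contact: vertical force never reaches ", threshold, " N")
  if (all(above)) {
    warning("force exceeds the threshold for the whole record; using boundary events")
    runs <- data.frame(start = 1L, end = n)
  } else {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
  }
  dur <- (runs$end - runs$start + 1L) / fs
  plausible <- runs[dur >= min_stance, , drop = FALSE]
  if (nrow(plausible) == 0L)
    stop("no contact of plausible duration (>= ", min_stance, " s) found")
  if (nrow(plausible) > 1L)
    stop("ambiguous record: ", nrow(plausible), " supra-threshold contacts at samples ",
         paste(sprintf("[%d-%d]", plausible$start, plausible$end), collapse = ", "))
  hs <- plausible$start[1]
  to <- plausible$end[1] + 1L     # first sample back below threshold
  if (to > n) to <- n             # boundary contact
  stance <- (to - hs) / fs
  if (stance > max_stance)
    warning(sprintf("stance duration %.2f s exceeds the plausible maximum %.2f s",
                    stance, max_stance))
  structure(list(heel_strike = hs, toe_off = to,
                 t_heel_strike = (hs - 1) / fs, t_toe_off = (to - 1) / fs,
                 stance_time = stance, threshold = threshold),
            class = "gait_events")
}

#' Filter, synchronize and crop a trial to its stance phase
#'
#' Markers are low-pass filtered at `markers_fc` and forces at `forces_fc`
#' (zero-lag Butterworth, at the original sampling rates). Gait events are
#' located on the force clock, mapped to the nearest marker samples, and all
#' channels are cropped to `[heel strike, toe off]`. Force channels are
#' resampled onto the marker clock after filtering (exact decimation when
#' the force clock contains the marker instants, cubic spline otherwise).
#' A marker gap inside stance rejects the trial.
#'
#' @param trial a [gait_trial()] object.
#' @param markers_fc,forces_fc cutoffs, Hz (defaults 10 and 50).
#' @param order single-pass Butterworth order.
#' @param threshold gait event threshold, N.
#' @param min_stance,max_stance plausible stance bounds, s.
#' @return a `stance_phase` object: stance-local `time`, filtered cropped
#'   `markers`, force record `force` on the marker clock, `events`,
#'   `stance_time` and the `subject`/`condition`/`measured_speed` metadata.
#' @export
segment_stance <- function(trial, markers_fc = 10, forces_fc = 50, order = 2,
                           threshold = 50, min_stance = 0.3, max_stance = 1.5) {
  stopifnot(inherits(trial, "gait_trial"))
  mk <- trial$markers; fp <- trial$forceplate
  ff <- apply_filter_mat(fp$force, fp$sample_rate, forces_fc, order)
  fm <- apply_filter_mat(fp$moment, fp$sample_rate, forces_fc, order)
  ev <- detect_gait_events(ff[, 3], fp$sample_rate, threshold = threshold,
                           min_stance = min_stance, max_stance = max_stance)
  # map event times onto the marker clock
  i_hs <- which.min(abs(mk$time - ev$t_heel_strike))
  i_to <- which.min(abs(mk$time - ev$t_toe_off))
  if (i_to <= i_hs) stop("stance collapses to a single marker sample")
  sel <- i_hs:i_to
  if (any(mk$gaps[sel, ]))
    stop("trial rejected: marker gap inside the stance window (labels: ",
         paste(unique(mk$labels[which(colSums(mk$gaps[sel, , drop = FALSE]) > 0)]),
               collapse = ", "), ")")
  npos <- mk$positions
  for (k in 1:3) npos[, , k] <- apply_filter_mat(npos[, , k, drop = FALSE][, , 1],
                                                 mk$sample_rate, markers_fc, order)
  t_m <- mk$time[sel]
  pos_c <- npos[sel, , , drop = FALSE]
  force_i <- resample_to(fp$time, ff, t_m)
  mom_i <- resample_to(fp$time, fm, t_m)
  markers_f <- marker_trajectories(pos_c, mk$labels, mk$sample_rate, time = t_m)
  force_f <- force_plate_record(force_i, mom_i, fp$plate_origin,
                                mk$sample_rate, time = t_m)
  structure(list(time = t_m - t_m[1], markers = markers_f, force = force_f,
                 events = ev, stance_time = t_m[length(t_m)] - t_m[1],
                 subject = trial$subject, condition = trial$condition,
                 measured_speed = trial$measured_speed,
                 sample_rate = mk$sample_rate),
            class = "stance_phase")
}

apply_filter_mat <- function(x, fs, fc, order) {
  m <- as.matrix(x)
  out <- lowpass_filter(m, fs, fc, order)
  matrix(out, nrow = nrow(m), ncol = ncol(m))
}

# Resample columns of y (sampled at times t) onto times t_new: exact sample
# picking when the grids nest, cubic spline otherwise.
resample_to <- function(t, y, t_new) {
  y <- as.matrix(y)
  idx <- vapply(t_new, function(tt) {
    i <- which.min(abs(t - tt)); if (abs(t[i] - tt) < 1e-9) i else NA_integer_
  }, integer(1))
  if (!anyNA(idx)) return(y[idx, , drop = FALSE])
  out <- matrix(0, length(t_new), ncol(y))
  for (j in seq_len(ncol(y)))
    out[, j] <- stats::spline(t, y[, j], xout = t_new, method = "natural")$y
  out
}

#' Resample a series to a fixed number of points over 0--100% stance
#'
#' Linear interpolation onto `n_points` equally spaced points spanning the
#' full series; endpoint values are preserved exactly.
#'
#' @param series numeric vector or time x d matrix.
#' @param n_points number of output points (default 101).
#' @return resampled vector/matrix with an attribute `pct` giving the
#'   percent-stance grid.
#' @export
time_normalize <- function(series, n_points = 101) {
  if (n_points < 2) stop("n_points must be at least 2")
  vec <- is.null(dim(series))
  y <- if (vec) matrix(series, ncol = 1) else as.matrix(series)
  n <- nrow(y)
  if (n < 2) stop("series must have at least 2 samples")
  x <- seq(0, 1, length.out = n)
  xo <- seq(0, 1, length.out = n_points)
  out <- apply(y, 2, function(col) stats::approx(x, col, xout = xo)$y)
  out <- matrix(out, nrow = n_points)
  attr(out, "pct") <- xo * 100
  if (vec) {
    v <- drop(out); attr(v, "pct") <- xo * 100; v
  } else out
}
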