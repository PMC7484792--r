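# The three stance power series of the ankle-foot system and the nine
# scalar outcome features (peak power and positive/negative work of the
# ankle, the foot, and their sum).

#' Six degrees-of-freedom ankle joint power
#'
#' \deqn{P_{ankle} = F_{ankle} \cdot \Delta V_{ankle}
#'   + M_{ankle} \cdot \omega_{ankle}}
#' where \eqn{\Delta V_{ankle}} is the difference between the ankle-point
#' velocities carried by the shank and by the foot
#' (\eqn{v_{com} + \omega \times (r_{ankle} - r_{com})} for each segment)
#' and \eqn{\omega_{ankle} = \omega_{shank} - \omega_{foot}}. Positive power
#' is energy generation flowing into the foot.
#'
#' @param loads [newton_euler_foot()] output.
#' @param foot_kin,shank_kin [segment_kinematics()] of foot and shank on the
#'   same clock.
#' @return numeric vector, W.
#' @export
ankle_power <- function(loads, foot_kin, shank_kin) {
  n <- nrow(loads$force)
  if (nrow(foot_kin$com_position) != n || nrow(shank_kin$com_position) != n)
    stop("clock mismatch between loads and segment kinematics")
  v_foot <- foot_kin$com_velocity +
    row_cross(foot_kin$angular_velocity, loads$ankle_point - foot_kin$com_position)
  v_shank <- shank_kin$com_velocity +
    row_cross(shank_kin$angular_velocity, loads$ankle_point - shank_kin$com_position)
  dv <- v_shank - v_foot
  w_rel <- shank_kin$angular_velocity - foot_kin$angular_velocity
  row_dot(loads$force, dv) + row_dot(loads$moment, w_rel)
}

#' Distal foot segment power
#'
#' \deqn{P_{foot} = GRF \cdot [V_{cm} + \omega_{foot} \times R_{cop/cm}]
#'   + M_{free} \cdot \omega_{foot}}
#' with \eqn{R_{cop/cm} = r_{cop} - r_{com}}. Samples where the COP is
#' undefined (vertical force below the contact threshold) are forced to 0.
#'
#' @param contact [cop_and_free_moment()] output.
#' @param foot_kin [segment_kinematics()] of the foot on the same clock.
#' @return numeric vector, W.
#' @export
foot_power <- function(contact, foot_kin) {
  n <- nrow(contact$grf)
  if (nrow(foot_kin$com_position) != n)
    stop("clock mismatch between contact kinetics and foot kinematics")
  r <- contact$cop - foot_kin$com_position
  v_cop <- foot_kin$com_velocity + row_cross(foot_kin$angular_velocity, r)
  p <- row_dot(contact$grf, v_cop) +
    row_dot(contact$free_moment, foot_kin$angular_velocity)
  p[!contact$valid] <- 0
  p
}

#' Total ankle-foot power
#'
#' Samplewise sum \eqn{P_{sum} = P_{ankle} + P_{foot}}.
#' @param p_ankle,p_foot power series on a shared clock, W.
#' @export
sum_power <- function(p_ankle, p_foot) {
  if (length(p_ankle) != length(p_foot))
    stop("clock mismatch: power series differ in length")
  p_ankle + p_foot
}

#' Stance power series container
#'
#' @param time stance-local time, s.
#' @param p_ankle,p_foot power series, W; `p_sum` is computed.
#' @param meta optional list of subject/condition metadata.
#' @param normalized_by_mass TRUE when the series are W/kg.
#' @export
power_series <- function(time, p_ankle, p_foot, meta = list(),
                         normalized_by_mass = FALSE) {
  stopifnot(length(time) == length(p_ankle), length(p_ankle) == length(p_foot))
  structure(list(time = time, p_ankle = p_ankle, p_foot = p_foot,
                 p_sum = sum_power(p_ankle, p_foot), meta = meta,
                 normalized_by_mass = normalized_by_mass),
            class = "power_series")
}

#' @export
print.power_series <- function(x, ...) {
  u <- if (x$normalized_by_mass) "W/kg" else "W"
  cat(sprintf("<power_series> %d samples over %.3f s stance\n",
              length(x$time), max(x$time)))
  cat(sprintf("  peak P_ankle %.1f %s | min P_foot %.1f %s | peak P_sum %.1f %s\n",
              max(x$p_ankle), u, min(x$p_foot), u, max(x$p_sum), u))
  invisible(x)
}

#' Plot the three stance power curves
#' @param x a `power_series`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.power_series <- function(x, ...) {
  u <- if (x$normalized_by_mass) "power (W/kg)" else "power (W)"
  graphics::matplot(100 * x$time / max(x$time),
                    cbind(x$p_ankle, x$p_foot, x$p_sum), type = "l",
                    lty = 1, col = c("#1b6ca8", "#d1495b", "#222222"),
                    xlab = "stance (%)", ylab = u, ...)
  graphics::legend("topleft", c("ankle", "foot", "sum"), lty = 1,
                   col = c("#1b6ca8", "#d1495b", "#222222"), bty = "n")
  invisible(x)
}

#' Propulsion-phase window of a stance power series
#'
#' The window runs from the last negative-to-positive zero crossing of
#' `p_sum` before toe off, to toe off. When the series never crosses zero
#' upward the final 50% of stance is used with a warning.
#'
#' @param p_sum total power series over stance, W.
#' @return integer index window (vector of sample indices).
#' @export
propulsion_window <- function(p_sum) {
  n <- length(p_sum)
  if (all(p_sum == 0)) stop("degenerate window: power series is identically zero")
  up <- which(p_sum[-n] < 0 & p_sum[-1] >= 0)
  if (length(up) == 0L) {
    warning("no upward zero crossing of P_sum; falling back to the final 50% of stance")
    return(seq.int(floor(n / 2) + 1L, n))
  }
  seq.int(up[length(up)] + 1L, n)
}

#' Positive, negative or net mechanical work of a power series
#'
#' Trapezoidal integral over a sample window. Positive work integrates
#' `max(P, 0)`, negative work `min(P, 0)`, so positive + negative = net
#' exactly.
#'
#' @param power power series, W.
#' @param time time vector, s.
#' @param window index window (default: full series).
#' @param sign `"positive"`, `"negative"` or `"net"`.
#' @return work, J.
#' @export
work <- function(power, time, window = seq_along(power),
                 sign = c("net", "positive", "negative")) {
  sign <- match.arg(sign)
  if (length(window) == 0L) {
    warning("empty work window; returning 0")
    return(0)
  }
  if (min(window) < 1L || max(window) > length(power))
    stop("work window outside the series")
  p <- power[window]
  p <- switch(sign, positive = pmax(p, 0), negative = pmin(p, 0), net = p)
  if (length(p) < 2L) return(0)
  pracma::trapz(time[window], p)
}

#' Nine outcome features of one stance
#'
#' Peak powers are taken inside the propulsion window: the maxima of
#' `P_ankle` and `P_sum`, and for `P_foot` the magnitude of its minimum
#' (foot absorption peak, reported positive; the signed series is kept in
#' the input). Works are the positive/negative trapezoidal integrals over
#' the full stance for all three series; for the foot this equals
#' integrating over its absorption (P < 0) and generation (P > 0)
#' sub-intervals.
#'
#' @param ps a [power_series()].
#' @return named numeric vector with elements `peak_ankle`, `peak_foot`,
#'   `peak_sum` (W) and `wpos_ankle`, `wpos_foot`, `wpos_sum`, `wneg_ankle`,
#'   `wneg_foot`, `wneg_sum` (J).
#' @export
stance_features <- function(ps) {
  stopifnot(inherits(ps, "power_series"))
  win <- propulsion_window(ps$p_sum)
  c(peak_ankle = max(ps$p_ankle[win]),
    peak_foot = -min(ps$p_foot[win]),
    peak_sum = max(ps$p_sum[win]),
    wpos_ankle = work(ps$p_ankle, ps$time, sign = "positive"),
    wpos_foot = work(ps$p_foot, ps$time, sign = "positive"),
    wpos_sum = work(ps$p_sum, ps$time, sign = "positive"),
    wneg_ankle = work(ps$p_ankle, ps$time, sign = "negative"),
    wneg_foot = work(ps$p_foot, ps$time, sign = "negative"),
    wneg_sum = work(ps$p_sum, ps$time, sign = "negative"))
}

FEATURE_NAMES <- c("peak_ankle", "peak_foot", "peak_sum",
                   "wpos_ankle", "wpos_foot", "wpos_sum",
                   "wneg_ankle", "wneg_foot", "wneg_sum")

#' Average per-trial features into one subject x condition record
#'
#' Features are computed per stance and then averaged across a subject's
#' trials within a speed condition. Fewer trials than `min_trials` raises an
#' exclusion error (the laboratory protocol used six representative trials;
#' synthetic studies may use fewer).
#'
#' @param series_list list of [power_series()] from the same subject and
#'   condition.
#' @param subject a [subject_info()].
#' @param condition speed condition label.
#' @param speed mean measured speed of the trials, m/s.
#' @param min_trials minimum trial count (default 3).
#' @return one-row data.frame: `subject_id`, `condition`, `speed`,
#'   `age_group` (0 young / 1 older), `age`, the nine features.
#' @export
extract_features <- function(series_list, subject, condition, speed,
                             min_trials = 3) {
  if (length(series_list) < min_trials)
    stop("excluded: only ", length(series_list), " valid trial(s) for subject ",
         subject$subject_id, " at ", condition, " (minimum ", min_trials, ")")
  feats <- vapply(series_list, stance_features, numeric(9))
  out <- data.frame(subject_id = subject$subject_id, condition = condition,
                    speed = speed,
                    age_group = as.integer(subject$age_group == "older"),
                    age = subject$age)
  out[FEATURE_NAMES] <- rowMeans(feats)
  out
}
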