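# Newton-Euler inverse dynamics of the foot segment. The reported loads are
# the force and couple applied BY the shank ON the foot at the ankle centre,
# the convention under which the segment energy balance (see
# energy_balance_residual) closes with positive power meaning energy flow
# into the foot.

#' Ankle force and moment by foot-segment inverse dynamics
#'
#' Solves the rigid foot segment's Newton and Euler equations for the load
#' transmitted across the ankle:
#' \deqn{F_{ankle} = m a_{com} - m g - GRF}
#' \deqn{M_{ankle} = I\dot\omega + \omega \times I\omega
#'   - (r_{ankle} - r_{com}) \times F_{ankle}
#'   - (r_{cop} - r_{com}) \times GRF - M_{free}}
#' with the inertia tensor rotated into the lab frame per sample. The
#' moment is the pure couple at the ankle; together with `F_ankle` acting at
#' the ankle centre both balance equations close exactly at every sample.
#'
#' @param foot_kin [segment_kinematics()] of the foot, including
#'   `joint_point` = ankle centre (or pass `ankle_point`).
#' @param contact [cop_and_free_moment()] output on the same clock.
#' @param inertia [foot_inertial()] parameters of the foot.
#' @param ankle_point T x 3 ankle centre positions; defaults to
#'   `foot_kin$joint_point`.
#' @param g gravity vector, m/s^2 (lab frame, Z up).
#' @return object of class `joint_loads`: `force`, `moment` (T x 3, lab
#'   frame), `ankle_point`, `fs`.
#' @export
newton_euler_foot <- function(foot_kin, contact, inertia,
                              ankle_point = foot_kin$joint_point,
                              g = c(0, 0, -9.80665)) {
  n <- nrow(foot_kin$com_position)
  if (nrow(contact$grf) != n)
    stop("clock mismatch: kinematics (", n, ") vs contact (", nrow(contact$grf),
         ") samples")
  if (is.null(ankle_point)) stop("an ankle centre trajectory is required")
  m <- inertia$mass
  gmat <- as_mat3(g, n)
  F_ankle <- m * foot_kin$com_acceleration - m * gmat - contact$grf
  # lab-frame inertia and rate of change of angular momentum about the COM
  Iw <- matrix(0, n, 3); Iwd <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    R <- foot_kin$rotation[, , i]
    I_lab <- R %*% inertia$moi %*% t(R)
    Iw[i, ] <- I_lab %*% foot_kin$angular_velocity[i, ]
    Iwd[i, ] <- I_lab %*% foot_kin$angular_acceleration[i, ]
  }
  gyro <- row_cross(foot_kin$angular_velocity, Iw)
  r_ank <- ankle_point - foot_kin$com_position
  r_cop <- contact$cop - foot_kin$com_position
  M_ankle <- Iwd + gyro - row_cross(r_ank, F_ankle) -
    row_cross(r_cop, contact$grf) - contact$free_moment
  structure(list(force = F_ankle, moment = M_ankle, ankle_point = ankle_point,
                 fs = foot_kin$fs), class = "joint_loads")
}

#' Power bookkeeping residual of the foot segment
#'
#' The sum of all external powers on the rigid foot -- ankle force at the
#' ankle point, ankle couple, GRF at the (foot-fixed material point under
#' the) COP, free moment, and gravity -- must equal the time derivative of
#' the segment's kinetic energy. The residual of this balance, evaluated
#' with the pipeline's own numerical derivative, is the package's primary
#' mechanical self-check.
#'
#' @inheritParams newton_euler_foot
#' @param loads [newton_euler_foot()] output.
#' @return list with `residual` (W, per sample), `power_in` (total external
#'   power, W), `dE` (d/dt kinetic energy, W), `rms_relative` (RMS residual
#'   over peak |power_in|).
#' @export
energy_balance_residual <- function(loads, foot_kin, contact, inertia,
                                    g = c(0, 0, -9.80665)) {
  n <- nrow(foot_kin$com_position)
  m <- inertia$mass
  w <- foot_kin$angular_velocity
  v_ank <- foot_kin$com_velocity +
    row_cross(w, loads$ankle_point - foot_kin$com_position)
  v_cop <- foot_kin$com_velocity +
    row_cross(w, contact$cop - foot_kin$com_position)
  Iw <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    R <- foot_kin$rotation[, , i]
    Iw[i, ] <- (R %*% inertia$moi %*% t(R)) %*% w[i, ]
  }
  p_in <- row_dot(loads$force, v_ank) + row_dot(loads$moment, w) +
    row_dot(contact$grf, v_cop) + row_dot(contact$free_moment, w) +
    m * row_dot(as_mat3(g, n), foot_kin$com_velocity)
  ke <- 0.5 * m * rowSums(foot_kin$com_velocity^2) + 0.5 * row_dot(w, Iw)
  dE <- differentiate(ke, foot_kin$fs)
  res <- p_in - dE
  list(residual = res, power_in = p_in, dE = dE,
       rms_relative = sqrt(mean(res^2)) / max(abs(p_in)))
}
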