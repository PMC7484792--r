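# Segment kinematics and contact kinetics: rigid pose from marker clouds,
# angular velocity from rotation histories, centre of pressure and free
# moment from plate signals, and anthropometric inertial parameters.

#' Numerical time derivative (central differences)
#'
#' Central differences at interior samples, first-order one-sided at the two
#' end samples.
#'
#' @param series numeric vector or time x d matrix.
#' @param fs sampling rate, Hz.
#' @return array of the same shape.
#' @export
differentiate <- function(series, fs) {
  vec <- is.null(dim(series))
  y <- if (vec) matrix(series, ncol = 1) else as.matrix(series)
  n <- nrow(y)
  if (n < 3) stop("differentiate needs at least 3 samples")
  d <- y
  d[2:(n - 1), ] <- (y[3:n, , drop = FALSE] - y[1:(n - 2), , drop = FALSE]) * fs / 2
  d[1, ] <- (y[2, ] - y[1, ]) * fs
  d[n, ] <- (y[n, ] - y[n - 1, ]) * fs
  if (vec) drop(d) else d
}

#' Define a rigid segment from marker labels
#'
#' `local` holds the marker coordinates in the segment frame with the origin
#' at the segment centre of mass, so the fitted pose translation is the COM
#' position directly. `joint_local` optionally locates a joint centre (e.g.
#' the ankle as the malleoli midpoint) in the same frame.
#'
#' @param name segment name (`"foot"` or `"shank"`).
#' @param labels marker names (>= 3, non-collinear).
#' @param local k x 3 matrix of segment-frame marker coordinates, m.
#' @param joint_local optional length-3 segment-frame joint centre, m.
#' @export
segment_def <- function(name, labels, local, joint_local = NULL) {
  local <- as.matrix(local)
  stopifnot(length(labels) >= 3L, nrow(local) == length(labels), ncol(local) == 3L)
  structure(list(name = name, labels = labels, local = local,
                 joint_local = joint_local), class = "segment_def")
}

#' Least-squares rigid pose of a segment over time
#'
#' Fits the lab-from-segment rotation and the COM position at every sample
#' by the Kabsch algorithm on the segment's markers.
#'
#' @param markers a [marker_trajectories()] object (gap-free over the fitted
#'   span for the segment's labels).
#' @param def a [segment_def()].
#' @return list with `rotation` (3 x 3 x T), `com_position` (T x 3) and
#'   `joint_point` (T x 3 or NULL).
#' @export
segment_pose <- function(markers, def) {
  idx <- match(def$labels, markers$labels)
  if (anyNA(idx))
    stop("markers missing for segment '", def$name, "': ",
         paste(def$labels[is.na(idx)], collapse = ", "))
  n <- dim(markers$positions)[1]
  R <- array(0, c(3, 3, n))
  com <- matrix(0, n, 3)
  jp <- if (is.null(def$joint_local)) NULL else matrix(0, n, 3)
  for (i in seq_len(n)) {
    y <- markers$positions[i, idx, , drop = TRUE]
    if (anyNA(y)) stop("marker gap at sample ", i, " for segment '", def$name, "'")
    fit <- kabsch(def$local, matrix(y, ncol = 3))
    R[, , i] <- fit$rotation
    com[i, ] <- fit$translation
    if (!is.null(jp)) jp[i, ] <- fit$translation + fit$rotation %*% def$joint_local
  }
  list(rotation = R, com_position = com, joint_point = jp)
}

#' Angular velocity from a rotation-matrix time series
#'
#' Extracts the lab-frame angular velocity from the skew-symmetric part of
#' `Rdot R^T`, with `Rdot` by central differences (one-sided at the ends).
#'
#' @param rotation 3 x 3 x T array of orthonormal lab-from-segment rotations.
#' @param fs sampling rate, Hz.
#' @return T x 3 matrix of angular velocity, rad/s, lab frame.
#' @export
angular_velocity <- function(rotation, fs) {
  n <- dim(rotation)[3]
  if (n < 2) stop("angular_velocity needs at least 2 samples")
  Rdot <- array(0, dim(rotation))
  for (a in 1:3) for (b in 1:3)
    Rdot[a, b, ] <- differentiate(rotation[a, b, ], fs)
  w <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    W <- Rdot[, , i] %*% t(rotation[, , i])
    W <- (W - t(W)) / 2
    w[i, ] <- c(W[3, 2], W[1, 3], W[2, 1])
  }
  w
}

#' Full segment kinematics over a stance window
#'
#' Pose, COM velocity/acceleration and angular velocity/acceleration for one
#' segment.
#'
#' @param markers filtered [marker_trajectories()] (e.g. from
#'   [segment_stance()]).
#' @param def a [segment_def()].
#' @param fs sampling rate, Hz; defaults to the marker rate.
#' @return object of class `segment_kinematics` with fields `segment`,
#'   `rotation`, `com_position`, `com_velocity`, `com_acceleration`,
#'   `angular_velocity`, `angular_acceleration`, `joint_point`, `fs`.
#' @export
segment_kinematics <- function(markers, def, fs = markers$sample_rate) {
  pose <- segment_pose(markers, def)
  w <- angular_velocity(pose$rotation, fs)
  structure(list(segment = def$name, rotation = pose$rotation,
                 com_position = pose$com_position,
                 com_velocity = differentiate(pose$com_position, fs),
                 com_acceleration = differentiate(differentiate(pose$com_position, fs), fs),
                 angular_velocity = w,
                 angular_acceleration = differentiate(w, fs),
                 joint_point = pose$joint_point, fs = fs),
            class = "segment_kinematics")
}

#' Centre of pressure and free moment from a force-plate record
#'
#' With moments expressed about a plate origin lying in the surface plane,
#' the centre of pressure is `COPx = -My/Fz`, `COPy = Mx/Fz` (relative to
#' the origin) and the free moment is the vertical residual about the COP,
#' `Mz_free = Mz - (COPx Fy - COPy Fx)`. Samples with vertical force below
#' `threshold` have no defined COP; the last valid value is held there and
#' the validity mask is returned so downstream power terms can be zeroed.
#'
#' @param record a [force_plate_record()].
#' @param threshold minimum vertical force for a defined COP, N.
#' @return object of class `contact_kinetics`: `grf` (T x 3, N), `cop`
#'   (T x 3 lab frame, on the plate surface), `free_moment` (T x 3, only the
#'   vertical component non-zero), `valid` (logical T), `threshold`, `time`.
#' @export
cop_and_free_moment <- function(record, threshold = 50) {
  fz <- record$force[, 3]
  if (all(fz <= 0)) stop("no contact: vertical force is never positive")
  valid <- fz >= threshold
  n <- nrow(record$force)
  copx <- ifelse(valid, -record$moment[, 2] / fz, NA_real_)
  copy <- ifelse(valid, record$moment[, 1] / fz, NA_real_)
  mz_free <- ifelse(valid,
                    record$moment[, 3] - (copx * record$force[, 2] -
                                          copy * record$force[, 1]),
                    0)
  # hold last valid COP through sub-threshold spans (backfill a leading span)
  filled <- fill_hold(cbind(copx, copy))
  cop <- cbind(filled[, 1] + record$plate_origin[1],
               filled[, 2] + record$plate_origin[2],
               rep(record$plate_origin[3], n))
  fm <- cbind(0, 0, mz_free)
  dimnames(cop) <- NULL; dimnames(fm) <- NULL
  structure(list(grf = record$force, cop = cop,
                 free_moment = fm, valid = valid,
                 threshold = threshold, time = record$time),
            class = "contact_kinetics")
}

fill_hold <- function(m) {
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- which(!is.na(v))
    if (length(ok) == 0L) { m[, j] <- 0; next }
    v[seq_len(ok[1])] <- v[ok[1]]
    for (i in seq_along(v)) if (is.na(v[i])) v[i] <- v[i - 1]
    m[, j] <- v
  }
  m
}

#' Segment inertial parameters from an anthropometric table
#'
#' Scales published segment mass fractions, COM offsets and radii of
#' gyration to a subject. The default table is the adjusted Zatsiorsky
#' segment inertia set (de Leva 1996), shipped as a CSV resource; the table
#' id is recorded in the result for provenance.
#'
#' @param mass_body whole-body mass, kg.
#' @param segment_length segment length (foot length or shank length), m.
#' @param table anthropometric table id (`"deleva_male"` or
#'   `"deleva_female"`).
#' @param segment `"foot"` or `"shank"`.
#' @return object of class `inertial_params`: `mass` (kg), `com_offset`
#'   (fraction of segment length from the proximal end), `moi` (3 x 3
#'   diagonal inertia tensor about the COM in the segment frame, kg m^2,
#'   axes ordered sagittal/transverse/longitudinal), `table`, `segment`.
#' @export
foot_inertial <- function(mass_body, segment_length, table = "deleva_male",
                          segment = "foot") {
  if (mass_body <= 0) stop("body mass must be positive")
  if (segment_length <= 0) stop("degenerate geometry: segment length must be positive")
  path <- system.file("extdata", "anthropometry_deleva.csv", package = "footpower")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  row <- tab[tab$table_id == table & tab$segment == segment, ]
  if (nrow(row) != 1L)
    stop("unknown anthropometric table/segment: ", table, "/", segment)
  m <- mass_body * row$mass_fraction
  rg <- c(row$rg_sagittal, row$rg_transverse, row$rg_longitudinal) * segment_length
  structure(list(mass = m, com_offset = row$com_fraction,
                 moi = diag(m * rg^2), table = table, segment = segment),
            class = "inertial_params")
}
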