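# Small 3D geometry kernel used throughout: row-wise vector algebra on
# time x 3 matrices, rotation-matrix utilities, rigid (Kabsch) pose fits.
# All quantities live in a right-handed lab frame with Z vertical up; metres.

#' Row-wise cross product of two time x 3 matrices
#'
#' @param a,b numeric matrices with 3 columns and equal row counts.
#' @return matrix of the same shape with `a[i,] x b[i,]` in row i.
#' @keywords internal
row_cross <- function(a, b) {
  a <- as_mat3(a, nrow(as_mat3(b)))
  b <- as_mat3(b, nrow(a))
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Row-wise dot product
#' @keywords internal
row_dot <- function(a, b) {
  a <- as_mat3(a, nrow(as_mat3(b)))
  b <- as_mat3(b, nrow(a))
  rowSums(a * b)
}

# Coerce a length-3 vector to an n x 3 matrix (recycled), or pass a matrix
# through after a shape check.
as_mat3 <- function(x, n = NULL) {
  if (is.matrix(x)) {
    if (ncol(x) != 3L) stop("expected a 3-column matrix")
    return(x)
  }
  if (length(x) != 3L) stop("expected a length-3 vector or time x 3 matrix")
  if (is.null(n)) n <- 1L
  matrix(x, nrow = n, ncol = 3L, byrow = TRUE)
}

#' Rotation matrix about a fixed axis
#'
#' Rodrigues' formula for a right-handed rotation of `theta` radians about
#' the (normalized) axis `axis`.
#' @keywords internal
rot_axis_angle <- function(axis, theta) {
  n <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -n[3], n[2],
                n[3], 0, -n[1],
                -n[2], n[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# Check orthonormality of a 3 x 3 x T rotation array.
check_rotations <- function(R, tol = 1e-6) {
  for (k in seq_len(dim(R)[3])) {
    Rk <- R[, , k]
    if (max(abs(crossprod(Rk) - diag(3))) > tol || det(Rk) < 0)
      stop("rotation matrices must be orthonormal with determinant +1")
  }
  invisible(TRUE)
}

#' Least-squares rigid pose (Kabsch) of a marker cloud
#'
#' Finds rotation R and translation d minimizing sum ||y_i - (R x_i + d)||^2
#' for template points `x` (k x 3, segment frame) and measured points `y`
#' (k x 3, lab frame).
#'
#' @return list with `rotation` (3x3 lab-from-segment) and `translation`
#'   (position of the template origin in the lab frame).
#' @keywords internal
kabsch <- function(x, y) {
  if (nrow(x) < 3L) stop("at least 3 markers are required for a rigid pose")
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  s <- svd(crossprod(xc, yc))
  if (s$d[2] < 1e-12 * max(s$d[1], 1e-300))
    stop("degenerate (collinear) marker configuration: rigid pose is not identifiable")
  D <- diag(c(1, 1, sign(det(s$v %*% t(s$u)))))
  R <- s$v %*% D %*% t(s$u)
  list(rotation = R, translation = as.numeric(cy - R %*% cx))
}

# Rotation matrix -> unit quaternion (w, x, y, z). Used by tests as an
# independent route to angular velocity; kept here because it is also handy
# for interpolation.
rot_to_quat <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}
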