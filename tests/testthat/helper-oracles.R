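# Independent oracles used across the suite. These deliberately take
# different computational routes from the package code they check.

# Angular velocity via quaternion logarithms: q(t) from the rotation
# matrices, finite-differenced, omega = 2 * vec(qdot * conj(q)).
quat_omega_oracle <- function(R, fs) {
  n <- dim(R)[3]
  q <- t(vapply(seq_len(n), function(i) footpower:::rot_to_quat(R[, , i]),
                numeric(4)))
  # enforce continuity of the double cover
  for (i in 2:n) if (sum(q[i, ] * q[i - 1, ]) < 0) q[i, ] <- -q[i, ]
  qdot <- q
  qdot[2:(n - 1), ] <- (q[3:n, ] - q[1:(n - 2), ]) * fs / 2
  qdot[1, ] <- (q[2, ] - q[1, ]) * fs
  qdot[n, ] <- (q[n, ] - q[n - 1, ]) * fs
  quat_mul <- function(a, b) c(
    a[1] * b[1] - sum(a[2:4] * b[2:4]),
    a[1] * b[2:4] + b[1] * a[2:4] + c(a[3] * b[4] - a[4] * b[3],
                                      a[4] * b[2] - a[2] * b[4],
                                      a[2] * b[3] - a[3] * b[2]))
  t(vapply(seq_len(n), function(i) {
    w <- 2 * quat_mul(qdot[i, ], c(q[i, 1], -q[i, 2:4]))
    w[2:4]
  }, numeric(3)))
}

# Analytic magnitude response of the package's dual-pass low-pass at
# frequency f: the digital Butterworth filter evaluated on the unit circle,
# squared for the forward-backward pass.
butter_gain_oracle <- function(f, fs, fc, order = 2) {
  bf <- signal::butter(order, fc / (fs / 2), type = "low")
  w <- 2 * pi * f / fs
  z <- exp(-1i * w * seq(0, length(bf$b) - 1))
  h <- sum(bf$b * z) / sum(bf$a * z)
  Mod(h)^2
}

# Fit the amplitude of a sinusoid at known frequency over the central
# portion of a record (avoids filter edge transients).
fit_amplitude <- function(x, f, fs) {
  n <- length(x)
  sel <- floor(n / 4):ceiling(3 * n / 4)
  t <- (sel - 1) / fs
  co <- stats::coef(stats::lm(x[sel] ~ sin(2 * pi * f * t) + cos(2 * pi * f * t) - 1))
  sqrt(sum(co^2))
}

# A smooth random rotation sequence: random fixed axis, sum-of-sines angle.
random_rotation_series <- function(n, fs, seed) {
  set.seed(seed)
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  amp <- stats::runif(2, 0.05, 0.3); fr <- stats::runif(2, 0.5, 2)
  ph <- stats::runif(2, 0, 2 * pi)
  t <- (seq_len(n) - 1) / fs
  th <- amp[1] * sin(2 * pi * fr[1] * t + ph[1]) +
    amp[2] * sin(2 * pi * fr[2] * t + ph[2])
  R <- array(0, c(3, 3, n))
  for (i in seq_len(n)) R[, , i] <- footpower:::rot_axis_angle(axis, th[i])
  list(R = R, axis = axis,
       omega_true = outer(2 * pi * (amp[1] * fr[1] * cos(2 * pi * fr[1] * t + ph[1]) +
                                    amp[2] * fr[2] * cos(2 * pi * fr[2] * t + ph[2])),
                          axis))
}

# Align a trial's ground truth to the samples retained in a stance window.
truth_stance_index <- function(truth, stance) {
  t0 <- stance$markers$time[1]
  t1 <- stance$markers$time[length(stance$markers$time)]
  which(truth$time >= t0 - 1e-9 & truth$time <= t1 + 1e-9)
}
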