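make_cloud_markers <- function(local, R_series, com, labels, fs = 150,
                               noise_sd = 0) {
  n <- dim(R_series)[3]
  pos <- array(0, c(n, nrow(local), 3))
  for (i in seq_len(n))
    for (j in seq_len(nrow(local)))
      pos[i, j, ] <- com[i, ] + R_series[, , i] %*% local[j, ] +
        rnorm(3, 0, noise_sd)
  marker_trajectories(pos, labels, fs)
}

test_that("rigid pose estimation is equivariant under rigid transforms", {
  set.seed(1)
  local <- rbind(c(0.1, 0, 0), c(0, 0.08, 0), c(0, 0, 0.06), c(0.03, 0.03, 0.02))
  def <- segment_def("foot", paste0("M", 1:4), local)
  rr <- random_rotation_series(40, 150, seed = 2)
  com <- cbind(0.1 + 0.01 * sin(1:40 / 5), 0.02 * cos(1:40 / 7), 0.05 + 0 * 1:40)
  mk <- make_cloud_markers(local, rr$R, com, def$labels)
  pose <- segment_pose(mk, def)
  expect_equal(pose$com_position, com, tolerance = 1e-10)

  # translation shifts the COM only
  mk2 <- mk
  mk2$positions <- sweep(mk$positions, 3, c(0.1, 0, 0), `+`)
  pose2 <- segment_pose(mk2, def)
  expect_equal(pose2$com_position, sweep(com, 2, c(0.1, 0, 0), `+`),
               tolerance = 1e-10)
  expect_equal(pose2$rotation, pose$rotation, tolerance = 1e-10)

  # premultiplied rotation about Z
  Q <- footpower:::rot_axis_angle(c(0, 0, 1), pi / 2)
  mk3 <- mk
  for (i in 1:40) mk3$positions[i, , ] <- t(Q %*% t(mk$positions[i, , ]))
  pose3 <- segment_pose(mk3, def)
  for (i in 1:40)
    expect_equal(pose3$rotation[, , i], Q %*% pose$rotation[, , i],
                 tolerance = 1e-10)

  collinear <- segment_def("bad", paste0("M", 1:3),
                           rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0, 0)))
  mkc <- make_cloud_markers(collinear$local, rr$R[, , 1:5, drop = FALSE],
                            com[1:5, ], collinear$labels)
  expect_error(segment_pose(mkc, collinear), "collinear")
})

test_that("pose recovery from noisy markers stays within 0.5 deg and 2 mm", {
  set.seed(3)
  local <- rbind(c(0.20, 0.02, -0.05), c(-0.15, 0, -0.04),
                 c(0.06, -0.15, 0), c(0.04, 0.14, 0.03),
                 c(0.10, 0.10, 0.15), c(-0.10, -0.10, 0.12),
                 c(0.15, -0.08, 0.10), c(-0.05, 0.12, -0.10))
  def <- segment_def("seg", paste0("M", 1:8), local)
  rr <- random_rotation_series(60, 150, seed = 4)
  com <- cbind(0.1 + 0.02 * sin(1:60 / 8), 0.01 * cos(1:60 / 9), 0.06 + 0 * 1:60)
  mk <- make_cloud_markers(local, rr$R, com, def$labels, noise_sd = 1e-3)
  pose <- segment_pose(mk, def)
  expect_lt(max(sqrt(rowSums((pose$com_position - com)^2))), 2e-3)
  ang_err <- vapply(1:60, function(i) {
    dR <- t(pose$rotation[, , i]) %*% rr$R[, , i]
    acos(pmin(1, (sum(diag(dR)) - 1) / 2))
  }, numeric(1))
  expect_lt(max(ang_err) * 180 / pi, 0.5)
})

test_that("angular velocity matches closed forms and the quaternion oracle", {
  n <- 60; fs <- 150
  # constant rotation -> zero
  Rc <- array(footpower:::rot_axis_angle(c(1, 1, 0) / sqrt(2), 0.4), c(3, 3, n))
  expect_equal(angular_velocity(Rc, fs), matrix(0, n, 3), tolerance = 1e-12)
  # uniform spin about Z at 2 rad/s (fine sampling: the discretization error
  # of the central difference is (omega/fs)^2/6 relative)
  fsf <- 5000
  Rz <- array(0, c(3, 3, n))
  for (i in 1:n) Rz[, , i] <- footpower:::rot_axis_angle(c(0, 0, 1),
                                                         2 * (i - 1) / fsf)
  w <- angular_velocity(Rz, fsf)
  expect_equal(w[2:(n - 1), ], matrix(rep(c(0, 0, 2), each = n - 2), ncol = 3),
               tolerance = 1e-6)
  # random smooth motions vs the quaternion-log oracle (sampled finely enough
  # that both routes are within their asymptotic regime)
  worst <- 0
  for (s in 1:100) {
    rr <- random_rotation_series(80, 1000, seed = 100 + s)
    w1 <- angular_velocity(rr$R, 1000)
    w2 <- quat_omega_oracle(rr$R, 1000)
    worst <- max(worst, max(abs(w1 - w2)))
  }
  expect_lt(worst, 1e-4)
  expect_error(angular_velocity(Rz[, , 1, drop = FALSE], fs), "at least 2")
})

test_that("differentiate matches analytic derivatives", {
  fs <- 150; t <- (0:149) / fs
  expect_equal(differentiate(3 * t, fs), rep(3, 150), tolerance = 1e-9)
  expect_equal(differentiate(rep(5, 150), fs), rep(0, 150), tolerance = 1e-12)
  d <- differentiate(sin(2 * pi * t), fs)
  expect_lt(max(abs(d - 2 * pi * cos(2 * pi * t))[2:149]), 1e-2)
  expect_error(differentiate(1:2, fs), "at least 3")
})

test_that("COP and free moment follow the plate conventions", {
  n <- 10
  rec <- force_plate_record(matrix(rep(c(0, 0, 500), each = n), n, 3),
                            matrix(0, n, 3), sample_rate = 300)
  ck <- cop_and_free_moment(rec)
  expect_equal(ck$cop, matrix(0, n, 3))
  expect_equal(ck$free_moment, matrix(0, n, 3))

  rec2 <- force_plate_record(matrix(rep(c(0, 0, 500), each = n), n, 3),
                             matrix(rep(c(0, -50, 0), each = n), n, 3),
                             sample_rate = 300)
  expect_equal(cop_and_free_moment(rec2)$cop[, 1], rep(0.1, n))

  rec3 <- force_plate_record(matrix(rep(c(0, 0, 500), each = n), n, 3),
                             matrix(rep(c(0, 0, 10), each = n), n, 3),
                             sample_rate = 300)
  expect_equal(cop_and_free_moment(rec3)$free_moment,
               matrix(rep(c(0, 0, 10), each = n), n, 3))

  expect_error(cop_and_free_moment(
    force_plate_record(matrix(0, n, 3), matrix(0, n, 3))), "no contact")

  # COP on the plate surface, free moment strictly vertical, held when invalid
  g <- generate_trial(synthetic_trial_spec(seed = 5))
  st <- segment_stance(g$trial)
  ck4 <- cop_and_free_moment(st$force)
  expect_true(all(ck4$cop[, 3] == st$force$plate_origin[3]))
  expect_true(all(ck4$free_moment[, 1:2] == 0))
  expect_false(anyNA(ck4$cop))
})

test_that("anthropometric inertia scales with mass and rejects bad input", {
  ip <- foot_inertial(68.4, 0.26)
  tab <- read.csv(system.file("extdata", "anthropometry_deleva.csv",
                              package = "footpower"))
  frac <- tab$mass_fraction[tab$table_id == "deleva_male" & tab$segment == "foot"]
  expect_equal(ip$mass, 68.4 * frac)
  expect_true(all(diag(ip$moi) > 0))
  ip2 <- foot_inertial(2 * 68.4, 0.26)
  expect_equal(ip2$mass, 2 * ip$mass)
  expect_equal(ip2$moi, 2 * ip$moi)
  expect_error(foot_inertial(68.4, 0), "degenerate")
  expect_error(foot_inertial(68.4, 0.26, table = "nope"), "unknown")
})
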