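test_that("ankle power reduces to the dot-product definition", {
  n <- 5
  mk_kin <- function(com_v, omega, com = c(0, 0, 0)) {
    structure(list(rotation = array(diag(3), c(3, 3, n)),
                   com_position = matrix(com, n, 3, byrow = TRUE),
                   com_velocity = matrix(com_v, n, 3, byrow = TRUE),
                   com_acceleration = matrix(0, n, 3),
                   angular_velocity = matrix(omega, n, 3, byrow = TRUE),
                   angular_acceleration = matrix(0, n, 3),
                   joint_point = NULL, fs = 150),
              class = "segment_kinematics")
  }
  ank <- matrix(0, n, 3)
  loads <- structure(list(force = matrix(c(10, 0, 0), n, 3, byrow = TRUE),
                          moment = matrix(c(0, 5, 0), n, 3, byrow = TRUE),
                          ankle_point = ank, fs = 150), class = "joint_loads")
  foot <- mk_kin(c(0, 0, 0), c(0, 0, 0))
  shank <- mk_kin(c(0.2, 0, 0), c(0, 1, 0))
  # F.dV = 10*0.2 = 2 W; M.w_rel = 5*1 = 5 W
  expect_equal(ankle_power(loads, foot, shank), rep(7, n))
  # zero loads -> zero power
  loads0 <- loads; loads0$force[] <- 0; loads0$moment[] <- 0
  expect_equal(ankle_power(loads0, foot, shank), rep(0, n))
  # welded limit: identical segment motion -> zero power for any load
  expect_equal(ankle_power(loads, shank, shank), rep(0, n))
})

test_that("foot power implements the COP/free-moment formulation", {
  n <- 4
  foot <- structure(list(rotation = array(diag(3), c(3, 3, n)),
                         com_position = matrix(0, n, 3),
                         com_velocity = matrix(0, n, 3),
                         com_acceleration = matrix(0, n, 3),
                         angular_velocity = matrix(c(0, 0, 1), n, 3, byrow = TRUE),
                         angular_acceleration = matrix(0, n, 3),
                         joint_point = NULL, fs = 150),
                    class = "segment_kinematics")
  contact <- structure(list(grf = matrix(c(0, 100, 0), n, 3, byrow = TRUE),
                            cop = matrix(c(0.1, 0, 0), n, 3, byrow = TRUE),
                            free_moment = matrix(c(0, 0, 2), n, 3, byrow = TRUE),
                            valid = rep(TRUE, n), threshold = 50,
                            time = (0:(n - 1)) / 150), class = "contact_kinetics")
  # GRF.(w x R) = 100 * 0.1 = 10 W, plus M_free.w = 2 W
  expect_equal(foot_power(contact, foot), rep(12, n))
  # foot at rest -> zero regardless of load
  still <- foot; still$angular_velocity[] <- 0
  expect_equal(foot_power(contact, still), rep(0, n))
  # zero load -> zero
  c0 <- contact; c0$grf[] <- 0; c0$free_moment[] <- 0
  expect_equal(foot_power(c0, foot), rep(0, n))
  # invalid samples forced to zero
  cm <- contact; cm$valid[2] <- FALSE
  expect_equal(foot_power(cm, foot), c(12, 0, 12, 12))
})

test_that("sum power is the exact samplewise sum and is linear", {
  a <- c(1, 2, 3); b <- c(2, -2, 0.5)
  expect_identical(sum_power(a, b), a + b)
  expect_equal(sum_power(a, -a), rep(0, 3))
  expect_equal(sum_power(a + b, b), sum_power(a, b) + b)
  expect_error(sum_power(a, b[1:2]), "clock mismatch")
})

test_that("propulsion window starts at the last upward zero crossing", {
  n <- 100
  p <- c(rep(-1, 30), rep(1, 10), rep(-1, 30), seq(-0.01, 2, length.out = 30))
  win <- propulsion_window(p)
  expect_equal(win[1], which(p[-n] < 0 & p[-1] >= 0)[2] + 1L)
  expect_equal(win[length(win)], n)
  # known max inside the window is recovered
  expect_equal(max(p[win]), 2)
  expect_warning(w2 <- propulsion_window(rep(1, 50)), "final 50%")
  expect_equal(w2, 26:50)
  expect_error(propulsion_window(rep(0, 10)), "degenerate")
})

test_that("work integrals follow closed forms and decompose exactly", {
  t <- seq(0, 1, length.out = 1001)
  expect_equal(work(rep(1, 1001), t, sign = "positive"), 1)
  expect_equal(work(rep(1, 1001), t, sign = "negative"), 0)
  p <- t - 0.5
  expect_equal(work(p, t, sign = "net"), 0, tolerance = 1e-12)
  expect_equal(work(p, t, sign = "positive"), 0.125, tolerance = 1e-6)
  expect_equal(work(p, t, sign = "negative"), -0.125, tolerance = 1e-6)
  s <- sin(2 * pi * t)
  expect_equal(work(s, t, sign = "positive"), -work(s, t, sign = "negative"),
               tolerance = 1e-12)
  expect_equal(work(s, t, sign = "net"), 0, tolerance = 1e-12)
  expect_warning(w0 <- work(p, t, window = integer(0)), "empty")
  expect_equal(w0, 0)
  expect_error(work(p, t, window = 1000:1002), "outside")
})

test_that("per-stance features obey the decomposition identity and averaging", {
  g <- generate_trial(synthetic_trial_spec(seed = 61))
  ps <- analyze_trial(g$trial)$powers
  f <- stance_features(ps)
  for (v in c("ankle", "foot", "sum")) {
    net <- work(ps[[paste0("p_", v)]], ps$time, sign = "net")
    expect_equal(f[[paste0("wpos_", v)]] + f[[paste0("wneg_", v)]], net,
                 tolerance = 1e-9)
  }
  expect_true(all(f[paste0("wpos_", c("ankle", "foot", "sum"))] >= 0))
  expect_true(all(f[paste0("wneg_", c("ankle", "foot", "sum"))] <= 0))
  expect_equal(ps$p_sum, ps$p_ankle + ps$p_foot)

  subj <- g$trial$subject
  rec <- extract_features(list(ps, ps, ps), subj, "comfortable", 1.23)
  expect_equal(unlist(rec[footpower:::FEATURE_NAMES]), f,
               ignore_attr = TRUE)
  expect_error(extract_features(list(ps), subj, "comfortable", 1.23),
               "excluded")
})

test_that("powers are linear in the applied loads", {
  g <- generate_trial(synthetic_trial_spec(seed = 62))
  an <- analyze_trial(g$trial)
  loads2 <- an$loads
  loads2$force <- 2 * loads2$force
  loads2$moment <- 2 * loads2$moment
  expect_equal(ankle_power(loads2, an$foot_kin, an$shank_kin),
               2 * ankle_power(an$loads, an$foot_kin, an$shank_kin),
               tolerance = 1e-12)
  contact2 <- an$contact
  contact2$grf <- 2 * contact2$grf
  contact2$free_moment <- 2 * contact2$free_moment
  expect_equal(foot_power(contact2, an$foot_kin),
               2 * foot_power(an$contact, an$foot_kin), tolerance = 1e-12)
})

test_that("features are robust to the sampling discretization", {
  g1 <- generate_trial(synthetic_trial_spec(seed = 63))
  g4 <- generate_trial(synthetic_trial_spec(seed = 63, fs_markers = 600,
                                            fs_force = 1200))
  f1 <- stance_features(analyze_trial(g1$trial)$powers)
  f4 <- stance_features(analyze_trial(g4$trial)$powers)
  scale <- max(abs(f1))
  expect_lt(max(abs(f1 - f4)) / scale, 0.01)
})
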