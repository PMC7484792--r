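# Synthetic walking trials with analytic ground truth. Foot and shank
# trajectories are prescribed as sums of sines (closed-form velocities and
# accelerations) and rotations about fixed axes (closed-form angular
# velocity); the ground reaction force, centre of pressure and free moment
# are prescribed over a single-stance contact window; the ankle loads are
# then computed FORWARD from the Newton-Euler equations, so the emitted
# trial is dynamically consistent by construction and every pipeline stage
# has an exact reference.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Specification of one synthetic walking trial
#'
#' Defaults emulate a barefoot comfortable-speed pass: 0.63 s of
#' supra-threshold stance (the young-group comfortable mean), a double-hump
#' vertical force, markers at 150 Hz and forces at 300 Hz. With
#' `randomize = TRUE` the trajectory phases and amplitudes are jittered
#' reproducibly from `seed`, so different seeds give different (still
#' noiseless, still consistent) trials.
#'
#' @param seed integer seed; same seed + spec gives bit-identical output.
#' @param stance_time target supra-threshold contact duration, s.
#' @param peak_force peak vertical force, N.
#' @param subject a [subject_info()]; default is a young subject with the
#'   study-average anthropometry (68.4 kg, 1.71 m).
#' @param condition,measured_speed condition label and pass speed.
#' @param marker_noise_sd,force_noise_sd additive Gaussian noise, m and N.
#' @param fs_markers,fs_force sampling rates, Hz.
#' @param threshold gait-event force threshold the contact window is shaped
#'   around, N.
#' @param pad quiet time before and after contact, s.
#' @param randomize jitter trajectory phases/amplitudes from the seed.
#' @param motion_scale multiplier on all trajectory amplitudes; 0 gives a
#'   static foot and shank under the prescribed load.
#' @return object of class `synthetic_trial_spec`.
#' @export
synthetic_trial_spec <- function(seed = 1L, stance_time = 0.63,
                                 peak_force = 750, subject = NULL,
                                 condition = "comfortable",
                                 measured_speed = 1.23,
                                 marker_noise_sd = 0, force_noise_sd = 0,
                                 fs_markers = 150, fs_force = 300,
                                 threshold = 50, pad = 0.25,
                                 randomize = TRUE, motion_scale = 1) {
  if (is.null(subject))
    subject <- subject_info("synth01", age = 28, height = 1.71, mass = 68.4,
                            leg_length = 0.88, comfortable_speed = 1.23)
  stopifnot(stance_time > 0, peak_force > threshold, pad > 0)
  structure(list(seed = as.integer(seed), stance_time = stance_time,
                 peak_force = peak_force, subject = subject,
                 condition = condition, measured_speed = measured_speed,
                 marker_noise_sd = marker_noise_sd,
                 force_noise_sd = force_noise_sd,
                 fs_markers = fs_markers, fs_force = fs_force,
                 threshold = threshold, pad = pad, randomize = randomize,
                 motion_scale = motion_scale),
            class = "synthetic_trial_spec")
}

# marker layouts in segment frames (origin at the segment COM); the ankle
# centre is the malleoli midpoint, rigid in the shank frame
FOOT_LOCAL <- rbind(TOE = c(0.10, 0.01, -0.04),
                    HEEL = c(-0.07, 0.00, -0.03),
                    FOOT_LAT = c(0.03, -0.05, 0.00),
                    FOOT_MED = c(0.02, 0.04, 0.02))
SHANK_ANKLE_LOCAL <- c(0.02, -0.01, -0.30)
SHANK_LOCAL <- rbind(TIB_ANT = c(0.04, 0.00, -0.10),
                     TIB_LAT = c(0.00, -0.05, -0.05),
                     TIB_UP = c(0.01, 0.01, 0.12),
                     ANK_MED = SHANK_ANKLE_LOCAL + c(0, 0.04, 0),
                     ANK_LAT = SHANK_ANKLE_LOCAL + c(0, -0.04, 0))

#' Segment definitions matching the synthetic marker set
#'
#' Foot pose from four foot-fixed markers; shank pose from three shaft
#' markers plus the two malleoli, whose midpoint defines the ankle centre.
#' @return list with elements `foot` and `shank` ([segment_def()]s).
#' @export
synthetic_segment_defs <- function() {
  list(foot = segment_def("foot", rownames(FOOT_LOCAL), FOOT_LOCAL),
       shank = segment_def("shank", rownames(SHANK_LOCAL), SHANK_LOCAL,
                           joint_local = SHANK_ANKLE_LOCAL))
}

# double-hump contact shape on s in [0,1]
contact_shape <- function(s) sin(pi * s) + 0.3 * sin(3 * pi * s)

# closed-form building blocks -------------------------------------------------

make_sine_traj <- function(base, amp, freq, phase) {
  force(base); force(amp); force(freq); force(phase)
  w <- 2 * pi * freq
  list(pos = function(t) sweep(cbind(amp[1] * sin(w[1] * t + phase[1]),
                                     amp[2] * sin(w[2] * t + phase[2]),
                                     amp[3] * sin(w[3] * t + phase[3])),
                               2, base, `+`),
       vel = function(t) cbind(amp[1] * w[1] * cos(w[1] * t + phase[1]),
                               amp[2] * w[2] * cos(w[2] * t + phase[2]),
                               amp[3] * w[3] * cos(w[3] * t + phase[3])),
       acc = function(t) cbind(-amp[1] * w[1]^2 * sin(w[1] * t + phase[1]),
                               -amp[2] * w[2]^2 * sin(w[2] * t + phase[2]),
                               -amp[3] * w[3]^2 * sin(w[3] * t + phase[3])))
}

make_sine_rot <- function(axis, amp, freq, phase) {
  axis <- axis / sqrt(sum(axis^2))
  w <- 2 * pi * freq
  list(R = function(t) {
         out <- array(0, c(3, 3, length(t)))
         th <- amp * sin(w * t + phase)
         for (i in seq_along(t)) out[, , i] <- rot_axis_angle(axis, th[i])
         out
       },
       omega = function(t) outer(amp * w * cos(w * t + phase), axis),
       omegadot = function(t) outer(-amp * w^2 * sin(w * t + phase), axis))
}

# Build the analytic model of one trial: a list of closed-form functions of
# time plus scalar layout facts. All randomness is resolved here.
build_trial_model <- function(spec) {
  jit <- with_seed(spec$seed, if (spec$randomize) {
    list(ph = stats::runif(8, 0, 2 * pi), sc = stats::runif(8, 0.8, 1.2))
  } else list(ph = rep(c(0.3, 1.1, 2.0, 0.7, 1.7, 0.2, 2.5, 0.9), length.out = 8),
              sc = rep(1, 8)))
  thr_frac <- spec$threshold / spec$peak_force
  gmax <- stats::optimize(contact_shape, c(0, 0.5), maximum = TRUE)$objective
  s_star <- stats::uniroot(function(s) contact_shape(s) / gmax - thr_frac,
                           c(1e-9, 0.45), tol = 1e-12)$root
  Tc <- spec$stance_time / (1 - 2 * s_star)
  t0 <- spec$pad
  duration <- Tc + 2 * spec$pad

  ms <- spec$motion_scale %||% 1
  foot_tr <- make_sine_traj(c(0.12, 0, 0.06),
                            ms * c(0.012, 0.006, 0.010) * jit$sc[1:3],
                            c(1.1, 0.9, 1.3), jit$ph[1:3])
  foot_rot <- make_sine_rot(c(0.15, 0.97, 0.20), ms * 0.15 * jit$sc[4], 1.2,
                            jit$ph[4])
  shank_tr <- make_sine_traj(c(0.05, 0.02, 0.40),
                             ms * c(0.015, 0.008, 0.012) * jit$sc[5:7],
                             c(0.8, 1.2, 1.0), jit$ph[5:7])
  shank_rot <- make_sine_rot(c(0.10, 0.99, 0.00), ms * 0.20 * jit$sc[8], 1.0,
                             jit$ph[8])

  foot_length <- 0.152 * spec$subject$height
  inertia <- foot_inertial(spec$subject$mass, foot_length)

  sfun <- function(t) pmin(pmax((t - t0) / Tc, 0), 1)
  in_contact <- function(t) t >= t0 & t <= t0 + Tc
  grf <- function(t) {
    s <- sfun(t); on <- in_contact(t)
    fz <- spec$peak_force * contact_shape(s) / gmax
    fx <- -0.15 * spec$peak_force * sin(2 * pi * s) * sin(pi * s)
    fy <- 0.04 * spec$peak_force * sin(2 * pi * s + 0.8) * sin(pi * s)
    cbind(fx * on, fy * on, pmax(fz, 0) * on)
  }
  cop <- function(t) {
    s <- sfun(t)
    cbind(0.05 + 0.20 * (3 * s^2 - 2 * s^3), 0.01 * sin(pi * s), 0)
  }
  free_moment <- function(t) {
    s <- sfun(t)
    cbind(0, 0, 3 * sin(2 * pi * s) * sin(pi * s) * in_contact(t))
  }
  cop_path <- cop(seq(t0, t0 + Tc, length.out = 50))
  if (any(cop_path[, 1] < -0.1 | cop_path[, 1] > 0.5 |
          cop_path[, 2] < -0.2 | cop_path[, 2] > 0.2))
    stop("spec error: COP trajectory leaves the plate surface")

  list(spec = spec, t0 = t0, Tc = Tc, duration = duration, s_star = s_star,
       t_heel_strike = t0 + s_star * Tc, t_toe_off = t0 + (1 - s_star) * Tc,
       foot_tr = foot_tr, foot_rot = foot_rot, shank_tr = shank_tr,
       shank_rot = shank_rot, inertia = inertia, foot_length = foot_length,
       grf = grf, cop = cop, free_moment = free_moment)
}

# Evaluate every mechanical ground-truth quantity at times t.
truth_at <- function(model, t, g = c(0, 0, -9.80665)) {
  m <- model$inertia$mass
  n <- length(t)
  r_f <- model$foot_tr$pos(t); v_f <- model$foot_tr$vel(t); a_f <- model$foot_tr$acc(t)
  R_f <- model$foot_rot$R(t); w_f <- model$foot_rot$omega(t)
  wd_f <- model$foot_rot$omegadot(t)
  r_s <- model$shank_tr$pos(t); v_s <- model$shank_tr$vel(t)
  R_s <- model$shank_rot$R(t); w_s <- model$shank_rot$omega(t)
  ank_off <- t(apply(matrix(seq_len(n)), 1, function(i) R_s[, , i] %*% SHANK_ANKLE_LOCAL))
  r_ank <- r_s + ank_off
  v_ank_shank <- v_s + row_cross(w_s, ank_off)
  grf <- model$grf(t); cop <- model$cop(t); mfree <- model$free_moment(t)
  F_ankle <- m * a_f - m * as_mat3(g, n) - grf
  Iw <- matrix(0, n, 3); Iwd <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    I_lab <- R_f[, , i] %*% model$inertia$moi %*% t(R_f[, , i])
    Iw[i, ] <- I_lab %*% w_f[i, ]
    Iwd[i, ] <- I_lab %*% wd_f[i, ]
  }
  M_ankle <- Iwd + row_cross(w_f, Iw) - row_cross(r_ank - r_f, F_ankle) -
    row_cross(cop - r_f, grf) - mfree
  v_ank_foot <- v_f + row_cross(w_f, r_ank - r_f)
  p_ankle <- row_dot(F_ankle, v_ank_shank - v_ank_foot) +
    row_dot(M_ankle, w_s - w_f)
  p_foot <- row_dot(grf, v_f + row_cross(w_f, cop - r_f)) + row_dot(mfree, w_f)
  list(time = t, foot_com = r_f, foot_vel = v_f, foot_acc = a_f,
       foot_rotation = R_f, foot_omega = w_f, foot_omegadot = wd_f,
       shank_com = r_s, shank_vel = v_s, shank_rotation = R_s,
       shank_omega = w_s, ankle_point = r_ank, grf = grf, cop = cop,
       free_moment = mfree, F_ankle = F_ankle, M_ankle = M_ankle,
       p_ankle = p_ankle, p_foot = p_foot, p_sum = p_ankle + p_foot)
}

#' Generate one dynamically consistent synthetic trial
#'
#' Returns the trial in the ordinary [gait_trial()] container (markers at
#' `fs_markers`, plate signals at `fs_force`, optional Gaussian noise) plus
#' a ground-truth list holding the exact kinematics, ankle loads and power
#' series sampled on the marker clock, the true event times, and the nine
#' outcome features computed from the analytic power series on a fine
#' (1500 Hz) grid.
#'
#' @param spec a [synthetic_trial_spec()].
#' @return list with elements `trial` and `truth`.
#' @export
generate_trial <- function(spec = synthetic_trial_spec()) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  model <- build_trial_model(spec)
  t_m <- seq(0, model$duration, by = 1 / spec$fs_markers)
  t_f <- seq(0, model$duration, by = 1 / spec$fs_force)
  truth <- truth_at(model, t_m)

  # markers: rigid attachment + noise
  nm <- length(t_m)
  labels <- c(rownames(FOOT_LOCAL), rownames(SHANK_LOCAL))
  pos <- array(0, c(nm, length(labels), 3))
  noise <- with_seed(spec$seed + 1L, list(
    mk = array(stats::rnorm(nm * length(labels) * 3, 0, spec$marker_noise_sd),
               c(nm, length(labels), 3)),
    ff = matrix(stats::rnorm(length(t_f) * 3, 0, spec$force_noise_sd),
                ncol = 3),
    fm = matrix(stats::rnorm(length(t_f) * 3, 0, 0.3 * spec$force_noise_sd),
                ncol = 3)))
  for (i in seq_len(nm)) {
    Rf <- truth$foot_rotation[, , i]; Rs <- truth$shank_rotation[, , i]
    for (j in seq_len(nrow(FOOT_LOCAL)))
      pos[i, j, ] <- truth$foot_com[i, ] + Rf %*% FOOT_LOCAL[j, ]
    for (j in seq_len(nrow(SHANK_LOCAL)))
      pos[i, nrow(FOOT_LOCAL) + j, ] <- truth$shank_com[i, ] + Rs %*% SHANK_LOCAL[j, ]
  }
  pos <- pos + noise$mk
  markers <- marker_trajectories(pos, labels, spec$fs_markers, time = t_m)

  tf_truth <- truth_at(model, t_f)
  force <- tf_truth$grf + noise$ff
  moment <- row_cross(tf_truth$cop, tf_truth$grf) + tf_truth$free_moment + noise$fm
  plate <- force_plate_record(force, moment, c(0, 0, 0), spec$fs_force,
                              time = t_f)
  trial <- gait_trial(spec$subject, spec$condition, spec$measured_speed,
                      markers, plate)

  # analytic-series features on a fine grid over the true stance window
  t_fine <- seq(model$t_heel_strike, model$t_toe_off, by = 1 / 1500)
  fine <- truth_at(model, t_fine)
  ps_true <- power_series(t_fine - t_fine[1], fine$p_ankle, fine$p_foot)
  truth$features <- tryCatch(suppressWarnings(stance_features(ps_true)),
                             error = function(e) NULL)  # degenerate static specs
  truth$stance_time <- spec$stance_time
  truth$t_heel_strike <- model$t_heel_strike
  truth$t_toe_off <- model$t_toe_off
  truth$inertia <- model$inertia
  truth$foot_length <- model$foot_length
  truth$spec <- spec
  list(trial = trial, truth = truth)
}

#' Specification of a synthetic feature table
#'
#' Inverts the analysis model: per-subject comfortable speeds are drawn from
#' group distributions (defaults: young 1.23 +/- 0.17 m/s, older
#' 1.21 +/- 0.20 m/s), slow/fast conditions are +/- 30% of comfortable, and
#' each feature is built as
#' `beta0 + beta_s z(speed) + beta_a group + beta_sa z(speed) group +
#' subject intercept + noise`, with `z(speed)` standardized within the
#' table. `confound = TRUE` replaces the group speed distributions with
#' separated ones (young 1.37 +/- 0.09, older 1.05 +/- 0.13 m/s) so a true
#' null age effect masquerades as an age difference unless speed is in the
#' model.
#'
#' @param seed integer seed.
#' @param n_young,n_older subjects per group.
#' @param beta0,beta_s,beta_a,beta_sa true model coefficients.
#' @param sigma_subject random-intercept SD.
#' @param sigma_eps residual SD.
#' @param speed_young,speed_older `c(mean, sd)` of comfortable speed, m/s.
#' @param features feature column names to synthesize.
#' @param confound use the separated speed distributions.
#' @return object of class `synthetic_feature_spec`.
#' @export
synthetic_feature_spec <- function(seed = 1L, n_young = 24, n_older = 16,
                                   beta0 = 0, beta_s = 0.8, beta_a = 0,
                                   beta_sa = 0, sigma_subject = 0.3,
                                   sigma_eps = 0.4,
                                   speed_young = c(1.23, 0.17),
                                   speed_older = c(1.21, 0.20),
                                   features = FEATURE_NAMES,
                                   confound = FALSE) {
  if (sigma_subject < 0 || sigma_eps < 0)
    stop("spec error: noise SDs must be non-negative")
  if (confound) {
    speed_young <- c(1.37, 0.09)
    speed_older <- c(1.05, 0.13)
  }
  structure(list(seed = as.integer(seed), n_young = n_young, n_older = n_older,
                 beta0 = beta0, beta_s = beta_s, beta_a = beta_a,
                 beta_sa = beta_sa, sigma_subject = sigma_subject,
                 sigma_eps = sigma_eps, speed_young = speed_young,
                 speed_older = speed_older, features = features,
                 confound = confound),
            class = "synthetic_feature_spec")
}

#' Generate a feature table with known mixed-effects structure
#'
#' @param spec a [synthetic_feature_spec()].
#' @return list with `table` (data.frame: subject_id, condition, speed,
#'   age_group, age, one column per feature) and `truth` (the coefficients
#'   and SDs used). Features are on the model scale: fit them with
#'   `standardize_response = FALSE` to recover the true coefficients
#'   directly.
#' @export
generate_feature_table <- function(spec = synthetic_feature_spec()) {
  stopifnot(inherits(spec, "synthetic_feature_spec"))
  with_seed(spec$seed, {
    n <- spec$n_young + spec$n_older
    grp <- c(rep(0L, spec$n_young), rep(1L, spec$n_older))
    comf <- ifelse(grp == 0,
                   stats::rnorm(n, spec$speed_young[1], spec$speed_young[2]),
                   stats::rnorm(n, spec$speed_older[1], spec$speed_older[2]))
    comf <- pmax(comf, 0.4)
    age <- ifelse(grp == 0,
                  pmin(pmax(stats::rnorm(n, 27.6, 4.4), 18), 40),
                  pmax(stats::rnorm(n, 62.9, 7.4), 55))
    tab <- data.frame(
      subject_id = rep(sprintf("S%02d", seq_len(n)), each = 3),
      condition = rep(c("slow", "comfortable", "fast"), times = n),
      speed = as.vector(rbind(0.7 * comf, comf, 1.3 * comf)),
      age_group = rep(grp, each = 3),
      age = rep(age, each = 3))
    z <- as.numeric(standardize(tab$speed))
    for (f in spec$features) {
      b <- rep(stats::rnorm(n, 0, spec$sigma_subject), each = 3)
      eps <- stats::rnorm(nrow(tab), 0, spec$sigma_eps)
      tab[[f]] <- spec$beta0 + spec$beta_s * z + spec$beta_a * tab$age_group +
        spec$beta_sa * z * tab$age_group + b + eps
    }
    list(table = tab,
         truth = list(beta0 = spec$beta0, beta_s = spec$beta_s,
                      beta_a = spec$beta_a, beta_sa = spec$beta_sa,
                      sigma_subject = spec$sigma_subject,
                      sigma_eps = spec$sigma_eps, seed = spec$seed))
  })
}

#' Write a synthetic trial to the on-disk dataset layout
#'
#' Produces the same layout [load_trial()] reads: `subjects.yaml` at the
#' root, and `trial<k>_{markers,forces}.tsv` + `trial<k>_meta.yaml` under
#' `<root>/<subject>/<condition>/`. The ground truth, when given, is saved
#' as a JSON sidecar (`trial<k>_truth.json`) holding the scalar truth
#' (event times, stance time, features) and the power series on the marker
#' clock.
#'
#' @param trial a [gait_trial()].
#' @param out_dir dataset root directory.
#' @param truth optional truth list from [generate_trial()].
#' @param trial_number trial index within the condition.
#' @return the trial directory, invisibly.
#' @export
write_trial <- function(trial, out_dir, truth = NULL, trial_number = 1) {
  sub <- trial$subject
  dir <- file.path(out_dir, sub$subject_id, trial$condition)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  # subject registry: append if absent
  reg_path <- file.path(out_dir, "subjects.yaml")
  reg <- if (file.exists(reg_path)) yaml::read_yaml(reg_path) else list()
  if (!any(vapply(reg, function(s) identical(s$subject_id, sub$subject_id),
                  logical(1)))) {
    reg[[length(reg) + 1L]] <- unclass(sub)
    yaml::write_yaml(reg, reg_path)
  }
  stem <- file.path(dir, sprintf("trial%02d", trial_number))
  write_marker_file(trial$markers, paste0(stem, "_markers.tsv"))
  write_force_file(trial$forceplate, paste0(stem, "_forces.tsv"))
  yaml::write_yaml(list(measured_speed = trial$measured_speed,
                        marker_units = "m",
                        marker_rate = trial$markers$sample_rate,
                        force_rate = trial$forceplate$sample_rate,
                        plate_origin = as.list(trial$forceplate$plate_origin)),
                   paste0(stem, "_meta.yaml"))
  if (!is.null(truth)) {
    side <- list(schema = "footpower/truth/v1",
                 stance_time = truth$stance_time,
                 t_heel_strike = truth$t_heel_strike,
                 t_toe_off = truth$t_toe_off,
                 features = as.list(truth$features),
                 time = truth$time,
                 p_ankle = truth$p_ankle, p_foot = truth$p_foot,
                 p_sum = truth$p_sum)
    jsonlite::write_json(side, paste0(stem, "_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Reload a ground-truth sidecar written by [write_trial()]
#' @param path path to a `*_truth.json` file.
#' @return validated truth list.
#' @export
read_truth_sidecar <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("schema", "stance_time", "t_heel_strike", "t_toe_off",
            "features", "time", "p_ankle", "p_foot", "p_sum")
  missing <- setdiff(need, names(x))
  if (length(missing) || !identical(x$schema, "footpower/truth/v1"))
    stop("invalid truth sidecar ", path, ": missing ",
         paste(missing, collapse = ", "))
  x
}
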