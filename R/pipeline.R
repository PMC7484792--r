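# End-to-end orchestration: single-trial mechanical analysis, study-level
# feature tables, the four-model regression ladder for all nine features,
# ensemble curves and report files.

#' Mechanical analysis of one trial
#'
#' Runs the full per-trial chain: zero-lag filtering and stance
#' segmentation, rigid pose and velocities of foot and shank, centre of
#' pressure and free moment, Newton-Euler ankle loads, and the three stance
#' power series.
#'
#' @param trial a [gait_trial()].
#' @param defs segment definitions (default: the synthetic marker set from
#'   [synthetic_segment_defs()]).
#' @param inertia optional [foot_inertial()] parameters; by default derived
#'   from the subject's mass and an estimated foot length of 15.2% of
#'   stature using `anthropometric_table`.
#' @param anthropometric_table table id for the default inertia.
#' @param markers_fc,forces_fc,filter_order,threshold preprocessing
#'   settings (defaults 10 Hz, 50 Hz, order 2, 50 N).
#' @param normalize_by_mass report power series in W/kg.
#' @return object of class `trial_analysis`: `stance`, `foot_kin`,
#'   `shank_kin`, `contact`, `loads`, `powers`, `inertia`.
#' @export
analyze_trial <- function(trial, defs = synthetic_segment_defs(),
                          inertia = NULL,
                          anthropometric_table = "deleva_male",
                          markers_fc = 10, forces_fc = 50, filter_order = 2,
                          threshold = 50, normalize_by_mass = FALSE) {
  stance <- segment_stance(trial, markers_fc = markers_fc,
                           forces_fc = forces_fc, order = filter_order,
                           threshold = threshold)
  foot_kin <- segment_kinematics(stance$markers, defs$foot)
  shank_kin <- segment_kinematics(stance$markers, defs$shank)
  contact <- cop_and_free_moment(stance$force, threshold)
  if (is.null(inertia))
    inertia <- foot_inertial(trial$subject$mass, 0.152 * trial$subject$height,
                             table = anthropometric_table)
  loads <- newton_euler_foot(foot_kin, contact, inertia,
                             ankle_point = shank_kin$joint_point)
  p_a <- ankle_power(loads, foot_kin, shank_kin)
  p_f <- foot_power(contact, foot_kin)
  scale <- if (normalize_by_mass) 1 / trial$subject$mass else 1
  powers <- power_series(stance$time, p_a * scale, p_f * scale,
                         meta = list(subject_id = trial$subject$subject_id,
                                     condition = trial$condition,
                                     speed = trial$measured_speed,
                                     age_group = trial$subject$age_group),
                         normalized_by_mass = normalize_by_mass)
  structure(list(stance = stance, foot_kin = foot_kin, shank_kin = shank_kin,
                 contact = contact, loads = loads, powers = powers,
                 inertia = inertia), class = "trial_analysis")
}

#' Build a feature table from analyzed trials
#'
#' Groups trial analyses by subject x condition, averages per-trial features
#' and assembles the long-format table the regression stage consumes.
#' Groups with fewer than `min_trials` valid trials are excluded and listed.
#'
#' @param analyses list of [analyze_trial()] results (or of `gait_trial`s,
#'   which are analyzed first with `...` passed on).
#' @param subjects named list of [subject_info()] keyed by subject_id; taken
#'   from the trials when analyzing from scratch.
#' @param min_trials minimum trials per subject x condition.
#' @param ... passed to [analyze_trial()] when raw trials are given.
#' @return list with `table` (data.frame) and `exclusions` (character).
#' @export
build_feature_table <- function(analyses, subjects = NULL, min_trials = 3, ...) {
  if (length(analyses) && inherits(analyses[[1]], "gait_trial")) {
    subjects <- subjects %||% stats::setNames(
      lapply(analyses, `[[`, "subject"),
      vapply(analyses, function(tr) tr$subject$subject_id, character(1)))
    analyses <- lapply(analyses, analyze_trial, ...)
  }
  key <- vapply(analyses, function(a)
    paste(a$powers$meta$subject_id, a$powers$meta$condition, sep = "|"),
    character(1))
  rows <- list(); excl <- character()
  for (k in unique(key)) {
    grp <- analyses[key == k]
    meta <- grp[[1]]$powers$meta
    subj <- subjects[[meta$subject_id]]
    if (is.null(subj)) subj <- grp[[1]]$stance$subject
    res <- tryCatch(
      extract_features(lapply(grp, `[[`, "powers"), subj, meta$condition,
                       mean(vapply(grp, function(a) a$powers$meta$speed,
                                   numeric(1))),
                       min_trials = min_trials),
      error = function(e) conditionMessage(e))
    if (is.character(res)) excl <- c(excl, res) else rows[[length(rows) + 1L]] <- res
  }
  list(table = if (length(rows)) do.call(rbind, rows) else NULL,
       exclusions = excl)
}

#' Ensemble mean +/- SD power curves
#'
#' Time-normalizes every stance to `n_points` over 0--100% stance and
#' returns pointwise means and SDs per group for each of the three power
#' series.
#'
#' @param series_list list of [power_series()].
#' @param groups grouping labels, one per series (default: one group).
#' @param n_points points on the percent-stance grid.
#' @return long data.frame: `pct`, `group`, `variable`, `mean`, `sd`, `n`.
#' @export
ensemble_curves <- function(series_list, groups = NULL, n_points = 101) {
  if (is.null(groups)) groups <- rep("all", length(series_list))
  stopifnot(length(groups) == length(series_list))
  pct <- seq(0, 100, length.out = n_points)
  out <- list()
  for (g in unique(groups)) {
    sel <- series_list[groups == g]
    for (var in c("p_ankle", "p_foot", "p_sum")) {
      m <- vapply(sel, function(ps) as.numeric(time_normalize(ps[[var]], n_points)),
                  numeric(n_points))
      m <- matrix(m, nrow = n_points)
      out[[length(out) + 1L]] <- data.frame(
        pct = pct, group = g, variable = var,
        mean = rowMeans(m),
        sd = apply(m, 1, stats::sd),
        n = ncol(m))
    }
  }
  do.call(rbind, out)
}

#' Run the full regression stage and emit the report bundle
#'
#' Fits the four-model ladder for every feature, computes the
#' likelihood-ratio comparisons for each added term, and (optionally)
#' writes `features.csv`, `ladder.csv`, `lrt.csv` and `provenance.json`
#' under `out_dir`.
#'
#' @param table feature table (subject_id, condition, speed, age_group,
#'   age, feature columns).
#' @param features feature columns to analyze (default: the nine standard
#'   names present).
#' @param standardize_response standardize features before fitting
#'   (the study convention).
#' @param ddf p-value reference, see [fit_lmm()].
#' @param out_dir optional output directory for the CSV/JSON bundle.
#' @return list with `ladders`, `report`, `lrt`, `provenance`.
#' @export
run_regression_report <- function(table, features = NULL,
                                  standardize_response = TRUE,
                                  ddf = "residual", out_dir = NULL) {
  if (is.null(table) || nrow(table) == 0L) stop("empty feature table")
  if (is.null(features)) {
    features <- intersect(FEATURE_NAMES, names(table))
    if (length(features) == 0L)
      features <- setdiff(names(table),
                          c("subject_id", "condition", "speed", "age_group", "age"))
  }
  ladders <- lapply(features, function(f)
    fit_lmm_ladder(table, f, standardize_response = standardize_response,
                   ddf = ddf))
  names(ladders) <- features
  report <- ladder_report(ladders)
  lrt <- do.call(rbind, lapply(features, function(f) {
    lad <- ladders[[f]]
    rbind(
      data.frame(feature = f, comparison = "S vs S+A",
                 as.data.frame(likelihood_ratio_test(lad$S, lad$`S+A`))),
      data.frame(feature = f, comparison = "S+A vs S+A+SxA",
                 as.data.frame(likelihood_ratio_test(lad$`S+A`, lad$`S+A+SxA`))))
  }))
  prov <- list(package = "footpower",
               version = as.character(utils::packageVersion("footpower")),
               r_version = R.version.string,
               features = features,
               standardize_response = standardize_response, ddf = ddf,
               n_rows = nrow(table),
               n_subjects = length(unique(table$subject_id)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table, file.path(out_dir, "features.csv"), row.names = FALSE)
    utils::write.csv(report, file.path(out_dir, "ladder.csv"), row.names = FALSE)
    utils::write.csv(lrt, file.path(out_dir, "lrt.csv"), row.names = FALSE)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(ladders = ladders, report = report, lrt = lrt, provenance = prov)
}

#' Regression ladders on a prepared open-dataset feature table
#'
#' Thin adapter for a laboratory dataset already converted to the package's
#' feature-table layout (`features.csv` with columns `subject_id`,
#' `condition`, `speed`, `age_group`, `age` and the nine features, one row
#' per subject x condition). Runs the standardized ladder for every feature
#' and returns the report plus the headline standardized speed slopes.
#'
#' @param dataset_root directory containing `features.csv`.
#' @return list with `report`, `lrt`, and `key_values` (named vector:
#'   `beta_s_peak_ankle`, `beta_s_wneg_foot`, `beta_a_wneg_foot_adj`,
#'   `mean_abs_beta_s` across the nine speed-only slopes).
#' @export
reproduce_benchmark <- function(dataset_root) {
  path <- file.path(dataset_root, "features.csv")
  if (!file.exists(path))
    stop("no features.csv under ", dataset_root,
         "; convert the open dataset to the documented layout first")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  res <- run_regression_report(tab)
  rep <- res$report
  sp <- rep[rep$model == "Speed", ]
  adj <- rep[rep$model == "Speed + AgeGroup", ]
  key <- c(beta_s_peak_ankle = sp$beta_s[sp$feature == "peak_ankle"],
           beta_s_wneg_foot = sp$beta_s[sp$feature == "wneg_foot"],
           beta_a_wneg_foot_adj = adj$beta_a[adj$feature == "wneg_foot"],
           mean_abs_beta_s = mean(abs(sp$beta_s)))
  c(res, list(key_values = key))
}
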