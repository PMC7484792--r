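# Statistical stage: standardized linear mixed-effects regressions of the
# nine stance features on walking speed and age group with a per-subject
# random intercept, the four-model ladder, likelihood-ratio comparisons,
# demographic t-tests with Cohen's d, and Jarque-Bera residual diagnostics.

#' Standardize a numeric column to mean 0, SD 1
#'
#' Uses the sample SD (n - 1 denominator). The transform parameters are
#' attached as attributes `mean` and `sd` for back-mapping.
#'
#' @param x numeric vector without NAs.
#' @return z-scores with attributes `mean` and `sd`.
#' @export
standardize <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s <= 0) stop("cannot standardize a constant column")
  structure((x - m) / s, mean = m, sd = s)
}

model_label <- function(predictors) {
  map <- c(speed = "Speed", age = "AgeGroup", `speed:age` = "Speed x AgeGroup")
  paste(map[predictors], collapse = " + ")
}

#' Fit one mixed-effects regression of a feature on speed/age terms
#'
#' Fits `feature ~ <terms> + (1 | subject)` twice, following the two-step
#' convention: a maximum-likelihood fit supplies the log-likelihood and AIC
#' used for model comparison, and a REML fit supplies unbiased coefficient
#' estimates, their standard errors, confidence intervals and p-values.
#' Speed enters standardized (z-scored within the analyzed rows); the
#' response is standardized too unless `standardize_response = FALSE` (used
#' when the response is already on the model scale, e.g. simulation output).
#' AgeGroup is coded young = 0, older = 1.
#'
#' Coefficient CIs use the asymptotic normal approximation on the REML
#' standard errors; p-values use a t reference with residual degrees of
#' freedom by default (`ddf = "normal"` switches to z-tests). A fit that
#' converges with zero random-intercept variance is flagged (`singular`),
#' not treated as an error.
#'
#' @param table feature table: one row per subject x condition with columns
#'   `subject_id`, `speed`, `age_group` (0/1) and the feature.
#' @param feature feature column name.
#' @param predictors subset of `c("speed", "age", "speed:age")`.
#' @param standardize_response standardize the feature before fitting.
#' @param ddf `"residual"` (t with n - p df) or `"normal"` (z-test).
#' @param conf_level CI level (default 0.95).
#' @param age_continuous use standardized continuous age instead of the
#'   binary group for the `age` term (robustness variant).
#' @return object of class `lmm_result`.
#' @export
fit_lmm <- function(table, feature, predictors = "speed",
                    standardize_response = TRUE, ddf = c("residual", "normal"),
                    conf_level = 0.95, age_continuous = FALSE) {
  ddf <- match.arg(ddf)
  stopifnot(feature %in% names(table))
  bad <- setdiff(predictors, c("speed", "age", "speed:age"))
  if (length(bad)) stop("unknown predictors: ", paste(bad, collapse = ", "))
  d <- table[stats::complete.cases(table[, c("subject_id", "speed", "age_group",
                                             feature)]), , drop = FALSE]
  dat <- data.frame(subject_id = factor(d$subject_id),
                    z_speed = as.numeric(standardize(d$speed)))
  dat$age_term <- if (age_continuous) as.numeric(standardize(d$age)) else d$age_group
  dat$y <- if (standardize_response) as.numeric(standardize(d[[feature]])) else d[[feature]]
  terms <- c(speed = "z_speed", age = "age_term", `speed:age` = "z_speed:age_term")
  rhs <- paste(c(terms[predictors], "(1 | subject_id)"), collapse = " + ")
  fml <- stats::as.formula(paste("y ~", rhs))
  quiet_fit <- function(...) withCallingHandlers(
    lme4::lmer(...),
    message = function(m) invokeRestart("muffleMessage"))
  ml <- quiet_fit(fml, data = dat, REML = FALSE)
  reml <- quiet_fit(fml, data = dat, REML = TRUE)
  beta <- lme4::fixef(reml)
  # on degenerate (zero-variance) data the covariance of the fixed effects
  # is not estimable; report NA uncertainty rather than failing
  se <- tryCatch(
    suppressWarnings(stats::coef(summary(reml))[, "Std. Error"]),
    error = function(e) stats::setNames(rep(NA_real_, length(beta)),
                                        names(beta)))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- cbind(lower = beta - zq * se, upper = beta + zq * se)
  stat <- beta / se
  n <- nrow(dat); p_fixed <- length(beta)
  p <- if (ddf == "normal") 2 * stats::pnorm(-abs(stat))
       else 2 * stats::pt(-abs(stat), df = n - p_fixed)
  vc <- as.data.frame(lme4::VarCorr(reml))
  res <- stats::residuals(reml)
  fixed_pred <- stats::predict(reml, re.form = NA)
  r2 <- if (stats::sd(fixed_pred) > 0) stats::cor(dat$y, fixed_pred)^2 else 0
  jb <- jarque_bera(res)
  structure(list(feature = feature, predictors = predictors,
                 model = model_label(predictors),
                 beta = beta, se = se, ci95 = ci, p_values = p,
                 llf = as.numeric(stats::logLik(ml)), aic = stats::AIC(ml),
                 r2_fixed = r2,
                 random_intercept_var = vc$vcov[vc$grp == "subject_id"],
                 residual_var = vc$vcov[vc$grp == "Residual"],
                 jb_stat = jb$statistic, jb_p = jb$p_value,
                 singular = lme4::isSingular(reml),
                 n_obs = n, n_subjects = nlevels(dat$subject_id),
                 ddf = ddf, fits = list(ml = ml, reml = reml)),
            class = "lmm_result")
}

#' @export
print.lmm_result <- function(x, ...) {
  cat(sprintf("<lmm_result> %s ~ %s + (1 | subject)   [n = %d obs, %d subjects]\n",
              x$feature, x$model, x$n_obs, x$n_subjects))
  tab <- data.frame(beta = round(x$beta, 3), se = round(x$se, 3),
                    ci_lo = round(x$ci95[, 1], 3), ci_hi = round(x$ci95[, 2], 3),
                    p = signif(x$p_values, 3))
  print(tab)
  cat(sprintf("  LLF %.1f | AIC %.1f | R2(fixed) %.2f | JB p %.3f%s\n",
              x$llf, x$aic, x$r2_fixed, x$jb_p,
              if (x$singular) " | singular random-effect fit" else ""))
  invisible(x)
}

#' Squared correlation between observed and fixed-effects predictions
#'
#' The goodness-of-fit metric reported alongside each model: the squared
#' Pearson correlation between the observed response and the prediction
#' using only the fixed factors (random intercepts excluded).
#'
#' @param result an [fit_lmm()] result.
#' @return R-squared in `[0, 1]`.
#' @export
r2_fixed <- function(result) {
  stopifnot(inherits(result, "lmm_result"))
  result$r2_fixed
}

#' Likelihood-ratio test between nested model fits
#'
#' Compares the ML log-likelihoods of two models fitted to the same rows:
#' `2 (llf_full - llf_nested) ~ chi^2` with df = the difference in the
#' number of fixed-effect parameters.
#'
#' @param nested,full [fit_lmm()] results with nested predictor sets.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(nested, full) {
  stopifnot(inherits(nested, "lmm_result"), inherits(full, "lmm_result"))
  if (!all(nested$predictors %in% full$predictors))
    stop("models are not nested")
  if (nested$n_obs != full$n_obs)
    stop("models were fitted to different numbers of rows")
  stat <- 2 * (full$llf - nested$llf)
  if (stat < -1e-8) stop("negative LR statistic: fits are inconsistent")
  stat <- max(stat, 0)
  df <- length(full$beta) - length(nested$beta)
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Independent two-sample comparison with Cohen's d
#'
#' Pooled-variance two-tailed t-test between two groups. The t statistic is
#' for `group2 - group1` (e.g. older minus young) and Cohen's d is the
#' absolute standardized mean difference with the pooled, df-weighted SD.
#'
#' @param group1,group2 numeric samples.
#' @return list with `t`, `df`, `p_value`, `d`.
#' @export
group_compare <- function(group1, group2) {
  group_compare_summary(mean(group1), stats::sd(group1), length(group1),
                        mean(group2), stats::sd(group2), length(group2))
}

#' Two-sample comparison from printed summary statistics
#'
#' Same computation as [group_compare()] but from means, SDs and sizes, so
#' published tables can be checked directly.
#'
#' @param mean1,sd1,n1 first group (e.g. young).
#' @param mean2,sd2,n2 second group (e.g. older).
#' @return list with `t`, `df`, `p_value`, `d`.
#' @export
group_compare_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  if (sp == 0) return(list(t = 0, df = df, p_value = 1, d = 0))
  t <- (mean2 - mean1) / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df),
       d = abs(mean1 - mean2) / sp)
}

#' Jarque-Bera normality test
#'
#' `JB = n/6 (skewness^2 + excess_kurtosis^2 / 4)` referred to a chi-squared
#' distribution with 2 df.
#'
#' @param x numeric sample (e.g. model residuals).
#' @return list with `statistic`, `p_value`, `skewness`, `kurtosis_excess`.
#' @export
jarque_bera <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 4) stop("jarque_bera needs at least 4 observations")
  xc <- x - mean(x)
  m2 <- mean(xc^2)
  if (m2 == 0) return(list(statistic = 0, p_value = 1, skewness = 0,
                           kurtosis_excess = 0))
  s <- mean(xc^3) / m2^1.5
  k <- mean(xc^4) / m2^2 - 3
  jb <- n / 6 * (s^2 + k^2 / 4)
  list(statistic = jb, p_value = stats::pchisq(jb, 2, lower.tail = FALSE),
       skewness = s, kurtosis_excess = k)
}

#' Fit the four-model ladder for one feature
#'
#' Models, in reporting order: Speed only; AgeGroup only; Speed + AgeGroup;
#' Speed + AgeGroup + Speed x AgeGroup.
#'
#' @inheritParams fit_lmm
#' @return object of class `lmm_ladder`: a named list of `lmm_result`.
#' @export
fit_lmm_ladder <- function(table, feature, standardize_response = TRUE,
                           ddf = "residual", age_continuous = FALSE) {
  specs <- list(S = "speed", A = "age", `S+A` = c("speed", "age"),
                `S+A+SxA` = c("speed", "age", "speed:age"))
  out <- lapply(specs, function(p)
    fit_lmm(table, feature, predictors = p,
            standardize_response = standardize_response, ddf = ddf,
            age_continuous = age_continuous))
  structure(out, class = "lmm_ladder", feature = feature)
}

coef_or_na <- function(res, term) {
  i <- match(term, names(res$beta))
  if (is.na(i)) rep(NA_real_, 4)
  else c(res$beta[i], res$ci95[i, 1], res$ci95[i, 2], res$p_values[i])
}

#' Flatten a ladder (or several) into a report table
#'
#' One row per feature x model with the standardized slopes, their 95% CIs
#' and p-values, LLF, AIC and fixed-effects R-squared -- the same columns as
#' the published regression summaries.
#'
#' @param ladders a single `lmm_ladder` or a named list of them.
#' @return data.frame.
#' @export
ladder_report <- function(ladders) {
  if (inherits(ladders, "lmm_ladder")) ladders <- list(ladders)
  rows <- list()
  for (lad in ladders) {
    for (res in lad) {
      s <- coef_or_na(res, "z_speed")
      a <- coef_or_na(res, "age_term")
      sa <- coef_or_na(res, "z_speed:age_term")
      rows[[length(rows) + 1L]] <- data.frame(
        feature = res$feature, model = res$model,
        beta_s = s[1], beta_s_lo = s[2], beta_s_hi = s[3], p_s = s[4],
        beta_a = a[1], beta_a_lo = a[2], beta_a_hi = a[3], p_a = a[4],
        beta_sa = sa[1], beta_sa_lo = sa[2], beta_sa_hi = sa[3], p_sa = sa[4],
        llf = res$llf, aic = res$aic, r2 = res$r2_fixed,
        singular = res$singular)
    }
  }
  do.call(rbind, rows)
}

#' Speed-confounding subset analysis
#'
#' Reproduces the confounding demonstration: subjects are ranked by
#' comfortable speed within age group, the slower half of the older group
#' and the faster half of the young group are retained (ceiling(N/2) each),
#' and for every feature the models `feature ~ AgeGroup` and
#' `feature ~ AgeGroup + Speed` are fitted on the subset. Features and
#' Speed are standardized within the analyzed subset.
#'
#' @param table feature table with a `condition` column containing
#'   `"comfortable"` rows.
#' @param features feature columns to analyze (default: the nine standard
#'   features present in the table).
#' @param ddf passed to [fit_lmm()].
#' @return data.frame, one row per feature: AgeGroup slope and p under the
#'   age-only and age+speed models, the Speed slope in the adjusted model,
#'   and the shift `delta_beta_a`. The selected subject ids are attached as
#'   attribute `subset_ids`.
#' @export
subset_confound_analysis <- function(table, features = NULL, ddf = "residual") {
  if (is.null(features)) features <- intersect(FEATURE_NAMES, names(table))
  if (length(features) == 0L) features <- setdiff(
    names(table), c("subject_id", "condition", "speed", "age_group", "age"))
  comf <- table[table$condition == "comfortable", ]
  pick_half <- function(grp, slower) {
    g <- comf[comf$age_group == grp, ]
    g <- g[order(g$speed, decreasing = !slower), ]
    k <- ceiling(nrow(g) / 2)
    if (k < 2) stop("age group too small to halve (", nrow(g), " subjects)")
    g$subject_id[seq_len(k)]
  }
  ids <- c(pick_half(1, slower = TRUE), pick_half(0, slower = FALSE))
  sub <- table[table$subject_id %in% ids, ]
  rows <- lapply(features, function(f) {
    alone <- fit_lmm(sub, f, predictors = "age", ddf = ddf)
    adj <- fit_lmm(sub, f, predictors = c("speed", "age"), ddf = ddf)
    data.frame(feature = f,
               beta_a_alone = alone$beta[["age_term"]],
               p_a_alone = alone$p_values[["age_term"]],
               beta_a_adjusted = adj$beta[["age_term"]],
               p_a_adjusted = adj$p_values[["age_term"]],
               beta_s_adjusted = adj$beta[["z_speed"]],
               p_s_adjusted = adj$p_values[["z_speed"]])
  })
  out <- do.call(rbind, rows)
  out$delta_beta_a <- out$beta_a_adjusted - out$beta_a_alone
  attr(out, "subset_ids") <- ids
  out
}
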