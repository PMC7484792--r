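test_that("standardization is exact, affine-invariant and pins the SD convention", {
  set.seed(1)
  x <- rnorm(50, 10, 3)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(as.numeric(standardize(2.5 * x + 7)), as.numeric(z),
               tolerance = 1e-12)
  # sample SD (n-1): (1,2,3) -> (-1, 0, 1)
  expect_equal(as.numeric(standardize(c(1, 2, 3))), c(-1, 0, 1))
  expect_equal(attr(standardize(c(1, 2, 3)), "sd"), 1)
  expect_error(standardize(rep(4, 10)), "constant")
})

test_that("noiseless tables are fitted exactly and ML/REML agree when balanced", {
  ft <- generate_feature_table(synthetic_feature_spec(
    seed = 2, beta_s = 1, beta_a = 0, sigma_subject = 0, sigma_eps = 0))
  r <- fit_lmm(ft$table, "peak_ankle", predictors = "speed",
               standardize_response = FALSE)
  expect_equal(unname(r$beta["z_speed"]), 1, tolerance = 1e-6)

  ft2 <- generate_feature_table(synthetic_feature_spec(seed = 3, beta_s = 0.8,
                                                       beta_a = 0.4))
  # with a design whose fixed effects are constant within subject, GLS
  # reduces to OLS and the ML and REML coefficients coincide exactly
  ra <- fit_lmm(ft2$table, "peak_sum", predictors = "age")
  expect_equal(unname(lme4::fixef(ra$fits$ml)),
               unname(lme4::fixef(ra$fits$reml)), tolerance = 1e-6)
  # result invariants: AIC = 2k - 2 LLF with k = fixed effects + 2 variances
  r2 <- fit_lmm(ft2$table, "peak_sum", predictors = c("speed", "age"))
  k <- length(r2$beta) + 2
  expect_equal(r2$aic, 2 * k - 2 * r2$llf, tolerance = 1e-8)
  expect_true(all(r2$ci95[, 1] <= r2$beta & r2$beta <= r2$ci95[, 2]))
})

test_that("a pure-noise feature rarely excludes zero from the speed CI", {
  hits <- 0
  for (s in 1:100) {
    ft <- generate_feature_table(synthetic_feature_spec(
      seed = 1000 + s, beta_s = 0, beta_a = 0, features = "peak_ankle"))
    r <- fit_lmm(ft$table, "peak_ankle", predictors = "speed",
                 standardize_response = FALSE)
    if (r$ci95["z_speed", 1] <= 0 && 0 <= r$ci95["z_speed", 2]) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("likelihood ratio tests behave on nested, identical and invalid pairs", {
  ft <- generate_feature_table(synthetic_feature_spec(seed = 4, beta_a = 0))
  a <- fit_lmm(ft$table, "peak_ankle", predictors = "speed")
  b <- fit_lmm(ft$table, "peak_ankle", predictors = c("speed", "age"))
  lrt <- likelihood_ratio_test(a, b)
  expect_gte(lrt$statistic, 0)
  expect_equal(lrt$df, 1)
  same <- likelihood_ratio_test(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(likelihood_ratio_test(b, fit_lmm(ft$table, "peak_ankle",
                                                predictors = "age")),
               "not nested")
})

test_that("adding a null age term is usually unsupported by the LRT", {
  rejections <- 0
  for (s in 1:50) {
    ft <- generate_feature_table(synthetic_feature_spec(
      seed = 2000 + s, beta_s = 0.8, beta_a = 0, features = "peak_ankle"))
    a <- fit_lmm(ft$table, "peak_ankle", predictors = "speed")
    b <- fit_lmm(ft$table, "peak_ankle", predictors = c("speed", "age"))
    if (likelihood_ratio_test(a, b)$p_value < 0.05) rejections <- rejections + 1
  }
  expect_lte(rejections / 50, 0.2)
})

test_that("fixed-effects R2 tracks the constructed variance partition", {
  # perfect linear data -> R2 = 1
  ft <- generate_feature_table(synthetic_feature_spec(
    seed = 5, beta_s = 1, sigma_subject = 0, sigma_eps = 0))
  expect_equal(r2_fixed(fit_lmm(ft$table, "peak_ankle", "speed",
                                standardize_response = FALSE)), 1,
               tolerance = 1e-9)
  # pure noise -> near zero
  ftn <- generate_feature_table(synthetic_feature_spec(
    seed = 6, beta_s = 0, sigma_subject = 0, sigma_eps = 1))
  expect_lt(r2_fixed(fit_lmm(ftn$table, "peak_ankle", "speed",
                             standardize_response = FALSE)), 0.1)
  # fixed 0.6 / random 0.2 / noise 0.2 of total variance -> R2 ~ 0.6
  r2s <- vapply(1:100, function(s) {
    ft <- generate_feature_table(synthetic_feature_spec(
      seed = 3000 + s, beta_s = sqrt(0.6), beta_a = 0,
      sigma_subject = sqrt(0.2), sigma_eps = sqrt(0.2),
      features = "peak_ankle"))
    r2_fixed(fit_lmm(ft$table, "peak_ankle", "speed",
                     standardize_response = FALSE))
  }, numeric(1))
  expect_lt(abs(mean(r2s) - 0.6), 0.05)
})

test_that("group comparisons reproduce pooled-SD effect sizes", {
  h <- group_compare_summary(1.71, 0.11, 24, 1.61, 0.10, 16)
  expect_lt(abs(h$d - 0.94), 0.005)
  expect_lt(h$t, 0)  # older group shorter
  m <- group_compare_summary(68.4, 12.2, 24, 65.8, 10.1, 16)
  expect_lt(abs(m$d - 0.23), 0.005)
  set.seed(7)
  x <- rnorm(20)
  same <- group_compare(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$d, 0)
  expect_equal(same$p_value, 1)
  # raw-sample and summary routes agree
  y <- rnorm(15, 0.5)
  expect_equal(group_compare(x, y)$t,
               group_compare_summary(mean(x), sd(x), 20, mean(y), sd(y), 15)$t)
})

test_that("Jarque-Bera is calibrated on normal data and detects skew", {
  ok <- 0
  for (s in 1:30) {
    set.seed(4000 + s)
    if (jarque_bera(rnorm(10000))$p_value > 0.01) ok <- ok + 1
  }
  expect_gte(ok, 29)
  set.seed(8)
  expect_lt(jarque_bera(rexp(1000))$p_value, 0.001)
  # symmetric, zero-excess sample has JB = 0 by the formula
  z <- c(-1.5, -0.5, 0.5, 1.5)  # skew 0
  jb <- jarque_bera(z)
  expect_equal(jb$skewness, 0)
  expect_equal(jb$statistic, 4 / 6 * (jb$kurtosis_excess^2 / 4))
})

test_that("AIC ordering is invariant to the feature's scale", {
  ft <- generate_feature_table(synthetic_feature_spec(seed = 9, beta_a = 0.3,
                                                      features = "peak_ankle"))
  t2 <- ft$table
  t2$peak_ankle <- 7.3 * t2$peak_ankle + 2
  for (pred in list("speed", c("speed", "age"))) {
    a1 <- fit_lmm(ft$table, "peak_ankle", pred)$aic
    a2 <- fit_lmm(t2, "peak_ankle", pred)$aic
    expect_equal(a1, a2, tolerance = 1e-6)
  }
})

test_that("subset confound analysis selects ceiling halves and shifts effects", {
  ft <- generate_feature_table(synthetic_feature_spec(
    seed = 10, n_young = 24, n_older = 16, beta_s = 0.8, beta_a = 0))
  sc <- subset_confound_analysis(ft$table, features = "peak_ankle")
  ids <- attr(sc, "subset_ids")
  expect_equal(length(ids), ceiling(24 / 2) + ceiling(16 / 2))
  sub <- ft$table[ft$table$subject_id %in% ids &
                    ft$table$condition == "comfortable", ]
  expect_gt(mean(sub$speed[sub$age_group == 0]),
            mean(sub$speed[sub$age_group == 1]))

  # when the subset halves end up with matching speeds (negligible
  # between-subject speed spread), there is no effect-size shift
  deltas <- vapply(1:10, function(s) {
    ft2 <- generate_feature_table(synthetic_feature_spec(
      seed = 5000 + s, beta_s = 0.8, beta_a = 0,
      speed_young = c(1.22, 1e-3), speed_older = c(1.22, 1e-3),
      features = "peak_ankle"))
    subset_confound_analysis(ft2$table, features = "peak_ankle")$delta_beta_a
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 0.1)

  tiny <- ft$table[ft$table$subject_id %in% c("S01", "S25"), ]
  expect_error(subset_confound_analysis(tiny, features = "peak_ankle"),
               "too small")
})

test_that("the continuous-age robustness variant fits the same ladder", {
  ft <- generate_feature_table(synthetic_feature_spec(seed = 11, beta_a = 0,
                                                      features = "peak_ankle"))
  r <- fit_lmm(ft$table, "peak_ankle", predictors = c("speed", "age"),
               age_continuous = TRUE)
  expect_true("age_term" %in% names(r$beta))
  # null age: CI straddles zero with a binary or a continuous coding
  expect_true(r$ci95["age_term", 1] < 0 && r$ci95["age_term", 2] > 0)
})
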