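test_that("rank tests return p = 1 for identical group distributions", {
  v <- rep(c(1, 2, 3, 4, 5), 2)
  g <- rep(1:2, each = 5)
  cmp <- compare_groups(v, g, "continuous", normality_rule = "nonnormal")
  expect_equal(cmp$omnibus$p_raw, 1)
  expect_equal(cmp$omnibus$test_used, "mann-whitney")
})

test_that("test selection follows the normality screen and group count", {
  set.seed(5)
  g4 <- rep(1:4, each = 15)
  v_norm <- rnorm(60) + g4 / 2
  cmp <- compare_groups(v_norm, g4, "continuous", normality_rule = "normal")
  expect_equal(cmp$omnibus$test_used, "anova")
  cmp2 <- compare_groups(v_norm, g4, "continuous", normality_rule = "nonnormal")
  expect_equal(cmp2$omnibus$test_used, "kruskal-wallis")
  v_skew <- exp(rnorm(60) * 1.5)
  cmp3 <- compare_groups(v_skew, g4, "continuous")
  expect_equal(cmp3$omnibus$test_used, "kruskal-wallis")
  cmp4 <- compare_groups(rep(7, 60), g4, "continuous")
  expect_match(cmp4$omnibus$test_used, "constant")
  expect_error(compare_groups(rnorm(3), c(1, 2, 2), "continuous"),
               ">= 2 groups")
})

test_that("Fisher's exact test matches hypergeometric enumeration", {
  x <- rep(c(1, 0), c(10, 10))
  g <- rep(1:2, each = 10)
  cmp <- compare_groups(x, g, "categorical")
  expect_equal(cmp$omnibus$test_used, "fisher")
  tab <- table(factor(g), factor(x))
  expect_equal(cmp$omnibus$p_raw, fisher_oracle_2x2(tab), tolerance = 1e-9)
  expect_equal(cmp$omnibus$p_raw, 2 / choose(20, 10), tolerance = 1e-9)
  # a larger balanced table with big expected counts uses chi-square
  set.seed(2)
  x2 <- rbinom(200, 1, 0.5)
  g2 <- rep(1:2, each = 100)
  cmp2 <- compare_groups(x2, g2, "categorical")
  expect_equal(cmp2$omnibus$test_used, "chi-square")
})

test_that("pairwise Bonferroni uses the number of comparisons", {
  set.seed(9)
  g <- rep(1:4, each = 12)
  v <- rnorm(48) + (g == 4)
  cmp <- compare_groups(v, g, "continuous")
  expect_equal(nrow(cmp$pairwise), 6)
  expect_true(all(cmp$pairwise$multiplier == 6))
  expect_equal(cmp$pairwise$p_adjusted,
               pmin(1, cmp$pairwise$p_raw * 6))
  # the worked rule: raw 0.01 with 6 tests adjusts to 0.06
  expect_equal(min(1, 0.01 * 6), 0.06)
})

test_that("risk score reduces to the closed form and is monotone", {
  co <- load_risk_coefficients()
  cv <- data.frame(age_years = 50, max_wall_thickness_mm = 20,
                   la_diameter_mm = 40, max_lvot_gradient_mmHg = 10,
                   fh_scd = 0, nsvt = 0, syncope = 0)
  zero <- co
  zero$coefficients <- lapply(zero$coefficients, function(x) 0)
  expect_equal(hcm_risk_scd(cv, zero),
               (1 - co$baseline_survival_5yr) * 100, tolerance = 1e-12)
  # flipping a positive-weight binary factor strictly increases risk
  base <- hcm_risk_scd(cv, co)
  cv_nsvt <- cv; cv_nsvt$nsvt <- 1
  expect_gt(hcm_risk_scd(cv_nsvt, co), base)
  dbl <- co
  dbl$coefficients$nsvt <- 2 * dbl$coefficients$nsvt
  expect_gt(hcm_risk_scd(cv_nsvt, dbl), hcm_risk_scd(cv_nsvt, co))
  expect_error(hcm_risk_scd(cv[, -1], co), "missing covariate")
  cv_na <- cv; cv_na$la_diameter_mm <- NA
  expect_error(hcm_risk_scd(cv_na, co), "does not impute")
})

test_that("incomplete coefficient configs are rejected", {
  co <- load_risk_coefficients()
  bad <- co
  bad$coefficients$nsvt <- NULL
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(bad, tmp, auto_unbox = TRUE)
  expect_error(load_risk_coefficients(tmp), "incomplete")
})

test_that("risk categories split at 4 and 6 percent", {
  expect_equal(as.character(risk_category(c(2.5, 4, 5.9, 6, 10))),
               c("low", "intermediate", "intermediate", "high", "high"))
  expect_error(risk_category(-1), ">= 0")
})

test_that("group summaries join by id and flag configured contrasts", {
  set.seed(14)
  n_g <- c(20, 24, 19, 22)
  cl <- data.frame(subject_id = sprintf("S%03d", 1:85),
                   cluster = rep(1:4, n_g))
  # TWI prevalences configured per group as 100% / 0% / 21% / 5%
  twi <- unlist(mapply(function(n, p) rbinom(n, 1, p), n_g,
                       c(1, 0, 0.21, 0.05)))
  cov <- data.frame(subject_id = cl$subject_id, twi = twi,
                    age_years = rnorm(85, 46, 13))
  s <- summarize_groups(features = NULL, clusters = cl, covariates = cov)
  twi_row <- s$tests[s$tests$variable == "twi", ]
  expect_true(twi_row$test_used %in% c("fisher", "chi-square"))
  expect_lt(twi_row$min_pairwise_p_adjusted, 0.05)
  # permuted labels: omnibus p-values are uniform under the null
  set.seed(15)
  pnull <- replicate(200, {
    gp <- sample(cl$cluster)
    stats::kruskal.test(cov$age_years, factor(gp))$p.value
  })
  expect_gt(stats::ks.test(pnull, "punif")$p.value, 0.01)
  # single group: descriptives only
  one <- summarize_groups(NULL, data.frame(subject_id = cl$subject_id[1:20],
                                           cluster = 1),
                          cov[1:20, ])
  expect_null(one$tests)
  expect_error(summarize_groups(NULL, cl, cov[1:50, ]), "do not match")
})

test_that("cohort covariates give the configured risk ordering", {
  set.seed(31)
  cfg <- default_covariate_config()
  co <- load_risk_coefficients()
  groups <- names(cfg)
  meds <- vapply(groups, function(g) {
    cv <- do.call(rbind, lapply(1:120, function(i)
      hcmecg:::sample_covariates(cfg[[g]], g, sprintf("%s%03d", g, i))))
    stats::median(hcm_risk_scd(cv, co))
  }, numeric(1))
  expect_equal(names(which.max(meds)), "normal_inverted_T")
  expect_gt(meds["normal_inverted_T"], meds["normal_upright_T"])
})
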