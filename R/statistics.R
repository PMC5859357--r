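# Group-level statistics for phenotype subgroups and the 2014 ESC HCM
# Risk-SCD calculator. Two-sided tests throughout; Bonferroni adjustment by
# explicit multiplier (number of pairwise comparisons).

#' Compare a feature across phenotype groups
#'
#' Continuous data: a Shapiro-Wilk normality screen at alpha = 0.05 in every
#' group decides between t-test / one-way ANOVA (all groups normal) and
#' Mann-Whitney U / Kruskal-Wallis. Categorical data: Chi-square, or Fisher's
#' exact test when any expected cell count is 5 or below. Pairwise post-hoc
#' tests carry a Bonferroni multiplier equal to the number of pairwise
#' comparisons (p_adjusted = min(1, p_raw * multiplier)).
#'
#' @param values numeric vector (continuous) or vector coercible to factor
#'   (categorical).
#' @param groups group labels, same length as `values`.
#' @param type `"continuous"` or `"categorical"`.
#' @param normality_rule `"auto"` (Shapiro screen), `"normal"` or
#'   `"nonnormal"` to force the test family.
#' @return list of class `group_comparison`: `omnibus` (one-row data.frame
#'   with feature test, statistic, p_raw, p_adjusted, multiplier) and
#'   `pairwise` (data.frame, one row per group pair).
#' @export
compare_groups <- function(values, groups,
                           type = c("continuous", "categorical"),
                           normality_rule = c("auto", "normal", "nonnormal")) {
  type <- match.arg(type)
  normality_rule <- match.arg(normality_rule)
  groups <- factor(groups)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- droplevels(groups[keep])
  lv <- levels(groups)
  if (length(lv) < 2 || any(table(groups) < 2))
    stop("compare_groups needs >= 2 groups with >= 2 members each")

  run_cont <- function(v, g) {
    g <- droplevels(factor(g))
    if (stats::sd(v) < 1e-12)
      return(list(test = "none (constant values)", stat = NA_real_,
                  p = NA_real_))
    normal <- switch(normality_rule,
      normal = TRUE, nonnormal = FALSE,
      auto = all(vapply(split(v, g), function(x) {
        if (length(x) < 3 || stats::sd(x) < 1e-12) return(FALSE)
        stats::shapiro.test(x)$p.value >= 0.05
      }, logical(1))))
    if (nlevels(g) == 2) {
      if (normal) {
        t <- stats::t.test(v ~ g)
        list(test = "t-test", stat = unname(t$statistic), p = t$p.value)
      } else {
        w <- suppressWarnings(stats::wilcox.test(v ~ g, exact = FALSE,
                                                 correct = TRUE))
        list(test = "mann-whitney", stat = unname(w$statistic), p = w$p.value)
      }
    } else {
      if (normal) {
        a <- stats::aov(v ~ g)
        s <- summary(a)[[1]]
        list(test = "anova", stat = s$`F value`[1], p = s$`Pr(>F)`[1])
      } else {
        k <- stats::kruskal.test(v, g)
        list(test = "kruskal-wallis", stat = unname(k$statistic),
             p = k$p.value)
      }
    }
  }
  run_cat <- function(v, g) {
    tab <- table(droplevels(factor(g)), factor(v))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (ncol(tab) < 2)
      return(list(test = "none (constant values)", stat = NA_real_,
                  p = NA_real_))
    exp_cnt <- suppressWarnings(stats::chisq.test(tab)$expected)
    if (any(exp_cnt <= 5)) {
      f <- stats::fisher.test(tab, workspace = 2e7)
      list(test = "fisher", stat = NA_real_, p = f$p.value)
    } else {
      c2 <- stats::chisq.test(tab, correct = FALSE)
      list(test = "chi-square", stat = unname(c2$statistic), p = c2$p.value)
    }
  }
  run1 <- if (type == "continuous") run_cont else run_cat

  omni <- run1(values, groups)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  mult <- length(pairs)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    sel <- groups %in% pr
    r <- run1(values[sel], groups[sel])
    data.frame(group1 = pr[1], group2 = pr[2], test_used = r$test,
               statistic = r$stat, p_raw = r$p,
               p_adjusted = if (is.na(r$p)) NA_real_ else min(1, r$p * mult),
               multiplier = mult, stringsAsFactors = FALSE)
  }))
  structure(list(
    omnibus = data.frame(test_used = omni$test, statistic = omni$stat,
                         p_raw = omni$p,
                         p_adjusted = omni$p,   # single omnibus test
                         multiplier = 1, stringsAsFactors = FALSE),
    pairwise = pw
  ), class = "group_comparison")
}

#' Load HCM Risk-SCD model coefficients from a JSON config
#'
#' The 5-year sudden-cardiac-death risk model of the 2014 ESC guidelines is a
#' Cox-type prognostic index over seven clinical variables; its published
#' coefficients and baseline survival are externalised to a citation-stamped
#' JSON file rather than hard-coded. The packaged default
#' (`inst/extdata/hcm_risk_scd_coefficients.json`) carries the coefficients
#' of O'Mahony et al. (2014), Eur Heart J 35:2010-2020.
#'
#' @param path path to the JSON file; default the packaged config.
#' @return list with `baseline_survival_5yr` and named `coefficients`.
#' @export
load_risk_coefficients <- function(path = system.file(
  "extdata", "hcm_risk_scd_coefficients.json", package = "hcmecg")) {
  cfg <- jsonlite::fromJSON(path)
  needed <- c("max_wall_thickness_mm", "max_wall_thickness_mm_squared",
              "la_diameter_mm", "max_lvot_gradient_mmHg", "fh_scd", "nsvt",
              "syncope", "age_years")
  missing <- setdiff(needed, names(cfg$coefficients))
  if (length(missing))
    stop("risk coefficient config incomplete; missing: ",
         paste(missing, collapse = ", "))
  if (is.null(cfg$baseline_survival_5yr) ||
      cfg$baseline_survival_5yr <= 0 || cfg$baseline_survival_5yr > 1)
    stop("risk coefficient config needs baseline_survival_5yr in (0, 1]")
  cfg
}

#' HCM Risk-SCD score (5-year risk of sudden cardiac death, percent)
#'
#' Prognostic index PI = b1*MWT + b2*MWT^2 + b3*LA + b4*LVOT + b5*FHSCD +
#' b6*NSVT + b7*syncope + b8*age; risk = (1 - S0^exp(PI)) * 100 with S0 the
#' 5-year baseline survival. All seven clinical variables must be present;
#' missing values raise an error rather than being imputed.
#'
#' @param covariates data.frame with columns age_years,
#'   max_wall_thickness_mm, la_diameter_mm, max_lvot_gradient_mmHg, fh_scd,
#'   nsvt, syncope (binary risk factors as 0/1).
#' @param coefficients configuration from [load_risk_coefficients()].
#' @return numeric vector of risk percentages at 5 years.
#' @export
hcm_risk_scd <- function(covariates, coefficients = load_risk_coefficients()) {
  needed <- c("age_years", "max_wall_thickness_mm", "la_diameter_mm",
              "max_lvot_gradient_mmHg", "fh_scd", "nsvt", "syncope")
  missing <- setdiff(needed, colnames(covariates))
  if (length(missing))
    stop("missing covariate column(s): ", paste(missing, collapse = ", "))
  if (any(is.na(covariates[, needed])))
    stop("missing covariate values; the risk score does not impute")
  b <- coefficients$coefficients
  mwt <- covariates$max_wall_thickness_mm
  pi_ <- b$max_wall_thickness_mm * mwt +
    b$max_wall_thickness_mm_squared * mwt^2 +
    b$la_diameter_mm * covariates$la_diameter_mm +
    b$max_lvot_gradient_mmHg * covariates$max_lvot_gradient_mmHg +
    b$fh_scd * covariates$fh_scd +
    b$nsvt * covariates$nsvt +
    b$syncope * covariates$syncope +
    b$age_years * covariates$age_years
  (1 - coefficients$baseline_survival_5yr^exp(pi_)) * 100
}

#' Risk category from the HCM Risk-SCD percentage
#'
#' `< 4`% is low risk, `[4, 6)`% intermediate (ICD may be considered), and
#' `>= 6`% high risk (ICD recommended).
#'
#' @param risk_percent numeric vector of 5-year risk percentages (>= 0).
#' @return factor with levels low, intermediate, high.
#' @export
risk_category <- function(risk_percent) {
  if (any(risk_percent < 0)) stop("risk_percent must be >= 0")
  cut(risk_percent, breaks = c(-Inf, 4, 6, Inf),
      labels = c("low", "intermediate", "high"), right = FALSE)
}

#' Per-cluster summary table with group comparisons
#'
#' Joins the feature table, cluster assignment and clinical covariates by
#' subject id and produces, per variable: group descriptives (mean +/- sd for
#' normal, median (range) for non-normal continuous variables; n (%) for
#' categoricals) and the omnibus / post-hoc comparison p-values from
#' [compare_groups()]. Noise subjects (cluster 0) are excluded from testing.
#'
#' @param features data.frame with `subject_id` (other columns optional).
#' @param clusters data.frame with `subject_id` and `cluster`.
#' @param covariates data.frame with `subject_id` and clinical columns.
#' @param variables character vector of variable names to summarise; default
#'   all covariate columns (plus any feature columns named).
#' @param categorical character vector naming which variables are
#'   categorical; default: non-numeric columns and 0/1 columns.
#' @return list of class `group_summary`: `table` (data.frame, one row per
#'   variable x group), `tests` (one row per variable), `n_groups`.
#' @export
summarize_groups <- function(features, clusters, covariates,
                             variables = NULL, categorical = NULL) {
  j1 <- merge(clusters, covariates, by = "subject_id", all = FALSE)
  bad <- union(setdiff(clusters$subject_id, covariates$subject_id),
               setdiff(covariates$subject_id, clusters$subject_id))
  if (length(bad))
    stop("subject ids do not match across inputs: ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (!is.null(features) && ncol(features) > 1) {
    extra_bad <- setdiff(features$subject_id, clusters$subject_id)
    if (length(extra_bad))
      stop("subject ids do not match across inputs: ",
           paste(utils::head(extra_bad, 10), collapse = ", "))
    j1 <- merge(j1, features, by = "subject_id", all = FALSE)
  }
  dat <- j1[j1$cluster != 0, , drop = FALSE]
  if (is.null(variables))
    variables <- setdiff(colnames(dat), c("subject_id", "cluster"))
  if (is.null(categorical))
    categorical <- variables[vapply(variables, function(v) {
      x <- dat[[v]]
      !is.numeric(x) || all(x %in% c(0, 1, NA))
    }, logical(1))]
  groups <- factor(dat$cluster)
  multi <- nlevels(groups) >= 2 && all(table(groups) >= 2)

  rows <- list(); tests <- list()
  for (v in variables) {
    x <- dat[[v]]
    is_cat <- v %in% categorical
    for (g in levels(groups)) {
      xg <- x[groups == g]
      desc <- if (is_cat) {
        tt <- table(factor(xg))
        paste(sprintf("%s: %d (%.0f%%)", names(tt), as.integer(tt),
                      100 * as.integer(tt) / length(xg)), collapse = "; ")
      } else {
        normal <- length(xg) >= 3 && stats::sd(xg) > 1e-12 &&
          stats::shapiro.test(xg)$p.value >= 0.05
        if (normal) sprintf("%.1f ± %.1f", mean(xg), stats::sd(xg))
        else sprintf("%.1f (%.1f-%.1f)", stats::median(xg), min(xg), max(xg))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, cluster = g, n = length(xg), summary = desc,
        stringsAsFactors = FALSE)
    }
    if (multi) {
      cmp <- tryCatch(
        compare_groups(if (is_cat) as.character(x) else x, groups,
                       type = if (is_cat) "categorical" else "continuous"),
        error = function(e) NULL)
      tests[[length(tests) + 1L]] <- data.frame(
        variable = v,
        test_used = if (is.null(cmp)) "none" else cmp$omnibus$test_used,
        p_raw = if (is.null(cmp)) NA_real_ else cmp$omnibus$p_raw,
        min_pairwise_p_adjusted = if (is.null(cmp)) NA_real_ else
          suppressWarnings(min(cmp$pairwise$p_adjusted, na.rm = TRUE)),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows),
                 tests = if (length(tests)) do.call(rbind, tests) else NULL,
                 n_groups = nlevels(groups)),
            class = "group_summary")
}
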