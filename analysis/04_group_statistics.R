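#!/usr/bin/env Rscript
# Step 4: clinical characterisation of the phenotype clusters.
#
# Computes the HCM Risk-SCD score (2014 ESC model, published coefficients
# from the packaged config) and its low/intermediate/high category per
# subject, then compares covariates, risk scores and headline ECG features
# across the four combined-clustering phenotypes (normality-screened tests,
# Fisher/chi-square for categoricals, Bonferroni-adjusted post-hoc pairs).
# Writes results/risk_scores.csv and results/group_summary*.csv.

suppressMessages(library(hcmecg))

covs <- utils::read.csv("results/cohort/covariates.csv")
clusters <- utils::read.csv("results/clusters_qrs_plus_t.csv")
feats <- utils::read.csv("results/features.csv", check.names = FALSE)

coef_cfg <- load_risk_coefficients()
covs$risk_scd_pct <- hcm_risk_scd(covs, coef_cfg)
covs$risk_category <- as.character(risk_category(covs$risk_scd_pct))
utils::write.csv(covs[, c("subject_id", "risk_scd_pct", "risk_category")],
                 "results/risk_scores.csv", row.names = FALSE)

cat("Median HCM Risk-SCD score by cluster:\n")
m <- merge(clusters, covs, by = "subject_id")
m <- m[m$cluster != 0, ]
print(round(tapply(m$risk_scd_pct, m$cluster, stats::median), 2))

ecg_cols <- c("subject_id", "qrs_axis_deg", "qrs_duration_ms",
              "qrs_amplitude_uV", "t_axis_deg", "twi", "giant_twi",
              "tpeak_tend_ms", "qtc_ms", "jtc_ms")
s <- summarize_groups(features = feats[, intersect(ecg_cols, colnames(feats))],
                      clusters = clusters,
                      covariates = covs[, setdiff(colnames(covs),
                                                  "hypertrophy_morphology")])
utils::write.csv(s$table, "results/group_summary.csv", row.names = FALSE)
utils::write.csv(s$tests, "results/group_summary_tests.csv",
                 row.names = FALSE)

sig <- s$tests[!is.na(s$tests$p_raw) & s$tests$p_raw < 0.05, "variable"]
cat("Variables with omnibus p < 0.05 across clusters:\n  ",
    paste(sig, collapse = ", "), "\n")
cat("Summaries written to results/group_summary.csv / _tests.csv\n")
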