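#!/usr/bin/env Rscript
# Stage 5 — drug-related-mortality risk model: LASSO-Cox selection,
# multivariable Cox, linear risk score, median-split stratification and
# time-dependent ROC at 30/60/90 days.

suppressMessages(library(faerspv))

qdir <- "results/quarters"
files <- list.files(qdir, pattern = "\\.txt$", full.names = TRUE)
names(files) <- tolower(sub("\\..*$", "", basename(files)))
universe <- deduplicate_cases(read_faers_quarter(files))
cohort <- filter_indication(
  match_drug(universe, list(c("durvalumab", "imfinzi"),
                            c("tremelimumab", "imjudo"))),
  "hepatocellular carcinoma")
truth <- truth_load(file.path(qdir, "truth.json"))
signals <- detect_signals(cohort, universe)
positive <- signals$pt[signals$consensus]

m <- fit_mortality_model(cohort, positive, seed = 20240101)
cat(sprintf("design: %d complete cases, %d fatal events, %d candidate PTs\n",
            nrow(m$design), sum(m$design$event),
            length(attr(m$design, "candidate_pts"))))
cat("lambda.min:", m$lasso$lambda_min, "| selected:",
    paste(m$lasso$selected_vars, collapse = ", "), "\n")
if (!is.null(m$cox)) {
  print(m$cox$table)
  planted <- names(unlist(truth$cox_coefficients))
  cat("planted mortality factors among selected:",
      sum(planted %in% m$lasso$selected_vars), "of", length(planted), "\n")
  cat(sprintf("median risk-score cutoff %.3f; high vs low log-rank p = %.3g\n",
              m$strata$median_cutoff, m$strata$logrank_p))
  print(m$roc)
  data.table::fwrite(m$cox$table, "results/riskmodel_cox.csv")
  data.table::fwrite(m$roc, "results/riskmodel_auc.csv")
  data.table::fwrite(
    data.table::data.table(caseid = m$design$caseid, score = m$scores,
                           group = m$strata$group),
    "results/riskmodel_scores.csv")
}

# Under the observed documentation rates (~40% missing sex, ~36% missing age,
# ~26% unusable onset dates) only the strongest factors survive selection.
# Repeat the selection under complete documentation to show that the planted
# six-factor model is recoverable when the design is not starved of cases.
cat("\n--- selection under complete documentation (no missingness) ---\n")
cfg_full <- synth_config(
  n_background_reports = 0, n_cohort_reports = 700,
  demographics = list(
    sex = c(F = 0.18, M = 0.82),
    age_group = c("<18" = 0.03, "18-64" = 0.21, "65-79" = 0.53, ">=80" = 0.23),
    occupation = c(MD = 0.917, PH = 0.024, OT = 0.032, CN = 0.010,
                   missing = 0.017),
    country = c(JP = 0.713, US = 0.091, FR = 0.053, CN = 0.017, CA = 0.015,
                other = 0.111),
    year = c("2020" = 0.073, "2021" = 0.003, "2022" = 0.004, "2023" = 0.235,
             "2024" = 0.685)),
  mortality = list(baseline_hazard = 0.0065,
                   coefficients = published_risk_coefficients(),
                   censor_day = 365),
  missingness = c(event_dt = 0, start_dt = 0, event_month_prec = 0),
  duplicate_rate = 0)
sim_full <- synth_generate(cfg_full, seed = 20240101)
co_full <- deduplicate_cases(sim_full$raw)
d_full <- build_design_matrix(co_full, names(cfg_full$planted_signals))
sel_full <- lasso_cox_select(d_full, seed = 20240101)
cat(sprintf("complete design: %d cases, %d events\n",
            nrow(d_full), sum(d_full$event)))
planted <- names(published_risk_coefficients())
cat("planted factors selected:", sum(planted %in% sel_full$selected_vars),
    "of", length(planted), "\n")
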