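# LASSO-Cox selection, Cox estimation, risk scoring, stratification and
# time-dependent ROC.

# direct PH simulator: binary covariates, exponential baseline, uniform
# administrative censoring
sim_surv <- function(n, beta, prev = 0.3, h0 = 0.01, cmax = 200, seed = 1) {
  set.seed(seed)
  p <- length(beta)
  x <- matrix(rbinom(n * p, 1, prev), n, p,
              dimnames = list(NULL, paste0("v", seq_len(p))))
  t_event <- rexp(n, h0 * exp(drop(x %*% beta)))
  cens <- runif(n, 0, cmax)
  d <- data.table::data.table(caseid = as.character(seq_len(n)),
                              time_days = pmax(pmin(t_event, cens), 0.01),
                              event = as.integer(t_event <= cens))
  cbind(d, data.table::as.data.table(x))
}

test_that("design matrix applies completeness and candidate-floor rules", {
  cfg <- recovery_config(n_cohort = 300)
  sim <- synth_generate(cfg, seed = 61)
  co <- deduplicate_cases(sim$raw)
  planted <- names(cfg$planted_signals)
  d <- build_design_matrix(co, planted, min_pt_cases = 2)
  # independent recount of eligible PTs straight from the generated tables
  tto <- compute_tto(co)
  per_case <- unique(tto[, c("caseid", "sex", "age_years")])
  complete <- per_case$caseid[per_case$sex %in% c("F", "M") &
                                !is.na(per_case$age_years)]
  ptl <- unique(tto[tto$caseid %in% complete & tolower(tto$pt) %in% tolower(planted),
                    c("caseid", "pt")])
  eligible <- names(which(table(ptl$pt) >= 2))
  expect_setequal(attr(d, "candidate_pts"), eligible)
  expect_setequal(setdiff(names(d), c("caseid", "time_days", "event",
                                      "sex_male", "age_years")), eligible)
  expect_equal(nrow(d), length(complete))
  # a higher floor drops rarer PTs
  d5 <- build_design_matrix(co, planted, min_pt_cases = 5)
  expect_true(all(attr(d5, "candidate_pts") %in% eligible))
  expect_setequal(attr(d5, "candidate_pts"), names(which(table(ptl$pt) >= 5)))
  expect_error(build_design_matrix(co, planted, min_records = 1e6),
               "not identifiable")
})

test_that("penalty limits: everything zero at large lambda, Cox at zero", {
  d <- sim_surv(400, beta = c(1.5, 0, 0.8), seed = 3)
  sel <- lasso_cox_select(d, seed = 5)
  xy <- faerspv:::design_xy(d)
  fit <- sel$cvfit$glmnet.fit
  expect_true(all(as.matrix(coef(fit, s = max(fit$lambda) * 10)) == 0))
  cf0 <- as.matrix(coef(fit, s = 0, exact = TRUE, x = xy$x, y = xy$y,
                        thresh = 1e-14))[, 1]
  cox <- survival::coxph(xy$y ~ xy$x, ties = "breslow")
  expect_equal(unname(cf0), unname(coef(cox)), tolerance = 1e-4)
})

test_that("a strong factor among noise is selected almost surely", {
  hits <- 0L
  for (s in 1:50) {
    d <- sim_surv(400, beta = c(log(8), rep(0, 20)), prev = 0.25, seed = 700 + s)
    sel <- lasso_cox_select(d, seed = s)
    hits <- hits + ("v1" %in% sel$selected_vars)
  }
  expect_gte(hits / 50, 0.95)
})

test_that("Cox recovers a planted log-hazard with nominal coverage", {
  cover <- 0L
  for (s in 1:100) {
    d <- sim_surv(500, beta = log(2), prev = 0.4, seed = 900 + s)
    fit <- cox_fit(d, "v1")
    lo <- log(fit$table$hr_lo); hi <- log(fit$table$hr_hi)
    cover <- cover + (lo <= log(2) && log(2) <= hi)
  }
  expect_gte(cover / 100, 0.90)
})

test_that("null-covariate p-values are uniform", {
  p <- numeric(200)
  for (s in 1:200) {
    d <- sim_surv(200, beta = 0, prev = 0.5, seed = 2000 + s)
    p[s] <- suppressWarnings(cox_fit(d, "v1"))$table$p
  }
  ks <- ks.test(p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("hazard ratios are invariant to the time unit", {
  d <- sim_surv(300, beta = c(0.9, -0.4), seed = 17)
  f1 <- suppressWarnings(cox_fit(d, c("v1", "v2")))
  d2 <- data.table::copy(d)
  d2$time_days <- d2$time_days * 2
  f2 <- suppressWarnings(cox_fit(d2, c("v1", "v2")))
  expect_equal(f1$table$hr, f2$table$hr, tolerance = 1e-8)
})

test_that("the risk score is the published linear predictor", {
  beta <- published_risk_coefficients()
  zero <- setNames(as.list(rep(0, length(beta))), names(beta))
  expect_equal(risk_score(zero, beta), 0)
  one <- zero; one[["immune thrombocytopenia"]] <- 1
  expect_equal(risk_score(one, beta), 2.5828)
  two <- zero
  two[["immune-mediated enterocolitis"]] <- 1
  two[["myocarditis"]] <- 1
  expect_equal(risk_score(two, beta), 1.1487 + 1.5122)
  expect_error(risk_score(zero[-1], beta), "lacks model variable")
})

test_that("median stratification splits ties low and detects planted separation", {
  d <- data.table::data.table(caseid = as.character(1:4),
                              time_days = c(10, 20, 5, 8),
                              event = c(0L, 0L, 1L, 1L))
  st <- stratify_and_test(c(0, 0, 1, 1), d)
  expect_equal(st$median_cutoff, 0.5)
  expect_equal(as.character(st$group), c("low", "low", "high", "high"))
  # planted two-population hazard ratio of 5 (jitter breaks all-tied medians)
  hits <- 0L
  for (s in 1:100) {
    d2 <- sim_surv(300, beta = log(5), prev = 0.5, seed = 3000 + s)
    sc <- d2$v1 + runif(300, 0, 1e-3)
    st2 <- stratify_and_test(sc, d2)
    hits <- hits + (st2$logrank_p < 0.01)
  }
  expect_gte(hits / 100, 0.95)
  # permuting scores destroys the association
  set.seed(41)
  d3 <- sim_surv(300, beta = log(5), prev = 0.5, seed = 77)
  p_perm <- replicate(60, stratify_and_test(sample(d3$v1), d3)$logrank_p)
  expect_gt(median(p_perm), 0.2)
  # degenerate all-equal scores: single group, no test
  expect_warning(st4 <- stratify_and_test(rep(1, 4), d), "degenerate")
  expect_true(is.na(st4$logrank_p))
})

test_that("time-dependent AUC matches oracles and score-transform invariance", {
  # uninformative score
  set.seed(6)
  d <- sim_surv(1000, beta = 0, prev = 0.5, h0 = 0.02, seed = 8)
  sc <- rnorm(1000)
  auc0 <- time_dependent_roc(sc, d, horizons = 30)$auc
  expect_lt(abs(auc0 - 0.5), 0.05)
  # perfect separation, no censoring
  d2 <- data.table::data.table(caseid = as.character(1:40),
                               time_days = c(seq(1, 20), seq(100, 119)),
                               event = rep(c(1L, 0L), each = 20))
  sc2 <- c(rep(2, 20), rep(1, 20))
  expect_equal(time_dependent_roc(sc2, d2, horizons = 50)$auc, 1.0)
  # no censoring: equals the brute-force pairwise binary AUC
  set.seed(9)
  n <- 150
  tt <- rexp(n, 0.02)
  d3 <- data.table::data.table(caseid = as.character(1:n), time_days = tt,
                               event = 1L)
  sc3 <- -tt + rnorm(n, sd = 20)
  tau <- 40
  case <- tt <= tau; ctrl <- tt > tau
  pairs <- outer(sc3[case], sc3[ctrl], ">") + 0.5 * outer(sc3[case], sc3[ctrl], "==")
  expect_equal(time_dependent_roc(sc3, d3, horizons = tau)$auc,
               mean(pairs))
  # invariant to strictly increasing transforms
  expect_equal(time_dependent_roc(exp(sc3), d3, horizons = tau)$auc,
               time_dependent_roc(sc3, d3, horizons = tau)$auc)
  # no events before the horizon: flagged NA
  expect_true(is.na(time_dependent_roc(sc2, d2, horizons = 0.5)$auc))
})

test_that("high-risk groups carry at least the low-risk event rate on planted data", {
  cfg <- recovery_config(n_cohort = 700)
  sim <- synth_generate(cfg, seed = 71)
  co <- deduplicate_cases(sim$raw)
  m <- suppressWarnings(
    fit_mortality_model(co, names(cfg$planted_signals), seed = 71))
  expect_false(is.null(m$cox))
  rate <- tapply(m$design$event, m$strata$group, mean)
  expect_gte(rate[["high"]], rate[["low"]])
  expect_true(all(m$roc$auc > 0.5, na.rm = TRUE))
})
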