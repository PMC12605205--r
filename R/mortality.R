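# Drug-related mortality risk modelling.
#
# One survival record per case: time runs from therapy start to the onset of
# the fatal adverse event (EVENT_DT of reports with outcome code DE);
# non-fatal reports are administratively censored at their last recorded
# event date (FAERS has no follow-up beyond the report). Candidate
# covariates are sex, age and indicators of the consensus-positive PTs.
# Variable selection is L1-penalised Cox with cross-validated deviance;
# selected variables go into an unpenalised Cox fit whose coefficients
# define a linear risk score.

#' Build the survival design matrix
#'
#' Keeps cases with complete sex, age and a usable onset interval, and adds
#' an indicator column per candidate PT (consensus-positive PTs occurring in
#' at least `min_pt_cases` retained cases).
#'
#' @param cases deduplicated `faers_cases` cohort.
#' @param signal_pts character vector of consensus-positive PTs.
#' @param min_pt_cases candidate floor: a PT must occur in at least this many
#'   retained cases to enter the model (default 2).
#' @param impute_month passed to [compute_tto()].
#' @param min_records hard floor on usable records (default 20) below which
#'   the model is not identifiable.
#' @return data.table with columns `caseid`, `time_days`, `event`,
#'   `sex_male`, `age_years`, and one 0/1 column per candidate PT (original
#'   PT names); candidate PTs attached as attribute `candidate_pts`.
#' @export
build_design_matrix <- function(cases, signal_pts, min_pt_cases = 2,
                                impute_month = FALSE, min_records = 20) {
  tto <- compute_tto(cases, impute_month = impute_month)
  per_case <- tto[, list(time_days = tto_days[1L], fatal = fatal[1L],
                         sex = sex[1L], age_years = age_years[1L]),
                  by = "caseid"]
  per_case <- per_case[per_case$sex %in% c("F", "M") & !is.na(per_case$age_years)]
  per_case$time_days <- pmax(per_case$time_days, 0.5)
  if (nrow(per_case) < min_records) {
    stop("only ", nrow(per_case),
         " usable records with complete sex/age/TTO; model not identifiable")
  }
  ptl <- unique(tto[, c("caseid", "pt")])
  ptl <- ptl[ptl$caseid %in% per_case$caseid &
               tolower(ptl$pt) %in% tolower(trimws(signal_pts))]
  counts <- table(ptl$pt)
  candidates <- names(counts)[counts >= min_pt_cases]
  out <- data.table::data.table(caseid = per_case$caseid,
                                time_days = as.numeric(per_case$time_days),
                                event = as.integer(per_case$fatal),
                                sex_male = as.integer(per_case$sex == "M"),
                                age_years = per_case$age_years)
  for (p in sort(candidates)) {
    has <- out$caseid %in% ptl$caseid[ptl$pt == p]
    data.table::set(out, j = p, value = as.integer(has))
  }
  data.table::setattr(out, "candidate_pts", sort(candidates))
  out[]
}

design_xy <- function(design, vars = NULL) {
  covs <- setdiff(names(design), c("caseid", "time_days", "event"))
  if (!is.null(vars)) covs <- intersect(covs, vars)
  x <- as.matrix(design[, covs, with = FALSE])
  storage.mode(x) <- "double"
  y <- survival::Surv(design$time_days, design$event)
  list(x = x, y = y, covs = covs)
}

#' LASSO-penalised Cox variable selection
#'
#' L1-penalised Cox partial likelihood over `glmnet`'s log-spaced lambda
#' grid, with k-fold cross-validation of the partial-likelihood deviance;
#' the selected variables are those with non-zero coefficients at the
#' deviance-minimising `lambda.min`.
#'
#' @param design from [build_design_matrix()].
#' @param nfolds cross-validation folds (default 10).
#' @param seed RNG seed controlling the fold assignment.
#' @return list with `cvfit` (the `cv.glmnet` object), `lambda_min`,
#'   `selected_vars` (possibly empty, with a warning) and `coefficients`
#'   at `lambda.min`.
#' @export
lasso_cox_select <- function(design, nfolds = 10, seed = 1) {
  xy <- design_xy(design)
  if (sum(design$event) < 2 * nfolds) {
    warning("fewer than 2 events per fold on average; CV deviance is unstable")
  }
  set.seed(seed)
  foldid <- sample(rep(seq_len(nfolds), length.out = nrow(xy$x)))
  cvfit <- glmnet::cv.glmnet(xy$x, xy$y, family = "cox", foldid = foldid)
  cf <- as.matrix(coef(cvfit, s = "lambda.min"))[, 1]
  selected <- names(cf)[cf != 0]
  if (!length(selected)) warning("LASSO selected no variables at lambda.min")
  list(cvfit = cvfit, lambda_min = cvfit$lambda.min,
       selected_vars = selected, coefficients = cf[cf != 0])
}

#' Multivariable Cox fit of selected variables
#'
#' Efron tie handling; Wald CIs and p-values. Variables with `p < 0.05` are
#' reported as independent risk factors.
#'
#' @param design from [build_design_matrix()].
#' @param vars covariate names to include.
#' @param conf CI level (default 0.95).
#' @return list with `fit` (the `coxph` object) and `table` (data.table of
#'   `var`, `coef`, `hr`, `hr_lo`, `hr_hi`, `p`, `independent`).
#' @export
cox_fit <- function(design, vars, conf = 0.95) {
  stopifnot(length(vars) > 0)
  xy <- design_xy(design, vars)
  if (sum(design$event) < 10 * length(vars)) {
    warning("fewer than 10 events per variable; estimates may be unstable")
  }
  df <- data.frame(xy$x, check.names = TRUE)
  safe <- names(df)
  df$.time <- design$time_days
  df$.event <- design$event
  fml <- as.formula(paste("survival::Surv(.time, .event) ~",
                          paste(safe, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (any(is.na(coef(fit)))) {
    stop("Cox fit failed (separation or collinearity) for variable(s): ",
         paste(xy$covs[is.na(coef(fit))], collapse = ", "))
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  beta <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  p <- 2 * stats::pnorm(-abs(beta / se))
  tab <- data.table::data.table(
    var = xy$covs, coef = unname(beta), hr = exp(unname(beta)),
    hr_lo = exp(unname(beta - z * se)), hr_hi = exp(unname(beta + z * se)),
    p = unname(p))
  tab$independent <- tab$p < 0.05
  list(fit = fit, table = tab)
}

#' Linear risk score
#'
#' Coefficient-weighted sum over the final-model variables only:
#' `score_i = sum_j beta_j x_ij`.
#'
#' @param design data.frame/data.table holding the model variables as
#'   columns (e.g. from [build_design_matrix()]), or a named list/vector of
#'   indicator values for a single patient.
#' @param coefficients named numeric vector of Cox coefficients (e.g. the
#'   published ones from [published_risk_coefficients()]).
#' @return numeric vector of risk scores.
#' @export
risk_score <- function(design, coefficients) {
  stopifnot(length(coefficients) > 0, !is.null(names(coefficients)))
  design <- if (is.data.frame(design)) {
    as.data.frame(design)
  } else {
    as.data.frame(as.list(design), check.names = FALSE)
  }
  missing_vars <- setdiff(names(coefficients), names(design))
  if (length(missing_vars)) {
    stop("design lacks model variable(s): ", paste(missing_vars, collapse = ", "))
  }
  x <- as.matrix(design[, names(coefficients), drop = FALSE])
  storage.mode(x) <- "double"
  as.numeric(x %*% coefficients)
}

#' Median-split risk stratification with log-rank test
#'
#' High risk: score strictly above the median; ties go to the low-risk
#' group. Degenerate all-equal scores yield a single group and no test.
#'
#' @param scores numeric risk scores, one per case.
#' @param design matching design table (`time_days`, `event`).
#' @return list with `group` (factor high/low), `median_cutoff`,
#'   `logrank_chisq`, `logrank_p`, and `km` (a `survfit` object or `NULL`).
#' @export
stratify_and_test <- function(scores, design) {
  stopifnot(length(scores) == nrow(design), length(scores) >= 4)
  med <- median(scores)
  group <- factor(ifelse(scores > med, "high", "low"), levels = c("low", "high"))
  if (nlevels(droplevels(group)) < 2L) {
    warning("degenerate scores: all cases in one group; log-rank test skipped")
    return(list(group = group, median_cutoff = med, logrank_chisq = NA_real_,
                logrank_p = NA_real_, km = NULL))
  }
  df <- data.frame(time = design$time_days, event = design$event, group = group)
  lr <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  list(group = group, median_cutoff = med, logrank_chisq = lr$chisq,
       logrank_p = pchisq(lr$chisq, df = 1, lower.tail = FALSE), km = km)
}

#' Time-dependent ROC AUC (cumulative cases / dynamic controls, IPCW)
#'
#' At horizon `tau`, cases are subjects with an observed event by `tau`,
#' controls are subjects still event-free at `tau`; both are weighted by the
#' inverse of the Kaplan-Meier estimate of the censoring distribution
#' (weights `1/G(T_i-)` for cases, `1/G(tau)` for controls). With no
#' censoring before `tau` this reduces to the empirical binary AUC.
#'
#' @param scores numeric risk scores (higher = riskier).
#' @param design matching design table (`time_days`, `event`).
#' @param horizons evaluation days; default `c(30, 60, 90)`.
#' @return data.table with columns `horizon`, `auc`, `n_cases`,
#'   `n_controls`; `auc` is `NA` (flagged) when a horizon has no event.
#' @export
time_dependent_roc <- function(scores, design, horizons = c(30, 60, 90)) {
  stopifnot(length(scores) == nrow(design))
  time <- design$time_days
  event <- design$event
  # censoring distribution G: KM of the censoring indicator
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(cfit$time, c(1, cfit$surv), right = FALSE)
  Gminus <- function(t) {
    # left limit G(t-)
    vapply(t, function(ti) {
      prev <- cfit$time < ti
      if (!any(prev)) 1 else c(1, cfit$surv)[max(which(prev)) + 1L]
    }, numeric(1))
  }
  out <- lapply(horizons, function(tau) {
    is_case <- event == 1 & time <= tau
    is_ctrl <- time > tau
    if (!any(is_case) || !any(is_ctrl)) {
      return(data.table::data.table(horizon = tau, auc = NA_real_,
                                    n_cases = sum(is_case),
                                    n_controls = sum(is_ctrl)))
    }
    wc <- 1 / pmax(Gminus(time[is_case]), 1e-10)
    wk <- rep(1 / pmax(G(tau), 1e-10), sum(is_ctrl))
    sc <- scores[is_case]
    sk <- scores[is_ctrl]
    # weighted probability that a case outranks a control (ties count half)
    gt <- outer(sc, sk, ">")
    eq <- outer(sc, sk, "==")
    W <- outer(wc, wk)
    auc <- sum(W * (gt + 0.5 * eq)) / sum(W)
    data.table::data.table(horizon = tau, auc = auc,
                           n_cases = sum(is_case), n_controls = sum(is_ctrl))
  })
  data.table::rbindlist(out)
}

#' Fit the full mortality risk model
#'
#' Convenience wrapper chaining [build_design_matrix()],
#' [lasso_cox_select()], [cox_fit()] on the selected variables,
#' [risk_score()], [stratify_and_test()] and [time_dependent_roc()].
#'
#' @inheritParams build_design_matrix
#' @inheritParams lasso_cox_select
#' @param horizons ROC evaluation days.
#' @return list with `design`, `lasso`, `cox`, `scores`, `strata`, `roc`;
#'   `cox` and downstream elements are `NULL` when the LASSO selects nothing.
#' @export
fit_mortality_model <- function(cases, signal_pts, min_pt_cases = 2,
                                nfolds = 10, seed = 1,
                                horizons = c(30, 60, 90)) {
  design <- build_design_matrix(cases, signal_pts, min_pt_cases = min_pt_cases)
  lasso <- lasso_cox_select(design, nfolds = nfolds, seed = seed)
  if (!length(lasso$selected_vars)) {
    return(list(design = design, lasso = lasso, cox = NULL, scores = NULL,
                strata = NULL, roc = NULL))
  }
  cox <- cox_fit(design, lasso$selected_vars)
  coefs <- setNames(cox$table$coef, cox$table$var)
  scores <- risk_score(design, coefs)
  strata <- stratify_and_test(scores, design)
  roc <- time_dependent_roc(scores, design, horizons)
  list(design = design, lasso = lasso, cox = cox, scores = scores,
       strata = strata, roc = roc)
}
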