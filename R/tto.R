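# Time-to-onset (TTO) analysis: onset intervals, Kaplan-Meier cumulative
# incidence with log-rank strata tests, and Weibull hazard-shape
# classification.
#
# TTO is the number of days from therapy start (earliest START_DT across the
# suspect drugs' therapy rows) to adverse-event onset (EVENT_DT). Records
# with a missing date, onset before start, or date precision worse than a
# day are excluded (optionally, month-precision dates can be imputed to the
# 15th).

#' Compute per-case, per-PT onset intervals
#'
#' @param cases deduplicated `faers_cases`.
#' @param impute_month if `TRUE`, month-precision dates (already imputed to
#'   the 15th at parse time) are accepted; default `FALSE` excludes them.
#' @return data.table with columns `caseid`, `pt`, `tto_days`, `sex`,
#'   `age_group`, `age_years`, `fatal`; exclusion counts are attached as
#'   attribute `exclusions`.
#' @export
compute_tto <- function(cases, impute_month = FALSE) {
  stopifnot(inherits(cases, "faers_cases"))
  ct <- cases$cases
  ther <- cases$tables$ther
  if (is.null(ther) || nrow(ther) == 0L) {
    warning("no therapy (THER) rows; 0 usable TTO records")
    start <- data.table::data.table(PRIMARYID = character(0),
                                    start = as.Date(character(0)),
                                    start_prec = character(0))
  } else {
    th <- data.table::data.table(PRIMARYID = ther$PRIMARYID,
                                 start = ther$START_DT,
                                 start_prec = ther$START_DT_PREC)
    th <- th[!is.na(th$start)]
    data.table::setorder(th, PRIMARYID, start)
    start <- th[, list(start = start[1L], start_prec = start_prec[1L]),
                by = "PRIMARYID"]
  }
  dm <- merge(
    data.table::data.table(PRIMARYID = ct$primaryid, caseid = ct$caseid,
                           event = ct$event_dt, event_prec = ct$event_prec,
                           sex = ct$sex, age_group = ct$age_group,
                           age_years = ct$age_years),
    start, by = "PRIMARYID", all.x = TRUE)
  ok_prec <- function(p) {
    if (impute_month) p %in% c("day", "month") else p == "day"
  }
  n0 <- nrow(dm)
  miss_date <- is.na(dm$event) | is.na(dm$start)
  bad_prec <- !miss_date & !(ok_prec(dm$event_prec) & ok_prec(dm$start_prec))
  neg <- !miss_date & !bad_prec & (dm$event < dm$start)
  keep <- !(miss_date | bad_prec | neg)
  excl <- c(total_cases = n0, missing_date = sum(miss_date),
            imprecise_date = sum(bad_prec), event_before_start = sum(neg),
            usable = sum(keep))
  dm <- dm[keep]
  dm$tto_days <- as.integer(dm$event - dm$start)
  fatal_ids <- unique(cases$tables$outc$PRIMARYID[
    toupper(trimws(cases$tables$outc$OUTC_COD)) == "DE"])
  dm$fatal <- dm$PRIMARYID %in% fatal_ids
  reac <- cases$tables$reac
  rl <- unique(data.table::data.table(PRIMARYID = reac$PRIMARYID,
                                      pt = trimws(reac$PT)))
  out <- merge(dm, rl, by = "PRIMARYID", allow.cartesian = TRUE)
  out <- out[, c("caseid", "pt", "tto_days", "sex", "age_group", "age_years",
                 "fatal", "PRIMARYID")]
  data.table::setorder(out, caseid, pt)
  data.table::setattr(out, "exclusions", excl)
  out[]
}

#' Summarise onset intervals
#'
#' Median with a binomial order-statistic 95% CI, IQR, range, and counts in
#' the half-open interval bins `[0,30)`, `[30,60)`, `[60,90)`, `[90,180)`,
#' `[180,365)`, `[365, Inf)`.
#'
#' @param tto_days numeric vector of onset intervals (days), or a data.frame
#'   with a `tto_days` column.
#' @return list with `n`, `median`, `median_ci`, `iqr`, `min`, `max`, and a
#'   `bins` data.table (`bin`, `n`, `pct`).
#' @export
tto_summary <- function(tto_days) {
  if (is.data.frame(tto_days)) tto_days <- tto_days$tto_days
  x <- tto_days[!is.na(tto_days)]
  if (!length(x)) stop("no usable onset intervals")
  n <- length(x)
  xs <- sort(x)
  # distribution-free CI for the median from binomial order statistics
  lo_rank <- qbinom(0.025, n, 0.5)
  hi_rank <- qbinom(0.975, n, 0.5) + 1L
  ci <- c(xs[max(lo_rank, 1L)], xs[min(hi_rank, n)])
  breaks <- c(0, 30, 60, 90, 180, 365, Inf)
  labs <- c("[0,30)", "[30,60)", "[60,90)", "[90,180)", "[180,365)", "[365,Inf)")
  bin <- cut(x, breaks = breaks, right = FALSE, labels = labs)
  bins <- data.table::data.table(bin = labs, n = as.integer(table(bin)))
  bins$pct <- 100 * bins$n / n
  list(n = n, median = median(x), median_ci = ci,
       iqr = unname(quantile(x, c(0.25, 0.75), type = 2)),
       min = min(x), max = max(x), bins = bins)
}

#' Kaplan-Meier onset curves with log-rank test across strata
#'
#' Onset times are fully observed (every report is an event), so the
#' product-limit estimate is the empirical cumulative incidence
#' complemented; the log-rank test is the unweighted Mantel-Haenszel
#' version from the `survival` package.
#'
#' @param tto_days numeric onset intervals.
#' @param strata optional factor of the same length; with a single stratum
#'   the curve is returned and the test omitted.
#' @return list with `fit` (a `survfit` object), `curve` (data.table of
#'   time/estimate/n_risk/stratum), `logrank_chisq`, `logrank_p` (both `NA`
#'   for a single stratum).
#' @export
km_curve <- function(tto_days, strata = NULL) {
  stopifnot(length(tto_days) > 0)
  ev <- rep(1L, length(tto_days))
  if (is.null(strata)) strata <- rep("all", length(tto_days))
  strata <- droplevels(factor(strata))
  df <- data.frame(time = tto_days, event = ev, stratum = strata)
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = df)
  sm <- summary(fit)
  stratum <- if (is.null(sm$strata)) rep(levels(strata)[1], length(sm$time)) else
    sub("^stratum=", "", as.character(sm$strata))
  curve <- data.table::data.table(time = sm$time, estimate = sm$surv,
                                  cuminc = 1 - sm$surv,
                                  n_risk = sm$n.risk, stratum = stratum)
  chisq <- p <- NA_real_
  if (nlevels(strata) > 1L) {
    if (min(table(strata)) < 2L) {
      warning("a stratum has fewer than 2 records; log-rank test omitted")
    } else {
      lr <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = df)
      chisq <- lr$chisq
      p <- pchisq(lr$chisq, df = nlevels(strata) - 1L, lower.tail = FALSE)
    }
  }
  list(fit = fit, curve = curve, logrank_chisq = chisq, logrank_p = p)
}

#' Weibull maximum-likelihood fit of onset times
#'
#' MLE of the Weibull shape and scale via the accelerated-failure-time
#' parameterisation, with 95% CIs from the inverse observed information on
#' the log scale, back-transformed (delta method). Zero-day onsets are
#' shifted by +0.5 day (the likelihood requires positive times); binning and
#' summaries elsewhere keep them intact.
#'
#' @param tto_days numeric onset intervals, `n >= 10`.
#' @param conf level for the CIs (default 0.95).
#' @return object of class `weibull_fit`: list with `shape`, `shape_ci`,
#'   `scale`, `scale_ci`, `n`, `loglik`, `category` (see
#'   [classify_failure()]).
#' @export
weibull_fit <- function(tto_days, conf = 0.95) {
  x <- tto_days[!is.na(tto_days)]
  if (length(x) < 10) stop("Weibull fit requires at least 10 onset records (got ",
                           length(x), ")")
  x[x == 0] <- 0.5
  z <- stats::qnorm(1 - (1 - conf) / 2)
  fit <- survival::survreg(survival::Surv(x, rep(1L, length(x))) ~ 1,
                           dist = "weibull")
  if (is.na(fit$scale) || fit$scale <= 0) stop("Weibull fit did not converge")
  # survreg: log(T) = mu + sigma*W; Weibull shape = 1/sigma, scale = exp(mu)
  mu <- unname(coef(fit)[1])
  log_sigma <- log(fit$scale)
  V <- vcov(fit)   # parameters (mu, log sigma)
  se_mu <- sqrt(V[1, 1])
  se_logsigma <- sqrt(V[2, 2])
  shape <- 1 / fit$scale
  shape_ci <- exp(c(-log_sigma - z * se_logsigma, -log_sigma + z * se_logsigma))
  scale_w <- exp(mu)
  scale_ci <- exp(c(mu - z * se_mu, mu + z * se_mu))
  out <- structure(list(shape = shape, shape_ci = shape_ci,
                        scale = scale_w, scale_ci = scale_ci,
                        n = length(x), loglik = fit$loglik[1]),
                   class = "weibull_fit")
  out$category <- classify_failure(out)
  out
}

#' Classify a Weibull fit into a hazard-trajectory category
#'
#' Shape `beta < 1` with CI upper limit `< 1`: decreasing hazard
#' (`early_failure`); CI containing 1: constant hazard (`random_failure`);
#' `beta > 1` with CI lower limit `> 1`: increasing hazard
#' (`wear_out_failure`). The three cases are exhaustive and mutually
#' exclusive whenever `lo <= shape <= hi`.
#'
#' @param fit a `weibull_fit`, or a numeric shape if `lo`/`hi` are given.
#' @param lo,hi optional CI bounds when `fit` is a bare shape value.
#' @return one of `"early_failure"`, `"random_failure"`,
#'   `"wear_out_failure"`.
#' @export
classify_failure <- function(fit, lo = NULL, hi = NULL) {
  if (inherits(fit, "weibull_fit")) {
    shape <- fit$shape; lo <- fit$shape_ci[1]; hi <- fit$shape_ci[2]
  } else {
    shape <- fit
    stopifnot(!is.null(lo), !is.null(hi))
  }
  stopifnot(lo <= hi)
  if (hi < 1) "early_failure"
  else if (lo > 1) "wear_out_failure"
  else "random_failure"
}
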