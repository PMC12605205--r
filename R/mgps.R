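# DuMouchel multi-item gamma Poisson shrinker (MGPS).
#
# Model: the report count a for a drug-event pair is Poisson with mean
# lambda * E, where E is the count expected under independence and the
# relative reporting rate lambda has a two-component gamma mixture prior
#   lambda ~ w Ga(alpha1, beta1) + (1 - w) Ga(alpha2, beta2)   (rate param.)
# The marginal of a is then a mixture of negative binomials
#   w NB(a; alpha1, beta1/(beta1+E)) + (1-w) NB(a; alpha2, beta2/(beta2+E)),
# maximised over the five hyperparameters. The posterior of lambda given
# (a, E) is again a two-gamma mixture, from which EBGM (posterior geometric
# mean) and EBGM05 (posterior 5th percentile) follow in closed form /
# by root-finding.

.mgps_start <- c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, w = 1 / 3)

# log marginal likelihood contributions, numerically safe mixture
mgps_loglik <- function(theta, a, E) {
  alpha1 <- exp(theta[1]); beta1 <- exp(theta[2])
  alpha2 <- exp(theta[3]); beta2 <- exp(theta[4])
  w <- stats::plogis(theta[5])
  w <- min(max(w, 1e-10), 1 - 1e-10)
  l1 <- log(w) + dnbinom(a, size = alpha1, prob = beta1 / (beta1 + E), log = TRUE)
  l2 <- log(1 - w) + dnbinom(a, size = alpha2, prob = beta2 / (beta2 + E), log = TRUE)
  m <- pmax(l1, l2)
  sum(m + log(exp(l1 - m) + exp(l2 - m)))
}

#' Fit the MGPS two-gamma mixture prior
#'
#' Maximises the marginal (negative binomial mixture) likelihood of the
#' observed pair counts over the five hyperparameters by quasi-Newton ascent
#' on the log/logit scale from the canonical start
#' `(0.2, 0.1, 2, 4, 1/3)`, with multi-start fallback on non-convergence.
#'
#' @param a integer vector of observed pair counts (one per drug-event pair).
#' @param E numeric vector of expected counts under independence.
#' @param min_pairs minimum number of pairs for a stable fit; default 50.
#' @return an object of class `mgps_prior`: list with `alpha1, beta1, alpha2,
#'   beta2, w, loglik, convergence`.
#' @export
mgps_fit <- function(a, E, min_pairs = 50) {
  stopifnot(length(a) == length(E), all(E > 0), all(a >= 0))
  if (length(a) < min_pairs) {
    stop("MGPS prior fit needs at least ", min_pairs, " drug-event pairs (got ",
         length(a), ")")
  }
  starts <- list(
    .mgps_start,
    c(alpha1 = 1, beta1 = 1, alpha2 = 1, beta2 = 1, w = 0.5),
    c(alpha1 = 0.5, beta1 = 0.5, alpha2 = 5, beta2 = 2, w = 0.2)
  )
  best <- NULL
  for (s in starts) {
    theta0 <- c(log(s[1:4]), stats::qlogis(s[5]))
    fit <- tryCatch(
      optim(theta0, function(th) -mgps_loglik(th, a, E),
            method = "L-BFGS-B", lower = c(rep(-10, 4), -12),
            upper = c(rep(10, 4), 12), control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
    if (fit$convergence == 0) { best <- if (fit$value <= best$value) fit else best; break }
  }
  if (is.null(best)) stop("MGPS prior fit failed from all starting points")
  if (best$convergence != 0) {
    stop("MGPS prior fit did not converge; best loglik ", -best$value,
         " at (", paste(signif(c(exp(best$par[1:4]), stats::plogis(best$par[5])), 4),
                        collapse = ", "), ")")
  }
  th <- best$par
  structure(list(alpha1 = exp(th[[1]]), beta1 = exp(th[[2]]),
                 alpha2 = exp(th[[3]]), beta2 = exp(th[[4]]),
                 w = stats::plogis(th[[5]]),
                 loglik = -best$value, convergence = best$convergence),
            class = "mgps_prior")
}

# posterior mixture weight of component 1 given (a, E)
mgps_posterior_weight <- function(a, E, prior) {
  l1 <- log(prior$w) +
    dnbinom(a, size = prior$alpha1, prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- log(1 - prior$w) +
    dnbinom(a, size = prior$alpha2, prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  1 / (1 + exp(l2 - l1))
}

#' Empirical Bayes geometric mean and its lower 5% bound
#'
#' The posterior of the relative reporting rate is the two-gamma mixture
#' `Q Ga(alpha1 + a, beta1 + E) + (1-Q) Ga(alpha2 + a, beta2 + E)`.
#' `EBGM = exp(E[log lambda | a, E])` via the digamma closed form;
#' `EBGM05` is the 5th percentile of the posterior mixture, found by
#' bisection on its CDF (bracketed by the component quantiles).
#'
#' @param a,E observed and expected counts (vectorised).
#' @param prior an `mgps_prior` from [mgps_fit()].
#' @return data.table with columns `ebgm`, `ebgm05`.
#' @export
ebgm_stats <- function(a, E, prior) {
  stopifnot(inherits(prior, "mgps_prior"))
  Q <- mgps_posterior_weight(a, E, prior)
  s1 <- prior$alpha1 + a; r1 <- prior$beta1 + E
  s2 <- prior$alpha2 + a; r2 <- prior$beta2 + E
  elog <- Q * (digamma(s1) - log(r1)) + (1 - Q) * (digamma(s2) - log(r2))
  ebgm <- exp(elog)
  q1 <- qgamma(0.05, s1, rate = r1)
  q2 <- qgamma(0.05, s2, rate = r2)
  lo <- pmin(q1, q2)
  hi <- pmax(q1, q2)
  mix_cdf <- function(x) Q * pgamma(x, s1, rate = r1) + (1 - Q) * pgamma(x, s2, rate = r2)
  for (i in seq_len(70)) {
    mid <- (lo + hi) / 2
    below <- mix_cdf(mid) < 0.05
    lo <- ifelse(below, mid, lo)
    hi <- ifelse(below, hi, mid)
  }
  data.table::data.table(ebgm = ebgm, ebgm05 = (lo + hi) / 2)
}
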