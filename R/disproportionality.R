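# Disproportionality statistics on 2x2 contingency tables.
#
# All four screening algorithms operate on the same report-level 2x2 table
# for one drug(-combination)-event pair:
#
#                     target PT    other PTs
#   target cohort        a            b
#   rest of universe     c            d
#
# The counting unit is the deduplicated report: a report contributes at most
# one to each cell regardless of how many times it lists the PT.

#' Build the 2x2 contingency table for one preferred term
#'
#' @param cohort deduplicated `faers_cases` for the target drug cohort.
#' @param universe deduplicated `faers_cases` for the whole report universe;
#'   the cohort must be a subset of it.
#' @param pt preferred term (matched case-insensitively, trimmed).
#' @return a `contingency` object: list with integer `a`, `b`, `c`, `d`, and
#'   derived `N`, `E` (expected count of `a` under independence).
#' @export
build_contingency <- function(cohort, universe, pt) {
  co_ids <- cohort$tables$demo$PRIMARYID
  un_ids <- universe$tables$demo$PRIMARYID
  if (!all(co_ids %in% un_ids)) stop("cohort is not a subset of the universe")
  ptn <- tolower(trimws(pt))
  reac <- universe$tables$reac
  with_pt <- unique(reac$PRIMARYID[tolower(trimws(reac$PT)) == ptn])
  a <- sum(co_ids %in% with_pt)
  b <- length(co_ids) - a
  c_ <- sum(!(with_pt %in% co_ids) & with_pt %in% un_ids)
  d <- length(un_ids) - a - b - c_
  new_contingency(a, b, c_, d)
}

new_contingency <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  N <- a + b + c + d
  structure(list(a = a, b = b, c = c, d = d, N = N,
                 E = if (N > 0) (a + b) * (a + c) / N else 0),
            class = "contingency")
}

# Report-level counts for every PT observed in the cohort, in one pass.
# Returns data.table(pt, a, b, c, d).
build_contingency_all <- function(cohort, universe) {
  co_ids <- cohort$tables$demo$PRIMARYID
  un_ids <- universe$tables$demo$PRIMARYID
  if (!all(co_ids %in% un_ids)) stop("cohort is not a subset of the universe")
  reac <- universe$tables$reac[universe$tables$reac$PRIMARYID %in% un_ids]
  rl <- unique(data.table::data.table(
    PRIMARYID = reac$PRIMARYID, pt = tolower(trimws(reac$PT)),
    pt_label = trimws(reac$PT)))
  rl <- unique(rl, by = c("PRIMARYID", "pt"))
  rl$in_cohort <- rl$PRIMARYID %in% co_ids
  counts <- rl[, list(a = sum(in_cohort), total = .N,
                      pt_label = pt_label[1L]), by = "pt"]
  counts <- counts[counts$a > 0L]
  n_co <- length(co_ids)
  n_un <- length(un_ids)
  data.table::data.table(
    pt = counts$pt_label,
    a = counts$a,
    b = n_co - counts$a,
    c = counts$total - counts$a,
    d = n_un - n_co - (counts$total - counts$a))
}

# Haldane-Anscombe continuity handling: +0.5 to all cells when a >= 1 and
# exactly one of b, c, d is zero. Returns list(a,b,c,d, defined) vectorised.
continuity_adjust <- function(a, b, c, d) {
  zeros <- (b == 0) + (c == 0) + (d == 0)
  adj <- a >= 1 & zeros == 1
  undef <- a >= 1 & zeros > 1
  list(a = ifelse(adj, a + 0.5, a), b = ifelse(adj, b + 0.5, b),
       c = ifelse(adj, c + 0.5, c), d = ifelse(adj, d + 0.5, d),
       defined = a >= 1 & !undef & !(zeros >= 1 & !adj))
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad/bc`, CI `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`.
#' A zero in exactly one of b, c, d (with `a >= 1`) triggers the
#' Haldane-Anscombe +0.5 adjustment of all cells; tables with `a = 0` or
#' several zero cells are flagged undefined (`NA`), never silent infinities.
#'
#' @param t a `contingency` object, or a data.frame/list with columns
#'   `a, b, c, d` (vectorised).
#' @return data.table with columns `ror`, `ror_lo`, `ror_hi`.
#' @export
ror_stats <- function(t) {
  a <- as.numeric(t$a); b <- as.numeric(t$b)
  c <- as.numeric(t$c); d <- as.numeric(t$d)
  cc <- continuity_adjust(a, b, c, d)
  ror <- (cc$a * cc$d) / (cc$b * cc$c)
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  out <- data.table::data.table(
    ror = ror, ror_lo = ror * exp(-1.96 * se), ror_hi = ror * exp(1.96 * se))
  out[!cc$defined, c("ror", "ror_lo", "ror_hi") := NA_real_]
  out[]
}

#' Proportional reporting ratio, CI, and Yates-corrected chi-square
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]`,
#' CI `exp(log PRR +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`, and the
#' continuity-corrected chi-square
#' `N (|ad - bc| - N/2)^2 / [(a+b)(c+d)(a+c)(b+d)]`.
#' Zero-cell handling as in [ror_stats()]; `c = 0` (after adjustment rules)
#' is flagged undefined.
#'
#' @inheritParams ror_stats
#' @return data.table with columns `prr`, `prr_lo`, `prr_hi`, `chi2`.
#' @export
prr_stats <- function(t) {
  a <- as.numeric(t$a); b <- as.numeric(t$b)
  c <- as.numeric(t$c); d <- as.numeric(t$d)
  cc <- continuity_adjust(a, b, c, d)
  prr <- (cc$a / (cc$a + cc$b)) / (cc$c / (cc$c + cc$d))
  se <- sqrt(1 / cc$a - 1 / (cc$a + cc$b) + 1 / cc$c - 1 / (cc$c + cc$d))
  N <- a + b + c + d
  num <- pmax(abs(a * d - b * c) - N / 2, 0)
  chi2 <- N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  out <- data.table::data.table(
    prr = prr, prr_lo = prr * exp(-1.96 * se), prr_hi = prr * exp(1.96 * se),
    chi2 = chi2)
  out[!cc$defined, c("prr", "prr_lo", "prr_hi") := NA_real_]
  out[]
}

#' BCPNN information component with lower credibility bound
#'
#' `IC = log2[(a + 0.5) / (E + 0.5)]` with `E = (a+b)(a+c)/N`. The default
#' lower bound `IC025` is the exact 2.5% quantile of the gamma posterior
#' `Ga(a + 0.5, rate = E + 0.5)` of the observed-to-expected ratio on the
#' log2 scale (the Noren credibility interval). The closed-form
#' approximation `IC - 3.3 (a+0.5)^{-1/2} - 2 (a+0.5)^{-3/2}` is available
#' via `method = "approx"`.
#'
#' @inheritParams ror_stats
#' @param method `"gamma"` (default, exact quantile) or `"approx"`.
#' @return data.table with columns `ic`, `ic025`.
#' @export
bcpnn_ic <- function(t, method = c("gamma", "approx")) {
  method <- match.arg(method)
  a <- as.numeric(t$a); b <- as.numeric(t$b)
  c <- as.numeric(t$c); d <- as.numeric(t$d)
  N <- a + b + c + d
  E <- ifelse(N > 0, (a + b) * (a + c) / N, 0)
  ic <- log2((a + 0.5) / (E + 0.5))
  ic025 <- if (method == "gamma") {
    log2(qgamma(0.025, shape = a + 0.5, rate = E + 0.5))
  } else {
    ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5)
  }
  data.table::data.table(ic = ic, ic025 = ic025)
}

# Two-sided p-value for the 2x2 table: Yates-corrected chi-square, switching
# to Fisher's exact test when any expected cell count is below 5.
contingency_pvalue <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  N <- a + b + c + d
  e11 <- (a + b) * (a + c) / N
  e12 <- (a + b) * (b + d) / N
  e21 <- (c + d) * (a + c) / N
  e22 <- (c + d) * (b + d) / N
  small <- e11 < 5 | e12 < 5 | e21 < 5 | e22 < 5
  num <- pmax(abs(a * d - b * c) - N / 2, 0)
  chi2 <- N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  for (i in which(small)) {
    p[i] <- fisher.test(matrix(c(a[i], b[i], c[i], d[i]), 2, byrow = TRUE))$p.value
  }
  pmin(pmax(p, 0), 1)   # guard against floating drift just past 1
}

#' Bonferroni adjustment of per-PT p-values
#'
#' `p_adj = min(1, p * m)` where `m` is the number of PTs tested; rank order
#' is preserved.
#'
#' @param p_raw numeric vector of raw p-values in `[0, 1]`.
#' @param m number of comparisons; defaults to `length(p_raw)`.
#' @return numeric vector of adjusted p-values.
#' @export
bonferroni_adjust <- function(p_raw, m = length(p_raw)) {
  stopifnot(all(p_raw >= 0 & p_raw <= 1, na.rm = TRUE))
  pmin(1, p_raw * m)
}

#' Default consensus signal thresholds
#'
#' Standard published criteria: ROR positive if `a >= 3` and the CI lower
#' bound exceeds 1; PRR positive if `a >= 3`, `PRR >= 2` and `chi2 >= 4`;
#' BCPNN positive if `IC025 > 0`; MGPS positive if `EBGM05 >= 2`. A signal
#' is called only when all four agree.
#'
#' @param ror_min_a,ror_lo minimum case count / CI lower bound for ROR.
#' @param prr_min_a,prr_min,chi2_min PRR criteria.
#' @param ic025_min BCPNN criterion (exclusive bound).
#' @param ebgm05_min MGPS criterion (inclusive bound).
#' @return list of thresholds.
#' @export
signal_thresholds <- function(ror_min_a = 3, ror_lo = 1,
                              prr_min_a = 3, prr_min = 2, chi2_min = 4,
                              ic025_min = 0, ebgm05_min = 2) {
  list(ror_min_a = ror_min_a, ror_lo = ror_lo, prr_min_a = prr_min_a,
       prr_min = prr_min, chi2_min = chi2_min, ic025_min = ic025_min,
       ebgm05_min = ebgm05_min)
}

#' Per-algorithm verdicts and the consensus call
#'
#' An undefined statistic yields a `FALSE` verdict for that algorithm
#' (conservative). The consensus is the conjunction of all four verdicts.
#'
#' @param rec data.frame/data.table with columns `a`, `ror_lo`, `prr`,
#'   `chi2`, `ic025`, `ebgm05` (vectorised over rows).
#' @param thresholds from [signal_thresholds()].
#' @return data.table with logical columns `pos_ror`, `pos_prr`, `pos_bcpnn`,
#'   `pos_mgps`, `consensus`.
#' @export
consensus_signal <- function(rec, thresholds = signal_thresholds()) {
  th <- thresholds
  ok <- function(x) !is.na(x) & x
  pos_ror <- ok(rec$a >= th$ror_min_a & rec$ror_lo > th$ror_lo)
  pos_prr <- ok(rec$a >= th$prr_min_a & rec$prr >= th$prr_min & rec$chi2 >= th$chi2_min)
  pos_bcpnn <- ok(rec$ic025 > th$ic025_min)
  pos_mgps <- ok(rec$ebgm05 >= th$ebgm05_min)
  data.table::data.table(
    pos_ror = pos_ror, pos_prr = pos_prr, pos_bcpnn = pos_bcpnn,
    pos_mgps = pos_mgps,
    consensus = pos_ror & pos_prr & pos_bcpnn & pos_mgps)
}

#' Annotate signal records with IME/DME membership and unexpectedness
#'
#' Flags are set by exact case-insensitive PT match against the user-supplied
#' EMA important/designated medical event term lists. An "unexpected" signal
#' is a consensus-positive PT absent from the drug label term list.
#'
#' @param rec signal record table with columns `pt` and `consensus`.
#' @param ime_terms,dme_terms,label_terms character vectors of PT terms
#'   (`NULL` to skip the corresponding flag, with a warning for the lists).
#' @return `rec` with logical columns `ime`, `dme`, `unexpected` appended.
#' @export
annotate_signals <- function(rec, ime_terms = NULL, dme_terms = NULL,
                             label_terms = NULL) {
  rec <- data.table::as.data.table(rec)
  ptn <- tolower(trimws(rec$pt))
  flag <- function(terms) {
    if (is.null(terms)) return(rep(NA, nrow(rec)))
    ptn %in% tolower(trimws(terms))
  }
  if (is.null(ime_terms)) warning("no IME term list supplied; IME flag omitted")
  if (is.null(dme_terms)) warning("no DME term list supplied; DME flag omitted")
  rec$ime <- flag(ime_terms)
  rec$dme <- flag(dme_terms)
  rec$unexpected <- if (is.null(label_terms)) {
    rep(NA, nrow(rec))
  } else {
    rec$consensus & !(ptn %in% tolower(trimws(label_terms)))
  }
  rec[]
}

#' Full four-algorithm disproportionality screen of a cohort
#'
#' Builds the per-PT 2x2 tables, computes ROR/PRR (+ Yates chi-square and
#' p-value), the BCPNN information component, fits the MGPS empirical-Bayes
#' prior on all drug-event pairs of the universe and scores EBGM/EBGM05,
#' applies the Bonferroni correction over the tested PTs, and calls the
#' consensus verdicts.
#'
#' @param cohort,universe deduplicated `faers_cases`; cohort must be a subset
#'   of the universe.
#' @param thresholds consensus thresholds, see [signal_thresholds()].
#' @param pt_soc optional `data.frame(pt, soc)` mapping used to attach SOC
#'   labels.
#' @param ime_terms,dme_terms,label_terms optional term lists for
#'   [annotate_signals()]; flags omitted when `NULL`.
#' @param ic_method BCPNN interval variant, see [bcpnn_ic()].
#' @param prior optionally, a pre-fitted [mgps_fit()] prior to reuse.
#' @return data.table, one row per PT with counts, all statistics, `p_raw`,
#'   `p_adj`, per-algorithm verdicts, `consensus` and flags, sorted by
#'   descending case count.
#' @export
detect_signals <- function(cohort, universe, thresholds = signal_thresholds(),
                           pt_soc = NULL, ime_terms = NULL, dme_terms = NULL,
                           label_terms = NULL, ic_method = "gamma",
                           prior = NULL) {
  tabs <- build_contingency_all(cohort, universe)
  if (nrow(tabs) == 0L) {
    warning("cohort has no adverse-event terms; empty signal table")
    return(tabs)
  }
  if (is.null(prior)) {
    pairs <- universe_pair_counts(universe)
    prior <- mgps_fit(pairs$a, pairs$E)
  }
  res <- cbind(tabs, ror_stats(tabs), prr_stats(tabs),
               bcpnn_ic(tabs, method = ic_method))
  N <- res$a + res$b + res$c + res$d
  res$E <- (res$a + res$b) * (res$a + res$c) / N
  eb <- ebgm_stats(res$a, res$E, prior)
  res$ebgm <- eb$ebgm
  res$ebgm05 <- eb$ebgm05
  res$p_raw <- contingency_pvalue(res$a, res$b, res$c, res$d)
  res$p_adj <- bonferroni_adjust(res$p_raw, m = nrow(res))
  res <- cbind(res, consensus_signal(res, thresholds))
  if (!is.null(pt_soc)) {
    map <- data.table::as.data.table(pt_soc)
    res$soc <- map$soc[match(tolower(trimws(res$pt)), tolower(trimws(map$pt)))]
  }
  if (!is.null(ime_terms) || !is.null(dme_terms) || !is.null(label_terms)) {
    res <- suppressWarnings(
      annotate_signals(res, ime_terms, dme_terms, label_terms))
  }
  data.table::setorderv(res, c("a", "pt"), order = c(-1L, 1L))
  data.table::setattr(res, "mgps_prior", prior)
  res[]
}

# Per (drug, PT) report counts and expected counts over the whole universe,
# the fitting set for the MGPS prior (shrinkage is designed for the full
# drug-event matrix, not a single cohort).
universe_pair_counts <- function(universe) {
  drug <- universe$tables$drug
  reac <- universe$tables$reac
  dd <- unique(data.table::data.table(PRIMARYID = drug$PRIMARYID,
                                      drug = normalize_term(drug$DRUGNAME)))
  rr <- unique(data.table::data.table(PRIMARYID = reac$PRIMARYID,
                                      pt = tolower(trimws(reac$PT))))
  N <- nrow(universe$tables$demo)
  n_drug <- dd[, list(n_drug = .N), by = "drug"]
  n_pt <- rr[, list(n_pt = .N), by = "pt"]
  pairs <- merge(dd, rr, by = "PRIMARYID", allow.cartesian = TRUE)
  pairs <- pairs[, list(a = .N), by = c("drug", "pt")]
  pairs <- merge(pairs, n_drug, by = "drug")
  pairs <- merge(pairs, n_pt, by = "pt")
  pairs$E <- pairs$n_drug * pairs$n_pt / N
  pairs[]
}
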