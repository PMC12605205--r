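---
title: "Spontaneous-report signal detection and mortality risk modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spontaneous-report signal detection and mortality risk modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`faerspv` implements the analysis pipeline of a FAERS-style pharmacovigilance
study of a two-drug immunotherapy combination (durvalumab plus tremelimumab)
in hepatocellular carcinoma: cohort extraction from quarterly ASCII tables,
four-algorithm disproportionality screening, time-to-onset (TTO) modelling,
and a LASSO-Cox risk score for drug-related mortality. Because the live FAERS
database cannot ship with a package, a synthetic generator with a
planted-truth ledger stands in for it; every stage is tested against either
closed-form oracles or that ledger.

## Report universe and cohort

FAERS distributes one row per *report version* (`PRIMARYID`) of a *case*
(`CASEID`). All counting here is at the deduplicated case level: for each
case the version with the latest FDA receipt date is kept, ties broken
toward the largest `PRIMARYID`. The cited FDA practice does not pin down the
tie-break; latest-date-then-largest-id is the community convention and is
fixed here so the operation is deterministic and idempotent.

Drug matching is deliberately not fuzzy in the edit-distance sense: names
are lower-cased, stripped of non-alphanumerics, and compared by substring.
This makes "IMFINZI." match "imfinzi" while remaining fully auditable. A
case enters the combination cohort only if **every** required agent matches
in an allowed role; the default accepts primary suspect, secondary suspect,
concomitant and interacting roles (the inclusive mode), and `roles = "PS"`
gives the stricter primary-suspect-only cohort. The indication filter is an
exact case-insensitive match on `INDI_PT`.

Ages are normalised to years (`DEC` ×10, `YR` ×1, `MON` ÷12, `WK` ÷52,
`DY` ÷365, `HR` ÷8760); values above 120 years are treated as data errors
and set to missing. Partial dates (YYYYMM, YYYY) are representable and
flagged; the TTO stage excludes anything coarser than day precision unless
month-precision imputation (day 15) is explicitly enabled — onset estimates
from imprecise dates would otherwise masquerade as observed day counts.

One open point is the denominator universe for disproportionality: the full
deduplicated database versus only reports with a usable PT. The package uses
the full deduplicated universe; in practice almost every report carries at
least one PT, so the difference is negligible, and the full universe keeps
the margins of the 2×2 tables interpretable as report counts.

## Disproportionality statistics

All four algorithms operate on the same report-level 2×2 table for a
drug–event pair — `a` cohort reports with the PT, `b` without, `c`/`d` the
same split outside the cohort, `N = a+b+c+d`, `E = (a+b)(a+c)/N`:

* **ROR** `= ad/bc`, CI `exp(log ROR ± 1.96·√(1/a+1/b+1/c+1/d))`;
* **PRR** `= [a/(a+b)]/[c/(c+d)]`, CI analogous, plus the Yates-corrected
  chi-square `N(|ad−bc|−N/2)² / [(a+b)(c+d)(a+c)(b+d)]`;
* **BCPNN information component** `IC = log2[(a+0.5)/(E+0.5)]`. Two lower
  bounds are implemented: the exact 2.5% quantile of the gamma posterior
  `Ga(a+0.5, rate E+0.5)` of the observed-to-expected ratio (the Norén
  credibility interval, the default) and the classical closed-form
  approximation `IC − 3.3(a+0.5)^(−1/2) − 2(a+0.5)^(−3/2)`. The two differ
  by a few hundredths of a log2 unit at moderate counts;
* **MGPS**: the DuMouchel gamma-Poisson shrinker. The relative reporting
  rate has a two-component gamma mixture prior fitted by maximising the
  negative-binomial mixture marginal likelihood over all drug–event pairs of
  the **universe** (not the cohort alone — shrinkage is designed for the
  full drug-event matrix), by bounded quasi-Newton from the canonical start
  (0.2, 0.1, 2, 4, 1/3) with multi-start fallback. `EBGM` is the posterior
  geometric mean (digamma closed form); `EBGM05` the posterior 5th
  percentile by bisection on the mixture CDF. On data simulated under exact
  independence the fitted prior legitimately degenerates toward a point mass
  at 1 (the truth); the optimiser is box-bounded so this stays numerically
  stable.

Zero cells: when `a ≥ 1` and exactly one of `b, c, d` is zero, the
Haldane–Anscombe +0.5 is added to all cells; `a = 0` or several zero cells
yield flagged `NA` statistics — never silent infinities, and an undefined
statistic votes *negative* in the consensus.

Per-PT p-values are Yates-corrected chi-square, switching to Fisher's exact
test when any expected cell is below 5 (the source study names only the
Bonferroni correction; a per-PT p is implied by its volcano plot).
Bonferroni uses `m =` number of PTs tested in the cohort. A **consensus
signal** requires all four algorithms at the standard published thresholds
(ROR: `a ≥ 3` and CI lower bound > 1; PRR: `a ≥ 3`, `PRR ≥ 2`, chi-square
≥ 4; `IC025 > 0`; `EBGM05 ≥ 2`); every threshold is a configurable
parameter of `signal_thresholds()`. IME/DME/label-term annotation is exact
case-insensitive PT matching against user-supplied lists — the EMA lists and
package inserts are licensed/owned elsewhere and are consumed as files,
never redistributed.

## Time to onset

TTO is `EVENT_DT − START_DT` in days, with the earliest start across the
suspect agents' therapy rows. Zero-day onsets are real (event on the start
date): they stay intact for binning (`[0,30)`, `[30,60)`, `[60,90)`,
`[90,180)`, `[180,365)`, `[365,∞)`) and are shifted by +0.5 day only inside
the Weibull likelihood, which requires positive support. The median's 95% CI
is the distribution-free binomial order-statistic interval.

Onsets in a spontaneous-report database are all observed (a report exists
because the event happened), so the Kaplan–Meier estimate is the complement
of the empirical cumulative incidence and the log-rank test (unweighted
Mantel–Haenszel) compares strata. Reports and patients differ (a patient
can carry several PTs): distribution summaries are AE-level, KM/log-rank is
patient-level on the first event, and both views are exported.

Weibull fits use the accelerated-failure-time parameterisation
(`survreg`); the shape is `1/σ` and its CI comes from the observed
information of `log σ`, delta-method back-transformed, so the interval is
always positive. Hazard classes follow the usual shape rule — CI entirely
below 1: early failure (decreasing risk); CI containing 1: random failure;
CI entirely above 1: wear-out failure (increasing risk). Per-PT fits
require n ≥ 10; smaller PTs are reported as insufficient rather than
fitted.

## Mortality risk model

One survival record per case: time from therapy start to the fatal AE onset
(`EVENT_DT` of reports whose outcome codes include `DE`), with non-fatal
reports censored at their recorded AE onset — FAERS has no follow-up beyond
the report, so this administrative censoring is the only defensible scheme.
Candidates are sex, age (continuous by default) and indicators of
consensus-positive PTs present in at least 2 complete cases; a singleton
indicator cannot support a coefficient, so the floor defaults to 2 and is
exposed as a parameter. Selection is
L1-penalised Cox over `glmnet`'s λ grid with 10-fold cross-validated
partial-likelihood deviance at a recorded fold seed, taking `lambda.min`
(the deviance minimiser, matching the published optimal-λ choice).
Selected variables enter an unpenalised Cox fit (Efron ties, Wald
inference, no further multiplicity adjustment — the source reports raw Wald
p). The risk score is the coefficient-weighted indicator sum over the final
model; groups split at the median with ties to low; discrimination uses the
cumulative-case/dynamic-control AUC with inverse-probability-of-censoring
weights (weights `1/G(T−)` for cases, `1/G(τ)` for controls, `G` the KM
estimate of the censoring distribution) at 30/60/90 days. With no censoring
before the horizon this reduces exactly to the pairwise empirical AUC,
which is how it is tested.

## The synthetic generator

`synth_config()` defaults *are* the emulated study conditions: 715 cohort
reports over a 20,000-report background; demographic marginals copied from
the published Table-1 proportions (including its missingness: ~41% missing
sex, ~36% missing age); ~12% missing event dates, 5% month-precision events
and 15% missing therapy starts; a 10% duplicate-report rate; reporting
ratios for twelve planted PTs in the range of the published top-20 signals;
the three published onset-time shapes (0.41/1.32/1.97 on enterocolitis,
drug-induced liver injury and liver disorder) with a default
Weibull(1.1, 42 days) elsewhere, chosen so the cohort's overall median TTO
lands near the observed ~25 days; and the six published mortality
log-hazards (2.5828 … 1.5122) over an exponential baseline of
0.005/day with 365-day administrative censoring, calibrated a priori so the
fatal share of cohort reports approximates the observed ~26%.

Mechanics worth knowing when interpreting tests:

* Each report draws 1–5 PTs (truncated Poisson); the 2×2 unit is the
  report, so a PT counts once per report however often it is listed.
* Planted PTs get their draw probability multiplied by λ and the remaining
  probability mass is rescaled over the unplanted terms, so the planted
  cohort-to-background reporting ratio *is* λ; a boost pushing total mass
  past 1 is a hard error.
* The onset model of a report anchors to its first listed PT that carries
  an explicit Weibull model (else the first PT); the fatal process competes
  with that onset — death before the non-fatal onset (and within the
  window) yields outcome `DE` with `EVENT_DT` at the sampled death time.
  Consequently the per-PT onset samples of a PT that is *also* a mortality
  risk factor are contaminated by early exponential death times; at the
  default cohort size this can soften an early-failure call toward
  random-failure for the enterocolitis shape. That is a property of the
  emulated reporting process, not of the estimator, and the estimator-level
  tests therefore check shape recovery on clean Weibull draws separately.
* Duplicates are extra report versions with strictly earlier FDA dates, so
  deduplication provably restores the planted case count.

What the generator does **not** emulate: reporting dynamics (stimulated
reporting, seasonality), drug–event dependence in the background (pairs are
independent given the margins, which makes the fitted MGPS prior tighter
than on real FAERS), name misspellings beyond punctuation/case variants,
and free-text fields. Green tests on synthetic data therefore demonstrate
correctness of the estimators and plumbing under a known truth — not that
real-FAERS effect sizes will be reproduced.

## Problem sizes and numerical choices

The test suite and the analysis drivers run the full pipeline at a
20,000-report background, property checks at up to 100,000 background
reports, the null false-positive study over 10,000 simulated PTs, and the
six-factor selection study over 50 seeds at 700 complete cases (~180–200
events) — sizes chosen to exercise every code path at desk scale. The
mortality-recovery condition uses complete demographic documentation
because selection operates on complete cases only; under the observed
Table-1 missingness the design shrinks to ~200 cases and only the strongest
factors survive, which `analysis/05_mortality.R` demonstrates side by side.

Numerical details: all 2×2 arithmetic is done in double precision (case
counts times database margins overflow 32-bit integers); Fisher p-values
are clamped to [0, 1] against floating drift; the EBGM05 bisection runs 70
halvings between the component gamma quantiles, giving ~1e-12 relative
precision; the MGPS optimiser works on log/logit-transformed parameters in
a [−10, 10] box; `cv.glmnet` folds are assigned from a recorded seed so
every selection is reproducible.

## Known limitations

* The MGPS prior fit can sit at the box bound on exactly-independent
  synthetic data (a point-mass prior is the truth there); on real FAERS-like
  heterogeneous data it is interior.
* The IPCW AUC uses a single KM censoring estimate (no covariate-dependent
  censoring model).
* No stratified or interaction disproportionality (age/sex-stratified MGPS,
  multi-drug Ω shrinkage), no interval-censored TTO likelihoods, no
  competing-risk mortality model, and no external validation of the risk
  score — mirroring the scope of the emulated study.
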