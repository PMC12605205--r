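# Synthetic FAERS generator: determinism, bookkeeping, planted structure.

test_that("identical seeds give bit-identical output", {
  cfg <- synth_config(n_background_reports = 500, n_cohort_reports = 100)
  a <- synth_generate(cfg, seed = 11)
  b <- synth_generate(cfg, seed = 11)
  for (nm in names(a$raw$tables)) {
    expect_equal(as.data.frame(a$raw$tables[[nm]]),
                 as.data.frame(b$raw$tables[[nm]]), label = nm)
  }
  expect_equal(unclass(a$truth), unclass(b$truth))
  c_ <- synth_generate(cfg, seed = 12)
  expect_false(identical(a$raw$tables$demo, c_$raw$tables$demo))
})

test_that("duplicate injection books exactly as planted", {
  cfg <- synth_config(n_background_reports = 800, n_cohort_reports = 200,
                      duplicate_rate = 0.1)
  sim <- synth_generate(cfg, seed = 3)
  expect_equal(nrow(sim$raw$tables$demo), 1100L)
  expect_equal(truth_ledger(sim$truth, "n_duplicates"), 100)
  dedup <- deduplicate_cases(sim$raw)
  expect_equal(n_cases(dedup), 1000L)
  expect_equal(dedup$n_duplicates_removed, 100L)
})

test_that("cohort filters recover exactly the planted combination cases", {
  cfg <- synth_config(n_background_reports = 3000, n_cohort_reports = 250)
  sim <- synth_generate(cfg, seed = 21)
  uni <- deduplicate_cases(sim$raw)
  co <- filter_indication(
    match_drug(uni, list(c("durvalumab", "imfinzi"),
                         c("tremelimumab", "imjudo"))),
    "hepatocellular carcinoma")
  expect_equal(n_cases(co), 250L)
  expect_setequal(co$tables$demo$CASEID,
                  truth_ledger(sim$truth, "cohort_caseids"))
})

test_that("the truth ledger exposes planted values and survives JSON round-trip", {
  cfg <- synth_config(n_background_reports = 200, n_cohort_reports = 100)
  sim <- synth_generate(cfg, seed = 5)
  lam <- truth_ledger(sim$truth, "lambda")
  expect_equal(lam[["immune-mediated enterocolitis"]], 28)
  expect_true(all(names(lam) %in% cfg$pt_vocabulary$pt))
  expect_error(truth_ledger(sim$truth, "nonsense"), "unknown")
  path <- withr::local_tempfile(fileext = ".json")
  truth_save(sim$truth, path)
  back <- truth_load(path)
  expect_equal(back$lambda, sim$truth$lambda)
  expect_equal(back$cox_coefficients, sim$truth$cox_coefficients)
  expect_equal(back$n_cohort, sim$truth$n_cohort)
})

test_that("an infeasible reporting-ratio boost is a hard error", {
  vocab <- default_pt_vocabulary()
  expect_error(
    synth_generate(synth_config(
      n_background_reports = 10, n_cohort_reports = 10,
      planted_signals = c(nausea = 2000))),
    "infeasible renormalization")
})

test_that("the empirical reporting ratio of a planted PT converges to lambda", {
  cfg <- synth_config(n_background_reports = 1e5, n_cohort_reports = 3000)
  sim <- synth_generate(cfg, seed = 77)
  uni <- deduplicate_cases(sim$raw)
  co <- filter_indication(
    match_drug(uni, list(c("durvalumab", "imfinzi"),
                         c("tremelimumab", "imjudo"))),
    "hepatocellular carcinoma")
  tabs <- faerspv:::build_contingency_all(co, uni)
  for (ptn in c("liver disorder", "immune-mediated enterocolitis")) {
    row <- tabs[tolower(tabs$pt) == ptn]
    prr <- (row$a / (row$a + row$b)) / (row$c / (row$c + row$d))
    lambda <- truth_ledger(sim$truth, "lambda")[[ptn]]
    expect_lt(abs(prr - lambda) / lambda, 0.15)
  }
})

test_that("generated onset times reproduce the planted Weibull median", {
  # isolate the onset process: no planted signals, negligible fatal hazard
  cfg <- synth_config(
    n_background_reports = 0, n_cohort_reports = 500,
    planted_signals = NULL,
    mortality = list(baseline_hazard = 1e-9,
                     coefficients = published_risk_coefficients(),
                     censor_day = 365),
    missingness = c(event_dt = 0, start_dt = 0, event_month_prec = 0),
    duplicate_rate = 0)
  sim <- synth_generate(cfg, seed = 9)
  co <- deduplicate_cases(sim$raw)
  tto <- compute_tto(co)
  first <- tto[, list(t = tto_days[1]), by = "caseid"]
  km <- km_curve(first$t)
  km_median <- unname(summary(km$fit)$table["median"])
  closed_form <- 42 * log(2)^(1 / 1.1)
  expect_lt(abs(km_median - closed_form) / closed_form, 0.10)
})

test_that("an all-null universe yields no consensus signals", {
  cfg <- synth_config(n_background_reports = 8000, n_cohort_reports = 400,
                      planted_signals = NULL)
  sim <- synth_generate(cfg, seed = 31)
  uni <- deduplicate_cases(sim$raw)
  co <- filter_indication(
    match_drug(uni, list(c("durvalumab", "imfinzi"),
                         c("tremelimumab", "imjudo"))),
    "hepatocellular carcinoma")
  sig <- detect_signals(co, uni)
  expect_equal(sum(sig$consensus), 0L)
})

test_that("written quarters can be re-read and analysed identically", {
  dir <- withr::local_tempdir()
  cfg <- synth_config(n_background_reports = 400, n_cohort_reports = 80)
  sim <- synth_generate(cfg, seed = 13)
  paths <- write_faers_tables(sim$raw, dir)
  back <- read_faers_quarter(paths)
  expect_equal(unname(back$row_counts), unname(sim$raw$row_counts))
  a <- deduplicate_cases(sim$raw)
  b <- deduplicate_cases(back)
  expect_setequal(a$tables$demo$PRIMARYID, b$tables$demo$PRIMARYID)
  expect_equal(data.table::setorder(data.table::copy(a$cases), caseid),
               data.table::setorder(data.table::copy(b$cases), caseid))
})
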