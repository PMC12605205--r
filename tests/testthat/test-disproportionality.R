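# 2x2 construction and the four screening statistics against independent
# oracles (hand evaluation, base-R chi-square, closed forms).

ct <- function(a, b, c, d) faerspv:::new_contingency(a, b, c, d)

test_that("contingency counting matches the brute-force oracle", {
  # universe of 100 reports, cohort of 10, PT on 4 cohort + 6 outside
  spec <- data.frame(
    caseid = 1:100,
    drug = c(rep("targetdrug", 10), rep("otherdrug", 90)),
    pts = c(rep("Headache;Nausea", 4), rep("Nausea", 6),
            rep("Headache", 6), rep("Fatigue", 84)),
    stringsAsFactors = FALSE)
  uni <- cases_from_spec(spec)
  co <- match_drug(uni, list("targetdrug"))
  t1 <- build_contingency(co, uni, "Headache")
  expect_equal(c(t1$a, t1$b, t1$c, t1$d), c(4, 6, 6, 84))
  expect_equal(t1$N, 100)
  expect_equal(t1$E, 10 * 10 / 100)
  # PT absent everywhere
  t0 <- build_contingency(co, uni, "Vertigo")
  expect_equal(c(t0$a, t0$b, t0$c, t0$d), c(0, 10, 0, 90))
  # a sums over PTs to at least the number of cohort reports with any PT
  tabs <- faerspv:::build_contingency_all(co, uni)
  expect_gte(sum(tabs$a), 10)
  # cohort must be a subset of the universe
  expect_error(build_contingency(uni, co, "Headache"), "subset")
  # a null report increments only d and moves E
  spec2 <- rbind(spec, data.frame(caseid = 101, drug = "thirddrug",
                                  pts = "Chills"))
  uni2 <- cases_from_spec(spec2)
  t2 <- build_contingency(match_drug(uni2, list("targetdrug")), uni2, "Headache")
  expect_equal(c(t2$a, t2$b, t2$c, t2$d), c(4, 6, 6, 85))
  expect_lt(t2$E, t1$E)
})

test_that("ROR matches hand evaluation and its null symmetry", {
  r <- ror_stats(ct(10, 90, 100, 9900))
  expect_equal(r$ror, 11.0)
  # frozen from independent evaluation of the closed form:
  # exp(log(11) +/- 1.96 sqrt(1/10 + 1/90 + 1/100 + 1/9900))
  expect_equal(r$ror_lo, 5.559515, tolerance = 1e-6)
  expect_equal(r$ror_hi, 21.764489, tolerance = 1e-6)
  expect_equal(ror_stats(ct(5, 50, 10, 100))$ror, 1.0)
})

test_that("PRR and Yates chi-square match hand and stats-library oracles", {
  p <- prr_stats(ct(10, 90, 100, 9900))
  expect_equal(p$prr, 10.0)
  oracle <- suppressWarnings(chisq.test(matrix(c(10, 90, 100, 9900), 2, byrow = TRUE),
                       correct = TRUE))
  expect_equal(p$chi2, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(prr_stats(ct(5, 50, 10, 100))$prr, 1.0)
  # p-value route agrees with the chi-square oracle when expected cells are
  # large, and with Fisher when they are small
  big <- chisq.test(matrix(c(30, 970, 100, 9900), 2, byrow = TRUE),
                    correct = TRUE)
  expect_equal(faerspv:::contingency_pvalue(30, 970, 100, 9900),
               big$p.value, tolerance = 1e-10)
  expect_equal(faerspv:::contingency_pvalue(10, 90, 100, 9900),
               fisher.test(matrix(c(10, 90, 100, 9900), 2, byrow = TRUE))$p.value,
               tolerance = 1e-10)
  # small expected cells switch to Fisher
  f <- fisher.test(matrix(c(2, 8, 3, 9987), 2, byrow = TRUE))
  expect_equal(faerspv:::contingency_pvalue(2, 8, 3, 9987), f$p.value)
})

test_that("zero cells are continuity-adjusted or flagged, never infinite", {
  r <- ror_stats(ct(3, 0, 5, 100))     # one zero cell, a >= 1: +0.5 everywhere
  expect_equal(r$ror, (3.5 * 100.5) / (0.5 * 5.5))
  expect_true(is.finite(r$ror_hi))
  expect_true(is.na(ror_stats(ct(0, 10, 5, 100))$ror))     # a = 0: undefined
  expect_true(is.na(ror_stats(ct(2, 0, 0, 100))$ror))      # two zero cells
  expect_true(is.na(prr_stats(ct(0, 10, 5, 100))$prr))
})

test_that("information component matches hand evaluation and bounds", {
  # a = E gives IC = 0 exactly
  expect_equal(bcpnn_ic(ct(4, 6, 36, 54))$ic, 0)
  b <- bcpnn_ic(ct(10, 90, 100, 9900))
  expect_equal(b$ic, 2.724099, tolerance = 1e-6)
  # frozen gamma-quantile lower bound (Noren interval)
  expect_equal(b$ic025, 1.693957, tolerance = 1e-5)
  apx <- bcpnn_ic(ct(10, 90, 100, 9900), method = "approx")
  expect_equal(apx$ic025, 2.724099 - 3.3 / sqrt(10.5) - 2 * 10.5^-1.5,
               tolerance = 1e-6)
  # lower quantile sits below the point estimate for all tables with a >= 1
  set.seed(4)
  for (i in 1:50) {
    tt <- ct(sample(1:50, 1), sample(0:200, 1), sample(0:200, 1),
             sample(10:5000, 1))
    bb <- bcpnn_ic(tt)
    expect_lt(bb$ic025, bb$ic)
  }
})

test_that("ROR and PRR sit on the same side of 1 (algebraic identity)", {
  set.seed(7)
  for (i in 1:200) {
    a <- sample(1:40, 1); b <- sample(1:400, 1)
    c_ <- sample(1:400, 1); d <- sample(1:9000, 1)
    r <- ror_stats(ct(a, b, c_, d))$ror
    p <- prr_stats(ct(a, b, c_, d))$prr
    expect_equal(sign(r - p), sign(r - 1), label = sprintf("(%d,%d,%d,%d)", a, b, c_, d))
  }
})

test_that("Bonferroni correction caps at 1 and preserves ranking", {
  expect_equal(bonferroni_adjust(0.001, m = 50), 0.05)
  expect_equal(bonferroni_adjust(0.5, m = 10), 1.0)
  p <- c(0.001, 0.04, 0.2, 0.0005)
  adj <- bonferroni_adjust(p, m = 20)
  expect_equal(order(adj), order(p))
  expect_equal(adj, p.adjust(p, method = "bonferroni", n = 20))
})

test_that("consensus requires all four algorithms and a case-count floor", {
  rec <- data.frame(a = 2, ror_lo = 50, prr = 60, chi2 = 100, ic025 = 3,
                    ebgm05 = 10)
  v <- consensus_signal(rec)
  expect_false(v$consensus)   # a = 2 fails the count floor despite a huge ROR
  rec$a <- 3
  expect_true(consensus_signal(rec)$consensus)
  # an undefined statistic is a conservative FALSE
  rec$ror_lo <- NA_real_
  v2 <- consensus_signal(rec)
  expect_false(v2$pos_ror)
  expect_false(v2$consensus)
})

test_that("IME/DME/unexpected annotation flags by exact PT match", {
  rec <- data.frame(pt = c("Anaphylactic reaction", "Nausea", "Colitis"),
                    consensus = c(TRUE, TRUE, FALSE))
  out <- annotate_signals(rec,
                          ime_terms = c("anaphylactic reaction", "colitis"),
                          dme_terms = "Anaphylactic Reaction",
                          label_terms = "nausea")
  expect_equal(out$ime, c(TRUE, FALSE, TRUE))
  expect_equal(out$dme, c(TRUE, FALSE, FALSE))
  # unexpected = consensus AND not on the label
  expect_equal(out$unexpected, c(TRUE, FALSE, FALSE))
  w <- capture_warnings(annotate_signals(rec))
  expect_true(any(grepl("IME", w)) && any(grepl("DME", w)))
})
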