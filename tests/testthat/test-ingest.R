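# Reading, deduplication, cohort filters and the demographic summary.

test_that("quarter files round-trip through the $-delimited reader", {
  dir <- withr::local_tempdir()
  raw0 <- as_faers_tables(tiny_quarter_tables())
  paths <- write_faers_tables(raw0, dir)
  raw <- read_faers_quarter(paths)
  expect_equal(unname(raw$row_counts), unname(raw0$row_counts))
  demo <- raw$tables$demo
  # one blank EVENT_DT and one month-precision date survive as flagged values
  expect_equal(sum(is.na(demo$EVENT_DT)), 1L)
  expect_true(is.na(demo$EVENT_DT[demo$PRIMARYID == "100301"]))
  expect_equal(demo$EVENT_DT_PREC[demo$PRIMARYID == "100401"], "month")
  expect_equal(as.character(demo$EVENT_DT[demo$PRIMARYID == "100401"]),
               "2024-03-15")
  expect_true(all(raw$tables$drug$ROLE_COD %in% c("PS", "SS", "C", "I")))
})

test_that("missing mandatory columns and empty files are reported", {
  dir <- withr::local_tempdir()
  bad <- tiny_quarter_tables()
  bad$drug$ROLE_COD <- NULL
  write.table(bad$drug, file.path(dir, "DRUG.txt"), sep = "$",
              quote = FALSE, row.names = FALSE)
  expect_error(faerspv:::read_faers_table(file.path(dir, "DRUG.txt"), "drug"),
               "ROLE_COD")
  writeLines(character(0), file.path(dir, "REAC.txt"))
  w <- capture_warnings(
    empty <- faerspv:::read_faers_table(file.path(dir, "REAC.txt"), "reac"))
  expect_true(any(grepl("empty", w)))
  expect_equal(nrow(empty), 0L)
  expect_error(read_faers_quarter(c(demo = "x")), "mandatory table")
})

test_that("ages normalise across FAERS unit codes and implausible values drop", {
  expect_equal(normalize_age("72", "YR"), 72)
  expect_equal(normalize_age("6", "MON"), 0.5)
  expect_equal(normalize_age(c("7.2", "730", "52", "8760"),
                             c("DEC", "DY", "WK", "HR")),
               c(72, 2, 1, 1))
  expect_true(is.na(normalize_age("130", "YR")))
  expect_true(is.na(normalize_age("abc", "YR")))
  expect_equal(as.character(age_group(c(5, 18, 64, 65, 80, NA))),
               c("<18", "18-64", "18-64", "65-79", ">=80", "missing"))
})

test_that("deduplication keeps the latest report version per case", {
  cases <- tiny_cases()
  # caseid 1001 has versions at 20240101 and 20240301: the later one stays
  expect_equal(n_cases(cases), 6L)
  expect_true("100102" %in% cases$tables$demo$PRIMARYID)
  expect_false("100101" %in% cases$tables$demo$PRIMARYID)
  # child rows of the dropped version are dropped with it
  expect_false("100101" %in% cases$tables$drug$PRIMARYID)
  expect_equal(cases$n_duplicates_removed, 1L)
  # idempotence
  again <- deduplicate_cases(cases)
  expect_equal(sort(again$tables$demo$PRIMARYID),
               sort(cases$tables$demo$PRIMARYID))
  expect_equal(again$n_duplicates_removed, 0L)
})

test_that("FDA_DT ties break toward the largest primaryid", {
  demo <- data.frame(PRIMARYID = c("51", "502"), CASEID = c("9", "9"),
                     FDA_DT = c("20240101", "20240101"), EVENT_DT = "",
                     stringsAsFactors = FALSE)
  cases <- deduplicate_cases(as_faers_tables(list(
    demo = demo,
    drug = data.frame(PRIMARYID = "51", DRUGNAME = "x", ROLE_COD = "PS"),
    reac = data.frame(PRIMARYID = "51", PT = "Nausea"))))
  expect_equal(cases$tables$demo$PRIMARYID, "502")
})

test_that("drug matching is case/punctuation-insensitive and requires every agent", {
  cases <- tiny_cases()
  combo <- match_drug(cases, list(c("durvalumab", "imfinzi"),
                                  c("tremelimumab", "imjudo")))
  # 1001 (IMFINZI./Imjudo), 1002 (durvalumab/TREMELIMUMAB SS), 1005 match;
  # 1003 has durvalumab only and is excluded from the combination cohort
  expect_setequal(combo$tables$demo$CASEID, c("1001", "1002", "1005"))
  strict <- match_drug(cases, list(c("durvalumab", "imfinzi"),
                                   c("tremelimumab", "imjudo")),
                       roles = "PS")
  # 1002 lists tremelimumab as secondary suspect only
  expect_setequal(strict$tables$demo$CASEID, c("1001", "1005"))
  expect_warning(match_drug(cases, list("nonexistentdrug")), "empty cohort")
})

test_that("indication filter keeps exact case-insensitive matches only", {
  cases <- tiny_cases()
  hcc <- filter_indication(cases, "hepatocellular carcinoma")
  expect_setequal(hcc$tables$demo$CASEID, c("1001", "1002", "1003", "1005"))
  # filters commute
  a <- filter_indication(match_drug(cases, list(c("imfinzi", "durvalumab"),
                                                c("imjudo", "tremelimumab"))),
                         "hepatocellular carcinoma")
  b <- match_drug(filter_indication(cases, "hepatocellular carcinoma"),
                  list(c("imfinzi", "durvalumab"), c("imjudo", "tremelimumab")))
  expect_setequal(a$tables$demo$CASEID, b$tables$demo$CASEID)
})

test_that("demographic summary reproduces the published marginal arithmetic", {
  demog <- summarize_demographics(table1_cases())
  male <- demog[demog$block == "Sex" & demog$category == "Male"]
  expect_equal(male$n, 348L)
  expect_equal(round(male$pct, 1), 48.7)
  expect_equal(attr(demog, "total_serious"), 634L)
  expect_equal(round(attr(demog, "total_serious_pct"), 1), 88.7)
  death <- demog[demog$block == "Serious outcome" & demog$category == "Death"]
  expect_equal(round(death$pct, 1), 26.4)
  # exclusive blocks sum to 100% up to rounding
  for (bl in c("Sex", "Age", "Occupation reporter", "Reporting country",
               "Reporting year")) {
    expect_equal(sum(demog$pct[demog$block == bl]), 100, tolerance = 1e-6)
  }
  ctry <- demog[demog$block == "Reporting country"]
  expect_equal(ctry$n[ctry$category == "Other countries"], 79L)
})

test_that("a report counts once per distinct serious-outcome category", {
  cases <- tiny_cases()
  demog <- summarize_demographics(cases)
  so <- demog[demog$block == "Serious outcome"]
  # case 1002 has HO+LT (counts once in each), 1001 DE, 1005 HO; 3 missing
  expect_equal(so$n[so$category == "Death"], 1L)
  expect_equal(so$n[so$category == "Hospitalization"], 2L)
  expect_equal(so$n[so$category == "Life-threatening events"], 1L)
  expect_equal(so$n[so$category == "Missing"], 3L)
  expect_equal(attr(demog, "total_serious"), 4L)
})
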