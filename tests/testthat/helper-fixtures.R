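# Shared in-code fixtures: no files on disk, everything built programmatically.

# A hand-sized quarter: 6 cases (one with a duplicate report version),
# two combination-cohort cases, one durvalumab-only case, partial dates.
tiny_quarter_tables <- function() {
  demo <- data.frame(
    PRIMARYID = c("100101", "100102", "100201", "100301", "100401", "100501", "100601"),
    CASEID    = c("1001",   "1001",   "1002",   "1003",   "1004",   "1005",   "1006"),
    FDA_DT    = c("20240101", "20240301", "20240210", "20240215", "20240310", "202402", "20240401"),
    EVENT_DT  = c("20240120", "20240126", "20240215", "",         "202403",   "20240215", "20240310"),
    SEX       = c("M", "M", "F", "", "M", "F", "M"),
    AGE       = c("72", "72", "6",  "81", "55", "", "40"),
    AGE_COD   = c("YR", "YR", "MON", "YR", "YR", "", "YR"),
    OCCP_COD  = c("MD", "MD", "PH", "CN", "MD", "OT", "MD"),
    REPORTER_COUNTRY = c("JP", "JP", "US", "FR", "JP", "JP", "US"),
    stringsAsFactors = FALSE
  )
  drug <- data.frame(
    PRIMARYID = c("100101", "100101", "100102", "100102", "100201", "100201",
                  "100301", "100401", "100401", "100501", "100501", "100601"),
    DRUG_SEQ  = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 1L, 2L, 1L, 2L, 1L),
    ROLE_COD  = c("PS", "PS", "PS", "PS", "PS", "SS", "PS", "PS", "C", "PS", "PS", "PS"),
    DRUGNAME  = c("IMFINZI.", "Imjudo", "IMFINZI.", "Imjudo", "durvalumab",
                  "TREMELIMUMAB", "DURVALUMAB", "sorafenib", "aspirin",
                  "Imfinzi", "imjudo", "lenvatinib"),
    stringsAsFactors = FALSE
  )
  reac <- data.frame(
    PRIMARYID = c("100101", "100102", "100102", "100201", "100301", "100401",
                  "100501", "100601"),
    PT = c("Colitis", "Colitis", "Pyrexia", "Immune-mediated enterocolitis",
           "Nausea", "Nausea", "Liver disorder", "Diarrhoea"),
    stringsAsFactors = FALSE
  )
  outc <- data.frame(
    PRIMARYID = c("100102", "100201", "100201", "100501"),
    OUTC_COD  = c("DE", "HO", "LT", "HO"),
    stringsAsFactors = FALSE
  )
  ther <- data.frame(
    PRIMARYID = c("100101", "100102", "100102", "100201", "100401", "100501"),
    DSG_DRUG_SEQ = c(1L, 1L, 2L, 1L, 1L, 1L),
    START_DT  = c("20240101", "20240101", "20240103", "20240120", "20240201", "202401"),
    stringsAsFactors = FALSE
  )
  indi <- data.frame(
    PRIMARYID = c("100101", "100102", "100201", "100301", "100401", "100501", "100601"),
    INDI_DRUG_SEQ = 1L,
    INDI_PT = c("Hepatocellular carcinoma", "Hepatocellular carcinoma",
                "HEPATOCELLULAR CARCINOMA", "Hepatocellular carcinoma",
                "Hypertension", "hepatocellular carcinoma", "Gastric cancer"),
    stringsAsFactors = FALSE
  )
  list(demo = demo, drug = drug, reac = reac, outc = outc, ther = ther,
       indi = indi)
}

tiny_cases <- function() {
  deduplicate_cases(as_faers_tables(tiny_quarter_tables()))
}

# Case set whose marginals reproduce the published demographic table exactly:
# disjoint serious-outcome assignment (189 + 1 + 193 + 75 + 176 + 81 = 715).
table1_cases <- function() {
  n <- 715
  rep_cat <- function(counts) {
    nm <- names(counts)
    nm[nm == "blank"] <- ""
    rep(nm, counts)
  }
  demo <- data.frame(
    PRIMARYID = as.character(1e6 + seq_len(n)),
    CASEID = as.character(2e6 + seq_len(n)),
    FDA_DT = paste0(rep_cat(c("2020" = 52, "2021" = 2, "2022" = 3,
                              "2023" = 168, "2024" = 490)), "0615"),
    EVENT_DT = "",
    SEX = rep_cat(c(F = 75, M = 348, blank = 292)),
    AGE = rep_cat(c("10" = 15, "40" = 96, "70" = 244, "85" = 103, blank = 257)),
    AGE_COD = "YR",
    OCCP_COD = rep_cat(c(MD = 656, PH = 17, OT = 23, CN = 7, blank = 12)),
    REPORTER_COUNTRY = rep_cat(c(JP = 510, US = 65, FR = 38, CN = 12, CA = 11,
                                 GB = 10, DE = 10, IT = 10, KR = 10, ES = 10,
                                 AU = 10, NL = 10, SE = 9)),
    stringsAsFactors = FALSE
  )
  oc <- rep_cat(c(DE = 189, DS = 1, HO = 193, LT = 75, OT = 176, blank = 81))
  outc <- data.frame(PRIMARYID = demo$PRIMARYID[oc != ""],
                     OUTC_COD = oc[oc != ""], stringsAsFactors = FALSE)
  drug <- data.frame(PRIMARYID = demo$PRIMARYID, DRUG_SEQ = 1L,
                     ROLE_COD = "PS", DRUGNAME = "IMFINZI",
                     stringsAsFactors = FALSE)
  reac <- data.frame(PRIMARYID = demo$PRIMARYID, PT = "Nausea",
                     stringsAsFactors = FALSE)
  deduplicate_cases(as_faers_tables(list(demo = demo, drug = drug,
                                         reac = reac, outc = outc)))
}

# Build a deduplicated case universe from a per-report spec: data.frame with
# columns caseid, drug (one name), pts (list column or ';'-separated), used
# for counting oracles.
cases_from_spec <- function(df) {
  pts <- strsplit(df$pts, ";", fixed = TRUE)
  demo <- data.frame(PRIMARYID = as.character(df$caseid),
                     CASEID = as.character(df$caseid),
                     FDA_DT = "20240601", EVENT_DT = "20240601",
                     SEX = "M", AGE = "60", AGE_COD = "YR",
                     OCCP_COD = "MD", REPORTER_COUNTRY = "JP",
                     stringsAsFactors = FALSE)
  drug <- data.frame(PRIMARYID = as.character(rep(df$caseid, 1L)),
                     DRUG_SEQ = 1L, ROLE_COD = "PS", DRUGNAME = df$drug,
                     stringsAsFactors = FALSE)
  reac <- data.frame(PRIMARYID = as.character(rep(df$caseid, lengths(pts))),
                     PT = unlist(pts), stringsAsFactors = FALSE)
  indi <- data.frame(PRIMARYID = as.character(df$caseid), INDI_DRUG_SEQ = 1L,
                     INDI_PT = if (!is.null(df$indication)) df$indication else "x",
                     stringsAsFactors = FALSE)
  deduplicate_cases(as_faers_tables(list(demo = demo, drug = drug,
                                         reac = reac, indi = indi)))
}

# Canonical DuMouchel prior used where a fixed, non-degenerate prior is
# needed independently of any fit.
canonical_prior <- function() {
  structure(list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, w = 1 / 3,
                 loglik = NA_real_, convergence = 0L),
            class = "mgps_prior")
}

# Study-condition config for the mortality-recovery check: complete
# demographic documentation and follow-up (no missingness), cohort-only.
recovery_config <- function(n_cohort = 700) {
  synth_config(
    n_background_reports = 0,
    n_cohort_reports = n_cohort,
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
}
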