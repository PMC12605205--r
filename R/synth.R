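# Synthetic FAERS generator with a planted-truth ledger.
#
# Emulates the structure of FAERS quarterly ASCII data: a large background of
# spontaneous reports over a drug/event vocabulary, plus a combination-therapy
# cohort (both target agents + the target indication) whose event profile
# carries planted multiplicative reporting ratios, per-PT Weibull onset-time
# distributions, and a proportional-hazards fatal-outcome process. Every
# planted quantity is recorded in a truth ledger so downstream stages can be
# tested against known ground truth.

#' Default preferred-term vocabulary for the synthetic generator
#'
#' A mix of named immune-related and hepatic adverse-event terms (the ones
#' carrying planted structure) and generic background terms, each with a SOC
#' assignment and a baseline reporting probability (normalised to sum to 1).
#'
#' @param n_background_terms number of generic filler terms.
#' @return `data.table` with columns `pt`, `soc`, `base_prob`.
#' @export
default_pt_vocabulary <- function(n_background_terms = 80) {
  named <- data.table::data.table(
    pt = c("immune-mediated enterocolitis", "liver disorder",
           "immune-mediated hepatic disorder", "colitis",
           "liver carcinoma ruptured", "cytokine release syndrome",
           "immune-mediated dermatitis", "myocarditis",
           "immune-mediated myocarditis", "enterocolitis",
           "drug-induced liver injury", "immune thrombocytopenia",
           "multiple organ dysfunction syndrome", "anaphylactic reaction",
           "nausea", "diarrhoea", "fatigue", "pyrexia", "rash",
           "decreased appetite", "anaemia", "vomiting",
           "malignant neoplasm progression", "hepatic function abnormal",
           "pruritus", "headache", "dyspnoea", "oedema peripheral",
           "pneumonia", "acute kidney injury", "hypothyroidism",
           "constipation", "abdominal pain"),
    soc = c("Gastrointestinal disorders", "Hepatobiliary disorders",
            "Hepatobiliary disorders", "Gastrointestinal disorders",
            "Neoplasms benign, malignant and unspecified",
            "Immune system disorders",
            "Skin and subcutaneous tissue disorders", "Cardiac disorders",
            "Cardiac disorders", "Gastrointestinal disorders",
            "Hepatobiliary disorders", "Blood and lymphatic system disorders",
            "General disorders and administration site conditions",
            "Immune system disorders",
            "Gastrointestinal disorders", "Gastrointestinal disorders",
            "General disorders and administration site conditions",
            "General disorders and administration site conditions",
            "Skin and subcutaneous tissue disorders",
            "Metabolism and nutrition disorders",
            "Blood and lymphatic system disorders",
            "Gastrointestinal disorders",
            "Neoplasms benign, malignant and unspecified",
            "Hepatobiliary disorders",
            "Skin and subcutaneous tissue disorders",
            "Nervous system disorders",
            "Respiratory, thoracic and mediastinal disorders",
            "General disorders and administration site conditions",
            "Infections and infestations", "Renal and urinary disorders",
            "Endocrine disorders", "Gastrointestinal disorders",
            "Gastrointestinal disorders"),
    base_prob = c(0.0012, 0.0062, 0.0004, 0.0034,
                  0.0016, 0.0005,
                  0.0002, 0.0021,
                  0.0003, 0.0010,
                  0.0015, 0.0006,
                  0.0017, 0.0003,
                  0.050, 0.050, 0.040, 0.030, 0.030,
                  0.025, 0.025, 0.025,
                  0.020, 0.015,
                  0.015, 0.020, 0.020, 0.015,
                  0.015, 0.010, 0.010,
                  0.015, 0.015)
  )
  k <- n_background_terms
  filler <- data.table::data.table(
    pt = sprintf("background event %03d", seq_len(k)),
    soc = sprintf("Background SOC %02d", (seq_len(k) - 1L) %% 10L + 1L),
    base_prob = 1 / seq_len(k)   # Zipf-like tail
  )
  remaining <- 1 - sum(named$base_prob)
  filler$base_prob <- filler$base_prob / sum(filler$base_prob) * remaining
  rbind(named, filler)
}

#' Published risk-score coefficients for the combination-therapy HCC cohort
#'
#' The reported multivariable Cox log-hazard coefficients of the six
#' independent risk factors for drug-related mortality under durvalumab plus
#' tremelimumab in hepatocellular carcinoma. Used as the generator's planted
#' mortality model and as input to [risk_score()] worked examples.
#'
#' @return named numeric vector of log-hazard coefficients.
#' @export
published_risk_coefficients <- function() {
  c("immune thrombocytopenia" = 2.5828,
    "immune-mediated dermatitis" = 2.3273,
    "immune-mediated enterocolitis" = 1.1487,
    "immune-mediated myocarditis" = 1.8384,
    "multiple organ dysfunction syndrome" = 2.0168,
    "myocarditis" = 1.5122)
}

#' Build a synthetic-FAERS configuration
#'
#' Defaults mirror the observed study conditions of the combination-therapy
#' HCC cohort: 715 cohort reports, Table-1-style demographic marginals,
#' reporting ratios in the range of the published top signals, the three
#' published Weibull onset-time patterns, and the published mortality
#' log-hazards with a baseline hazard calibrated so that roughly a quarter of
#' cohort reports are fatal within the 365-day window.
#'
#' @param n_background_reports background (non-cohort) report count.
#' @param n_cohort_reports combination-cohort report count.
#' @param pt_vocabulary `data.table(pt, soc, base_prob)`.
#' @param planted_signals named numeric vector of multiplicative reporting
#'   ratios (lambda >= 1) per PT; `NULL` for an all-null universe.
#' @param tto_models named list of `c(shape, scale)` per PT plus a
#'   `.default` entry, in days.
#' @param mortality list with `baseline_hazard` (per day), `coefficients`
#'   (named log-hazards over risk-factor PTs) and `censor_day`.
#' @param demographics list of named probability vectors for `sex`,
#'   `age_group`, `occupation`, `country`, `year` (each summing to 1).
#' @param duplicate_rate fraction of cases receiving an extra (earlier)
#'   report version.
#' @param missingness named rates: `event_dt`, `start_dt`, `event_month_prec`
#'   (event date reported at month precision only).
#' @param mean_extra_pts mean of the (truncated) Poisson count of additional
#'   PTs per report beyond the first; at most 5 PTs per report.
#' @param background_fatal_rate fatal-outcome probability for background
#'   reports (not modelled, scenery only).
#' @param seed default RNG seed stored with the config.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_background_reports = 20000,
                         n_cohort_reports = 715,
                         pt_vocabulary = default_pt_vocabulary(),
                         planted_signals = c(
                           "immune-mediated enterocolitis" = 28,
                           "liver disorder" = 5.3,
                           "immune-mediated hepatic disorder" = 66,
                           "colitis" = 6.3,
                           "liver carcinoma ruptured" = 12,
                           "cytokine release syndrome" = 32,
                           "immune-mediated dermatitis" = 55,
                           "myocarditis" = 5.5,
                           "immune-mediated myocarditis" = 30,
                           "drug-induced liver injury" = 6.8,
                           "immune thrombocytopenia" = 15,
                           "multiple organ dysfunction syndrome" = 4.5),
                         tto_models = list(
                           "immune-mediated enterocolitis" = c(shape = 0.41, scale = 30),
                           "drug-induced liver injury" = c(shape = 1.32, scale = 40),
                           "liver disorder" = c(shape = 1.97, scale = 60),
                           ".default" = c(shape = 1.1, scale = 42)),
                         mortality = list(
                           baseline_hazard = 0.005,
                           coefficients = published_risk_coefficients(),
                           censor_day = 365),
                         demographics = list(
                           sex = c(F = 0.105, M = 0.487, missing = 0.408),
                           age_group = c("<18" = 0.021, "18-64" = 0.134,
                                         "65-79" = 0.341, ">=80" = 0.144,
                                         missing = 0.359),
                           occupation = c(MD = 0.917, PH = 0.024, OT = 0.032,
                                          CN = 0.010, missing = 0.017),
                           country = c(JP = 0.713, US = 0.091, FR = 0.053,
                                       CN = 0.017, CA = 0.015, other = 0.111),
                           year = c("2020" = 0.073, "2021" = 0.003,
                                    "2022" = 0.004, "2023" = 0.235,
                                    "2024" = 0.685)),
                         duplicate_rate = 0.10,
                         missingness = c(event_dt = 0.12, start_dt = 0.15,
                                         event_month_prec = 0.05),
                         mean_extra_pts = 0.7,
                         background_fatal_rate = 0.15,
                         seed = 20240101) {
  cfg <- list(n_background_reports = n_background_reports,
              n_cohort_reports = n_cohort_reports,
              pt_vocabulary = pt_vocabulary,
              planted_signals = planted_signals,
              tto_models = tto_models,
              mortality = mortality,
              demographics = demographics,
              duplicate_rate = duplicate_rate,
              missingness = missingness,
              mean_extra_pts = mean_extra_pts,
              background_fatal_rate = background_fatal_rate,
              seed = seed)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_background_reports >= 0, cfg$n_cohort_reports >= 0)
  stopifnot(abs(sum(cfg$pt_vocabulary$base_prob) - 1) < 1e-8)
  for (m in names(cfg$demographics)) {
    s <- sum(cfg$demographics[[m]])
    # marginals copied from printed percentages may be off by rounding
    if (abs(s - 1) > 0.02) stop("demographic marginal '", m, "' does not sum to 1")
  }
  if (length(cfg$planted_signals)) {
    if (any(cfg$planted_signals < 1)) stop("planted reporting ratios must be >= 1")
    if (!all(names(cfg$planted_signals) %in% cfg$pt_vocabulary$pt)) {
      stop("planted signal PT not present in pt_vocabulary")
    }
  }
  shp <- vapply(cfg$tto_models, function(m) m[["shape"]], numeric(1))
  scl <- vapply(cfg$tto_models, function(m) m[["scale"]], numeric(1))
  stopifnot(all(shp > 0), all(scl > 0))
  invisible(cfg)
}

# cohort PT-draw probabilities: planted PTs get base * lambda, the remaining
# mass is rescaled over non-planted PTs. Errors out if the boosted mass is
# infeasible (>= 1).
cohort_pt_probs <- function(vocab, planted) {
  p <- vocab$base_prob
  names(p) <- vocab$pt
  if (!length(planted)) return(p)
  idx <- match(names(planted), vocab$pt)
  boosted <- p[idx] * planted
  if (sum(boosted) >= 1) {
    stop("infeasible renormalization: planted reporting ratios push PT probability mass >= 1")
  }
  rest <- setdiff(seq_along(p), idx)
  p[rest] <- p[rest] * (1 - sum(boosted)) / sum(p[rest])
  p[idx] <- boosted
  p
}

.bg_drugs <- c("sorafenib", "lenvatinib", "atezolizumab", "bevacizumab",
               "nivolumab", "pembrolizumab", "regorafenib", "cabozantinib",
               "ramucirumab", "cisplatin", "oxaliplatin", "fluorouracil",
               "metformin", "furosemide", "spironolactone", "entecavir",
               "tenofovir", "aspirin", "omeprazole", "dexamethasone")

.bg_indications <- c("Non-small cell lung cancer", "Renal cell carcinoma",
                     "Gastric cancer", "Hypertension", "Type 2 diabetes mellitus",
                     "Chronic hepatitis b", "Colorectal cancer", "Malignant melanoma")

.durva_aliases <- c("DURVALUMAB", "Imfinzi", "IMFINZI.", "durvalumab")
.treme_aliases <- c("TREMELIMUMAB", "Imjudo", "IMJUDO.", "tremelimumab")

sample_marginal <- function(n, marginal) {
  sample(names(marginal), n, replace = TRUE, prob = marginal)
}

#' Generate a synthetic FAERS quarter with known planted structure
#'
#' See [synth_config()] for the planted quantities. Output is bit-identical
#' for identical `(config, seed)`.
#'
#' @param config a `synth_config`.
#' @param seed integer RNG seed (defaults to the one in the config).
#' @return list with `raw` (a `faers_tables` object, as if read from disk)
#'   and `truth` (a `synth_truth` ledger; see [truth_ledger()]).
#' @export
synth_generate <- function(config = synth_config(), seed = config$seed) {
  validate_synth_config(config)
  set.seed(seed)
  n_bg <- config$n_background_reports
  n_co <- config$n_cohort_reports
  n <- n_bg + n_co
  vocab <- config$pt_vocabulary
  is_cohort <- c(rep(FALSE, n_bg), rep(TRUE, n_co))
  caseid <- 10000000L + seq_len(n)
  primaryid <- caseid * 100 + 1

  dg <- config$demographics
  sex <- sample_marginal(n, dg$sex)
  agegrp <- sample_marginal(n, dg$age_group)
  age_lo <- c("<18" = 2, "18-64" = 18, "65-79" = 65, ">=80" = 80)
  age_hi <- c("<18" = 17, "18-64" = 64, "65-79" = 79, ">=80" = 95)
  age <- rep(NA_real_, n)
  has_age <- agegrp != "missing"
  age[has_age] <- round(runif(sum(has_age), age_lo[agegrp[has_age]],
                              age_hi[agegrp[has_age]]))
  occ <- sample_marginal(n, dg$occupation)
  ctry <- sample_marginal(n, dg$country)
  other_idx <- ctry == "other"
  ctry[other_idx] <- sample(c("GB", "DE", "IT", "KR", "ES"),
                            sum(other_idx), replace = TRUE)
  year <- as.integer(sample_marginal(n, dg$year))
  start_date <- as.Date(paste0(year, "-01-01")) + sample(0:330, n, replace = TRUE)

  # PT draws: first ("index") PT drives the onset-time model
  k <- pmin(1L + rpois(n, config$mean_extra_pts), 5L)
  p_bg <- setNames(vocab$base_prob, vocab$pt)
  p_co <- cohort_pt_probs(vocab, config$planted_signals)
  draws_bg <- sample(vocab$pt, sum(k[!is_cohort]), replace = TRUE, prob = p_bg)
  draws_co <- sample(vocab$pt, sum(k[is_cohort]), replace = TRUE, prob = p_co)
  rid <- c(rep(which(!is_cohort), k[!is_cohort]), rep(which(is_cohort), k[is_cohort]))
  reac_long <- data.table::data.table(report = rid, pt = c(draws_bg, draws_co))
  reac_long <- unique(reac_long)            # a report lists a PT at most once
  data.table::setorder(reac_long, report)
  # the onset-time model of a report is anchored to its index event: the
  # first listed PT with an explicit onset model, else the first listed PT
  mod_pts <- setdiff(names(config$tto_models), ".default")
  index_pt <- reac_long[, list(pt = {
    hit <- pt[pt %in% mod_pts]
    if (length(hit)) hit[1L] else pt[1L]
  }), by = "report"]
  index_vec <- rep(NA_character_, n)
  index_vec[index_pt$report] <- index_pt$pt

  # onset times from the index PT's Weibull model
  mod_names <- setdiff(names(config$tto_models), ".default")
  shape <- vapply(config$tto_models, function(m) m[["shape"]], numeric(1))
  scale <- vapply(config$tto_models, function(m) m[["scale"]], numeric(1))
  midx <- match(index_vec, mod_names)
  sh <- ifelse(is.na(midx), shape[[".default"]], shape[mod_names][midx])
  sc <- ifelse(is.na(midx), scale[[".default"]], scale[mod_names][midx])
  onset <- floor(rweibull(n, shape = sh, scale = sc))

  # fatal-outcome process: exponential-baseline proportional hazards over the
  # follow-up window, driven by the risk-factor PT indicators
  beta <- config$mortality$coefficients
  h0 <- config$mortality$baseline_hazard
  cens <- config$mortality$censor_day
  lp <- rep(0, n)
  if (length(beta)) {
    for (ptn in names(beta)) {
      has <- unique(reac_long$report[reac_long$pt == ptn])
      lp[has] <- lp[has] + beta[[ptn]]
    }
  }
  # competing processes: the fatal AE onset (exponential-baseline PH) vs the
  # non-fatal AE onset (Weibull); the report records whichever comes first
  # within the follow-up window
  tdeath <- round(rexp(n, rate = h0 * exp(lp)))
  fatal <- is_cohort & tdeath <= onset & tdeath <= cens
  fatal[!is_cohort] <- runif(n_bg) < config$background_fatal_rate
  event_days <- ifelse(is_cohort & fatal, tdeath, onset)
  event_date <- start_date + event_days
  fda_date <- event_date + sample(5:120, n, replace = TRUE)

  # serious outcomes for non-fatal reports
  so_codes <- sample(c("HO", "LT", "OT", "DS", ""), n, replace = TRUE,
                     prob = c(0.367, 0.143, 0.335, 0.002, 0.153))
  outc_cod <- ifelse(fatal, "DE", so_codes)

  # drug rows
  bg_first <- sample(.bg_drugs, n_bg, replace = TRUE)
  solo <- runif(n_bg)
  bg_first[solo < 0.010] <- sample(.durva_aliases, sum(solo < 0.010), replace = TRUE)
  bg_first[solo >= 0.010 & solo < 0.015] <-
    sample(.treme_aliases, sum(solo >= 0.010 & solo < 0.015), replace = TRUE)
  bg_second_has <- runif(n_bg) < 0.4
  bg_second <- sample(.bg_drugs, n_bg, replace = TRUE)
  drug_rows <- list(
    data.table::data.table(report = which(!is_cohort), DRUG_SEQ = 1L,
                           ROLE_COD = "PS", DRUGNAME = bg_first),
    data.table::data.table(report = which(!is_cohort)[bg_second_has],
                           DRUG_SEQ = 2L, ROLE_COD = "C",
                           DRUGNAME = bg_second[bg_second_has])
  )
  co_idx <- which(is_cohort)
  treme_role <- ifelse(runif(n_co) < 0.85, "PS", "SS")
  conc_has <- runif(n_co) < 0.3
  drug_rows <- c(drug_rows, list(
    data.table::data.table(report = co_idx, DRUG_SEQ = 1L, ROLE_COD = "PS",
                           DRUGNAME = sample(.durva_aliases, n_co, replace = TRUE)),
    data.table::data.table(report = co_idx, DRUG_SEQ = 2L, ROLE_COD = treme_role,
                           DRUGNAME = sample(.treme_aliases, n_co, replace = TRUE)),
    data.table::data.table(report = co_idx[conc_has], DRUG_SEQ = 3L,
                           ROLE_COD = "C",
                           DRUGNAME = sample(.bg_drugs, sum(conc_has), replace = TRUE))
  ))
  drug_dt <- data.table::rbindlist(drug_rows)
  data.table::setorder(drug_dt, report, DRUG_SEQ)

  # therapy start rows for suspect drugs (second agent may start a few days
  # later; the earliest start is the analysis anchor)
  start_missing <- runif(n) < config$missingness[["start_dt"]]
  ther_rows <- list(
    data.table::data.table(report = seq_len(n), DSG_DRUG_SEQ = 1L,
                           START_DT = start_date),
    data.table::data.table(report = co_idx, DSG_DRUG_SEQ = 2L,
                           START_DT = start_date[co_idx] +
                             sample(0:3, n_co, replace = TRUE))
  )
  ther_dt <- data.table::rbindlist(ther_rows)
  ther_dt <- ther_dt[!start_missing[ther_dt$report]]
  data.table::setorder(ther_dt, report, DSG_DRUG_SEQ)

  # indications
  indi_pt <- rep(NA_character_, n)
  indi_pt[co_idx] <- sample(c("Hepatocellular carcinoma", "HEPATOCELLULAR CARCINOMA",
                              "hepatocellular carcinoma"),
                            n_co, replace = TRUE)
  bg_hcc <- runif(n_bg) < 0.03
  indi_pt[which(!is_cohort)] <- ifelse(
    bg_hcc, "Hepatocellular carcinoma",
    sample(.bg_indications, n_bg, replace = TRUE))

  # date formatting with missingness / partial precision
  event_str <- format(event_date, "%Y%m%d")
  ev_missing <- runif(n) < config$missingness[["event_dt"]]
  ev_month <- !ev_missing & runif(n) < config$missingness[["event_month_prec"]]
  event_str[ev_missing] <- ""
  event_str[ev_month] <- substr(event_str[ev_month], 1, 6)
  fda_str <- format(fda_date, "%Y%m%d")
  start_str <- format(ther_dt$START_DT, "%Y%m%d")

  demo <- data.table::data.table(
    PRIMARYID = as.character(primaryid),
    CASEID = as.character(caseid),
    FDA_DT = fda_str,
    EVENT_DT = event_str,
    SEX = ifelse(sex == "missing", "", sex),
    AGE = ifelse(is.na(age), "", as.character(age)),
    AGE_COD = ifelse(is.na(age), "", "YR"),
    OCCP_COD = ifelse(occ == "missing", "", occ),
    REPORTER_COUNTRY = ctry
  )
  pid_of <- function(report) as.character(primaryid[report])
  cid_of <- function(report) as.character(caseid[report])
  drug <- data.table::data.table(
    PRIMARYID = pid_of(drug_dt$report), CASEID = cid_of(drug_dt$report),
    DRUG_SEQ = drug_dt$DRUG_SEQ, ROLE_COD = drug_dt$ROLE_COD,
    DRUGNAME = drug_dt$DRUGNAME, PROD_AI = toupper(normalize_term(drug_dt$DRUGNAME)))
  reac <- data.table::data.table(
    PRIMARYID = pid_of(reac_long$report), CASEID = cid_of(reac_long$report),
    PT = reac_long$pt)
  has_outc <- outc_cod != ""
  outc <- data.table::data.table(
    PRIMARYID = pid_of(which(has_outc)), CASEID = cid_of(which(has_outc)),
    OUTC_COD = outc_cod[has_outc])
  rpsr <- data.table::data.table(
    PRIMARYID = as.character(primaryid), CASEID = as.character(caseid),
    RPSR_COD = "EXP")
  ther <- data.table::data.table(
    PRIMARYID = pid_of(ther_dt$report), CASEID = cid_of(ther_dt$report),
    DSG_DRUG_SEQ = ther_dt$DSG_DRUG_SEQ, START_DT = start_str)
  indi <- data.table::data.table(
    PRIMARYID = as.character(primaryid), CASEID = as.character(caseid),
    INDI_DRUG_SEQ = 1L, INDI_PT = indi_pt)

  # duplicate injection: extra report versions with earlier FDA dates
  n_dup <- round(config$duplicate_rate * n)
  if (n_dup > 0) {
    dup_rep <- sample(seq_len(n), n_dup, replace = FALSE)
    dup_pid <- as.character(caseid[dup_rep] * 100 + 2)
    dup_map <- data.table::data.table(
      PRIMARYID = as.character(primaryid[dup_rep]), NEWPID = dup_pid)
    dup_demo <- demo[match(dup_map$PRIMARYID, demo$PRIMARYID)]
    dup_demo$PRIMARYID <- dup_map$NEWPID
    dup_demo$FDA_DT <- format(fda_date[dup_rep] - sample(15:180, n_dup, replace = TRUE),
                              "%Y%m%d")
    demo <- rbind(demo, dup_demo)
    dup_child <- function(tb) {
      d <- tb[tb$PRIMARYID %in% dup_map$PRIMARYID]
      d$PRIMARYID <- dup_map$NEWPID[match(d$PRIMARYID, dup_map$PRIMARYID)]
      rbind(tb, d)
    }
    drug <- dup_child(drug); reac <- dup_child(reac); outc <- dup_child(outc)
    rpsr <- dup_child(rpsr); ther <- dup_child(ther); indi <- dup_child(indi)
  }

  raw <- as_faers_tables(list(demo = demo, drug = drug, reac = reac,
                              outc = outc, rpsr = rpsr, ther = ther,
                              indi = indi))

  co_reac <- reac_long[reac_long$report %in% co_idx]
  pt_counts <- co_reac[, list(n = data.table::uniqueN(report)), by = "pt"]
  tto_usable <- is_cohort & !ev_missing & !ev_month & !start_missing &
    event_days >= 0
  truth <- structure(list(
    seed = seed,
    lambda = as.list(config$planted_signals %||% setNames(numeric(0), character(0))),
    tto_models = lapply(config$tto_models, as.list),
    cox_coefficients = as.list(config$mortality$coefficients),
    baseline_hazard = config$mortality$baseline_hazard,
    censor_day = config$mortality$censor_day,
    n_cohort = n_co,
    n_background = n_bg,
    n_raw_versions = n + n_dup,
    n_duplicates = n_dup,
    cohort_caseids = as.character(caseid[co_idx]),
    cohort_pt_counts = setNames(as.list(pt_counts$n), pt_counts$pt),
    index_pt_counts = as.list(table(index_vec[co_idx])),
    n_fatal_cohort = sum(fatal[co_idx]),
    n_tto_usable = sum(tto_usable)
  ), class = "synth_truth")
  list(raw = raw, truth = truth)
}

#' Assemble a `faers_tables` object from in-memory tables
#'
#' Converts raw string tables (the on-disk FAERS representation) into the
#' parsed structure produced by [read_faers_quarter()], applying the same
#' date parsing. Useful for building small fixtures in code.
#'
#' @param tables named list of data.frames (`demo`, `drug`, `reac`, ...).
#' @return a `faers_tables` object.
#' @export
as_faers_tables <- function(tables) {
  tables <- lapply(tables, data.table::as.data.table)
  for (nm in names(tables)) {
    dt <- data.table::copy(tables[[nm]])
    for (col in names(dt)) {
      if (!is.character(dt[[col]])) data.table::set(dt, j = col, value = as.character(dt[[col]]))
    }
    for (dc in intersect(.faers_date_cols[[nm]] %||% character(0), names(dt))) {
      parsed <- parse_faers_date(dt[[dc]])
      data.table::set(dt, j = paste0(dc, "_RAW"), value = parsed$raw)
      data.table::set(dt, j = dc, value = parsed$date)
      data.table::set(dt, j = paste0(dc, "_PREC"), value = parsed$precision)
    }
    tables[[nm]] <- dt
  }
  structure(list(tables = tables,
                 row_counts = vapply(tables, nrow, integer(1))),
            class = "faers_tables")
}

#' Write FAERS-format $-delimited ASCII tables
#'
#' Emits the same dialect the reader consumes: one header line, `$` field
#' separator, one record per line. Parsed date columns are written from their
#' retained raw strings.
#'
#' @param raw a `faers_tables` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths (named by table).
#' @export
write_faers_tables <- function(raw, dir) {
  stopifnot(inherits(raw, "faers_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(raw$tables)) {
    dt <- data.table::copy(raw$tables[[nm]])
    for (dc in intersect(.faers_date_cols[[nm]] %||% character(0), names(dt))) {
      raw_col <- paste0(dc, "_RAW")
      if (raw_col %in% names(dt)) {
        data.table::set(dt, j = dc, value = dt[[raw_col]])
        data.table::set(dt, j = c(raw_col, paste0(dc, "_PREC")), value = NULL)
      }
    }
    p <- file.path(dir, paste0(toupper(nm), ".txt"))
    data.table::fwrite(dt, p, sep = "$", quote = FALSE, na = "")
    paths[nm] <- p
  }
  invisible(paths)
}

#' Accessors for the planted-truth ledger
#'
#' @param truth a `synth_truth` object from [synth_generate()].
#' @param what one of `"lambda"`, `"tto_models"`, `"cox_coefficients"`,
#'   `"n_cohort"`, `"cohort_pt_counts"`, or any other ledger field name.
#' @return the planted value(s).
#' @export
truth_ledger <- function(truth, what) {
  stopifnot(inherits(truth, "synth_truth"))
  if (!what %in% names(truth)) stop("unknown truth-ledger field: ", what)
  truth[[what]]
}

#' Save / load the truth ledger as JSON
#' @param truth a `synth_truth` object.
#' @param path JSON file path.
#' @return `truth_save` the path, invisibly; `truth_load` a `synth_truth`.
#' @export
truth_save <- function(truth, path) {
  stopifnot(inherits(truth, "synth_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname truth_save
#' @export
truth_load <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$lambda <- as.list(x$lambda)
  structure(x, class = "synth_truth")
}
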