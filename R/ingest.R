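# FAERS quarterly ASCII ingestion: reading, deduplication, cohort extraction.
#
# FAERS distributes each quarter as seven $-delimited ASCII tables keyed by
# PRIMARYID (one row per report version) and CASEID (one row per patient
# case): DEMO, DRUG, REAC, OUTC, RPSR, THER, INDI. A case can appear as
# several report versions; counting is always done on deduplicated cases.

.faers_table_names <- c("demo", "drug", "reac", "outc", "rpsr", "ther", "indi")

.faers_required_cols <- list(
  demo = c("PRIMARYID", "CASEID", "FDA_DT"),
  drug = c("PRIMARYID", "DRUGNAME", "ROLE_COD"),
  reac = c("PRIMARYID", "PT"),
  outc = c("PRIMARYID", "OUTC_COD"),
  rpsr = c("PRIMARYID"),
  ther = c("PRIMARYID", "START_DT"),
  indi = c("PRIMARYID", "INDI_PT")
)

.faers_date_cols <- list(
  demo = c("FDA_DT", "EVENT_DT"),
  ther = c("START_DT", "END_DT")
)

#' Read one FAERS quarter from $-delimited ASCII files
#'
#' Reads the per-table files of a FAERS quarter (DEMO, DRUG, REAC, OUTC,
#' RPSR, THER, INDI). Dates are parsed to `Date` columns with a companion
#' `*_PREC` precision flag (`"day"`, `"month"`, `"year"` or `NA`); the raw
#' string is retained so no information is lost on unparseable values.
#'
#' @param paths named character vector or list of file paths; names must be
#'   among `demo, drug, reac, outc, rpsr, ther, indi`. `demo`, `drug` and
#'   `reac` are mandatory.
#' @return an object of class `faers_tables`: a list with element `tables`
#'   (named list of `data.table`s) and `row_counts`.
#' @export
read_faers_quarter <- function(paths) {
  paths <- as.list(paths)
  if (is.null(names(paths)) || !all(nzchar(names(paths)))) {
    stop("`paths` must be a named vector/list (demo, drug, reac, ...)")
  }
  names(paths) <- tolower(names(paths))
  unknown <- setdiff(names(paths), .faers_table_names)
  if (length(unknown)) stop("unknown FAERS table name(s): ",
                            paste(unknown, collapse = ", "))
  for (req in c("demo", "drug", "reac")) {
    if (is.null(paths[[req]])) stop("missing mandatory table path: ", req)
  }
  tables <- list()
  for (nm in intersect(.faers_table_names, names(paths))) {
    dt <- read_faers_table(paths[[nm]], nm)
    tables[[nm]] <- dt
  }
  structure(
    list(tables = tables, row_counts = vapply(tables, nrow, integer(1))),
    class = "faers_tables"
  )
}

# Read a single $-delimited FAERS table, validate mandatory columns, parse
# date columns. Empty file -> empty table with a warning.
read_faers_table <- function(path, name) {
  name <- tolower(name)
  if (!file.exists(path)) stop("file not found for table ", name, ": ", path)
  dt <- tryCatch(
    data.table::fread(path, sep = "$", header = TRUE, quote = "",
                      colClasses = "character", fill = TRUE,
                      showProgress = FALSE),
    error = function(e) data.table::data.table()
  )
  if (nrow(dt) == 0L && ncol(dt) == 0L) {
    warning("table ", name, " is empty: ", path)
    dt <- data.table::as.data.table(
      setNames(rep(list(character(0)), length(.faers_required_cols[[name]])),
               .faers_required_cols[[name]]))
  }
  data.table::setnames(dt, toupper(names(dt)))
  # tolerate a trailing delimiter (fread may create an unnamed last column)
  blank <- names(dt)[names(dt) %in% c("", "V1") & seq_along(dt) == ncol(dt)]
  if (length(blank)) dt[, (blank) := NULL]
  missing_cols <- setdiff(.faers_required_cols[[name]], names(dt))
  if (length(missing_cols)) {
    stop("table ", name, " is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (dc in intersect(.faers_date_cols[[name]] %||% character(0), names(dt))) {
    parsed <- parse_faers_date(dt[[dc]])
    data.table::set(dt, j = paste0(dc, "_RAW"), value = parsed$raw)
    data.table::set(dt, j = dc, value = parsed$date)
    data.table::set(dt, j = paste0(dc, "_PREC"), value = parsed$precision)
  }
  if ("PRIMARYID" %in% names(dt)) {
    data.table::set(dt, j = "PRIMARYID", value = as.character(dt$PRIMARYID))
  }
  dt
}

#' Deduplicate FAERS reports to one report version per case
#'
#' FDA practice for FAERS analyses: keep, for every CASEID, the report
#' version (PRIMARYID) with the latest FDA receipt date (FDA_DT), breaking
#' ties by the largest PRIMARYID. Rows of child tables belonging to dropped
#' report versions are dropped with them.
#'
#' @param raw a `faers_tables` object from [read_faers_quarter()] (or the
#'   synthetic generator). Also accepts an already-deduplicated `faers_cases`
#'   object, on which it is the identity.
#' @return an object of class `faers_cases`: list with `tables` (filtered
#'   tables), `cases` (one row per case with normalised demographics),
#'   `provenance` (character log) and `n_duplicates_removed`.
#' @export
deduplicate_cases <- function(raw) {
  if (inherits(raw, "faers_cases")) raw <- list(tables = raw$tables)
  tables <- raw$tables
  demo <- tables$demo
  if (is.null(demo) || nrow(demo) == 0L) stop("demo table is empty")
  demo <- data.table::copy(demo)
  if (!"CASEID" %in% names(demo)) stop("demo table lacks CASEID")
  # numeric primaryid ordering where possible, lexicographic fallback
  pid_num <- suppressWarnings(as.numeric(demo$PRIMARYID))
  ord <- order(demo$CASEID, demo$FDA_DT, pid_num,
               method = "radix", na.last = FALSE)
  demo <- demo[ord]
  keep <- demo[, .SD[.N], by = "CASEID"]
  n_dropped <- nrow(demo) - nrow(keep)
  kept_pids <- keep$PRIMARYID
  out <- list()
  out$demo <- keep
  for (nm in setdiff(names(tables), "demo")) {
    tb <- tables[[nm]]
    out[[nm]] <- tb[tb$PRIMARYID %in% kept_pids]
  }
  structure(
    list(
      tables = out,
      cases = build_case_table(out),
      provenance = sprintf("deduplicated: %d raw report versions -> %d cases (%d removed)",
                           nrow(demo), nrow(keep), n_dropped),
      n_duplicates_removed = n_dropped
    ),
    class = "faers_cases"
  )
}

# Age-unit normalisation factors to years.
.age_factors <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                  DY = 1 / 365, HR = 1 / 8760)

#' Normalise FAERS ages to years
#'
#' @param age numeric or character age values.
#' @param age_cod FAERS unit codes (`DEC, YR, MON, WK, DY, HR`).
#' @param max_age ages above this (years) are treated as data errors and set
#'   to missing; default 120.
#' @return numeric vector of ages in years.
#' @export
normalize_age <- function(age, age_cod, max_age = 120) {
  a <- suppressWarnings(as.numeric(age))
  f <- .age_factors[toupper(trimws(as.character(age_cod)))]
  f[is.na(f)] <- NA_real_
  yrs <- a * unname(f)
  yrs[!is.na(yrs) & (yrs < 0 | yrs > max_age)] <- NA_real_
  yrs
}

#' Age bins used for demographic summaries
#' @param age_years numeric ages in years.
#' @return factor with levels `<18`, `18-64`, `65-79`, `>=80`, `missing`.
#' @export
age_group <- function(age_years) {
  g <- cut(age_years, breaks = c(-Inf, 18, 65, 80, Inf), right = FALSE,
           labels = c("<18", "18-64", "65-79", ">=80"))
  g <- as.character(g)
  g[is.na(g)] <- "missing"
  factor(g, levels = c("<18", "18-64", "65-79", ">=80", "missing"))
}

.occupation_map <- c(MD = "physician", PH = "pharmacist",
                     OT = "health-professional", HP = "health-professional",
                     RN = "health-professional", CN = "consumer")

# One row per case: demographics normalised to the categories used in the
# Table-1 style summary. Outcome codes live in tables$outc (multi-valued).
build_case_table <- function(tables) {
  demo <- tables$demo
  sex <- toupper(trimws(demo$SEX %||% rep(NA_character_, nrow(demo))))
  sex[!sex %in% c("F", "M")] <- "missing"
  age_years <- if (all(c("AGE", "AGE_COD") %in% names(demo))) {
    normalize_age(demo$AGE, demo$AGE_COD)
  } else rep(NA_real_, nrow(demo))
  occ <- .occupation_map[toupper(trimws(demo$OCCP_COD %||% rep(NA_character_, nrow(demo))))]
  occ[is.na(occ)] <- "missing"
  country <- trimws(demo$REPORTER_COUNTRY %||% rep(NA_character_, nrow(demo)))
  country[is.na(country) | country == ""] <- "missing"
  year <- as.integer(format(demo$FDA_DT, "%Y"))
  data.table::data.table(
    caseid = demo$CASEID,
    primaryid = demo$PRIMARYID,
    sex = sex,
    age_years = age_years,
    age_group = as.character(age_group(age_years)),
    occupation = unname(occ),
    country = country,
    year = year,
    event_dt = demo$EVENT_DT,
    event_prec = demo$EVENT_DT_PREC %||% rep(NA_character_, nrow(demo)),
    fda_dt = demo$FDA_DT
  )
}

# Subset a faers_cases object to a set of caseids, keeping provenance.
subset_cases <- function(cases, caseids, note) {
  stopifnot(inherits(cases, "faers_cases"))
  keep_demo <- cases$tables$demo[cases$tables$demo$CASEID %in% caseids]
  pids <- keep_demo$PRIMARYID
  tables <- lapply(cases$tables, function(tb) tb[tb$PRIMARYID %in% pids])
  tables$demo <- keep_demo
  structure(
    list(tables = tables,
         cases = cases$cases[cases$cases$caseid %in% caseids],
         provenance = c(cases$provenance,
                        sprintf("%s: %d cases retained", note, nrow(keep_demo))),
         n_duplicates_removed = cases$n_duplicates_removed),
    class = "faers_cases"
  )
}

#' Number of cases in a deduplicated case set
#' @param cases a `faers_cases` object.
#' @return integer count.
#' @export
n_cases <- function(cases) nrow(cases$tables$demo)

#' Restrict a case set to reports mentioning every required agent
#'
#' Implements the drug-name "fuzzy search": case-insensitive substring match
#' after stripping non-alphanumerics, against generic and trade names. A case
#' is kept only if EVERY element of `drug_sets` (one set of aliases per
#' required agent) is matched by at least one of its drug rows in an allowed
#' role — i.e. for a two-agent combination cohort, both agents must appear.
#'
#' @param cases a `faers_cases` object.
#' @param drug_sets list of character vectors; each vector holds the aliases
#'   (generic + trade names) of one required agent.
#' @param roles allowed FAERS role codes; default all of `PS, SS, C, I`
#'   (inclusive mode). Use `roles = "PS"` for the stricter
#'   primary-suspect-only mode.
#' @return filtered `faers_cases` (possibly empty, with a warning).
#' @export
match_drug <- function(cases, drug_sets, roles = c("PS", "SS", "C", "I")) {
  stopifnot(inherits(cases, "faers_cases"), length(drug_sets) > 0)
  if (!is.list(drug_sets)) drug_sets <- list(drug_sets)
  drug <- cases$tables$drug
  role_ok <- toupper(trimws(drug$ROLE_COD)) %in% toupper(roles)
  dn <- normalize_term(drug$DRUGNAME)
  pid2case <- cases$tables$demo[, c("PRIMARYID", "CASEID")]
  keep <- NULL
  for (aliases in drug_sets) {
    pat <- normalize_term(aliases)
    pat <- pat[nzchar(pat)]
    if (!length(pat)) stop("empty drug alias set")
    hit <- rep(FALSE, nrow(drug))
    for (p in pat) hit <- hit | grepl(p, dn, fixed = TRUE)
    pids <- unique(drug$PRIMARYID[hit & role_ok])
    ids <- unique(pid2case$CASEID[pid2case$PRIMARYID %in% pids])
    keep <- if (is.null(keep)) ids else intersect(keep, ids)
  }
  if (!length(keep)) warning("drug matching produced an empty cohort")
  subset_cases(cases, keep, sprintf("drug match (%d agents, roles %s)",
                                    length(drug_sets),
                                    paste(roles, collapse = "/")))
}

#' Restrict a case set to reports with a given indication
#'
#' @param cases a `faers_cases` object.
#' @param term indication preferred term, matched case-insensitively
#'   (whitespace-trimmed exact match) against `INDI_PT`.
#' @return filtered `faers_cases`.
#' @export
filter_indication <- function(cases, term) {
  stopifnot(inherits(cases, "faers_cases"), nzchar(term))
  indi <- cases$tables$indi
  if (is.null(indi)) stop("case set has no indication (INDI) table")
  hit <- tolower(trimws(indi$INDI_PT)) == tolower(trimws(term))
  pids <- unique(indi$PRIMARYID[hit])
  ids <- unique(cases$tables$demo$CASEID[cases$tables$demo$PRIMARYID %in% pids])
  subset_cases(cases, ids, sprintf("indication filter '%s'", term))
}

.serious_outcome_labels <- c(
  DE = "Death", DS = "Disability", HO = "Hospitalization",
  LT = "Life-threatening events", OT = "Other serious outcomes",
  CA = "Other serious outcomes", RI = "Other serious outcomes"
)

#' Table-1 style demographic summary of a case set
#'
#' Counts and percentages (denominator = total reports) for sex, age bins,
#' reporter occupation, serious outcomes (a report counts once per distinct
#' category present; reports with no outcome code are "Missing"), reporting
#' country (top `top_k` plus "Other countries") and reporting year. The
#' roll-up of the five serious-outcome categories is attached as attribute
#' `total_serious` together with its percentage.
#'
#' @param cases a `faers_cases` object.
#' @param top_k how many individual countries to list; default 5.
#' @return `data.table` with columns `block`, `category`, `n`, `pct`.
#' @export
summarize_demographics <- function(cases, top_k = 5) {
  ct <- cases$cases
  total <- nrow(ct)
  if (total == 0L) {
    res <- data.table::data.table(block = character(0), category = character(0),
                                  n = integer(0), pct = numeric(0))
    data.table::setattr(res, "total_reports", 0L)
    data.table::setattr(res, "total_serious", 0L)
    data.table::setattr(res, "total_serious_pct", NA_real_)
    return(res)
  }
  block <- function(name, x, levels = NULL) {
    tab <- table(x)
    if (!is.null(levels)) tab <- tab[intersect(levels, names(tab))]
    data.table::data.table(block = name, category = names(tab),
                           n = as.integer(tab),
                           pct = 100 * as.integer(tab) / total)
  }
  out <- list()
  out$sex <- block("Sex", factor(ct$sex, levels = c("F", "M", "missing"),
                                 labels = c("Female", "Male", "Missing")))
  out$age <- block("Age", factor(ct$age_group,
                                 levels = c("<18", "18-64", "65-79", ">=80", "missing"),
                                 labels = c("<18", "18-64", "65-79", ">=80", "Missing")))
  occ_lv <- c("physician", "pharmacist", "health-professional", "consumer", "missing")
  out$occ <- block("Occupation reporter",
                   factor(ct$occupation, levels = occ_lv,
                          labels = c("Physician", "Pharmacist",
                                     "Health-professional", "Consumer", "Missing")))
  # serious outcomes: one count per report per distinct category
  outc <- cases$tables$outc
  so_levels <- c("Death", "Disability", "Hospitalization",
                 "Life-threatening events", "Other serious outcomes")
  if (!is.null(outc) && nrow(outc)) {
    oc <- data.table::data.table(
      PRIMARYID = outc$PRIMARYID,
      cat = unname(.serious_outcome_labels[toupper(trimws(outc$OUTC_COD))]))
    oc <- oc[!is.na(oc$cat) & oc$PRIMARYID %in% ct$primaryid]
    oc <- unique(oc)
    counts <- table(factor(oc$cat, levels = so_levels))
    n_with_outcome <- length(unique(oc$PRIMARYID))
  } else {
    counts <- table(factor(character(0), levels = so_levels))
    n_with_outcome <- 0L
  }
  so <- data.table::data.table(
    block = "Serious outcome",
    category = c(so_levels, "Missing"),
    n = c(as.integer(counts), total - n_with_outcome))
  so$pct <- 100 * so$n / total
  out$so <- so
  # countries: top_k named, remainder pooled
  ctry <- ct$country
  tab <- sort(table(ctry[ctry != "missing"]), decreasing = TRUE)
  top <- head(names(tab), top_k)
  ctry_cat <- ifelse(ctry == "missing", "Missing",
                     ifelse(ctry %in% top, ctry, "Other countries"))
  lv <- c(top, "Other countries", if (any(ctry_cat == "Missing")) "Missing")
  out$ctry <- block("Reporting country", factor(ctry_cat, levels = lv))
  out$year <- block("Reporting year", factor(ct$year))
  res <- data.table::rbindlist(out)
  total_serious <- sum(so$n[so$category != "Missing"])
  data.table::setattr(res, "total_reports", total)
  data.table::setattr(res, "total_serious", total_serious)
  data.table::setattr(res, "total_serious_pct", 100 * total_serious / total)
  res[]
}
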