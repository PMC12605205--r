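# Publication-style output assembly and the end-to-end pipeline driver.

#' Build a pipeline run configuration
#'
#' @param quarter_dir directory holding the FAERS-format ASCII tables
#'   (`DEMO.txt`, `DRUG.txt`, ...), or `NULL` to simulate.
#' @param synth a [synth_config()] used when `quarter_dir` is `NULL`.
#' @param drug_sets list of alias vectors, one per required agent.
#' @param indication indication preferred term.
#' @param roles allowed drug role codes (`"PS"` only for the strict mode).
#' @param thresholds consensus thresholds from [signal_thresholds()].
#' @param ime_terms,dme_terms,label_terms optional PT term lists.
#' @param min_pt_cases,nfolds,horizons mortality-model settings.
#' @param seed RNG seed for simulation and CV folds.
#' @param out_dir output directory.
#' @return a `run_config` list (serialisable; hashed into every artifact).
#' @export
run_config <- function(quarter_dir = NULL,
                       synth = synth_config(),
                       drug_sets = list(c("durvalumab", "imfinzi"),
                                        c("tremelimumab", "imjudo")),
                       indication = "hepatocellular carcinoma",
                       roles = c("PS", "SS", "C", "I"),
                       thresholds = signal_thresholds(),
                       ime_terms = NULL, dme_terms = NULL, label_terms = NULL,
                       min_pt_cases = 2, nfolds = 10,
                       horizons = c(30, 60, 90),
                       seed = 20240101, out_dir = "results") {
  structure(list(quarter_dir = quarter_dir, synth = synth,
                 drug_sets = drug_sets, indication = indication,
                 roles = roles, thresholds = thresholds,
                 ime_terms = ime_terms, dme_terms = dme_terms,
                 label_terms = label_terms, min_pt_cases = min_pt_cases,
                 nfolds = nfolds, horizons = horizons, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Render a Table-1 style demographics CSV
#'
#' @param demographics from [summarize_demographics()].
#' @param path output CSV path, or `NULL` to only return the table.
#' @return data.table with `block`, `category`, `n`, `pct` (1 decimal).
#' @export
render_table1 <- function(demographics, path = NULL) {
  out <- data.table::copy(demographics)
  out$pct <- round(out$pct, 1)
  if (!is.null(path)) data.table::fwrite(out, path)
  out[]
}

#' Render a Table-2 style signal table
#'
#' Formats the four algorithms' statistics the way pharmacovigilance papers
#' print them — `ROR (lo-hi)`, `PRR (lo-hi)`, chi-square, `IC (IC025)`,
#' `EBGM (EBGM05)`, two decimals — sorted by descending case count (ties by
#' PT name), top `k` rows. `rank_by = "ror"` instead ranks by descending ROR.
#'
#' @param signals table from [detect_signals()].
#' @param k number of rows to keep (all, if fewer).
#' @param rank_by `"case"` (default) or `"ror"`.
#' @param path optional output CSV path.
#' @return formatted data.table.
#' @export
render_signal_table <- function(signals, k = 20, rank_by = c("case", "ror"),
                                path = NULL) {
  rank_by <- match.arg(rank_by)
  s <- data.table::as.data.table(signals)
  if (rank_by == "case") {
    data.table::setorderv(s, c("a", "pt"), order = c(-1L, 1L))
  } else {
    data.table::setorderv(s, c("ror", "pt"), order = c(-1L, 1L), na.last = TRUE)
  }
  s <- head(s, k)
  num2 <- function(x) ifelse(is.na(x), "NA", sub("\\.?0+$", "", formatC(round(x, 2), format = "f", digits = 2)))
  out <- data.table::data.table(
    pt = s$pt,
    soc = if ("soc" %in% names(s)) s$soc else NA_character_,
    case_n = s$a,
    ror_ci = sprintf("%s (%s-%s)", num2(s$ror), num2(s$ror_lo), num2(s$ror_hi)),
    prr_ci = sprintf("%s (%s-%s)", num2(s$prr), num2(s$prr_lo), num2(s$prr_hi)),
    chi2 = num2(s$chi2),
    ic_ic025 = sprintf("%s (%s)", num2(s$ic), num2(s$ic025)),
    ebgm_ebgm05 = sprintf("%s (%s)", num2(s$ebgm), num2(s$ebgm05)))
  if ("consensus" %in% names(s)) out$consensus <- s$consensus
  for (fl in intersect(c("ime", "dme", "unexpected"), names(s))) out[[fl]] <- s[[fl]]
  if (!is.null(path)) data.table::fwrite(out, path)
  out[]
}

write_stage_csv <- function(dt, path, hash) {
  dt <- data.table::as.data.table(dt)
  header <- sprintf("# config_hash: %s", hash)
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Run the whole pipeline: ingest, signals, onset analysis, risk model, reports
#'
#' Executes simulate/read, deduplication, cohort extraction, the
#' four-algorithm screen, the onset-time analysis and the mortality risk
#' model, writing CSV/JSON artifacts plus a run manifest (seed, config hash,
#' and row counts at every stage). Any stage error aborts with the stage
#' name; artifacts written up to that point are retained.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the in-memory results of every stage and
#'   the manifest.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  manifest <- list(seed = config$seed, config_hash = hash,
                   package_version = as.character(utils::packageVersion("faerspv")),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  ing <- stage("ingest", {
    if (is.null(config$quarter_dir)) {
      sim <- synth_generate(config$synth, seed = config$seed)
      list(raw = sim$raw, truth = sim$truth)
    } else {
      files <- list.files(config$quarter_dir, full.names = TRUE)
      names(files) <- tolower(sub("\\..*$", "", basename(files)))
      list(raw = read_faers_quarter(files[names(files) %in% .faers_table_names]),
           truth = NULL)
    }
  })
  raw <- ing$raw
  truth <- ing$truth
  manifest$stages$raw_reports <- unname(raw$row_counts["demo"])
  universe <- stage("deduplicate", deduplicate_cases(raw))
  manifest$stages$deduplicated_cases <- n_cases(universe)
  cohort <- stage("cohort", {
    co <- match_drug(universe, config$drug_sets, roles = config$roles)
    filter_indication(co, config$indication)
  })
  manifest$stages$cohort_cases <- n_cases(cohort)
  demog <- stage("demographics", summarize_demographics(cohort))
  render_table1(demog, file.path(config$out_dir, "table1_demographics.csv"))
  signals <- stage("signals", detect_signals(
    cohort, universe, thresholds = config$thresholds,
    ime_terms = config$ime_terms, dme_terms = config$dme_terms,
    label_terms = config$label_terms))
  manifest$stages$pts_tested <- nrow(signals)
  manifest$stages$consensus_signals <- sum(signals$consensus)
  write_stage_csv(signals, file.path(config$out_dir, "signals.csv"), hash)
  render_signal_table(signals, k = 20,
                      path = file.path(config$out_dir, "table2_top_signals.csv"))
  volcano <- data.table::data.table(pt = signals$pt,
                                    log_ror = log(signals$ror),
                                    neg_log10_p_adj = -log10(pmax(signals$p_adj, 1e-300)),
                                    case_n = signals$a)
  write_stage_csv(volcano, file.path(config$out_dir, "volcano.csv"), hash)
  tto_res <- stage("tto", {
    tto <- compute_tto(cohort)
    if (nrow(tto) == 0L) {
      list(records = tto, summary = NULL, km = NULL)
    } else {
      positive <- signals$pt[signals$consensus]
      tto$pt_positive <- tolower(tto$pt) %in% tolower(positive)
      first_ae <- tto[, list(tto_days = min(tto_days),
                             pt_positive = any(pt_positive),
                             sex = sex[1L], age_group = age_group[1L]),
                      by = "caseid"]
      km <- km_curve(first_ae$tto_days,
                     strata = ifelse(first_ae$pt_positive, "PT-positive", "PT-negative"))
      list(records = tto, summary = tto_summary(tto$tto_days),
           first_ae = first_ae, km = km)
    }
  })
  manifest$stages$tto_records <- nrow(tto_res$records)
  if (nrow(tto_res$records)) {
    write_stage_csv(tto_res$records[, c("caseid", "pt", "tto_days", "sex",
                                        "age_group", "fatal", "pt_positive")],
                    file.path(config$out_dir, "tto_records.csv"), hash)
    write_stage_csv(tto_res$summary$bins,
                    file.path(config$out_dir, "tto_bins.csv"), hash)
    write_stage_csv(tto_res$km$curve,
                    file.path(config$out_dir, "tto_km_curve.csv"), hash)
  }
  risk <- stage("riskmodel", {
    positive <- signals$pt[signals$consensus]
    if (!length(positive)) NULL else
      tryCatch(fit_mortality_model(cohort, positive,
                                   min_pt_cases = config$min_pt_cases,
                                   nfolds = config$nfolds, seed = config$seed,
                                   horizons = config$horizons),
               error = function(e) {
                 warning("risk model skipped: ", conditionMessage(e))
                 NULL
               })
  })
  if (!is.null(risk) && !is.null(risk$cox)) {
    manifest$stages$risk_model_records <- nrow(risk$design)
    manifest$stages$risk_model_events <- sum(risk$design$event)
    rm_json <- list(
      config_hash = hash,
      lambda_min = risk$lasso$lambda_min,
      selected_vars = risk$lasso$selected_vars,
      cox = as.list(setNames(risk$cox$table$coef, risk$cox$table$var)),
      hr = as.list(setNames(risk$cox$table$hr, risk$cox$table$var)),
      p = as.list(setNames(risk$cox$table$p, risk$cox$table$var)),
      median_cutoff = risk$strata$median_cutoff,
      logrank_p = risk$strata$logrank_p,
      auc = as.list(setNames(risk$roc$auc, paste0("day", risk$roc$horizon))))
    jsonlite::write_json(rm_json, file.path(config$out_dir, "riskmodel.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  manifest$provenance <- cohort$provenance
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) truth_save(truth, file.path(config$out_dir, "truth.json"))
  invisible(list(universe = universe, cohort = cohort, demographics = demog,
                 signals = signals, tto = tto_res, risk = risk,
                 truth = truth, manifest = manifest))
}
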