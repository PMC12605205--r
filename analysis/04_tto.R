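#!/usr/bin/env Rscript
# Stage 4 — time-to-onset: summary, interval bins, stratified Kaplan-Meier,
# Weibull hazard classes for the three PTs carrying planted onset models.

suppressMessages(library(faerspv))

qdir <- "results/quarters"
files <- list.files(qdir, pattern = "\\.txt$", full.names = TRUE)
names(files) <- tolower(sub("\\..*$", "", basename(files)))
universe <- deduplicate_cases(read_faers_quarter(files))
cohort <- filter_indication(
  match_drug(universe, list(c("durvalumab", "imfinzi"),
                            c("tremelimumab", "imjudo"))),
  "hepatocellular carcinoma")
truth <- truth_load(file.path(qdir, "truth.json"))
signals <- detect_signals(cohort, universe)

tto <- compute_tto(cohort)
excl <- attr(tto, "exclusions")
cat(sprintf("usable day-precision onset records: %d of %d cases (%d missing dates, %d imprecise, %d event before start)\n",
            excl["usable"], excl["total_cases"], excl["missing_date"],
            excl["imprecise_date"], excl["event_before_start"]))

s <- tto_summary(tto$tto_days)
cat(sprintf("median TTO %d days (95%% CI %d-%d), IQR %d-%d\n",
            s$median, s$median_ci[1], s$median_ci[2], s$iqr[1], s$iqr[2]))
data.table::fwrite(s$bins, "results/tto_bins.csv")
print(s$bins)

# patient-level KM stratified by consensus status of the patient's PTs
positive <- tolower(signals$pt[signals$consensus])
tto$pt_positive <- tolower(tto$pt) %in% positive
first_ae <- tto[, list(tto_days = min(tto_days), pt_positive = any(pt_positive),
                       sex = sex[1], age_group = age_group[1]), by = "caseid"]
for (strat in c("pt_positive", "sex", "age_group")) {
  km <- km_curve(first_ae$tto_days, strata = first_ae[[strat]])
  cat(sprintf("log-rank by %s: chisq = %.2f, p = %.3g\n",
              strat, km$logrank_chisq, km$logrank_p))
}
km <- km_curve(first_ae$tto_days,
               strata = ifelse(first_ae$pt_positive, "PT-positive", "PT-negative"))
data.table::fwrite(km$curve, "results/tto_km_curve.csv")

# Weibull hazard classes for the planted onset models
fits <- list()
for (p in c("immune-mediated enterocolitis", "drug-induced liver injury",
            "liver disorder")) {
  x <- tto$tto_days[tolower(tto$pt) == p]
  if (length(x) < 10) { cat(p, ": insufficient records (", length(x), ")\n"); next }
  f <- weibull_fit(x)
  planted <- truth$tto_models[[p]]
  cat(sprintf("%s: n=%d shape %.2f (%.2f-%.2f) -> %s   [planted shape %.2f]\n",
              p, f$n, f$shape, f$shape_ci[1], f$shape_ci[2], f$category,
              planted$shape))
  fits[[p]] <- data.table::data.table(
    pt = p, n = f$n, shape = f$shape, shape_lo = f$shape_ci[1],
    shape_hi = f$shape_ci[2], scale = f$scale, category = f$category)
}
data.table::fwrite(data.table::rbindlist(fits), "results/tto_weibull.csv")
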