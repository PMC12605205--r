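#!/usr/bin/env Rscript
# Stage 3 — four-algorithm disproportionality screen.
#
# Per PT appearing in the cohort: ROR and PRR with 95% CIs and the Yates
# chi-square, the BCPNN information component with its gamma-quantile lower
# bound, and the MGPS EBGM/EBGM05 under the empirical-Bayes prior fitted on
# all drug-event pairs of the deduplicated universe. Bonferroni-adjusted
# p-values and the all-four consensus verdict are attached, then checked
# against the generator's planted reporting ratios.

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
data.table::fwrite(signals, "results/signals.csv")
render_signal_table(signals, k = 20, path = "results/table2_top_signals.csv")

cat("PTs screened:", nrow(signals), "| consensus-positive:",
    sum(signals$consensus), "\n")
lambda <- unlist(truth$lambda)
strong <- names(lambda)[lambda >= 10]
called <- tolower(signals$pt[signals$consensus])
cat("planted reporting ratios >= 10 detected:",
    sum(strong %in% called), "of", length(strong), "\n")
fp <- setdiff(called, tolower(names(lambda)))
cat("consensus calls outside the planted set:", length(fp), "\n")
print(render_signal_table(signals, k = 10)[, c("pt", "case_n", "ror_ci",
                                               "ic_ic025", "ebgm_ebgm05")])
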