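#!/usr/bin/env Rscript
# Stage 2 — ingest, deduplicate, extract the combination cohort, Table 1.
#
# Reads the quarter written by 01_simulate.R, keeps one report version per
# case (latest FDA receipt date, ties to the largest primaryid), requires
# both agents (durvalumab/IMFINZI and tremelimumab/IMJUDO, any suspect or
# concomitant role) plus the hepatocellular-carcinoma indication, and writes
# the demographic summary.

suppressMessages(library(faerspv))

qdir <- "results/quarters"
files <- list.files(qdir, pattern = "\\.txt$", full.names = TRUE)
names(files) <- tolower(sub("\\..*$", "", basename(files)))
raw <- read_faers_quarter(files)

universe <- deduplicate_cases(raw)
cat(universe$provenance, sep = "\n")

cohort <- filter_indication(
  match_drug(universe, list(c("durvalumab", "imfinzi"),
                            c("tremelimumab", "imjudo"))),
  "hepatocellular carcinoma")
cat("combination + indication cohort:", n_cases(cohort), "cases\n")

demog <- summarize_demographics(cohort)
render_table1(demog, "results/table1_demographics.csv")
cat("serious-outcome roll-up:", attr(demog, "total_serious"),
    sprintf("(%.1f%% of %d reports)\n", attr(demog, "total_serious_pct"),
            attr(demog, "total_reports")))
print(demog[demog$block == "Sex"])
cat("wrote results/table1_demographics.csv\n")
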