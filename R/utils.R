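#' @import data.table
#' @importFrom stats median quantile pchisq qgamma pgamma dnbinom digamma
#'   fisher.test optim qbinom setNames rweibull rexp rbinom runif rpois rnorm
#'   coef vcov as.formula p.adjust sd
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalise a free-text term for matching
#'
#' Lower-cases and strips all non-alphanumeric characters. Used for the
#' "fuzzy" drug-name and term matching: deterministic, auditable,
#' case- and punctuation-insensitive substring comparison.
#'
#' @param x character vector.
#' @return character vector of normalised terms.
#' @export
normalize_term <- function(x) {
  gsub("[^a-z0-9]", "", tolower(as.character(x)))
}

# Parse FAERS date fields (YYYYMMDD integers or strings). Partial dates
# (YYYYMM, YYYY) are representable: the returned `date` is imputed to
# mid-period and `precision` flags how much of it is real.
parse_faers_date <- function(x) {
  s <- trimws(as.character(x))
  s[is.na(s) | s == "" | s == "NA"] <- NA_character_
  digits <- grepl("^[0-9]+$", s)
  n <- nchar(s)
  prec <- rep(NA_character_, length(s))
  prec[digits & n == 8L] <- "day"
  prec[digits & n == 6L] <- "month"
  prec[digits & n == 4L] <- "year"
  iso <- rep(NA_character_, length(s))
  i8 <- which(prec == "day")
  if (length(i8)) {
    iso[i8] <- paste0(substr(s[i8], 1, 4), "-", substr(s[i8], 5, 6), "-",
                      substr(s[i8], 7, 8))
  }
  i6 <- which(prec == "month")
  if (length(i6)) {
    iso[i6] <- paste0(substr(s[i6], 1, 4), "-", substr(s[i6], 5, 6), "-15")
  }
  i4 <- which(prec == "year")
  if (length(i4)) iso[i4] <- paste0(s[i4], "-07-01")
  date <- as.Date(iso)
  # impossible dates (e.g. 20240230) fall back to missing, raw kept by caller
  prec[!is.na(s) & is.na(date)] <- NA_character_
  list(date = date, precision = prec, raw = s)
}

# integer yyyymmdd from Date
date_to_int <- function(d) {
  as.integer(format(d, "%Y%m%d"))
}

#' Hash a run configuration
#'
#' Canonical-JSON MD5 hash embedded in every analysis artifact so outputs can
#' be traced to the exact configuration that produced them.
#'
#' @param config a list of configuration values.
#' @return a length-1 character MD5 hash.
#' @export
config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = FALSE)
  unname(tools::md5sum(tf))
}
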