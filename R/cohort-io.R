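#' @title Cohort records: schema, readers, writers and inclusion validation
#' @name cohort_io
#' @description
#' A cohort is a plain `data.frame` with one row per mother-newborn pair.
#' Gestational ages are stored internally as decimal weeks; "W+D" notation
#' (e.g. `"13+6"`) is converted at I/O as `W + D/7`. Missing values are empty
#' CSV fields, never sentinel numbers. Serial symphysis-fundal height (SFH)
#' measurements are stored as two parallel semicolon-separated columns
#' (`sfh_days`, `sfh_cm`) so that the file stays one-row-per-pregnancy.
NULL

# canonical column order of the cohort CSV schema (version "1")
.cohort_columns <- c(
  "woman_id", "cohort", "crl_mm", "ga_at_crl_scan",
  "hc1_mm", "hc2_mm", "bpd1_mm", "bpd2_mm", "ga_at_study_scan",
  "sfh_days", "sfh_cm", "sfh_days_to_birth",
  "dubowitz_ga_at_birth", "newborn_ga_crl",
  "birthweight_g", "sex", "malaria_exposed", "sampling_stratum"
)

.ga_columns <- c("ga_at_crl_scan", "ga_at_study_scan",
                 "dubowitz_ga_at_birth", "newborn_ga_crl")
.length_columns <- c("crl_mm", "hc1_mm", "hc2_mm", "bpd1_mm", "bpd2_mm")
.numeric_columns <- c(.length_columns, .ga_columns,
                      "sfh_days_to_birth", "birthweight_g")

#' Column names of the cohort CSV schema
#'
#' @param schema_version Schema tag; only `"1"` exists.
#' @return Character vector of column names in canonical order.
#' @export
cohort_schema <- function(schema_version = "1") {
  if (!identical(schema_version, "1")) {
    stop("unknown cohort schema version: ", schema_version)
  }
  .cohort_columns
}

#' Parse gestational ages given as "W+D" or decimal weeks
#'
#' `"13+6"` becomes `13 + 6/7`; plain numbers pass through unchanged, so the
#' two notations for the same value yield identical internal values.
#'
#' @param x Character (or numeric) vector.
#' @return Numeric vector of decimal weeks; empty strings become `NA`.
#' @examples
#' parse_ga_weeks(c("7+0", "13+6", "39.5", ""))
#' @export
parse_ga_weeks <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  out <- rep(NA_real_, length(x))
  empty <- is.na(x) | x == ""
  wd <- !empty & grepl("^\\d+\\+\\d$", x)
  if (any(wd)) {
    parts <- strsplit(x[wd], "+", fixed = TRUE)
    w <- vapply(parts, function(p) as.numeric(p[1]), numeric(1))
    d <- vapply(parts, function(p) as.numeric(p[2]), numeric(1))
    if (any(d > 6)) stop("days part of W+D gestational age must be 0-6")
    out[wd] <- w + d / 7
  }
  plain <- !empty & !wd
  if (any(plain)) {
    val <- suppressWarnings(as.numeric(x[plain]))
    if (anyNA(val)) {
      bad <- x[plain][is.na(val)]
      stop("unparseable gestational age value(s): ",
           paste(utils::head(bad, 3), collapse = ", "))
    }
    out[plain] <- val
  }
  out
}

.parse_num_list <- function(x) {
  # ";"-separated numeric list column -> list of numeric vectors
  x <- trimws(as.character(x))
  lapply(x, function(s) {
    if (is.na(s) || s == "") return(numeric(0))
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

.format_num <- function(x) {
  # full-precision numeric formatting so write/read round-trips exactly
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

#' Read a cohort CSV
#'
#' Parses the documented one-row-per-pregnancy schema. GA columns accept
#' either "W+D" notation or decimal weeks. Malformed rows raise errors naming
#' the offending line; physically impossible values (negative lengths or
#' weights) are rejected at parse time. Range-based inclusion rules are *not*
#' applied here -- see [validate_inclusion()], which flags rather than drops.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @param schema_version Schema tag (currently `"1"`).
#' @return A `data.frame` with the columns of [cohort_schema()].
#' @seealso [write_cohort()], [validate_inclusion()]
#' @export
read_cohort <- function(path, schema_version = "1") {
  if (!file.exists(path)) stop("cohort file does not exist: ", path)
  cols <- cohort_schema(schema_version)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols) > 0) {
    stop("cohort file header is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[cols]
  rec <- raw
  for (cl in .ga_columns) {
    rec[[cl]] <- tryCatch(parse_ga_weeks(raw[[cl]]), error = function(e) {
      stop("column ", cl, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  for (cl in setdiff(.numeric_columns, .ga_columns)) {
    x <- trimws(raw[[cl]])
    val <- suppressWarnings(as.numeric(ifelse(x == "", NA, x)))
    bad <- which(!is.na(x) & x != "" & is.na(val))
    if (length(bad) > 0) {
      stop("malformed numeric value in column ", cl,
           " at data line ", bad[1], ": '", x[bad[1]], "'")
    }
    rec[[cl]] <- val
  }
  for (cl in .length_columns) {
    neg <- which(!is.na(rec[[cl]]) & rec[[cl]] < 0)
    if (length(neg) > 0) {
      stop("impossible negative length in column ", cl,
           " at data line ", neg[1])
    }
  }
  if (any(!is.na(rec$birthweight_g) & rec$birthweight_g < 0)) {
    stop("impossible negative birthweight")
  }
  rec$sex <- ifelse(trimws(rec$sex) == "", "unknown", trimws(rec$sex))
  if (!all(rec$sex %in% c("female", "male", "unknown"))) {
    stop("sex must be one of female/male/unknown")
  }
  rec$malaria_exposed <- trimws(rec$malaria_exposed) %in%
    c("TRUE", "true", "1", "yes")
  rec$cohort <- trimws(rec$cohort)
  rec$sampling_stratum <- ifelse(trimws(rec$sampling_stratum) == "",
                                 NA_character_, trimws(rec$sampling_stratum))
  rec
}

#' Write a cohort CSV
#'
#' Numeric fields are written at full precision (17 significant digits) so
#' that `read_cohort(write_cohort(x))` reproduces them exactly.
#'
#' @param records Cohort `data.frame` (see [cohort_schema()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  cols <- cohort_schema()
  out <- records[cols]
  for (cl in .numeric_columns) out[[cl]] <- .format_num(out[[cl]])
  out$malaria_exposed <- ifelse(records$malaria_exposed, "TRUE", "FALSE")
  out$sampling_stratum <- ifelse(is.na(records$sampling_stratum), "",
                                 records$sampling_stratum)
  utf8 <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(utf8))
  utils::write.csv(out, utf8, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Extract one record's SFH series
#'
#' @param record One cohort row.
#' @return `data.frame` with columns `days` (integer days since first SFH
#'   visit) and `height_cm`; zero rows when no series was recorded.
#' @export
sfh_series <- function(record) {
  days <- .parse_num_list(record$sfh_days)[[1]]
  cm <- .parse_num_list(record$sfh_cm)[[1]]
  if (length(days) != length(cm)) {
    stop("sfh_days and sfh_cm have different lengths for woman ",
         record$woman_id)
  }
  data.frame(days = days, height_cm = cm)
}

# ordered inclusion rules per cohort; first failure is the recorded reason
.inclusion_rules <- function(cohort_rules) {
  crl_hi <- switch(cohort_rules, dubowitz = 41, biometry = 80,
                   stop("unknown cohort rule tag: ", cohort_rules))
  rules <- list(
    no_crl = function(r) is.na(r$crl_mm),
    crl_out_of_range = function(r) {
      !is.na(r$crl_mm) & (r$crl_mm < 10 | r$crl_mm > crl_hi)
    },
    ga_out_of_range = function(r) {
      is.na(r$newborn_ga_crl) | r$newborn_ga_crl < 28 | r$newborn_ga_crl > 45
    },
    invalid_birthweight = function(r) {
      is.na(r$birthweight_g) | r$birthweight_g <= 0
    }
  )
  if (cohort_rules == "dubowitz") {
    rules$no_dubowitz <- function(r) is.na(r$dubowitz_ga_at_birth)
  } else {
    rules$no_study_scan <- function(r) is.na(r$ga_at_study_scan)
    rules$scan_ga_out_of_range <- function(r) {
      !is.na(r$ga_at_study_scan) &
        (r$ga_at_study_scan < 16 | r$ga_at_study_scan > 40)
    }
    rules$missing_replicates <- function(r) {
      is.na(r$hc1_mm) | is.na(r$hc2_mm) | is.na(r$bpd1_mm) | is.na(r$bpd2_mm)
    }
  }
  rules
}

#' Validate cohort inclusion rules
#'
#' Applies the cohort's inclusion rules (early CRL window, viability bound,
#' complete Dubowitz sheet or complete replicate scan, positive birthweight)
#' and *flags* failing records rather than deleting them, so downstream
#' accounting of exclusions stays reproducible.
#'
#' @param records Cohort `data.frame`.
#' @param cohort_rules `"dubowitz"` (CRL 10-41 mm, Dubowitz GA required) or
#'   `"biometry"` (CRL 10-80 mm, study scan at 16-40 weeks with duplicate HC
#'   and BPD required).
#' @return An object of class `cohort_validation`: a list with `n_accepted`,
#'   `n_rejected`, `reasons` (named counts over every rule, zeros kept), and
#'   `records` -- the input with logical `included` and character
#'   `exclusion_reason` columns added.
#' @export
validate_inclusion <- function(records,
                               cohort_rules = c("dubowitz", "biometry")) {
  cohort_rules <- match.arg(cohort_rules)
  rules <- .inclusion_rules(cohort_rules)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  counts <- stats::setNames(integer(length(rules)), names(rules))
  for (nm in names(rules)) {
    hit <- if (n > 0) rules[[nm]](records) & is.na(reason) else logical(0)
    counts[nm] <- sum(hit)
    reason[hit] <- nm
  }
  records$included <- is.na(reason)
  records$exclusion_reason <- reason
  structure(
    list(n_accepted = sum(records$included),
         n_rejected = sum(!records$included),
         reasons = counts,
         cohort_rules = cohort_rules,
         records = records),
    class = "cohort_validation"
  )
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("Cohort validation (", x$cohort_rules, " rules)\n", sep = "")
  cat("  accepted:", x$n_accepted, " rejected:", x$n_rejected, "\n")
  nz <- x$reasons[x$reasons > 0]
  if (length(nz) > 0) {
    for (nm in names(nz)) cat("   -", nm, ":", nz[nm], "\n")
  }
  invisible(x)
}
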