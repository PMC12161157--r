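#' @keywords internal
"_PACKAGE"

# Harmonized microdata schema: column names, in the exact order used for
# reading and writing. age_at_fgm is an integer number of completed years,
# the token "INFANCY" (approximate early-childhood answer), or missing
# (empty string or "NA").
MICRODATA_COLUMNS <- c(
  "survey_id", "module", "current_age", "birth_cohort", "fgm_status",
  "age_at_fgm", "education", "dob_complete", "stratum_id", "cluster_id",
  "weight_norm"
)

INFANCY_TOKEN <- "INFANCY"

MODULE_LEVELS <- c("women", "daughters")
COHORT_LEVELS <- c("1960s", "1970s", "1980s", "1990s", "2000s", "2010s",
                   "post2020", "missing")
FGM_LEVELS <- c("yes", "no", "missing")
EDUCATION_LEVELS <- c("none", "primary", "secondary", "higher", "other",
                      "missing")
DOB_LEVELS <- c("complete", "imputed")

# Age eligibility by module: women answer for themselves at 15-49,
# daughters under 15 are proxy-reported by their mothers.
MODULE_AGE_RANGE <- list(women = c(15L, 49L), daughters = c(0L, 14L))

#' Read harmonized respondent microdata
#'
#' Reads a CSV of respondent-level records (one row per woman or per
#' daughter) in the harmonized schema and validates every row against the
#' schema invariants. Rows that violate an invariant are rejected with a
#' line-numbered diagnostic rather than aborting the read; a malformed
#' header (unknown or missing column) is a hard error.
#'
#' Internally the `age_at_fgm` column is split into an integer column
#' (`NA` when no exact age is available) and a logical `age_fgm_infancy`
#' flag marking approximate "during infancy" answers, plus a numeric
#' `n_rep` row-multiplicity column (1 for raw data; fractional
#' redistribution later sets it to the redistribution fractions so that
#' unweighted counts stay conserved).
#'
#' @param path Path to a CSV file with columns `survey_id, module,
#'   current_age, birth_cohort, fgm_status, age_at_fgm, education,
#'   dob_complete, stratum_id, cluster_id, weight_norm`. Missing values
#'   are encoded as the empty string or `"NA"`; `age_at_fgm` additionally
#'   accepts the token `"INFANCY"`.
#' @param weights_raw If `TRUE`, weights are in the DHS six-implied-decimal
#'   integer convention and are divided by 1e6 on read. Default `FALSE`
#'   (weights already survey-normalized to mean about 1).
#' @return A list with `records` (validated data frame) and `rejections`
#'   (data frame with columns `line`, `reason`; zero rows when clean).
#' @export
read_microdata <- function(path, weights_raw = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(0), check.names = FALSE,
                         strip.white = TRUE)
  unknown <- setdiff(names(raw), MICRODATA_COLUMNS)
  if (length(unknown) > 0) {
    stop("unknown column(s) in microdata file: ",
         paste(unknown, collapse = ", "))
  }
  missing_cols <- setdiff(MICRODATA_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in microdata file: ",
         paste(missing_cols, collapse = ", "))
  }
  raw <- raw[, MICRODATA_COLUMNS]
  parse_microdata(raw, weights_raw = weights_raw)
}

# Parse a character data frame in schema order into typed records plus a
# rejection report. Line numbers refer to data rows (header excluded).
parse_microdata <- function(raw, weights_raw = FALSE) {
  n <- nrow(raw)
  blank <- function(x) is.na(x) | x == "" | x == "NA"

  to_enum <- function(x, levels, missing_level = "missing") {
    x[blank(x)] <- missing_level
    x
  }

  rec <- data.frame(
    survey_id = raw$survey_id,
    module = raw$module,
    current_age = suppressWarnings(as.integer(raw$current_age)),
    birth_cohort = to_enum(raw$birth_cohort, COHORT_LEVELS),
    fgm_status = to_enum(raw$fgm_status, FGM_LEVELS),
    age_at_fgm = NA_integer_,
    age_fgm_infancy = FALSE,
    education = to_enum(raw$education, EDUCATION_LEVELS),
    dob_complete = raw$dob_complete,
    stratum_id = raw$stratum_id,
    cluster_id = raw$cluster_id,
    weight_norm = suppressWarnings(as.numeric(raw$weight_norm)),
    n_rep = 1,
    stringsAsFactors = FALSE
  )
  if (weights_raw) rec$weight_norm <- rec$weight_norm / 1e6

  aaf <- raw$age_at_fgm
  is_inf <- !blank(aaf) & toupper(aaf) == INFANCY_TOKEN
  is_num <- !blank(aaf) & !is_inf
  rec$age_fgm_infancy <- is_inf
  rec$age_at_fgm[is_num] <- suppressWarnings(as.integer(aaf[is_num]))

  reasons <- vector("list", 8)
  reject <- function(bad, reason) {
    if (any(bad)) data.frame(line = which(bad), reason = reason,
                             stringsAsFactors = FALSE)
    else NULL
  }
  bad_num_age <- is_num & is.na(rec$age_at_fgm)
  rng <- do.call(rbind, MODULE_AGE_RANGE[match(rec$module, names(MODULE_AGE_RANGE))])
  bad_module <- !(rec$module %in% MODULE_LEVELS)
  in_range <- !bad_module & !is.na(rec$current_age) &
    rec$current_age >= rng[, 1] & rec$current_age <= rng[, 2]
  reasons[[1]] <- reject(bad_module, "unknown module")
  reasons[[2]] <- reject(!bad_module & !in_range, "age outside module range")
  reasons[[3]] <- reject(bad_num_age, "non-integer age_at_fgm")
  has_age <- (!is.na(rec$age_at_fgm) & !bad_num_age) | rec$age_fgm_infancy
  reasons[[4]] <- reject(has_age & rec$fgm_status != "yes",
                         "age_at_fgm without fgm_status=yes")
  reasons[[5]] <- reject(!is.na(rec$age_at_fgm) & rec$age_at_fgm < 0,
                         "negative age_at_fgm")
  reasons[[6]] <- reject(is.na(rec$weight_norm) | rec$weight_norm <= 0,
                         "non-positive or missing weight_norm")
  reasons[[7]] <- reject(!(rec$fgm_status %in% FGM_LEVELS), "unknown fgm_status")
  reasons[[8]] <- reject(!(rec$dob_complete %in% DOB_LEVELS),
                         "unknown dob_complete")
  rejections <- do.call(rbind, reasons[!vapply(reasons, is.null, logical(1))])
  if (is.null(rejections)) {
    rejections <- data.frame(line = integer(0), reason = character(0),
                             stringsAsFactors = FALSE)
  } else {
    rejections <- rejections[!duplicated(rejections$line), , drop = FALSE]
    rejections <- rejections[order(rejections$line), , drop = FALSE]
    rownames(rejections) <- NULL
  }
  keep <- setdiff(seq_len(n), rejections$line)
  records <- rec[keep, , drop = FALSE]
  rownames(records) <- NULL
  check_design_nesting(records)
  list(records = records, rejections = rejections)
}

# Clusters must nest in strata and strata in surveys; violations indicate a
# broken harmonization upstream, so this is a hard error.
check_design_nesting <- function(records) {
  if (nrow(records) == 0) return(invisible(TRUE))
  st <- unique(records[, c("survey_id", "stratum_id")])
  if (anyDuplicated(st$stratum_id) > 0) {
    stop("stratum_id appears in more than one survey_id")
  }
  cl <- unique(records[, c("stratum_id", "cluster_id")])
  if (anyDuplicated(cl$cluster_id) > 0) {
    stop("cluster_id appears in more than one stratum_id")
  }
  invisible(TRUE)
}

#' Validate a records data frame against the schema invariants
#'
#' Applies the same row-level checks as [read_microdata()] to an in-memory
#' records data frame (e.g. generator output) and errors on the first
#' violation. Used in tests and at pipeline stage boundaries.
#'
#' @param records A records data frame.
#' @return Invisibly `TRUE`; errors with a diagnostic otherwise.
#' @export
validate_records <- function(records) {
  stopifnot(is.data.frame(records))
  needed <- c(setdiff(MICRODATA_COLUMNS, "age_at_fgm"),
              "age_at_fgm", "age_fgm_infancy")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  rng <- do.call(rbind,
                 MODULE_AGE_RANGE[match(records$module, names(MODULE_AGE_RANGE))])
  if (any(!(records$module %in% MODULE_LEVELS))) stop("unknown module value")
  if (any(records$current_age < rng[, 1] | records$current_age > rng[, 2])) {
    stop("current_age outside module range")
  }
  has_age <- !is.na(records$age_at_fgm) | records$age_fgm_infancy
  if (any(has_age & records$fgm_status != "yes")) {
    stop("age_at_fgm present without fgm_status=yes")
  }
  if (any(!is.na(records$age_at_fgm) & records$age_at_fgm < 0)) {
    stop("negative age_at_fgm")
  }
  if (any(!is.finite(records$weight_norm) | records$weight_norm <= 0)) {
    stop("non-positive weight_norm")
  }
  check_design_nesting(records)
  invisible(TRUE)
}

#' Write records back to the harmonized CSV schema
#'
#' Inverse of [read_microdata()]: recombines the internal integer age and
#' infancy flag into the single `age_at_fgm` column (integer, `"INFANCY"`,
#' or empty for missing) and writes the schema columns in their canonical
#' order. Reading the file back reproduces the records field by field.
#'
#' @param records Records data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_microdata <- function(records, path) {
  out <- records[, setdiff(MICRODATA_COLUMNS, "age_at_fgm"), drop = FALSE]
  aaf <- ifelse(records$age_fgm_infancy, INFANCY_TOKEN,
                ifelse(is.na(records$age_at_fgm), "",
                       as.character(records$age_at_fgm)))
  out$age_at_fgm <- aaf
  out <- out[, MICRODATA_COLUMNS]
  out$birth_cohort[out$birth_cohort == "missing"] <- ""
  out$fgm_status[out$fgm_status == "missing"] <- ""
  out$education[out$education == "missing"] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Write a result table to CSV
#'
#' Deterministic CSV writer for the pipeline's output tables: fixed column
#' order (as given), rows written in their current order, full numeric
#' precision so that re-reading round-trips values.
#'
#' @param table A non-empty data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) stop("empty table")
  num <- vapply(table, is.double, logical(1))
  out <- table
  out[num] <- lapply(out[num], function(x) {
    ifelse(is.na(x), NA_character_,
           ifelse(is.infinite(x), ifelse(x > 0, "Inf", "-Inf"),
                  format(x, digits = 15, scientific = FALSE, trim = TRUE)))
  })
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read per-survey eligible population totals
#'
#' @param path CSV with columns `survey_id, eligible_population` and
#'   optionally `module` for per-module totals.
#' @return Data frame of totals.
#' @export
read_population_totals <- function(path) {
  tot <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("survey_id", "eligible_population")
  if (!all(needed %in% names(tot))) {
    stop("totals file must have columns survey_id, eligible_population")
  }
  if (any(!is.finite(tot$eligible_population) | tot$eligible_population <= 0)) {
    stop("eligible_population must be positive")
  }
  tot
}
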