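# Fixture builders: valid in-memory records and microdata CSV text.

# A records data frame in the package's internal layout. Vectors are
# recycled to the longest length. Defaults make a valid women's-module row.
make_records <- function(n = NULL, survey_id = "SN2017", module = "women",
                         current_age = 30, birth_cohort = "1980s",
                         fgm_status = "yes", age_at_fgm = NA_integer_,
                         age_fgm_infancy = FALSE, education = "none",
                         dob_complete = "complete", stratum_id = NULL,
                         cluster_id = NULL, weight_norm = 1,
                         weight_denorm = NULL) {
  args <- list(survey_id = survey_id, module = module,
               current_age = current_age, birth_cohort = birth_cohort,
               fgm_status = fgm_status, age_at_fgm = age_at_fgm,
               age_fgm_infancy = age_fgm_infancy, education = education,
               dob_complete = dob_complete, weight_norm = weight_norm)
  if (is.null(n)) n <- max(lengths(args))
  df <- as.data.frame(lapply(args, rep_len, n), stringsAsFactors = FALSE)
  df$age_at_fgm <- as.integer(df$age_at_fgm)
  df$stratum_id <- rep_len(
    if (is.null(stratum_id)) paste0(df$survey_id, "_st1") else stratum_id, n)
  df$cluster_id <- rep_len(
    if (is.null(cluster_id)) paste0(df$stratum_id, "_c", seq_len(n))
    else cluster_id, n)
  df$n_rep <- 1
  if (!is.null(weight_denorm)) df$weight_denorm <- rep_len(weight_denorm, n)
  df[c("survey_id", "module", "current_age", "birth_cohort", "fgm_status",
       "age_at_fgm", "age_fgm_infancy", "education", "dob_complete",
       "stratum_id", "cluster_id", "weight_norm", "n_rep",
       if (!is.null(weight_denorm)) "weight_denorm")]
}

# Write microdata CSV text (schema order) to a temp file; rows are
# character vectors of the 11 schema fields.
write_microdata_text <- function(...) {
  header <- paste(c("survey_id", "module", "current_age", "birth_cohort",
                    "fgm_status", "age_at_fgm", "education", "dob_complete",
                    "stratum_id", "cluster_id", "weight_norm"),
                  collapse = ",")
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(c(header, unlist(list(...))), path)
  path
}

# Independent displacement oracle for the heaping model: enumerates, age
# by age, the mass that probability p moves onto the nearest multiple of
# 5 within the window. Deliberately loop-based and separate from
# heaped_pmf().
oracle_displaced_counts <- function(counts, p, window = 2) {
  ages <- seq_along(counts) - 1
  out <- counts
  for (i in seq_along(ages)) {
    a <- ages[i]
    t <- round(a / 5) * 5
    d <- abs(a - t)
    if (d >= 1 && d <= window && t <= max(ages)) {
      out[i] <- out[i] - counts[i] * p
      out[t + 1] <- out[t + 1] + counts[i] * p
    }
  }
  out
}

# Sort-and-scan oracle for the lower weighted median.
oracle_weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  half <- sum(w) / 2
  acc <- 0
  for (i in seq_along(x)) {
    acc <- acc + w[i]
    if (acc >= half) return(x[i])
  }
  NA_real_
}
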