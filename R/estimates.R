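# Weighted medians of age at FGM by birth cohort and module, and
# composition tables (sample by survey/module, education and date-of-birth
# completeness, birth cohort, age-at-FGM bands).

#' Lower weighted median
#'
#' The smallest value whose cumulative weight reaches half of the total
#' weight. With equal weights this equals the conventional lower median.
#'
#' @param values Numeric vector (ages in completed years).
#' @param weights Positive weights, recycled to length 1 if omitted.
#' @return The median value, or `NA` for an empty input.
#' @export
weighted_median <- function(values, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(values))
  keep <- !is.na(values) & !is.na(weights)
  values <- values[keep]
  weights <- weights[keep]
  if (length(values) == 0) return(NA_real_)
  stopifnot(all(weights > 0))
  o <- order(values)
  values <- values[o]
  weights <- weights[o]
  cw <- cumsum(weights)
  values[which(cw >= sum(weights) / 2)[1]]
}

COHORT_ORDER <- c("1960s", "1970s", "1980s", "1990s", "2000s", "2010s",
                  "post2020")

#' Median age at FGM by birth cohort and module
#'
#' Weighted (lower) median of the numeric age at FGM among FGM-positive
#' records, per birth cohort, for each module and for both modules pooled.
#' Cells with no FGM-positive mass are `NA`.
#'
#' @param records Records data frame (redistribution done; under
#'   fractional redistribution the medians use the fractional weights).
#' @param weighted Use analysis weights (default); `FALSE` uses row
#'   multiplicities only.
#' @return Data frame: `birth_cohort`, `both`, `women`, `daughters`.
#' @export
median_table <- function(records, weighted = TRUE) {
  w <- analysis_weight(records, weighted)
  use <- records$fgm_status == "yes" & !is.na(records$age_at_fgm)
  d <- records[use, , drop = FALSE]
  wu <- w[use]
  cohorts <- intersect(COHORT_ORDER, unique(d$birth_cohort))
  med <- function(sel) {
    if (!any(sel)) return(NA_real_)
    weighted_median(d$age_at_fgm[sel], wu[sel])
  }
  rows <- lapply(cohorts, function(co) {
    in_co <- d$birth_cohort == co
    data.frame(
      birth_cohort = co,
      both = med(in_co),
      women = med(in_co & d$module == "women"),
      daughters = med(in_co & d$module == "daughters"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Integer percentage, halves rounded away from zero
#'
#' The rounding convention of printed survey tables (not banker's
#' rounding): `percent_int(5689, 15688)` is 36.
#'
#' @param num,den Numerator and denominator counts.
#' @return Integer-valued percentage; `NA` where `den` is 0.
#' @export
percent_int <- function(num, den) {
  out <- floor(100 * num / den + 0.5)
  out[rep_len(den, length(out)) <= 0] <- NA_real_
  out
}

AGE_FGM_BANDS <- c("<1", "1-5", "6-10", "11-15", ">15", "missing")

age_fgm_band <- function(age, infancy) {
  out <- rep("missing", length(age))
  out[!is.na(age) & age < 1] <- "<1"
  out[!is.na(age) & age >= 1 & age <= 5] <- "1-5"
  out[!is.na(age) & age >= 6 & age <= 10] <- "6-10"
  out[!is.na(age) & age >= 11 & age <= 15] <- "11-15"
  out[!is.na(age) & age > 15] <- ">15"
  out[is.na(age) & infancy] <- "1-5"
  out
}

#' Sample-composition tables
#'
#' Unweighted counts (respecting the `n_rep` row multiplicity) and
#' integer-rounded percentages describing the pooled sample:
#' \describe{
#'   \item{by_survey}{observations and FGM cases per survey and module,
#'     plus pooled totals;}
#'   \item{composition}{education of women (mother's education for
#'     daughters) and completeness of date-of-birth reporting;}
#'   \item{by_cohort}{observations per birth cohort and module;}
#'   \item{age_at_fgm}{FGM-positive observations per age-at-FGM band
#'     (`<1, 1-5, 6-10, 11-15, >15, missing`) and module. Un-redistributed
#'     infancy codes are counted in the 1-5 band; fractional redistribution
#'     yields fractional band counts (stochastic mode keeps them integer).}
#' }
#'
#' @param records Records data frame.
#' @return Named list of data frames `by_survey`, `composition`,
#'   `by_cohort`, `age_at_fgm`.
#' @export
composition_tables <- function(records) {
  n <- records$n_rep %||% rep(1, nrow(records))
  yes <- records$fgm_status == "yes"

  cell <- function(sel) c(sum(n[sel]), sum(n[sel & yes]))
  surveys <- sort(unique(records$survey_id))
  t1 <- do.call(rbind, lapply(c(surveys, "total"), function(s) {
    in_s <- if (s == "total") rep(TRUE, nrow(records)) else records$survey_id == s
    do.call(rbind, lapply(c("women", "daughters", "both"), function(m) {
      sel <- in_s & (m == "both" | records$module == m)
      v <- cell(sel)
      data.frame(survey_id = s, module = m, n_obs = v[1], n_fgm = v[2],
                 pct_fgm = percent_int(v[2], v[1]), stringsAsFactors = FALSE)
    }))
  }))
  rownames(t1) <- NULL

  comp_block <- function(variable, values, levels) {
    total <- sum(n)
    do.call(rbind, lapply(levels, function(l) {
      data.frame(variable = variable, level = l,
                 n = sum(n[values == l]),
                 pct = percent_int(sum(n[values == l]), total),
                 stringsAsFactors = FALSE)
    }))
  }
  t2 <- rbind(
    comp_block("education", records$education, EDUCATION_LEVELS),
    comp_block("dob_complete", records$dob_complete, DOB_LEVELS)
  )
  rownames(t2) <- NULL

  cohorts <- c(COHORT_ORDER, "missing")
  total <- sum(n)
  t3 <- do.call(rbind, lapply(cohorts, function(co) {
    sel <- records$birth_cohort == co
    data.frame(
      birth_cohort = co,
      n_women = sum(n[sel & records$module == "women"]),
      n_daughters = sum(n[sel & records$module == "daughters"]),
      pct_total = percent_int(sum(n[sel]), total),
      stringsAsFactors = FALSE
    )
  }))
  t3 <- t3[t3$n_women + t3$n_daughters > 0 | t3$birth_cohort != "missing", ,
           drop = FALSE]
  rownames(t3) <- NULL

  band <- age_fgm_band(records$age_at_fgm, records$age_fgm_infancy)
  t4 <- do.call(rbind, lapply(c("women", "daughters"), function(m) {
    in_m <- yes & records$module == m
    denom <- sum(n[in_m])
    do.call(rbind, lapply(AGE_FGM_BANDS, function(b) {
      num <- sum(n[in_m & band == b])
      data.frame(module = m, band = b, n = num,
                 pct = percent_int(num, denom), stringsAsFactors = FALSE)
    }))
  }))
  rownames(t4) <- NULL

  list(by_survey = t1, composition = t2, by_cohort = t3, age_at_fgm = t4)
}

#' Data behind the age-structure figure
#'
#' Weighted count of FGM reports at each exact age, by survey and module —
#' the histogram in which heaping at ages 5, 10 and 15 is visible.
#'
#' @param records Records data frame (redistribution done).
#' @param weighted Use analysis weights (default).
#' @return Data frame: `survey_id`, `module`, `age`, `count`.
#' @export
age_structure_data <- function(records, weighted = TRUE) {
  w <- analysis_weight(records, weighted)
  use <- records$fgm_status == "yes" & !is.na(records$age_at_fgm)
  agg <- aggregate(list(count = w[use]),
                   by = list(survey_id = records$survey_id[use],
                             module = records$module[use],
                             age = records$age_at_fgm[use]),
                   FUN = sum)
  agg <- agg[order(agg$survey_id, agg$module, agg$age), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
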