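# Multi-survey pooling by weight denormalization.
#
# Each DHS ships weights normalized to mean 1 within the survey, which makes
# surveys of different sampling fractions incomparable when stacked. Pooling
# rescales each survey's weights so they sum to the eligible population
# (women 15-49 plus girls 0-14) in the survey year, restoring person units:
# a survey then influences pooled estimates in proportion to the population
# it represents, i.e. weights are adjusted for the likelihood of an
# observation being included in its survey.

#' Denormalize per-survey weights against population totals
#'
#' Computes `weight_denorm = weight_norm * eligible_population /
#' sum(weight_norm)` within each survey (or each survey-module cell when
#' `by_module = TRUE` and the totals carry a `module` column), so that the
#' denormalized weights of every survey sum exactly to its eligible
#' population.
#'
#' @param records Records data frame (see [read_microdata()]).
#' @param totals Data frame with columns `survey_id, eligible_population`
#'   and, if `by_module = TRUE`, `module`.
#' @param by_module Rescale each module separately against per-module
#'   totals. Default `FALSE`: one combined total per survey.
#' @return An object of class `pooled_dataset`: a list with `records`
#'   (input records plus `weight_denorm`) and `provenance` (per survey:
#'   record count, normalized and denormalized weight sums, total used).
#' @export
denormalize <- function(records, totals, by_module = FALSE) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  key <- if (by_module) {
    if (!"module" %in% names(totals)) {
      stop("by_module = TRUE requires a module column in totals")
    }
    paste(records$survey_id, records$module, sep = "\r")
  } else {
    records$survey_id
  }
  tot_key <- if (by_module) {
    paste(totals$survey_id, totals$module, sep = "\r")
  } else {
    totals$survey_id
  }
  if (anyDuplicated(tot_key) > 0) stop("duplicate rows in population totals")
  idx <- match(key, tot_key)
  if (anyNA(idx)) {
    miss <- unique(records$survey_id[is.na(idx)])
    stop("no population total for survey_id: ", paste(miss, collapse = ", "))
  }
  wsum <- tapply(records$weight_norm, key, sum)
  if (any(wsum <= 0)) stop("zero weight sum in a survey")
  scale <- totals$eligible_population[idx] / as.numeric(wsum[key])
  records$weight_denorm <- records$weight_norm * scale

  prov <- aggregate(
    cbind(n_records = rep(1, nrow(records)),
          weight_norm_sum = records$weight_norm,
          weight_denorm_sum = records$weight_denorm),
    by = list(survey_id = records$survey_id), FUN = sum
  )
  prov <- prov[order(prov$survey_id), , drop = FALSE]
  rownames(prov) <- NULL
  structure(list(records = records, provenance = prov),
            class = "pooled_dataset")
}

#' @export
print.pooled_dataset <- function(x, ...) {
  cat("Pooled dataset:", nrow(x$records), "records from",
      nrow(x$provenance), "survey(s)\n")
  print(x$provenance, row.names = FALSE)
  invisible(x)
}

# Analysis weight used throughout: denormalized when pooling has run,
# otherwise the survey-normalized weight, otherwise 1.
analysis_weight <- function(records, weighted = TRUE) {
  if (!weighted) return(records$n_rep %||% rep(1, nrow(records)))
  if (!is.null(records$weight_denorm)) return(records$weight_denorm)
  if (!is.null(records$weight_norm)) return(records$weight_norm)
  rep(1, nrow(records))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
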