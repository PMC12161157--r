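# Data-quality metrics: completeness of age-at-FGM reporting and the
# smooth-transition age-heaping index.
#
# Completeness is the share of FGM-positive records with a reported age at
# FGM; an infancy-coded answer counts as reported (it carries age
# information and is redistributed, not discarded). Heaping compares the
# weighted count of FGM reports at a round age (5, 10, 15) with the count
# expected under a smooth (locally linear) transition from the adjacent
# ages, i.e. the mean of the counts at ages a-1 and a+1; a ratio well
# above 1 marks digit preference. Classic indices such as Whipple's or
# Myers' are not applicable below age 10, which motivates this local index.

#' Completeness profile of age-at-FGM reporting
#'
#' For each group, computes the weighted share of FGM-positive records with
#' missing age at FGM (neither a numeric age nor an infancy code).
#'
#' @param records Records data frame.
#' @param group_by Grouping: `"age"`, `"module"`, `"age_module"` or
#'   `"survey_module"`.
#' @param weighted Use analysis weights (default); `FALSE` uses raw record
#'   counts (respecting the `n_rep` multiplicity).
#' @return Data frame with the grouping columns, `n_fgm_yes` (weighted
#'   FGM-positive mass), `share_missing_age` (`NA` if the group has no
#'   FGM-positive mass) and `undefined` flag.
#' @export
completeness_profile <- function(records,
                                 group_by = c("age_module", "age", "module",
                                              "survey_module"),
                                 weighted = TRUE) {
  group_by <- match.arg(group_by)
  w <- analysis_weight(records, weighted)
  groups <- switch(group_by,
    age = list(current_age = records$current_age),
    module = list(module = records$module),
    age_module = list(module = records$module,
                      current_age = records$current_age),
    survey_module = list(survey_id = records$survey_id,
                         module = records$module)
  )
  yes <- records$fgm_status == "yes"
  missing_age <- yes & is.na(records$age_at_fgm) & !records$age_fgm_infancy
  agg <- aggregate(
    cbind(n_fgm_yes = w * yes, missing_mass = w * missing_age),
    by = groups, FUN = sum
  )
  ord <- do.call(order, agg[names(groups)])
  agg <- agg[ord, , drop = FALSE]
  agg$share_missing_age <- ifelse(agg$n_fgm_yes > 0,
                                  agg$missing_mass / agg$n_fgm_yes, NA_real_)
  agg$undefined <- agg$n_fgm_yes <= 0
  agg$missing_mass <- NULL
  rownames(agg) <- NULL
  agg
}

# Weighted count of FGM reports at each integer age, per module.
weighted_age_counts <- function(records, weighted = TRUE) {
  w <- analysis_weight(records, weighted)
  use <- records$fgm_status == "yes" & !is.na(records$age_at_fgm)
  if (!any(use)) {
    return(data.frame(module = character(0), age = integer(0),
                      count = numeric(0)))
  }
  agg <- aggregate(list(count = w[use]),
                   by = list(module = records$module[use],
                             age = records$age_at_fgm[use]),
                   FUN = sum)
  agg[order(agg$module, agg$age), , drop = FALSE]
}

#' Smooth-transition age-heaping index
#'
#' For each target age `a`, the observed weighted count of FGM reports at
#' `a` is compared with the count expected under a smooth transition from
#' the adjacent ages, `(C(a-1) + C(a+1)) / 2`. The ratio observed/expected
#' equals 1 exactly whenever the age distribution is linear across
#' `{a-1, a, a+1}`, and is invariant to rescaling all weights.
#'
#' @param records Records data frame (redistribution done; remaining ages
#'   numeric where present).
#' @param target_ages Integer ages to test; default `c(5, 10, 15)`. Ages
#'   with `a - 1 < 0` are a hard error. For the daughters' module, target
#'   ages whose upper neighbour exceeds the module's maximum age (14) are
#'   skipped, so no row is emitted at age 15.
#' @param by_module Compute per module (default) or pooled.
#' @param weighted Use analysis weights (default).
#' @return Data frame with columns `module` (or `"all"`), `age`,
#'   `observed`, `expected`, `ratio` (`Inf` with `flag = TRUE` when
#'   expected is 0 and observed positive, `NA` when both are 0).
#' @export
heaping_index <- function(records, target_ages = c(5, 10, 15),
                          by_module = TRUE, weighted = TRUE) {
  if (any(target_ages < 1)) stop("target age must be at least 1")
  counts <- weighted_age_counts(records, weighted)
  if (!by_module) counts$module <- "all"
  modules <- unique(counts$module)
  out <- vector("list", length(modules))
  for (i in seq_along(modules)) {
    m <- modules[i]
    cm <- counts[counts$module == m, , drop = FALSE]
    cfun <- function(a) {
      v <- cm$count[match(a, cm$age)]
      ifelse(is.na(v), 0, v)
    }
    targets <- target_ages
    if (m == "daughters") {
      targets <- targets[targets + 1 <= MODULE_AGE_RANGE$daughters[2]]
    }
    if (length(targets) == 0) next
    observed <- cfun(targets)
    expected <- (cfun(targets - 1) + cfun(targets + 1)) / 2
    ratio <- ifelse(expected > 0, observed / expected,
                    ifelse(observed > 0, Inf, NA_real_))
    out[[i]] <- data.frame(module = m, age = targets, observed = observed,
                           expected = expected, ratio = ratio,
                           flag = expected <= 0, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) {
    res <- data.frame(module = character(0), age = integer(0),
                      observed = numeric(0), expected = numeric(0),
                      ratio = numeric(0), flag = logical(0))
  }
  rownames(res) <- NULL
  res
}
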