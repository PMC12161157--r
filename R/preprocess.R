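# Preprocessing: exclusion of inconsistent reports and redistribution of
# approximate "during infancy" ages at FGM.
#
# Women may answer their age at FGM only approximately ("during infancy").
# Such answers are kept, not dropped: each is redistributed over ages
# 0..infancy_max_age according to the distribution of precise responses at
# those ages by women in the same survey, either fractionally (each record
# split into fractional-weight copies; deterministic) or stochastically
# (one age drawn per record). Records whose reported age at FGM exceeds the
# respondent's current age are internally inconsistent and excluded first.

#' Exclude records with inconsistent age at FGM
#'
#' Removes records whose numeric `age_at_fgm` exceeds `current_age`
#' (equality is allowed). Infancy-coded and missing ages cannot be
#' inconsistent and are always retained. The operation is a pure filter
#' and is idempotent.
#'
#' @param records Records data frame.
#' @return List with `records` (retained rows) and `audit`, a list with
#'   `n_input`, `n_excluded_inconsistent` and a `per_survey` breakdown.
#' @export
exclude_inconsistent <- function(records) {
  bad <- !is.na(records$age_at_fgm) & records$age_at_fgm > records$current_age
  per_survey <- aggregate(
    cbind(n_input = rep(1, nrow(records)), n_excluded = as.integer(bad)),
    by = list(survey_id = records$survey_id), FUN = sum
  )
  per_survey <- per_survey[order(per_survey$survey_id), , drop = FALSE]
  rownames(per_survey) <- NULL
  out <- records[!bad, , drop = FALSE]
  rownames(out) <- NULL
  list(
    records = out,
    audit = list(
      n_input = nrow(records),
      n_excluded_inconsistent = sum(bad),
      per_survey = per_survey
    )
  )
}

#' Build per-survey anchor distributions for infancy redistribution
#'
#' For each survey, estimates the distribution of age at FGM over ages
#' `0..max_age` from precise (numeric) responses in the women's module,
#' weighted by the analysis weight. A survey with no precise early-age
#' women's responses falls back to the pooled all-survey distribution,
#' with a warning.
#'
#' @param records Records data frame (post-exclusion).
#' @param max_age Upper bound of the "infancy" age range in completed
#'   years; default 5.
#' @param weighted Use denormalized weights when available (default);
#'   `FALSE` tallies raw record counts.
#' @return An object of class `redistribution_plan`: a list with `weights`
#'   (matrix, one row per survey plus a `".pooled"` row, columns ages
#'   `0..max_age`, each row summing to 1), `max_age`, and `fallback`
#'   (survey ids that used the pooled distribution).
#' @export
build_anchor_distribution <- function(records, max_age = 5, weighted = TRUE) {
  w <- analysis_weight(records, weighted)
  use <- records$module == "women" & !is.na(records$age_at_fgm) &
    records$age_at_fgm <= max_age
  ages <- factor(records$age_at_fgm[use], levels = 0:max_age)
  surveys <- sort(unique(records$survey_id))
  tab <- matrix(0, nrow = length(surveys), ncol = max_age + 1,
                dimnames = list(surveys, as.character(0:max_age)))
  if (any(use)) {
    agg <- tapply(w[use], list(records$survey_id[use], ages), sum)
    agg[is.na(agg)] <- 0
    tab[rownames(agg), colnames(agg)] <- agg
  }
  pooled <- colSums(tab)
  if (sum(pooled) <= 0) {
    stop("no precise women's-module ages in 0..", max_age,
         " in any survey; cannot build anchor distribution")
  }
  fallback <- rownames(tab)[rowSums(tab) <= 0]
  if (length(fallback) > 0) {
    warning("no precise early-age responses in survey(s) ",
            paste(fallback, collapse = ", "),
            "; using pooled anchor distribution")
    tab[fallback, ] <- matrix(pooled, nrow = length(fallback),
                              ncol = length(pooled), byrow = TRUE)
  }
  tab <- rbind(tab, ".pooled" = pooled)
  tab <- tab / rowSums(tab)
  structure(list(weights = tab, max_age = max_age, fallback = fallback),
            class = "redistribution_plan")
}

#' Redistribute approximate infancy ages at FGM
#'
#' Replaces every infancy-coded record by exact ages `0..max_age` according
#' to its survey's anchor distribution. In `"fractional"` mode each record
#' becomes `max_age + 1` fractional-weight copies (weights and the `n_rep`
#' row-multiplicity column multiplied by the anchor weights), which is
#' deterministic and conserves weighted and unweighted FGM mass exactly. In
#' `"stochastic"` mode one age is drawn per record from the anchor
#' distribution, conserving mass exactly and the age composition in
#' expectation.
#'
#' @param records Records data frame.
#' @param plan A `redistribution_plan` from [build_anchor_distribution()].
#' @param mode `"fractional"` (default) or `"stochastic"`.
#' @param seed Integer seed, required for stochastic mode.
#' @return Records data frame with no infancy-coded rows remaining and an
#'   attribute `n_redistributed`.
#' @export
redistribute_infancy <- function(records, plan,
                                 mode = c("fractional", "stochastic"),
                                 seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(plan, "redistribution_plan"))
  idx <- which(records$age_fgm_infancy)
  if (length(idx) == 0) {
    attr(records, "n_redistributed") <- 0L
    return(records)
  }
  sids <- records$survey_id[idx]
  known <- sids %in% rownames(plan$weights)
  if (!all(known)) {
    stop("infancy-coded records in survey without a redistribution plan: ",
         paste(unique(sids[!known]), collapse = ", "))
  }
  W <- plan$weights[sids, , drop = FALSE]
  ages <- 0:plan$max_age
  if (mode == "fractional") {
    k <- length(ages)
    expand <- records[rep(idx, each = k), , drop = FALSE]
    frac <- as.vector(t(W))
    expand$age_at_fgm <- rep(ages, times = length(idx))
    expand$age_fgm_infancy <- FALSE
    expand$n_rep <- expand$n_rep * frac
    expand$weight_norm <- expand$weight_norm * frac
    if (!is.null(expand$weight_denorm)) {
      expand$weight_denorm <- expand$weight_denorm * frac
    }
    keep_frac <- expand$n_rep > 0
    out <- rbind(records[-idx, , drop = FALSE], expand[keep_frac, , drop = FALSE])
  } else {
    if (is.null(seed)) stop("stochastic mode requires a seed")
    out <- records
    set.seed(seed)
    u <- stats::runif(length(idx))
    cum <- t(apply(W, 1, cumsum))
    pick <- rowSums(u > cum) + 1L
    out$age_at_fgm[idx] <- ages[pick]
    out$age_fgm_infancy[idx] <- FALSE
  }
  rownames(out) <- NULL
  attr(out, "n_redistributed") <- length(idx)
  out
}
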