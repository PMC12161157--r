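# Synthetic DHS-like microdata with a known truth layer.
#
# Emulates the structure of the real surveys: a stratified two-stage
# cluster sample (PSUs within strata, respondents within PSUs) with
# weights equal to inverse inclusion probabilities normalized to mean 1
# per survey; two modules (women 15-49 self-reporting, daughters 0-14
# proxy-reported, education copied from a mother in the same cluster);
# an FGM truth layer (prevalence, true age-at-FGM distribution over ages
# 0..17); and a reporting layer applied in the order heap -> infancy-code
# -> missingness. By default the reporting distortions affect the women's
# (self-reported) module only — the proxy/self data-quality contrast the
# pipeline is built to measure — with per-module overrides available.

GEN_MAX_AGE_FGM <- 17L

#' Construct and validate a generator configuration
#'
#' @param surveys Data frame with columns `survey_id`, `year`, `n_strata`,
#'   `psus_per_stratum`, `respondents_per_psu`, `has_women`,
#'   `has_daughters`, `eligible_population`.
#' @param women_share Probability a respondent row belongs to the women's
#'   module when a survey carries both modules.
#' @param education_probs Named probabilities over
#'   `none, primary, secondary, higher, other` (must sum to 1).
#' @param dob_imputed_prob Probability the date of birth was imputed.
#' @param cohort_missing_prob Probability the birth cohort is missing.
#' @param prevalence Named per-module FGM prevalences
#'   `c(women = , daughters = )`.
#' @param age_fgm_probs List with elements `women` and `daughters`:
#'   probability vectors over true age at FGM 0..17 (each sums to 1; the
#'   draw is truncated at the respondent's current age and renormalized).
#' @param heap_prob Named per-module probabilities that a reported age
#'   within `heap_window` years of a multiple of 5 snaps to it.
#' @param heap_window Displacement window around multiples of 5 (years).
#' @param infancy_prob Named per-module probabilities that a reported age
#'   `<= infancy_max_age` is coded as the approximate `INFANCY` answer.
#' @param infancy_max_age Upper age of the infancy range (years).
#' @param missing_logit Named vector `c(intercept = , women = , age = )`:
#'   log-odds of *complete* age-at-FGM reporting. `intercept` is the
#'   daughters'-module baseline, `women` the module contrast (log odds
#'   ratio of complete reporting, women vs daughters), `age` an optional
#'   per-year-of-current-age slope.
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(surveys,
                             women_share = 0.57,
                             education_probs = c(none = 0.62, primary = 0.20,
                                                 secondary = 0.164,
                                                 higher = 0.015,
                                                 other = 0.001),
                             dob_imputed_prob = 0.64,
                             cohort_missing_prob = 0.005,
                             prevalence = c(women = 0.34, daughters = 0.20),
                             age_fgm_probs = default_age_fgm_probs(),
                             heap_prob = c(women = 0, daughters = 0),
                             heap_window = 2,
                             infancy_prob = c(women = 0, daughters = 0),
                             infancy_max_age = 5,
                             missing_logit = c(intercept = 10, women = 0,
                                               age = 0)) {
  stopifnot(is.data.frame(surveys))
  needed <- c("survey_id", "year", "n_strata", "psus_per_stratum",
              "respondents_per_psu", "has_women", "has_daughters",
              "eligible_population")
  miss <- setdiff(needed, names(surveys))
  if (length(miss) > 0) stop("surveys lacks column(s): ",
                             paste(miss, collapse = ", "))
  if (anyDuplicated(surveys$survey_id) > 0) stop("duplicate survey_id")
  if (any(surveys$n_strata < 1 | surveys$psus_per_stratum < 1 |
          surveys$respondents_per_psu < 1)) {
    stop("design sizes must be >= 1")
  }
  if (any(!surveys$has_women & !surveys$has_daughters)) {
    stop("each survey needs at least one module")
  }
  if (any(surveys$eligible_population <= 0)) {
    stop("eligible_population must be positive")
  }
  chk_prob <- function(x, nm) {
    if (any(x < 0 | x > 1)) stop(nm, " must be in [0, 1]")
  }
  chk_pmf <- function(x, nm) {
    if (any(x < 0) || abs(sum(x) - 1) > 1e-9) stop(nm, " must sum to 1")
  }
  chk_pmf(education_probs, "education_probs")
  if (!setequal(names(education_probs),
                setdiff(EDUCATION_LEVELS, "missing"))) {
    stop("education_probs must be named over ",
         paste(setdiff(EDUCATION_LEVELS, "missing"), collapse = ", "))
  }
  chk_prob(c(women_share, dob_imputed_prob, cohort_missing_prob),
           "shares/probabilities")
  chk_prob(prevalence, "prevalence")
  stopifnot(setequal(names(prevalence), MODULE_LEVELS))
  for (m in MODULE_LEVELS) {
    q <- age_fgm_probs[[m]]
    if (length(q) != GEN_MAX_AGE_FGM + 1) {
      stop("age_fgm_probs$", m, " must have ", GEN_MAX_AGE_FGM + 1,
           " entries (ages 0..", GEN_MAX_AGE_FGM, ")")
    }
    chk_pmf(q, paste0("age_fgm_probs$", m))
  }
  chk_prob(heap_prob, "heap_prob")
  chk_prob(infancy_prob, "infancy_prob")
  stopifnot(setequal(names(heap_prob), MODULE_LEVELS),
            setequal(names(infancy_prob), MODULE_LEVELS))
  if (heap_window < 1 || heap_window > 2) {
    stop("heap_window must be 1 or 2 (larger windows would displace ",
         "mass across adjacent multiples of 5)")
  }
  if (infancy_max_age < 0 || infancy_max_age > GEN_MAX_AGE_FGM) {
    stop("infancy_max_age out of range")
  }
  if (!all(c("intercept", "women") %in% names(missing_logit))) {
    stop("missing_logit needs named entries intercept and women")
  }
  if (!"age" %in% names(missing_logit)) missing_logit["age"] <- 0
  structure(list(surveys = surveys, women_share = women_share,
                 education_probs = education_probs,
                 dob_imputed_prob = dob_imputed_prob,
                 cohort_missing_prob = cohort_missing_prob,
                 prevalence = prevalence, age_fgm_probs = age_fgm_probs,
                 heap_prob = heap_prob, heap_window = heap_window,
                 infancy_prob = infancy_prob,
                 infancy_max_age = infancy_max_age,
                 missing_logit = missing_logit),
            class = "generator_config")
}

#' Default true age-at-FGM distributions
#'
#' Early-childhood-concentrated distributions over ages 0..17 emulating a
#' setting where FGM occurs mostly before age 5: for women about a fifth
#' of cases in the first year of life and roughly five per cent above age
#' 10; for daughters (younger, so their observed ages are further
#' truncated by current age) nearly half of cases in the first year.
#'
#' @return List with normalized probability vectors `women`, `daughters`.
#' @export
default_age_fgm_probs <- function() {
  women <- c(0.20, 0.18, 0.15, 0.13, 0.10, 0.08,
             0.045, 0.030, 0.020, 0.012, 0.008,
             0.006, 0.004, 0.003, 0.002, 0.0015, 0.0008, 0.0007)
  daughters <- c(0.47, 0.14, 0.11, 0.10, 0.07, 0.06,
                 0.012, 0.008, 0.005, 0.003, 0.002,
                 0.005, 0.003, 0.001, 0.001, 0, 0, 0)
  list(women = women / sum(women), daughters = daughters / sum(daughters))
}

#' Closed-form reported-age distribution under heaping
#'
#' Applies the displacement model analytically: each unit of mass at an
#' age within `window` years of a multiple of 5 (target within the
#' support) moves to that multiple with probability `p`. This is the
#' deterministic counterpart of the generator's heaping step, used to
#' derive the heaping ratio implied by a heap probability.
#'
#' @param q Probability vector over ages `0..length(q)-1`.
#' @param p Heap probability.
#' @param window Displacement window (years).
#' @return Displaced probability vector.
#' @export
heaped_pmf <- function(q, p, window = 2) {
  ages <- seq_along(q) - 1L
  target <- round(ages / 5) * 5L
  delta <- abs(ages - target)
  movable <- delta >= 1 & delta <= window & target <= max(ages)
  out <- q
  out[movable] <- out[movable] * (1 - p)
  moved <- tapply(q[movable] * p, target[movable], sum)
  idx <- as.integer(names(moved)) + 1L
  out[idx] <- out[idx] + moved
  out
}

#' Heaping ratio implied by a heap probability
#'
#' Smooth-transition ratio at a target age computed on the closed-form
#' displaced distribution from [heaped_pmf()].
#'
#' @inheritParams heaped_pmf
#' @param age Target age (multiple of 5).
#' @return The ratio `q'(age) / ((q'(age-1) + q'(age+1)) / 2)`.
#' @export
implied_heaping_ratio <- function(q, p, age = 5, window = 2) {
  qq <- heaped_pmf(q, p, window)
  qq[age + 1] / ((qq[age] + qq[age + 2]) / 2)
}

#' Heap probability achieving a target heaping ratio
#'
#' Inverts [implied_heaping_ratio()] in `p` by root finding.
#'
#' @inheritParams implied_heaping_ratio
#' @param ratio Target smooth-transition ratio at `age`.
#' @return Heap probability in (0, 1).
#' @export
heap_prob_for_ratio <- function(q, ratio, age = 5, window = 2) {
  f <- function(p) implied_heaping_ratio(q, p, age, window) - ratio
  stats::uniroot(f, c(0, 1 - 1e-9), tol = 1e-12)$root
}

#' Paper-conditions generator preset
#'
#' A documented configuration whose expected outputs approximate the
#' pooled Senegal DHS composition: FGM prevalence about 34% (women) and
#' 20% (daughters); missing age at FGM about 6% (women) and 1%
#' (daughters), i.e. a women-vs-daughters odds ratio of complete
#' reporting of 0.16 on a 99%-complete daughters' baseline; roughly 45%
#' of FGM-positive women answering "during infancy"; and a women's-module
#' heap probability solved so the displacement closed form gives a
#' smooth-transition ratio of 2.5 at age 5.
#'
#' @param n_surveys Number of survey waves (default 4, years from 2014).
#' @param n_strata,psus_per_stratum,respondents_per_psu Per-survey design
#'   sizes (defaults 12 strata x 4 PSUs x 40 respondents, about 1 920
#'   respondents per survey; scale these up for large-sample checks).
#' @return A `generator_config`.
#' @export
preset_paper_like <- function(n_surveys = 4, n_strata = 12,
                              psus_per_stratum = 4,
                              respondents_per_psu = 40) {
  years <- seq(2014, length.out = n_surveys)
  surveys <- data.frame(
    survey_id = sprintf("SN%d", years),
    year = years,
    n_strata = n_strata,
    psus_per_stratum = psus_per_stratum,
    respondents_per_psu = respondents_per_psu,
    has_women = TRUE,
    has_daughters = TRUE,
    eligible_population = 6e6 + 15e4 * (seq_len(n_surveys) - 1),
    stringsAsFactors = FALSE
  )
  q <- default_age_fgm_probs()
  p_heap <- heap_prob_for_ratio(q$women, ratio = 2.5, age = 5)
  generator_config(
    surveys = surveys,
    prevalence = c(women = 0.34, daughters = 0.20),
    age_fgm_probs = q,
    heap_prob = c(women = p_heap, daughters = 0),
    infancy_prob = c(women = 0.45, daughters = 0),
    missing_logit = c(intercept = stats::qlogis(0.99),
                      women = log(0.16), age = 0)
  )
}

# Decade bin of a birth year; years before 1970 are pooled into the
# oldest cohort.
cohort_bin <- function(birth_year) {
  ifelse(birth_year >= 2020, "post2020",
         COHORT_ORDER[pmax(1, pmin(6, (birth_year - 1960) %/% 10 + 1))])
}

#' Generate synthetic respondent microdata
#'
#' Draws a two-stage cluster sample per survey (PSU frame sizes vary
#' log-normally so inclusion probabilities, hence weights, vary), assigns
#' modules, demographics and FGM truth, then applies the reporting layer
#' in the order heap, infancy-code, missingness. All randomness flows from
#' the single seed.
#'
#' @param config A `generator_config`.
#' @param seed Integer master seed.
#' @return List with `records` (validated records data frame) and `truth`
#'   (data frame `row`, `true_age_fgm` for every FGM-positive record, row
#'   indices into `records`; generator parameters attached as attribute
#'   `config`).
#' @export
generate_microdata <- function(config, seed) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  pieces <- lapply(seq_len(nrow(config$surveys)), function(i) {
    generate_survey(config, config$surveys[i, ])
  })
  records <- do.call(rbind, pieces)
  rownames(records) <- NULL

  n <- nrow(records)
  is_w <- records$module == "women"

  # FGM truth
  prev <- config$prevalence[records$module]
  fgm <- stats::runif(n) < prev
  records$fgm_status <- ifelse(fgm, "yes", "no")
  true_age <- rep(NA_integer_, n)
  for (m in MODULE_LEVELS) {
    sel <- which(fgm & records$module == m)
    if (length(sel) == 0) next
    true_age[sel] <- draw_truncated_ages(config$age_fgm_probs[[m]],
                                         records$current_age[sel])
  }

  # Reporting layer: heap -> infancy-code -> missingness
  reported <- true_age
  pos <- which(fgm)
  target <- as.integer(round(reported[pos] / 5) * 5)
  delta <- abs(reported[pos] - target)
  movable <- delta >= 1 & delta <= config$heap_window &
    target <= GEN_MAX_AGE_FGM
  heap_p <- config$heap_prob[records$module[pos]]
  do_heap <- movable & stats::runif(length(pos)) < heap_p
  reported[pos[do_heap]] <- target[do_heap]

  inf_p <- config$infancy_prob[records$module[pos]]
  do_inf <- reported[pos] <= config$infancy_max_age &
    stats::runif(length(pos)) < inf_p

  lg <- config$missing_logit
  eta <- lg["intercept"] + lg["women"] * is_w[pos] +
    lg["age"] * records$current_age[pos]
  complete <- stats::runif(length(pos)) < stats::plogis(eta)

  records$age_at_fgm <- NA_integer_
  records$age_fgm_infancy <- FALSE
  keep_num <- pos[complete & !do_inf]
  records$age_at_fgm[keep_num] <- reported[keep_num]
  records$age_fgm_infancy[pos[complete & do_inf]] <- TRUE

  records <- records[, c(setdiff(MICRODATA_COLUMNS, "age_at_fgm")[1:5],
                         "age_at_fgm", "age_fgm_infancy",
                         setdiff(MICRODATA_COLUMNS, "age_at_fgm")[6:10],
                         "n_rep")]
  validate_records(records)
  truth <- data.frame(row = pos, true_age_fgm = true_age[pos])
  attr(truth, "config") <- config
  list(records = records, truth = truth)
}

# One survey's design frame and demographics (no FGM fields yet).
generate_survey <- function(config, sv) {
  H <- sv$n_strata
  m <- sv$psus_per_stratum
  nb <- sv$respondents_per_psu
  n_psu <- H * m
  # two-stage inclusion probability: m of M PSUs per stratum, nb of N_hj
  # respondents per sampled PSU; PSU frame sizes vary log-normally
  M <- m * 10
  N_hj <- pmax(nb, round(nb * exp(stats::rnorm(n_psu, 0, 0.35))))
  pi_psu <- (m / M) * (nb / N_hj)
  w_psu <- 1 / pi_psu

  stratum <- rep(seq_len(H), each = m)
  stratum_id <- sprintf("%s_st%02d", sv$survey_id, stratum)
  cluster_id <- sprintf("%s_st%02d_c%02d", sv$survey_id, stratum,
                        rep(seq_len(m), times = H))

  n <- n_psu * nb
  psu_row <- rep(seq_len(n_psu), each = nb)
  w <- w_psu[psu_row]
  w <- w / mean(w)  # normalized to mean 1 within the survey

  if (sv$has_women && sv$has_daughters) {
    module <- ifelse(stats::runif(n) < config$women_share, "women",
                     "daughters")
  } else if (sv$has_women) {
    module <- rep("women", n)
  } else {
    module <- rep("daughters", n)
  }
  age <- integer(n)
  age[module == "women"] <- sample(15:49, sum(module == "women"),
                                   replace = TRUE)
  age[module == "daughters"] <- sample(0:14, sum(module == "daughters"),
                                       replace = TRUE)
  cohort <- cohort_bin(sv$year - age)
  cohort[stats::runif(n) < config$cohort_missing_prob] <- "missing"

  edu_levels <- names(config$education_probs)
  education <- sample(edu_levels, n, replace = TRUE,
                      prob = config$education_probs)
  # daughters take their mother's education: copy from a random woman in
  # the same cluster (a cluster with no sampled woman keeps the draw)
  cl <- psu_row
  for (j in unique(cl[module == "daughters"])) {
    wom <- which(cl == j & module == "women")
    dau <- which(cl == j & module == "daughters")
    if (length(wom) > 0 && length(dau) > 0) {
      education[dau] <- education[wom[sample.int(length(wom), length(dau),
                                                 replace = TRUE)]]
    }
  }
  dob <- ifelse(stats::runif(n) < config$dob_imputed_prob, "imputed",
                "complete")
  data.frame(
    survey_id = sv$survey_id, module = module, current_age = age,
    birth_cohort = cohort, fgm_status = "no",
    age_at_fgm = NA_integer_, age_fgm_infancy = FALSE,
    education = education, dob_complete = dob,
    stratum_id = stratum_id[psu_row], cluster_id = cluster_id[psu_row],
    weight_norm = w, n_rep = 1, stringsAsFactors = FALSE
  )
}

# Inverse-CDF draw from a pmf over ages 0..length(q)-1, truncated at each
# record's current age and renormalized.
draw_truncated_ages <- function(q, current_age) {
  P <- cumsum(q)
  cap <- pmin(current_age, length(q) - 1L) + 1L
  u <- stats::runif(length(current_age)) * P[cap]
  age <- findInterval(u, P)
  pmin(age, cap - 1L)
}

#' Population totals implied by a generator configuration
#'
#' @param config A `generator_config`.
#' @return Data frame `survey_id`, `eligible_population` suitable for
#'   [denormalize()].
#' @export
config_population_totals <- function(config) {
  data.frame(survey_id = config$surveys$survey_id,
             eligible_population = config$surveys$eligible_population,
             stringsAsFactors = FALSE)
}

#' Read a generator configuration from a YAML file
#'
#' The file carries the [generator_config()] fields; `surveys` is a list
#' of per-survey maps. Omitted fields keep the constructor defaults.
#'
#' @param path YAML file path.
#' @return A `generator_config`.
#' @export
read_generator_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$surveys)) stop("config lacks surveys")
  surveys <- do.call(rbind, lapply(cfg$surveys, function(s) {
    as.data.frame(s, stringsAsFactors = FALSE)
  }))
  args <- cfg[setdiff(names(cfg), "surveys")]
  vecs <- c("education_probs", "prevalence", "heap_prob", "infancy_prob",
            "missing_logit")
  for (v in intersect(vecs, names(args))) args[[v]] <- unlist(args[[v]])
  if ("age_fgm_probs" %in% names(args)) {
    args$age_fgm_probs <- lapply(args$age_fgm_probs, unlist)
  }
  do.call(generator_config, c(list(surveys = surveys), args))
}
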