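# Published Senegal DHS 2005-2023 pooled summary counts (FGM frequency by
# wave and module, women's education and date-of-birth completeness, birth
# cohorts, age-at-FGM bands), shipped as plain CSVs under extdata. Used to
# check that the package's percentage arithmetic reproduces the printed
# integers from the printed numerators and denominators.

#' Published pooled Senegal DHS summary counts
#'
#' @param which One of `"by_survey"`, `"composition"`, `"cohorts"`,
#'   `"age_bands"`.
#' @return Data frame with counts and the published integer percentages
#'   (`printed_pct`).
#' @export
published_counts <- function(which = c("by_survey", "composition",
                                       "cohorts", "age_bands")) {
  which <- match.arg(which)
  file <- switch(which,
    by_survey = "senegal_fgm_by_survey.csv",
    composition = "senegal_composition.csv",
    cohorts = "senegal_cohorts.csv",
    age_bands = "senegal_age_at_fgm_bands.csv"
  )
  path <- system.file("extdata", file, package = "fgmq", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}
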