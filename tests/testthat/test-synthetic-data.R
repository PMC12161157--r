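cfg_small <- function(...) {
  surveys <- data.frame(
    survey_id = c("SNA", "SNB"), year = c(2015, 2017), n_strata = 4,
    psus_per_stratum = 3, respondents_per_psu = 30,
    has_women = TRUE, has_daughters = c(FALSE, TRUE),
    eligible_population = c(1e6, 2e6)
  )
  generator_config(surveys, ...)
}

test_that("generated records satisfy the schema invariants and design", {
  sim <- generate_microdata(cfg_small(), seed = 1)
  r <- sim$records
  expect_true(validate_records(r))
  expect_equal(nrow(r), 2 * 4 * 3 * 30)
  # normalized weights average 1 within each survey
  expect_equal(as.numeric(tapply(r$weight_norm, r$survey_id, mean)), c(1, 1),
               tolerance = 1e-12)
  # survey without a daughters' module emits only women
  expect_true(all(r$module[r$survey_id == "SNA"] == "women"))
  # truth recorded for every FGM-positive record, and only those
  expect_setequal(sim$truth$row, which(r$fgm_status == "yes"))
  expect_true(all(sim$truth$true_age_fgm >= 0 &
                    sim$truth$true_age_fgm <= 17))
  # truth never exceeds current age (truncated draw)
  expect_true(all(sim$truth$true_age_fgm <=
                    r$current_age[sim$truth$row]))
})

test_that("generation is reproducible under a fixed seed", {
  a <- generate_microdata(cfg_small(), seed = 99)
  b <- generate_microdata(cfg_small(), seed = 99)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$true_age_fgm, b$truth$true_age_fgm)
})

test_that("with no distortions the reported ages equal the truth", {
  cfg <- cfg_small(heap_prob = c(women = 0, daughters = 0),
                   infancy_prob = c(women = 0, daughters = 0),
                   missing_logit = c(intercept = 30, women = 0, age = 0))
  sim <- generate_microdata(cfg, seed = 2)
  r <- sim$records
  expect_false(any(r$age_fgm_infancy))
  expect_equal(r$age_at_fgm[sim$truth$row], sim$truth$true_age_fgm)
})

test_that("infancy probability 1 codes every early age as INFANCY", {
  cfg <- cfg_small(infancy_prob = c(women = 1, daughters = 1),
                   missing_logit = c(intercept = 30, women = 0, age = 0))
  sim <- generate_microdata(cfg, seed = 3)
  r <- sim$records
  is_early <- sim$truth$true_age_fgm <= 5
  early <- sim$truth$row[is_early]
  expect_true(all(r$age_fgm_infancy[early]))
  expect_true(all(is.na(r$age_at_fgm[early])))
  expect_equal(r$age_at_fgm[sim$truth$row[!is_early]],
               sim$truth$true_age_fgm[!is_early])
})

test_that("the configured module effect reproduces the empirical odds ratio", {
  surveys <- data.frame(
    survey_id = "SNOR", year = 2017, n_strata = 20, psus_per_stratum = 10,
    respondents_per_psu = 100, has_women = TRUE, has_daughters = TRUE,
    eligible_population = 6e6
  )
  cfg <- generator_config(surveys, women_share = 0.5,
                          prevalence = c(women = 1, daughters = 1),
                          missing_logit = c(intercept = 1, women = log(0.16),
                                            age = 0))
  sim <- generate_microdata(cfg, seed = 4)  # 20 000 FGM-positive records
  r <- sim$records
  complete <- !is.na(r$age_at_fgm) | r$age_fgm_infancy
  tab <- table(r$module, complete)
  or_hat <- (tab["women", "TRUE"] * tab["daughters", "FALSE"]) /
    (tab["women", "FALSE"] * tab["daughters", "TRUE"])
  se_log <- sqrt(sum(1 / tab))
  expect_true(abs(log(or_hat) - log(0.16)) < 3 * se_log)
})

test_that("the paper-conditions preset validates and hits its configured rates", {
  cfg <- preset_paper_like()
  expect_s3_class(cfg, "generator_config")
  expect_equal(stats::plogis(cfg$missing_logit[["intercept"]]), 0.99)
  expect_equal(exp(cfg$missing_logit[["women"]]), 0.16)
  expect_equal(
    implied_heaping_ratio(default_age_fgm_probs()$women,
                          cfg$heap_prob[["women"]], age = 5),
    2.5, tolerance = 1e-8)

  big <- preset_paper_like(n_strata = 25, psus_per_stratum = 10,
                           respondents_per_psu = 100)
  sim <- generate_microdata(big, seed = 5)  # 100 000 respondents
  r <- sim$records
  yes_w <- r$fgm_status == "yes" & r$module == "women"
  miss_w <- yes_w & is.na(r$age_at_fgm) & !r$age_fgm_infancy
  p_miss <- 1 - stats::plogis(big$missing_logit[["intercept"]] +
                                big$missing_logit[["women"]])
  se <- sqrt(p_miss * (1 - p_miss) / sum(yes_w))
  expect_true(abs(sum(miss_w) / sum(yes_w) - p_miss) < 3 * se)
  expect_lt(abs(p_miss - 0.06), 0.002)  # preset design target ~6%
  # prevalence within 3 binomial s.e. of the configured rates
  for (m in c("women", "daughters")) {
    n_m <- sum(r$module == m)
    p <- big$prevalence[[m]]
    expect_true(abs(mean(r$fgm_status[r$module == m] == "yes") - p) <
                  3 * sqrt(p * (1 - p) / n_m))
  }
})

test_that("redistribution reconstructs the true early-age distribution", {
  # infancy coding strikes ages 0..5 uniformly, so the precise survivors
  # keep the true shape and redistribution is consistent: at n = 100 000
  # FGM ages the reconstructed 0..5 distribution is within TV 0.02 of truth
  q <- default_age_fgm_probs()$women
  surveys <- data.frame(
    survey_id = "SNTV", year = 2017, n_strata = 25, psus_per_stratum = 10,
    respondents_per_psu = 400, has_women = TRUE, has_daughters = FALSE,
    eligible_population = 6e6
  )
  cfg <- generator_config(surveys, prevalence = c(women = 1, daughters = 1),
                          infancy_prob = c(women = 0.6, daughters = 0),
                          missing_logit = c(intercept = 30, women = 0,
                                            age = 0))
  sim <- generate_microdata(cfg, seed = 6)
  plan <- build_anchor_distribution(sim$records, weighted = FALSE)
  rec <- redistribute_infancy(sim$records, plan, mode = "fractional")
  early <- !is.na(rec$age_at_fgm) & rec$age_at_fgm <= 5
  reconstructed <- tapply(rec$n_rep[early], rec$age_at_fgm[early], sum)
  reconstructed <- as.numeric(reconstructed / sum(reconstructed))
  truth <- q[1:6] / sum(q[1:6])
  expect_lt(0.5 * sum(abs(reconstructed - truth)), 0.02)
})

test_that("infeasible configurations fail validation", {
  expect_error(cfg_small(prevalence = c(women = 1.2, daughters = 0.2)),
               "prevalence")
  expect_error(cfg_small(heap_window = 3), "heap_window")
  expect_error(cfg_small(education_probs = c(none = 0.5, primary = 0.2,
                                             secondary = 0.2, higher = 0.05,
                                             other = 0.01)),
               "sum to 1")
  bad_q <- default_age_fgm_probs()
  bad_q$women <- bad_q$women[1:10]
  expect_error(cfg_small(age_fgm_probs = bad_q), "age_fgm_probs")
})

test_that("a YAML config round-trips through the reader", {
  cfg <- cfg_small()
  path <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(list(
    surveys = split(cfg$surveys, seq_len(nrow(cfg$surveys))),
    prevalence = as.list(cfg$prevalence),
    heap_prob = as.list(c(women = 0.1, daughters = 0)),
    missing_logit = as.list(c(intercept = 2, women = log(0.5), age = 0))
  ), path)
  back <- read_generator_config(path)
  expect_s3_class(back, "generator_config")
  expect_equal(back$surveys$survey_id, cfg$surveys$survey_id)
  expect_equal(unname(back$heap_prob["women"]), 0.1)
  # YAML serializes reals at finite precision
  expect_equal(unname(back$missing_logit["women"]), log(0.5),
               tolerance = 1e-6)
})
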