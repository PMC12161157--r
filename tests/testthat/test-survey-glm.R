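# Inputs for a 2x2 exposure-outcome table, each observation its own PSU in
# a single stratum, unit weights.
toy_2x2 <- function(a, b, c, d) {
  x <- rep(c(1, 1, 0, 0), times = c(a, b, c, d))
  y <- rep(c(1, 0, 1, 0), times = c(a, b, c, d))
  n <- length(x)
  list(X = cbind("(Intercept)" = 1, exposure = x), y = y, w = rep(1, n),
       stratum = rep("s1", n), cluster = paste0("psu", seq_len(n)))
}

# Dense-matrix sandwich oracle for independent PSUs in one stratum.
oracle_sandwich <- function(X, y, w, beta) {
  mu <- plogis(drop(X %*% beta))
  A <- t(X) %*% (X * (w * mu * (1 - mu)))
  U <- X * (w * (y - mu))
  Uc <- sweep(U, 2, colMeans(U))
  n <- nrow(X)
  V <- solve(A) %*% (t(Uc) %*% Uc * n / (n - 1)) %*% solve(A)
  sqrt(diag(V))
}

test_that("a balanced 2x2 gives odds ratio 1", {
  fit <- fit_design_logit(toy_2x2(10, 10, 10, 10))
  expect_equal(fit$coefficients$or[2], 1.0, tolerance = 1e-8)
})

test_that("the fitted OR equals the cross-product ratio", {
  fit <- fit_design_logit(toy_2x2(40, 10, 20, 30))
  expect_equal(fit$coefficients$or[2], (40 * 30) / (10 * 20),
               tolerance = 1e-6)
  expect_true(fit$converged)
  expect_equal(fit$df, 100 - 1)
})

test_that("one-observation PSUs reproduce the dense sandwich oracle", {
  inputs <- toy_2x2(40, 10, 20, 30)
  fit <- fit_design_logit(inputs)
  se_oracle <- oracle_sandwich(inputs$X, inputs$y, inputs$w,
                               fit$coefficients$estimate)
  expect_equal(fit$coefficients$se, unname(se_oracle), tolerance = 1e-6)

  # and with unequal weights
  set.seed(41)
  inputs$w <- runif(length(inputs$y), 0.3, 2.5)
  fit_w <- fit_design_logit(inputs)
  se_oracle_w <- oracle_sandwich(inputs$X, inputs$y, inputs$w,
                                 fit_w$coefficients$estimate)
  expect_equal(fit_w$coefficients$se, unname(se_oracle_w), tolerance = 1e-6)
})

test_that("equal weights and independent PSUs match maximum likelihood", {
  set.seed(42)
  n <- 300
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x1 - 0.6 * x2))
  X <- cbind("(Intercept)" = 1, x1 = x1, x2 = x2)
  fit <- fit_design_logit(list(X = X, y = y, w = rep(1, n),
                               stratum = rep("s1", n),
                               cluster = paste0("c", seq_len(n))))
  ml <- glm(y ~ x1 + x2, family = binomial())
  expect_equal(fit$coefficients$estimate, unname(coef(ml)), tolerance = 1e-6)
})

test_that("replicating records with weight 1/k leaves estimates unchanged", {
  base <- toy_2x2(12, 7, 9, 14)
  fit0 <- fit_design_logit(base)
  k <- 4
  n <- length(base$y)
  idx <- rep(seq_len(n), each = k)
  rep_inputs <- list(X = base$X[idx, ], y = base$y[idx], w = rep(1 / k, n * k),
                     stratum = base$stratum[idx], cluster = base$cluster[idx])
  fitk <- fit_design_logit(rep_inputs)
  expect_equal(fitk$coefficients$estimate, fit0$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("the design matrix uses the published reference coding", {
  rec <- rbind(
    make_records(survey_id = "SN2005", module = "daughters", current_age = 3L,
                 birth_cohort = "2000s", age_at_fgm = 1L, education = "none",
                 dob_complete = "imputed", stratum_id = "SN2005_st1",
                 cluster_id = "SN2005_c1"),
    make_records(survey_id = "SN2017", module = "women", current_age = 30L,
                 age_at_fgm = NA_integer_, education = "secondary",
                 dob_complete = "complete", stratum_id = "SN2017_st1",
                 cluster_id = "SN2017_c1"),
    make_records(survey_id = "SN2017", module = "women", current_age = 40L,
                 age_at_fgm = 5L, education = "primary",
                 dob_complete = "imputed", stratum_id = "SN2017_st1",
                 cluster_id = "SN2017_c2"),
    make_records(survey_id = "SN2005", module = "women", current_age = 20L,
                 age_fgm_infancy = TRUE, education = "higher",
                 dob_complete = "complete", stratum_id = "SN2005_st1",
                 cluster_id = "SN2005_c2"),
    make_records(survey_id = "SN2017", module = "daughters", current_age = 10L,
                 birth_cohort = "2000s", age_at_fgm = 2L, education = "none",
                 dob_complete = "imputed", stratum_id = "SN2017_st1",
                 cluster_id = "SN2017_c3"),
    make_records(survey_id = "SN2005", module = "women", current_age = 25L,
                 age_at_fgm = 4L, education = "missing",
                 dob_complete = "complete", stratum_id = "SN2005_st1",
                 cluster_id = "SN2005_c3")
  )
  inp <- build_design_matrix(rec)
  # the education=missing record is dropped listwise and counted
  expect_equal(inp$n_dropped, 1)
  expect_equal(inp$n_used, 5)
  # outcome: reported (numeric or infancy) = 1, missing = 0
  expect_equal(inp$y, c(1, 0, 1, 1, 1))
  hand <- cbind(
    "(Intercept)" = rep(1, 5),
    surveySN2017 = c(0, 1, 1, 0, 1),
    modulewomen = c(0, 1, 1, 1, 0),
    age = c(3, 30, 40, 20, 10),
    educationprimary = c(0, 0, 1, 0, 0),
    educationsecondary = c(0, 1, 0, 0, 0),
    educationhigher = c(0, 0, 0, 1, 0),
    dobcomplete = c(0, 1, 0, 1, 0)
  )
  expect_equal(unname(inp$X[, colnames(hand)]), unname(hand))
  # reference cell: all dummies zero except intercept and age
  expect_equal(unname(inp$X[1, setdiff(colnames(inp$X),
                                       c("(Intercept)", "age"))]),
               rep(0, ncol(inp$X) - 2))
})

test_that("strata and clustering enter the variance, not the estimates", {
  set.seed(43)
  n <- 200
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(0.4 * x))
  X <- cbind("(Intercept)" = 1, x = x)
  w <- runif(n, 0.5, 2)
  iid <- fit_design_logit(list(X = X, y = y, w = w,
                               stratum = rep("s1", n),
                               cluster = paste0("c", 1:n)))
  clustered <- fit_design_logit(list(X = X, y = y, w = w,
                                     stratum = rep(c("s1", "s2"), each = n / 2),
                                     cluster = paste0("c", rep(1:20, each = 10))))
  expect_equal(clustered$coefficients$estimate, iid$coefficients$estimate,
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(clustered$coefficients$se,
                                iid$coefficients$se)))
  expect_equal(clustered$df, 20 - 2)
})
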