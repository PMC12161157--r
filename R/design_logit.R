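# Design-based logistic regression for completeness of age-at-FGM
# reporting.
#
# Point estimates solve the weighted logistic score equations by IRLS.
# Variance is by Taylor linearization: the per-record score residuals
# u_i = w_i (y_i - mu_i) x_i are summed to PSU (cluster) totals, centered
# within strata, and combined with the stratum factor n_h / (n_h - 1);
# the sandwich is A^{-1} V A^{-1} with A the weighted information
# t(X) diag(w mu (1-mu)) X. Confidence intervals are Wald on the log-odds
# scale with a t quantile at the design degrees of freedom
# (#PSUs - #strata), the standard complex-survey convention.

#' Build the model inputs for the completeness regression
#'
#' The outcome is defined on FGM-positive records only: 1 if age at FGM
#' was reported (a numeric age or an infancy code), 0 if missing.
#' Covariates use treatment coding with the references of the published
#' analysis convention: education = none, survey = earliest survey id,
#' module = daughters, date of birth = imputed; age enters as a single
#' continuous term (current age of the woman or daughter). Records with a
#' missing model covariate (or the rare `other` education, absent from the
#' published table layout) are dropped listwise and counted.
#'
#' @param records Records data frame.
#' @param terms Character vector among `"survey"`, `"module"`, `"age"`,
#'   `"education"`, `"dob"`.
#' @param survey_ref Reference survey id; default the lexicographically
#'   first (the earliest wave under year-based ids).
#' @return List with `X` (model matrix), `y`, `w` (analysis weights),
#'   `stratum`, `cluster`, `n_used`, `n_dropped`, `terms`.
#' @export
build_design_matrix <- function(records,
                                terms = c("survey", "module", "age",
                                          "education", "dob"),
                                survey_ref = NULL) {
  terms <- match.arg(terms, several.ok = TRUE)
  d <- records[records$fgm_status == "yes", , drop = FALSE]
  if (nrow(d) == 0) stop("no FGM-positive records")
  y <- as.numeric(!is.na(d$age_at_fgm) | d$age_fgm_infancy)

  drop <- rep(FALSE, nrow(d))
  # "other" education is too rare to estimate and absent from the published
  # table layout; dropped listwise together with missing
  if ("education" %in% terms) {
    drop <- drop | d$education %in% c("missing", "other")
  }
  n_dropped <- sum(drop)
  d <- d[!drop, , drop = FALSE]
  y <- y[!drop]

  df <- data.frame(row.names = seq_len(nrow(d)))
  if ("survey" %in% terms) {
    lev <- sort(unique(d$survey_id))
    if (is.null(survey_ref)) survey_ref <- lev[1]
    df$survey <- factor(d$survey_id, levels = c(survey_ref,
                                                setdiff(lev, survey_ref)))
  }
  if ("module" %in% terms) {
    df$module <- factor(d$module, levels = c("daughters", "women"))
  }
  if ("age" %in% terms) df$age <- d$current_age
  if ("education" %in% terms) {
    lev <- intersect(EDUCATION_LEVELS, unique(d$education))
    if (!"none" %in% lev) lev <- c("none", lev)
    df$education <- factor(d$education, levels = c("none",
                                                   setdiff(lev, "none")))
  }
  if ("dob" %in% terms) {
    df$dob <- factor(d$dob_complete, levels = c("imputed", "complete"))
  }
  # drop factor levels emptied by subsetting, with a warning
  for (v in names(df)) {
    if (is.factor(df[[v]])) {
      empty <- setdiff(levels(df[[v]]), as.character(unique(df[[v]])))
      empty <- setdiff(empty, levels(df[[v]])[1])
      if (length(empty) > 0) {
        warning("dropping empty level(s) of ", v, ": ",
                paste(empty, collapse = ", "))
        df[[v]] <- droplevels(df[[v]])
      }
      if (nlevels(df[[v]]) < 2) {
        warning("term ", v, " has a single level after subsetting; dropped")
        df[[v]] <- NULL
      }
    }
  }
  if (ncol(df) == 0) stop("no usable model terms")
  X <- stats::model.matrix(~ ., data = df)
  list(X = X, y = y, w = analysis_weight(d),
       stratum = d$stratum_id, cluster = d$cluster_id,
       n_used = nrow(d), n_dropped = n_dropped, terms = terms)
}

#' Fit a design-based logistic regression
#'
#' Weighted IRLS point estimates with Taylor-linearized (sandwich)
#' variance honouring strata and clusters; see the package vignette for
#' the estimator. Convergence is declared when the maximum absolute score
#' falls below `1e-8` or the relative deviance change below `1e-10`,
#' within 50 iterations.
#'
#' @param inputs List as returned by [build_design_matrix()], or any list
#'   with elements `X`, `y`, `w`, `stratum`, `cluster`.
#' @return Object of class `design_logit`: coefficient table (estimate,
#'   design SE, odds ratio, Wald-t 95% CI), covariance matrix, design
#'   degrees of freedom, iteration and convergence info.
#' @export
fit_design_logit <- function(inputs) {
  X <- inputs$X
  y <- inputs$y
  w <- inputs$w
  stopifnot(length(y) == nrow(X), length(w) == nrow(X), all(w > 0),
            all(y %in% c(0, 1)))
  p <- ncol(X)

  beta <- rep(0, p)
  if ("(Intercept)" %in% colnames(X)) {
    mu0 <- min(max(sum(w * y) / sum(w), 1e-6), 1 - 1e-6)
    beta[match("(Intercept)", colnames(X))] <- stats::qlogis(mu0)
  }
  dev_old <- Inf
  converged <- FALSE
  for (iter in seq_len(50)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    v <- mu * (1 - mu)
    score <- drop(crossprod(X, w * (y - mu)))
    dev <- -2 * sum(w * (y * log(mu) + (1 - y) * log1p(-mu)))
    if (max(abs(score)) < 1e-8 ||
        abs(dev - dev_old) < 1e-10 * (abs(dev_old) + 1e-10)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
    z <- eta + (y - mu) / v
    fit <- stats::lm.wfit(X, z, w * v)
    beta <- fit$coefficients
    if (anyNA(beta)) stop("singular design matrix in IRLS")
  }
  if (!converged) {
    stop("IRLS did not converge in 50 iterations; last estimates: ",
         paste(signif(beta, 6), collapse = ", "))
  }
  if (any(abs(beta[colnames(X) != "(Intercept)"]) > 15)) {
    warning("possible separation: |estimate| > 15")
  }

  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  v <- mu * (1 - mu)
  A <- crossprod(X, X * (w * v))
  V_score <- linearized_score_variance(X * (w * (y - mu)),
                                       inputs$cluster, inputs$stratum)
  Ainv <- solve(A)
  V <- Ainv %*% V_score$V %*% Ainv
  dimnames(V) <- list(colnames(X), colnames(X))
  se <- sqrt(diag(V))
  df <- V_score$df
  tq <- stats::qt(0.975, df)
  tab <- data.frame(
    term = colnames(X),
    estimate = unname(beta),
    se = unname(se),
    or = exp(unname(beta)),
    ci_low = exp(unname(beta) - tq * unname(se)),
    ci_high = exp(unname(beta) + tq * unname(se)),
    stringsAsFactors = FALSE
  )
  structure(list(coefficients = tab, vcov = V, df = df,
                 n_psu = V_score$n_psu, n_strata = V_score$n_strata,
                 n_used = length(y), n_dropped = inputs$n_dropped %||% 0L,
                 iterations = iter, deviance = dev, converged = TRUE),
            class = "design_logit")
}

# Variance of the total score under the stratified cluster design:
# PSU totals of the score residuals, centered within strata, stratum
# factor n_h / (n_h - 1). Strata with a single PSU cannot contribute a
# variance term and are skipped with a warning.
linearized_score_variance <- function(U, cluster, stratum) {
  psu_tot <- rowsum(U, group = cluster, reorder = TRUE)
  psu_stratum <- stratum[!duplicated(cluster)]
  names(psu_stratum) <- cluster[!duplicated(cluster)]
  psu_stratum <- psu_stratum[rownames(psu_tot)]
  p <- ncol(U)
  V <- matrix(0, p, p)
  n_psu <- nrow(psu_tot)
  strata <- unique(psu_stratum)
  singleton <- FALSE
  for (h in strata) {
    rows <- which(psu_stratum == h)
    n_h <- length(rows)
    if (n_h < 2) {
      singleton <- TRUE
      next
    }
    uh <- psu_tot[rows, , drop = FALSE]
    uh <- sweep(uh, 2, colMeans(uh))
    V <- V + crossprod(uh) * n_h / (n_h - 1)
  }
  if (singleton) {
    warning("stratum with a single PSU contributes no variance term")
  }
  df <- n_psu - length(strata)
  if (df < 1) stop("design degrees of freedom < 1")
  list(V = V, df = df, n_psu = n_psu, n_strata = length(strata))
}

#' @export
print.design_logit <- function(x, digits = 3, ...) {
  cat("Design-based logistic regression\n")
  cat(sprintf("  n = %d (dropped %d), PSUs = %d, strata = %d, df = %d\n",
              x$n_used, x$n_dropped, x$n_psu, x$n_strata, x$df))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Completeness regression mirroring the published table layout
#'
#' Convenience wrapper: builds the design matrix for the completeness
#' outcome and fits the design-based logit, returning an odds-ratio table
#' with one row per non-reference level (plus reference rows with OR 1).
#'
#' @inheritParams build_design_matrix
#' @return List with `fit` (the `design_logit` object) and `table`
#'   (data frame: term, level, or, ci_low, ci_high).
#' @export
completeness_model <- function(records,
                               terms = c("survey", "module", "age",
                                         "education", "dob"),
                               survey_ref = NULL) {
  inputs <- build_design_matrix(records, terms = terms,
                                survey_ref = survey_ref)
  fit <- fit_design_logit(inputs)
  tab <- fit$coefficients
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  out <- data.frame(term = tab$term, or = tab$or, ci_low = tab$ci_low,
                    ci_high = tab$ci_high, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  list(fit = fit, table = out)
}
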