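# One-sample Mendelian randomisation via weighted allele scores.

design_matrix <- function(x, cols) {
  if (!length(cols)) return(matrix(1, x$n, 1, dimnames = list(NULL, "(Intercept)")))
  cbind("(Intercept)" = 1, as.matrix(x$phenotypes[, cols, drop = FALSE]))
}

# Correct two-stage least squares for one endogenous regressor:
# instruments Z = [1, score, covars], regressors X = [1, exposure, covars].
tsls_fit <- function(y, exposure, score, covars_mat) {
  X <- cbind(1, exposure, covars_mat)
  Z <- cbind(1, score, covars_mat)
  Xhat <- Z %*% solve(crossprod(Z), crossprod(Z, X))
  beta <- solve(crossprod(Xhat), crossprod(Xhat, y))
  resid <- y - X %*% beta          # structural residuals, original X
  sigma2 <- sum(resid^2) / (length(y) - ncol(X))
  vcov <- sigma2 * solve(crossprod(Xhat))
  list(beta = beta[2], se = sqrt(vcov[2, 2]))
}

#' One-sample MR with a weighted allele score
#'
#' Continuous outcomes use two-stage least squares with the score (plus
#' covariates) as instruments. Binary outcomes use the ratio of the
#' reduced-form log-odds coefficient (logistic regression of the outcome on
#' the score and covariates) to the first-stage linear coefficient (exposure
#' on score and covariates), with a first-order delta-method standard
#' error — the score-based Wald estimator.
#'
#' @param x a `cohort`.
#' @param score numeric score vector (e.g. from [build_allele_score()]) with
#'   nonzero variance.
#' @param exposure_col,outcome_col phenotype column names.
#' @param covariates character vector of phenotype columns adjusted for.
#' @param binary_outcome `NULL` (auto-detect 0/1), or logical.
#' @param min_first_stage_p sanity threshold for the first-stage
#'   association; a weaker instrument triggers a warning, not an error.
#' @return An `mr_estimate` with method `"one_sample_ratio"` (binary) or
#'   `"one_sample_tsls"` (continuous); `extra` records the first-stage
#'   coefficient and p-value.
#' @export
one_sample_mr <- function(x, score, exposure_col, outcome_col,
                          covariates = character(), binary_outcome = NULL,
                          min_first_stage_p = 1e-3) {
  stopifnot(inherits(x, "cohort"))
  assert_that(stats::var(score) > 0, "allele score has zero variance")
  y <- x$phenotypes[[outcome_col]]
  e <- x$phenotypes[[exposure_col]]
  C <- if (length(covariates)) as.matrix(x$phenotypes[, covariates, drop = FALSE]) else NULL
  binary <- binary_outcome %||% all(y %in% c(0, 1))

  Z <- cbind(1, score, C)
  fs <- stats::lm.fit(Z, e)
  fs_sigma2 <- sum(fs$residuals^2) / (x$n - ncol(Z))
  ZtZinv <- chol2inv(chol(crossprod(Z)))
  fs_beta <- fs$coefficients[2]
  fs_se <- sqrt(fs_sigma2 * ZtZinv[2, 2])
  fs_p <- two_sided_p(fs_beta / fs_se)
  if (fs_p > min_first_stage_p) {
    warning(sprintf("weak first stage: score-exposure p = %.3g", fs_p))
  }

  if (binary) {
    rf <- stats::glm.fit(Z, y, family = stats::binomial())
    rf_vcov <- chol2inv(chol(crossprod(Z * sqrt(rf$weights))))
    rf_beta <- rf$coefficients[2]
    rf_se <- sqrt(rf_vcov[2, 2])
    est <- mr_estimate(rf_beta / fs_beta, rf_se / abs(fs_beta),
                       "one_sample_ratio", length(score),
                       extra = list(first_stage_beta = fs_beta,
                                    first_stage_p = fs_p,
                                    reduced_form_beta = rf_beta))
  } else {
    fit <- tsls_fit(y, e, score, C)
    est <- mr_estimate(fit$beta, fit$se, "one_sample_tsls", length(score),
                       extra = list(first_stage_beta = fs_beta,
                                    first_stage_p = fs_p))
  }
  est$n_snps <- NA_integer_  # score-based: SNP count lives with the score definition
  est
}

# Multivariable score-based ratio estimator: with scores S (n x q) for q
# exposures X (n x q), reduced-form coefficients g (outcome ~ S + covars)
# and first-stage coefficient matrix B[s, j] (score s -> exposure j), the
# chain y <- X <- S implies g = B c, so the causal coefficients are
# c = solve(B, g). The analogue of regression-based MVMR for
# individual-level data.
one_sample_mv_ratio <- function(x, scores, exposure_cols, outcome_col,
                                covariates = character(), binary_outcome = NULL) {
  stopifnot(inherits(x, "cohort"), is.matrix(scores) || is.data.frame(scores))
  S <- as.matrix(scores)
  q <- ncol(S)
  stopifnot(length(exposure_cols) == q)
  y <- x$phenotypes[[outcome_col]]
  C <- if (length(covariates)) as.matrix(x$phenotypes[, covariates, drop = FALSE]) else NULL
  binary <- binary_outcome %||% all(y %in% c(0, 1))
  Z <- cbind(1, S, C)
  sidx <- 1 + seq_len(q)

  B <- vapply(exposure_cols, function(col) {
    stats::lm.fit(Z, x$phenotypes[[col]])$coefficients[sidx]
  }, numeric(q))                       # q (scores) x q (exposures)
  g <- if (binary) {
    stats::glm.fit(Z, y, family = stats::binomial())$coefficients[sidx]
  } else {
    stats::lm.fit(Z, y)$coefficients[sidx]
  }
  cvec <- solve(B, g)
  stats::setNames(cvec, exposure_cols)
}

#' One-sample MR mediation with allele scores
#'
#' Product-of-coefficients mediation in a single cohort: `a` is the 2SLS
#' effect of the exposure on the mediator (exposure score as instrument);
#' `b` is the mediator's coefficient from the multivariable score-based
#' ratio estimator (outcome on exposure + mediator, instrumented by both
#' scores); the total effect uses the exposure score alone. With several
#' mediators the difference method is used instead:
#' `P = (T - D)/T` with `D` the exposure coefficient from the multivariable
#' estimator including all mediators. Uncertainty comes from a nonparametric
#' bootstrap over participants (percentile CIs), reproducible under `seed`.
#'
#' @param x a `cohort`.
#' @param scores named list/data.frame of score columns: first the exposure
#'   score, then one per mediator, in `c(exposure_col, mediator_cols)` order.
#' @param exposure_col,outcome_col phenotype columns.
#' @param mediator_cols one (product method) or several (difference method)
#'   phenotype columns.
#' @param covariates adjusted-for phenotype columns.
#' @param n_boot bootstrap replicates (0 skips the bootstrap: point
#'   estimates only, delta-method proportion se).
#' @param seed integer seed (required when `n_boot > 0`).
#' @param scale `"logit"` (default) or `"risk_difference"` (linear
#'   probability model replication).
#' @return A `mediation_estimate`.
#' @export
one_sample_mediation <- function(x, scores, exposure_col, mediator_cols,
                                 outcome_col, covariates = character(),
                                 n_boot = 1000, seed = NULL,
                                 scale = c("logit", "risk_difference")) {
  stopifnot(inherits(x, "cohort"))
  scale <- match.arg(scale)
  S <- as.matrix(as.data.frame(scores))
  stopifnot(ncol(S) == 1 + length(mediator_cols))
  binary <- scale == "logit"
  if (binary) {
    assert_that(all(x$phenotypes[[outcome_col]] %in% c(0, 1)),
                "logit scale requires a binary outcome")
  }

  point <- one_sample_mediation_point(x, S, exposure_col, mediator_cols,
                                      outcome_col, covariates, binary)

  boot <- NULL
  if (n_boot > 0) {
    assert_that(!is.null(seed), "a seed is required for the bootstrap")
    assert_that(n_boot >= 100, "n_boot must be >= 100 (or 0 to skip)")
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(x$n, x$n, replace = TRUE)
        bp <- one_sample_mediation_point(cohort_subset(x, i),
                                         S[i, , drop = FALSE], exposure_col,
                                         mediator_cols, outcome_col,
                                         covariates, binary)
        bp$proportion
      }, numeric(1))
    })
  }

  total <- list(beta = point$total, se = point$total_se)
  indirect <- list(beta = point$indirect, se = point$indirect_se)
  prop <- proportion_mediated(indirect, total, boot = boot)
  method <- if (length(mediator_cols) == 1) "product_two_step" else "difference_combined"
  mediation_estimate(total, indirect, prop, method,
                     direct = point$direct,
                     components = point$components,
                     labels = list(exposure = exposure_col,
                                   mediator = paste(mediator_cols, collapse = "+"),
                                   outcome = outcome_col))
}

one_sample_mediation_point <- function(x, S, exposure_col, mediator_cols,
                                       outcome_col, covariates, binary) {
  C <- if (length(covariates)) as.matrix(x$phenotypes[, covariates, drop = FALSE]) else NULL
  s_exp <- S[, 1]
  total_fit <- one_sample_mr(x, s_exp, exposure_col, outcome_col, covariates,
                             binary_outcome = binary, min_first_stage_p = 1)

  if (length(mediator_cols) == 1) {
    a_fit <- tsls_fit(x$phenotypes[[mediator_cols]], x$phenotypes[[exposure_col]],
                      s_exp, C)
    cvec <- one_sample_mv_ratio(x, S, c(exposure_col, mediator_cols),
                                outcome_col, covariates, binary)
    b <- list(beta = unname(cvec[mediator_cols]), se = NA_real_)
    a <- list(beta = a_fit$beta, se = a_fit$se)
    indirect_beta <- a$beta * b$beta
    list(total = total_fit$beta, total_se = total_fit$se,
         indirect = indirect_beta, indirect_se = NA_real_,
         direct = NULL, components = list(a = a, b = b),
         proportion = indirect_beta / total_fit$beta)
  } else {
    cvec <- one_sample_mv_ratio(x, S, c(exposure_col, mediator_cols),
                                outcome_col, covariates, binary)
    direct <- list(beta = unname(cvec[exposure_col]), se = NA_real_)
    indirect_beta <- total_fit$beta - direct$beta
    list(total = total_fit$beta, total_se = total_fit$se,
         indirect = indirect_beta, indirect_se = NA_real_,
         direct = direct, components = NULL,
         proportion = indirect_beta / total_fit$beta)
  }
}
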