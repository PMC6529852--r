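# Observational (non-genetic) regression analyses and mediation.

#' Observational total effect of an exposure on a binary outcome
#'
#' Multivariable logistic regression of the outcome on the exposure and
#' confounders; the exposure coefficient is reported per unit of the column
#' supplied (standardise the exposure per SD beforehand for per-SD
#' estimates).
#'
#' @param x a `cohort`.
#' @param exposure_col,outcome_col phenotype columns; the outcome must be
#'   binary for the logit scale.
#' @param confounders adjusted-for phenotype columns.
#' @param scale `"logit"` (default) or `"risk_difference"` (linear
#'   probability model).
#' @return An `mr_estimate`-shaped association with method
#'   `"observational_logit"` or `"observational_rd"`.
#' @export
observational_total <- function(x, exposure_col, outcome_col,
                                confounders = character(),
                                scale = c("logit", "risk_difference")) {
  stopifnot(inherits(x, "cohort"))
  scale <- match.arg(scale)
  y <- x$phenotypes[[outcome_col]]
  X <- cbind(1, as.matrix(x$phenotypes[, c(exposure_col, confounders), drop = FALSE]))
  if (scale == "logit") {
    assert_that(all(y %in% c(0, 1)), "outcome must be binary for the logit scale")
    fit <- stats::glm.fit(X, y, family = stats::binomial())
    if (!fit$converged || any(abs(fit$coefficients) > 20)) {
      stop_f("logistic fit did not converge (possible separation in '%s')",
             outcome_col)
    }
    V <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
    mr_estimate(fit$coefficients[2], sqrt(V[2, 2]), "observational_logit",
                1L, extra = list(n = x$n))
  } else {
    fit <- stats::lm.fit(X, y)
    sigma2 <- sum(fit$residuals^2) / (x$n - ncol(X))
    V <- sigma2 * chol2inv(chol(crossprod(X)))
    mr_estimate(fit$coefficients[2], sqrt(V[2, 2]), "observational_rd",
                1L, extra = list(n = x$n))
  }
}

obs_lm_coef <- function(X, y, j) {
  fit <- stats::lm.fit(X, y)
  sigma2 <- sum(fit$residuals^2) / (length(y) - ncol(X))
  V <- sigma2 * chol2inv(chol(crossprod(X)))
  list(beta = unname(fit$coefficients[j]), se = sqrt(V[j, j]))
}

obs_glm_coef <- function(X, y, j) {
  fit <- stats::glm.fit(X, y, family = stats::binomial())
  V <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  list(beta = unname(fit$coefficients[j]), se = sqrt(V[j, j]))
}

observational_mediation_point <- function(ph, exposure_col, mediator_cols,
                                          outcome_col, confounders, binary) {
  y <- ph[[outcome_col]]
  Cf <- if (length(confounders)) as.matrix(ph[, confounders, drop = FALSE]) else NULL
  e <- ph[[exposure_col]]
  Xt <- cbind(1, e, Cf)
  total <- if (binary) obs_glm_coef(Xt, y, 2) else obs_lm_coef(Xt, y, 2)

  if (length(mediator_cols) == 1) {
    m <- ph[[mediator_cols]]
    a <- obs_lm_coef(Xt, m, 2)                       # mediator ~ exposure + conf
    Xb <- cbind(1, m, e, Cf)                         # outcome ~ mediator + exposure + conf
    b <- if (binary) obs_glm_coef(Xb, y, 2) else obs_lm_coef(Xb, y, 2)
    indirect <- product_indirect(a, b)
    list(total = total, indirect = indirect, direct = NULL,
         components = list(a = a, b = b),
         proportion = indirect$beta / total$beta)
  } else {
    M <- as.matrix(ph[, mediator_cols, drop = FALSE])
    Xd <- cbind(1, e, M, Cf)                         # outcome ~ exposure + all mediators + conf
    direct <- if (binary) obs_glm_coef(Xd, y, 2) else obs_lm_coef(Xd, y, 2)
    indirect <- list(beta = total$beta - direct$beta,
                     se = sqrt(total$se^2 + direct$se^2))
    list(total = total, indirect = indirect, direct = direct,
         components = NULL,
         proportion = indirect$beta / total$beta)
  }
}

#' Observational regression mediation
#'
#' Single mediator — product of coefficients: `a` from linear regression of
#' the mediator on the exposure and confounders; `b` from logistic
#' regression of the outcome on the mediator, exposure and confounders;
#' indirect `= a*b` on the log-odds scale and `P = a*b/total`. Several
#' mediators — difference method: `P = (T - D)/T`, with `D` from the
#' outcome regression on exposure plus all mediators. Uncertainty via a
#' nonparametric bootstrap over participants (statistic recomputed per
#' resample, percentile CI), reproducible under `seed`. The
#' `"risk_difference"` scale replicates everything with linear probability
#' models.
#'
#' @param x a `cohort`.
#' @param exposure_col,outcome_col phenotype columns.
#' @param mediator_cols one or several phenotype columns.
#' @param confounders adjusted-for phenotype columns.
#' @param n_boot bootstrap replicates (>= 100, or 0 to skip and use the
#'   delta-method proportion se).
#' @param seed integer seed, required when `n_boot > 0`.
#' @param scale `"logit"` (default) or `"risk_difference"`.
#' @return A `mediation_estimate` with method `"product_observational"` or
#'   `"difference_combined"`.
#' @export
observational_mediation <- function(x, exposure_col, mediator_cols,
                                    outcome_col, confounders = character(),
                                    n_boot = 1000, seed = NULL,
                                    scale = c("logit", "risk_difference")) {
  stopifnot(inherits(x, "cohort"))
  scale <- match.arg(scale)
  binary <- scale == "logit"
  if (binary) {
    assert_that(all(x$phenotypes[[outcome_col]] %in% c(0, 1)),
                "logit scale requires a binary outcome")
  }
  ph <- x$phenotypes
  point <- observational_mediation_point(ph, exposure_col, mediator_cols,
                                         outcome_col, confounders, binary)
  boot <- NULL
  if (n_boot > 0) {
    assert_that(!is.null(seed), "a seed is required for the bootstrap")
    assert_that(n_boot >= 100, "n_boot must be >= 100 (or 0 to skip)")
    boot <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(nrow(ph), nrow(ph), replace = TRUE)
        observational_mediation_point(ph[i, , drop = FALSE], exposure_col,
                                      mediator_cols, outcome_col,
                                      confounders, binary)$proportion
      }, numeric(1))
    })
  }
  total <- point$total
  indirect <- point$indirect
  prop <- proportion_mediated(indirect, total, boot = boot)
  method <- if (length(mediator_cols) == 1) "product_observational" else "difference_combined"
  mediation_estimate(total, indirect, prop, method, direct = point$direct,
                     components = point$components,
                     labels = list(exposure = exposure_col,
                                   mediator = paste(mediator_cols, collapse = "+"),
                                   outcome = outcome_col))
}
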