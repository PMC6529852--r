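# Mediation constructions: product of coefficients (two-step MR) and the
# difference method, with the proportion mediated.
#
# All delta-method standard errors treat the component estimates as
# independent (no covariance terms): in the two-sample setting the pieces
# come from non-overlapping or weakly overlapping sources.

#' Indirect effect by the product of coefficients
#'
#' `indirect = a * b` where `a` is the exposure-mediator effect and `b` the
#' mediator-outcome effect conditional on the exposure, with the Sobel
#' (delta-method, no covariance) standard error
#' `sqrt(a^2 * se_b^2 + b^2 * se_a^2)`.
#'
#' @param a list with `beta`, `se` (exposure -> mediator), or an
#'   `mr_estimate`.
#' @param b list with `beta`, `se` (mediator -> outcome given exposure).
#' @return list with `beta` and `se`.
#' @export
product_indirect <- function(a, b) {
  assert_that(is_number(a$beta) && is_number(a$se) &&
                is_number(b$beta) && is_number(b$se),
              "a and b must carry finite beta and se")
  list(beta = a$beta * b$beta,
       se = sqrt(a$beta^2 * b$se^2 + b$beta^2 * a$se^2))
}

#' Proportion of a total effect that is mediated
#'
#' `P = indirect/total`, with a delta-method standard error treating the two
#' as independent: `|P| * sqrt((se_i/indirect)^2 + (se_t/total)^2)`. The 95%
#' CI is `P +/- 1.959964*se` and is deliberately not truncated to \[0, 1\].
#' When `indirect = 0` the delta se is undefined; `P = 0` is returned with
#' `se = NA` unless a bootstrap sample of proportions is supplied.
#'
#' @param indirect,total lists with `beta` and `se`.
#' @param boot optional numeric vector of bootstrap replicates of the
#'   proportion; when given, `se = sd(boot)` and the CI is the percentile
#'   interval.
#' @return list with `point`, `se`, `ci_low`, `ci_high`.
#' @export
proportion_mediated <- function(indirect, total, boot = NULL) {
  assert_that(is_number(total$beta) && total$beta != 0,
              "proportion undefined under null total effect")
  p <- indirect$beta / total$beta
  if (!is.null(boot)) {
    se <- stats::sd(boot)
    ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE, type = 7)
    return(list(point = p, se = se, ci_low = ci[1], ci_high = ci[2]))
  }
  if (indirect$beta == 0) {
    return(list(point = 0, se = NA_real_, ci_low = NA_real_, ci_high = NA_real_))
  }
  se <- abs(p) * sqrt((indirect$se / indirect$beta)^2 +
                        (total$se / total$beta)^2)
  list(point = p, se = se, ci_low = p - Z95 * se, ci_high = p + Z95 * se)
}

#' Construct a mediation estimate object
#'
#' @param total,indirect lists with `beta`, `se`.
#' @param direct list with `beta`, `se`, or `NULL` for product methods where
#'   it is not separately estimated.
#' @param proportion list from [proportion_mediated()].
#' @param method `"product_two_step"`, `"difference_combined"` or
#'   `"product_observational"`.
#' @param components optional list with `a` and `b` for product methods.
#' @param n_snps instrument count (NA for observational estimates).
#' @param labels optional named list (`exposure`, `mediator`, `outcome`).
#' @return Object of class `mediation_estimate`.
#' @export
mediation_estimate <- function(total, indirect, proportion, method,
                               direct = NULL, components = NULL,
                               n_snps = NA_integer_, labels = list()) {
  structure(list(total = total, direct = direct, indirect = indirect,
                 proportion = proportion, method = method,
                 components = components, n_snps = n_snps, labels = labels),
            class = "mediation_estimate")
}

#' @export
print.mediation_estimate <- function(x, ...) {
  lab <- x$labels
  cat(sprintf("<mediation_estimate> %s%s\n", x$method,
              if (length(lab)) sprintf(" [%s -> %s -> %s]",
                                       lab$exposure %||% "?", lab$mediator %||% "?",
                                       lab$outcome %||% "?") else ""))
  cat(sprintf("  total    %8.4f (SE %.4f)\n", x$total$beta, x$total$se))
  if (!is.null(x$direct))
    cat(sprintf("  direct   %8.4f (SE %.4f)\n", x$direct$beta, x$direct$se))
  cat(sprintf("  indirect %8.4f (SE %.4f)\n", x$indirect$beta, x$indirect$se))
  cat(sprintf("  proportion mediated: %s\n",
              format_pct_ci(x$proportion$point, x$proportion$ci_low,
                            x$proportion$ci_high)))
  invisible(x)
}

#' Two-step MR mediation for a single mediator
#'
#' The product-of-coefficients construction on summary data:
#' * `a` — IVW effect of the exposure on the mediator, using the exposure's
#'   instrument panel;
#' * `b` — the mediator's coefficient from multivariable MR of the outcome
#'   on (exposure, mediator) over the union of both instrument panels;
#' * `T` — IVW total effect of the exposure on the outcome;
#' * indirect `= a*b` (Sobel se), proportion `= a*b/T` (delta se).
#'
#' @param exposure `summary_set` of exposure associations covering both
#'   panels (e.g. an education GWAS).
#' @param mediator `summary_set` of mediator associations covering both
#'   panels.
#' @param outcome `summary_set` of outcome associations.
#' @param exposure_snps instrument ids for the exposure (default: all SNPs
#'   in `exposure`).
#' @param mediator_snps instrument ids for the mediator (default: all SNPs
#'   in `mediator`).
#' @param ... passed to [harmonise()].
#' @return A `mediation_estimate` with method `"product_two_step"`; `extra`
#'   fits are attached as attributes `a_fit`, `b_fit`, `total_fit`.
#' @export
two_step_mediation <- function(exposure, mediator, outcome,
                               exposure_snps = NULL, mediator_snps = NULL, ...) {
  stopifnot(inherits(exposure, "summary_set"), inherits(mediator, "summary_set"),
            inherits(outcome, "summary_set"))
  exposure_snps <- exposure_snps %||% exposure$data$snp_id
  mediator_snps <- mediator_snps %||% mediator$data$snp_id

  exp_panel <- subset_snps(exposure, intersect(exposure_snps, exposure$data$snp_id))
  a_fit <- ivw_fixed(harmonise(exp_panel, mediator, ...))
  total_fit <- ivw_fixed(harmonise(exp_panel, outcome, ...))

  union_snps <- union(exposure_snps, mediator_snps)
  exposures <- stats::setNames(list(exposure, mediator),
                               c(exposure$trait_name, mediator$trait_name))
  mh <- multi_harmonise(exposures, outcome, snps = union_snps, ...)
  b_fit <- mvmr_fit(mh)
  b <- mvmr_coef(b_fit, mediator$trait_name)

  a <- list(beta = a_fit$beta, se = a_fit$se)
  indirect <- product_indirect(a, b)
  total <- list(beta = total_fit$beta, se = total_fit$se)
  prop <- proportion_mediated(indirect, total)
  out <- mediation_estimate(total, indirect, prop, "product_two_step",
                            components = list(a = a, b = b),
                            n_snps = b_fit$n_snps,
                            labels = list(exposure = exposure$trait_name,
                                          mediator = mediator$trait_name,
                                          outcome = outcome$trait_name))
  attr(out, "a_fit") <- a_fit
  attr(out, "b_fit") <- b_fit
  attr(out, "total_fit") <- total_fit
  out
}

#' Combined mediation by the difference method
#'
#' For several mediators jointly: `P = (T - D)/T`, where `T` is the total
#' effect of the primary exposure and `D` its direct effect from a
#' multivariable MR including all mediators. The delta-method se treats `T`
#' and `D` as independent.
#'
#' @param total an `mr_estimate` (or list with `beta`, `se`) for the total
#'   effect.
#' @param direct an `mvmr_estimate` containing the primary exposure, or a
#'   list with `beta`, `se`.
#' @param exposure name of the primary exposure in `direct` (required when
#'   `direct` is an `mvmr_estimate`).
#' @param labels optional label list.
#' @return A `mediation_estimate` with method `"difference_combined"`.
#' @export
combined_difference <- function(total, direct, exposure = NULL, labels = list()) {
  t_ <- list(beta = total$beta, se = total$se)
  assert_that(is_number(t_$beta) && t_$beta != 0,
              "proportion undefined under null total effect")
  if (inherits(direct, "mvmr_estimate")) {
    assert_that(!is.null(exposure), "name the primary exposure in the MVMR fit")
    d_ <- mvmr_coef(direct, exposure)
    n_snps <- direct$n_snps
  } else {
    d_ <- list(beta = direct$beta, se = direct$se)
    n_snps <- NA_integer_
  }
  ind <- list(beta = t_$beta - d_$beta, se = sqrt(t_$se^2 + d_$se^2))
  prop <- proportion_mediated(ind, t_)
  mediation_estimate(t_, ind, prop, "difference_combined", direct = d_,
                     n_snps = n_snps, labels = labels)
}

#' Serialise mediation estimates to a flat results table
#'
#' @param estimates list of `mediation_estimate` objects (or one).
#' @return data.frame with columns `exposure mediator outcome method
#'   total_beta total_se direct_beta direct_se indirect_beta indirect_se
#'   prop prop_se prop_ci_low prop_ci_high n_snps`.
#' @export
mediation_results_table <- function(estimates) {
  if (inherits(estimates, "mediation_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e) {
    lab <- e$labels
    data.frame(exposure = lab$exposure %||% NA_character_,
               mediator = lab$mediator %||% NA_character_,
               outcome = lab$outcome %||% NA_character_,
               method = e$method,
               total_beta = e$total$beta, total_se = e$total$se,
               direct_beta = if (is.null(e$direct)) NA_real_ else e$direct$beta,
               direct_se = if (is.null(e$direct)) NA_real_ else e$direct$se,
               indirect_beta = e$indirect$beta, indirect_se = e$indirect$se,
               prop = e$proportion$point, prop_se = e$proportion$se,
               prop_ci_low = e$proportion$ci_low,
               prop_ci_high = e$proportion$ci_high,
               n_snps = e$n_snps, stringsAsFactors = FALSE)
  }))
}
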