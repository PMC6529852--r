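# Two-sample Mendelian randomisation estimators on harmonised summary data.
#
# All estimates for binary outcomes live on the log odds scale; odds ratios
# are produced only at report rendering (see render_report), because the
# mediation algebra downstream is linear on log odds.

#' Construct an MR estimate object
#'
#' @param beta point estimate (log odds for binary outcomes, SD/native units
#'   for continuous), per SD of the exposure.
#' @param se positive standard error.
#' @param method estimator tag.
#' @param n_snps number of instruments used.
#' @param pvalue optional; defaults to the two-sided Wald p.
#' @param extra named list of method-specific quantities.
#' @return Object of class `mr_estimate` with `ci_low`/`ci_high` the 95%
#'   Wald bounds (`beta +/- 1.959964*se`).
#' @export
mr_estimate <- function(beta, se, method, n_snps, pvalue = NULL, extra = list()) {
  beta <- unname(beta); se <- unname(se)
  assert_that(is_number(beta), "beta must be a finite number")
  assert_that(is_number(se) && se > 0, "se must be positive and finite")
  assert_that(n_snps >= 1, "n_snps must be >= 1")
  structure(list(beta = beta, se = se,
                 ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
                 pvalue = pvalue %||% two_sided_p(beta / se),
                 method = method, n_snps = as.integer(n_snps), extra = extra),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta %.4f (SE %.4f, 95%% CI %.4f to %.4f), p %.3g, %d SNP%s\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_snps,
              if (x$n_snps > 1) "s" else ""))
  cat(sprintf("  as odds ratio: %s\n", format_or_ci(x$beta, x$se)))
  invisible(x)
}

#' Single-SNP Wald ratio estimate
#'
#' The causal effect from one instrument: the SNP-outcome association
#' divided by the SNP-exposure association, with a delta-method standard
#' error. First-order: `sy/|bx|`. Second-order adds the exposure-side
#' uncertainty: `sqrt(sy^2/bx^2 + by^2*sx^2/bx^4)`.
#'
#' @param bx,sx SNP-exposure beta and SE.
#' @param by,sy SNP-outcome beta and SE.
#' @param se_order `"first"` or `"second"` delta-method order.
#' @param snp_id optional identifier recorded in `extra`.
#' @return An `mr_estimate` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(bx, sx, by, sy, se_order = c("first", "second"),
                       snp_id = NULL) {
  se_order <- match.arg(se_order)
  assert_that(is_number(bx) && bx != 0, "weak/zero instrument ratio undefined (bx = 0)")
  beta <- by / bx
  se <- if (se_order == "first") sy / abs(bx) else
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  mr_estimate(beta, se, "wald_ratio", 1L,
              extra = list(se_order = se_order, snp_id = snp_id))
}

wald_ratio_se <- function(bx, sx, by, sy, se_order) {
  if (se_order == "first") sy / abs(bx) else
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
}

#' Fixed-effect inverse-variance weighted MR estimate
#'
#' Pools the per-SNP Wald ratios `r_j` with weights `w_j = 1/se(r_j)^2`:
#' `beta = sum(w r)/sum(w)`, `se = sqrt(1/sum(w))`. With first-order weights
#' this is identical to weighted least squares of `by` on `bx` through the
#' origin with weights `1/sy^2`.
#'
#' @param h a `harmonised_set` with at least one row with `bx != 0`.
#' @param se_order delta-method order for the per-SNP ratio SEs
#'   (default `"first"`, the standard fixed-effect IVW).
#' @return An `mr_estimate` with method `"ivw_fixed"`.
#' @export
ivw_fixed <- function(h, se_order = c("first", "second")) {
  stopifnot(inherits(h, "harmonised_set"))
  se_order <- match.arg(se_order)
  r <- h$rows[h$rows$bx != 0, , drop = FALSE]
  assert_that(nrow(r) >= 1, "no usable instruments (all bx = 0)")
  ratios <- r$by / r$bx
  w <- 1 / wald_ratio_se(r$bx, r$sx, r$by, r$sy, se_order)^2
  beta <- sum(w * ratios) / sum(w)
  se <- sqrt(1 / sum(w))
  mr_estimate(beta, se, "ivw_fixed", nrow(r), extra = list(se_order = se_order))
}

#' MR-Egger regression
#'
#' Weighted least squares of `by` on `bx` with an intercept, weights
#' `1/sy^2`, after (optionally) orienting every SNP so its exposure effect
#' is non-negative. The slope is a pleiotropy-robust causal estimate; a
#' nonzero intercept indicates directional pleiotropy. Standard errors are
#' inflated by the multiplicative overdispersion factor
#' `max(1, sqrt(RSS/(k-2)))` unless `overdispersion = "fixed"`. The
#' intercept test uses a two-sided t distribution with `k - 2` df.
#'
#' @param h a `harmonised_set` with at least 3 rows.
#' @param orient flip SNP signs so `bx >= 0` before fitting (default TRUE).
#' @param overdispersion `"multiplicative"` (default) or `"fixed"`.
#' @return An `mr_estimate` with method `"egger"`; `extra` carries
#'   `egger_intercept`, `egger_intercept_se`, `egger_intercept_p` and the
#'   overdispersion `scale`.
#' @export
mr_egger <- function(h, orient = TRUE,
                     overdispersion = c("multiplicative", "fixed")) {
  stopifnot(inherits(h, "harmonised_set"))
  overdispersion <- match.arg(overdispersion)
  r <- h$rows
  k <- nrow(r)
  assert_that(k >= 3, "Egger requires >=3 instruments")
  bx <- r$bx; by <- r$by
  if (orient) {
    flip <- sign(bx); flip[flip == 0] <- 1
    bx <- bx * flip; by <- by * flip
  }
  w <- 1 / r$sy^2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  assert_that(abs(det) > .Machine$double.eps * sw * swxx,
              "degenerate exposure betas: Egger design is singular")
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- by - intercept - slope * bx
  rss <- sum(w * resid^2)
  scale <- if (overdispersion == "multiplicative") max(1, sqrt(rss / (k - 2))) else 1
  se_slope <- scale * sqrt(sw / det)
  se_int <- scale * sqrt(swxx / det)
  int_p <- 2 * stats::pt(-abs(intercept / se_int), df = k - 2)
  mr_estimate(slope, se_slope, "egger", k,
              extra = list(egger_intercept = intercept,
                           egger_intercept_se = se_int,
                           egger_intercept_p = int_p,
                           scale = scale))
}

# Weighted median of ratio estimates: sort ratios, normalise the
# inverse-variance weights, and linearly interpolate the ratio against the
# cumulative weight midpoints q_j = cumsum(w)_j - w_j/2 at q = 0.5.
weighted_median_point <- function(ratios, weights) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  q <- cumsum(w) - w / 2
  if (0.5 <= q[1]) return(r[1])
  if (0.5 >= q[length(q)]) return(r[length(r)])
  stats::approx(q, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted median MR estimate
#'
#' The inverse-variance weighted median of the per-SNP Wald ratios:
#' consistent when at least 50% of the weight comes from valid instruments.
#' The standard error is the standard deviation of the estimate over
#' `n_boot` parametric resamples drawing `bx_j ~ N(bx_j, sx_j)` and
#' `by_j ~ N(by_j, sy_j)`; results are bit-reproducible under `seed`.
#'
#' @param h a `harmonised_set` with at least 3 rows.
#' @param n_boot number of parametric bootstrap resamples (>= 100,
#'   default 1000).
#' @param seed integer seed for the bootstrap (mandatory).
#' @param se_order delta-method order for the ratio weights.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
weighted_median <- function(h, n_boot = 1000, seed,
                            se_order = c("first", "second")) {
  stopifnot(inherits(h, "harmonised_set"))
  se_order <- match.arg(se_order)
  assert_that(n_boot >= 100, "n_boot must be >= 100")
  assert_that(!missing(seed) && is_number(seed), "a numeric seed is required")
  r <- h$rows
  k <- nrow(r)
  assert_that(k >= 3, "weighted median requires >=3 instruments")
  ratios <- r$by / r$bx
  w <- 1 / wald_ratio_se(r$bx, r$sx, r$by, r$sy, se_order)^2
  est <- weighted_median_point(ratios, w)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bxb <- stats::rnorm(k, r$bx, r$sx)
      byb <- stats::rnorm(k, r$by, r$sy)
      ok <- bxb != 0
      wb <- 1 / wald_ratio_se(bxb[ok], r$sx[ok], byb[ok], r$sy[ok], se_order)^2
      weighted_median_point(byb[ok] / bxb[ok], wb)
    }, numeric(1))
  })
  se <- stats::sd(boots)
  mr_estimate(est, se, "weighted_median", k,
              extra = list(n_boot = n_boot, seed = seed))
}

#' Estimate a total causal effect from two summary sets
#'
#' Convenience wrapper: harmonises the exposure instrument panel against the
#' outcome associations and dispatches to the requested estimator.
#'
#' @param exposure,outcome `summary_set` objects.
#' @param method one of `"ivw_fixed"`, `"egger"`, `"weighted_median"`,
#'   `"wald_ratio"` (single-SNP panels only).
#' @param ... passed to [harmonise()] (e.g. `palindrome_policy`) and to the
#'   estimator (e.g. `n_boot`, `seed`).
#' @return An `mr_estimate`; the harmonised set is attached as
#'   `attr(x, "harmonised")`.
#' @export
estimate_total_effect <- function(exposure, outcome,
                                  method = c("ivw_fixed", "egger",
                                             "weighted_median", "wald_ratio"),
                                  ...) {
  method <- match.arg(method)
  dots <- list(...)
  harm_args <- dots[names(dots) %in% c("palindrome_policy", "eaf_ambiguity_window")]
  est_args <- dots[!names(dots) %in% names(harm_args)]
  h <- do.call(harmonise, c(list(exposure, outcome), harm_args))
  est <- switch(method,
    ivw_fixed = do.call(ivw_fixed, c(list(h), est_args)),
    egger = do.call(mr_egger, c(list(h), est_args)),
    weighted_median = do.call(weighted_median, c(list(h), est_args)),
    wald_ratio = {
      assert_that(nrow(h$rows) == 1,
                  "wald_ratio requires a single-SNP panel (%d found)", nrow(h$rows))
      with(h$rows, do.call(wald_ratio,
                           c(list(bx, sx, by, sy), est_args, list(snp_id = snp_id))))
    })
  attr(est, "harmonised") <- h
  est
}

#' Serialise MR estimates to a flat results table
#'
#' @param estimates list of `mr_estimate` objects.
#' @param exposure,outcome labels recycled across rows.
#' @return data.frame with columns `exposure outcome method n_snps beta se
#'   ci_low ci_high pvalue or or_low or_high extra_json`.
#' @export
mr_results_table <- function(estimates, exposure = "", outcome = "") {
  if (inherits(estimates, "mr_estimate")) estimates <- list(estimates)
  do.call(rbind, lapply(estimates, function(e) {
    data.frame(exposure = exposure, outcome = outcome, method = e$method,
               n_snps = e$n_snps, beta = e$beta, se = e$se,
               ci_low = e$ci_low, ci_high = e$ci_high, pvalue = e$pvalue,
               or = exp(e$beta), or_low = exp(e$ci_low), or_high = exp(e$ci_high),
               extra_json = as.character(jsonlite::toJSON(e$extra, auto_unbox = TRUE,
                                                          null = "null", digits = NA)),
               stringsAsFactors = FALSE)
  }))
}
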