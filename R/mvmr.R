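# Regression-based multivariable Mendelian randomisation.

#' Align several exposures and an outcome on a common effect allele
#'
#' Builds the design for multivariable MR: for each SNP, the association
#' betas with every exposure (all oriented to the first exposure's effect
#' allele) and with the outcome. SNPs lacking an association estimate for
#' any exposure or for the outcome are dropped and counted; the first
#' exposure listed is the primary one (e.g. education).
#'
#' @param exposures named list of `summary_set` objects; each must cover the
#'   requested SNPs. Names become the exposure names (defaults to the sets'
#'   trait names).
#' @param outcome a `summary_set`.
#' @param snps SNP ids to use (e.g. the union of the contributing instrument
#'   panels); default: SNPs present in every set.
#' @param ... passed to [harmonise()].
#' @return Object of class `multi_harmonised_set`: `exposure_names`,
#'   `rows` (data.frame with `snp_id`, `bx.<name>`, `sx.<name>`, `by`, `sy`),
#'   `dropped`.
#' @export
multi_harmonise <- function(exposures, outcome, snps = NULL, ...) {
  stopifnot(is.list(exposures), length(exposures) >= 1,
            inherits(outcome, "summary_set"))
  names(exposures) <- names(exposures) %||%
    vapply(exposures, function(s) s$trait_name, character(1))
  primary <- exposures[[1]]
  if (is.null(snps)) {
    snps <- Reduce(intersect, c(lapply(exposures, function(s) s$data$snp_id),
                                list(outcome$data$snp_id)))
  }
  assert_that(length(snps) > 0, "no SNPs shared across all input sets")

  # orient every other set (exposures 2..p and the outcome) to the primary
  # exposure's alleles via pairwise harmonisation restricted to `snps`
  prim <- subset_snps(primary, intersect(snps, primary$data$snp_id))
  aligned <- lapply(exposures[-1], function(s) harmonise(prim, s, ...))
  out_h <- harmonise(prim, outcome, ...)

  ids <- prim$data$snp_id
  keep <- ids %in% out_h$rows$snp_id
  for (h in aligned) keep <- keep & ids %in% h$rows$snp_id
  kept <- ids[keep]
  lost <- setdiff(union(snps, ids), kept)
  dropped <- data.frame(
    snp_id = lost,
    reason = rep("missing_or_unharmonisable_in_some_set", length(lost)),
    stringsAsFactors = FALSE)

  rows <- data.frame(snp_id = kept, stringsAsFactors = FALSE)
  pidx <- match(kept, prim$data$snp_id)
  rows[[paste0("bx.", names(exposures)[1])]] <- prim$data$beta[pidx]
  rows[[paste0("sx.", names(exposures)[1])]] <- prim$data$se[pidx]
  for (j in seq_along(aligned)) {
    hj <- aligned[[j]]$rows
    idx <- match(kept, hj$snp_id)
    rows[[paste0("bx.", names(exposures)[j + 1])]] <- hj$by[idx]
    rows[[paste0("sx.", names(exposures)[j + 1])]] <- hj$sy[idx]
  }
  oidx <- match(kept, out_h$rows$snp_id)
  rows$by <- out_h$rows$by[oidx]
  rows$sy <- out_h$rows$sy[oidx]

  multi_harmonised_set(
    bx = as.matrix(rows[, paste0("bx.", names(exposures)), drop = FALSE]),
    sx = as.matrix(rows[, paste0("sx.", names(exposures)), drop = FALSE]),
    by = rows$by, sy = rows$sy, snp_id = rows$snp_id,
    exposure_names = names(exposures),
    outcome_name = outcome$trait_name, dropped = dropped)
}

#' Construct a multi-exposure harmonised set from aligned matrices
#'
#' @param bx,sx k x p matrices of exposure betas and SEs (columns =
#'   exposures, first column = primary exposure).
#' @param by,sy outcome betas and SEs (length k).
#' @param snp_id optional identifiers.
#' @param exposure_names column labels (default from `colnames(bx)`).
#' @param outcome_name label.
#' @param dropped optional accounting data.frame.
#' @return A `multi_harmonised_set`.
#' @export
multi_harmonised_set <- function(bx, sx, by, sy, snp_id = NULL,
                                 exposure_names = colnames(bx),
                                 outcome_name = "outcome", dropped = NULL) {
  bx <- as.matrix(bx); sx <- as.matrix(sx)
  k <- nrow(bx)
  stopifnot(nrow(sx) == k, length(by) == k, length(sy) == k,
            ncol(sx) == ncol(bx))
  exposure_names <- exposure_names %||% paste0("exposure", seq_len(ncol(bx)))
  colnames(bx) <- colnames(sx) <- exposure_names
  ids <- snp_id %||% paste0("snp", seq_len(k))
  assert_that(!anyDuplicated(ids), "duplicate snp_id in multi-harmonised set")
  structure(list(exposure_names = exposure_names,
                 snp_id = ids, bx = bx, sx = sx, by = by, sy = sy,
                 outcome_name = outcome_name,
                 dropped = dropped %||% data.frame(snp_id = character(),
                                                   reason = character())),
            class = "multi_harmonised_set")
}

#' @export
print.multi_harmonised_set <- function(x, ...) {
  cat(sprintf("<multi_harmonised_set> (%s) -> %s: %d SNPs, %d dropped\n",
              paste(x$exposure_names, collapse = ", "), x$outcome_name,
              length(x$by), nrow(x$dropped)))
  invisible(x)
}

#' Fit regression-based multivariable MR
#'
#' Weighted least squares of the SNP-outcome betas on the matrix of
#' SNP-exposure betas with no intercept and weights `1/sy^2`. Each
#' coefficient is the direct effect of that exposure on the outcome,
#' conditional on the other exposures. Standard errors use the weighted
#' normal equations with multiplicative overdispersion
#' `max(1, sqrt(RSS/(k-p)))`.
#'
#' @param m a `multi_harmonised_set` with more SNPs than exposures and a
#'   full-column-rank exposure beta matrix.
#' @param overdispersion `"multiplicative"` (default) or `"fixed"`.
#' @return Object of class `mvmr_estimate`: `coefficients` data.frame
#'   (`exposure, beta, se, pvalue`), `n_snps`, `conditional_f` (per-exposure
#'   instrument-strength diagnostic, logged not contractual), `scale`.
#' @export
mvmr_fit <- function(m, overdispersion = c("multiplicative", "fixed")) {
  stopifnot(inherits(m, "multi_harmonised_set"))
  overdispersion <- match.arg(overdispersion)
  X <- m$bx; y <- m$by; w <- 1 / m$sy^2
  k <- nrow(X); p <- ncol(X)
  assert_that(k > p, "need more SNPs (%d) than exposures (%d)", k, p)
  XtWX <- crossprod(X * sqrt(w))
  qrx <- qr(XtWX)
  if (qrx$rank < p) {
    bad <- m$exposure_names[-qr(X)$pivot[seq_len(qr(X)$rank)]]
    stop_f("exposure beta matrix is rank deficient (collinear: %s)",
           paste(bad, collapse = ", "))
  }
  XtWy <- crossprod(X, w * y)
  beta <- solve(XtWX, XtWy)[, 1]
  resid <- y - X %*% beta
  rss <- sum(w * resid^2)
  scale <- if (overdispersion == "multiplicative") max(1, sqrt(rss / (k - p))) else 1
  vcov <- solve(XtWX) * scale^2
  se <- sqrt(diag(vcov))

  # conditional instrument-strength diagnostic: F-like statistic from
  # regressing each exposure's betas on the others' (precision-weighted)
  cond_f <- vapply(seq_len(p), function(j) {
    wj <- 1 / m$sx[, j]^2
    if (p == 1) return(mean(m$bx[, j]^2 * wj))
    others <- X[, -j, drop = FALSE]
    fit <- stats::lm.wfit(cbind(1, others), X[, j], wj)
    sum(wj * fit$residuals^2) / (k - p)
  }, numeric(1))

  structure(list(coefficients = data.frame(
    exposure = m$exposure_names, beta = beta, se = se,
    pvalue = two_sided_p(beta / se),
    row.names = NULL, stringsAsFactors = FALSE),
    n_snps = k, conditional_f = stats::setNames(cond_f, m$exposure_names),
    scale = scale, vcov = vcov),
    class = "mvmr_estimate")
}

#' @export
print.mvmr_estimate <- function(x, ...) {
  cat(sprintf("<mvmr_estimate> %d SNPs, overdispersion scale %.3f\n",
              x$n_snps, x$scale))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

#' Extract one exposure's coefficient from an MVMR fit
#'
#' @param fit an `mvmr_estimate`.
#' @param exposure exposure name.
#' @return list with `beta` and `se`.
#' @export
mvmr_coef <- function(fit, exposure) {
  stopifnot(inherits(fit, "mvmr_estimate"))
  i <- match(exposure, fit$coefficients$exposure)
  assert_that(!is.na(i), "no exposure '%s' in MVMR fit", exposure)
  list(beta = fit$coefficients$beta[i], se = fit$coefficients$se[i])
}
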