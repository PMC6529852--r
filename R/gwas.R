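# Per-SNP association scans on a cohort, producing summary_set objects.

#' Compute GWAS summary statistics for one trait in a cohort
#'
#' Per-SNP linear regression (continuous traits) or logistic regression
#' (binary traits) of the trait on the dosage plus covariates. Effect
#' alleles are the cohort's coded alleles and `eaf = mean(dosage)/2`.
#' Constant dosage columns are skipped and recorded in
#' `attr(result, "skipped")`.
#'
#' Binary traits without covariates are fitted with a vectorised
#' two-parameter Newton-Raphson scorer across SNP blocks (identical to
#' `glm` to numerical precision but hundreds of times faster for large
#' panels); with covariates each SNP falls back to `glm`.
#'
#' @param x a `cohort`.
#' @param trait_col phenotype column to scan.
#' @param covariates phenotype columns adjusted for.
#' @param snps SNP ids to scan (default: all).
#' @param trait_sd optional trait SD recorded on the resulting set.
#' @param per_sd flag the resulting set as per-SD-of-trait (set `TRUE` when
#'   the scanned trait column is already standardised).
#' @return A `summary_set` named after `trait_col`.
#' @export
compute_gwas_summaries <- function(x, trait_col, covariates = character(),
                                   snps = NULL, trait_sd = NA_real_,
                                   per_sd = FALSE) {
  stopifnot(inherits(x, "cohort"))
  assert_that(trait_col %in% names(x$phenotypes),
              "no phenotype column '%s'", trait_col)
  snps <- snps %||% x$snp_ids
  idx <- match(snps, x$snp_ids)
  assert_that(!anyNA(idx), "SNPs missing from cohort: %s",
              paste(snps[is.na(idx)], collapse = ", "))
  ss <- dosage_suffstats(x)
  y <- x$phenotypes[[trait_col]]
  n <- x$n
  binary <- all(y %in% c(0, 1))

  # variance from the cached class counts: sum(g^2) = c1 + 2*c2
  c1 <- ss$c1[idx]; c2 <- ss$c2[idx]
  keep <- (c1 + 2 * c2) - c1^2 / n > 0
  skipped <- data.frame(snp_id = snps[!keep],
                        reason = rep("constant_dosage", sum(!keep)),
                        stringsAsFactors = FALSE)
  idx <- idx[keep]; c1 <- c1[keep]; c2 <- c2[keep]
  full <- identical(idx, seq_len(ncol(x$genotypes)))
  G <- if (full) x$genotypes else x$genotypes[, idx, drop = FALSE]
  snps_k <- snps[keep]

  if (!binary) {
    res <- gwas_linear(G, y,
                       if (length(covariates)) as.matrix(x$phenotypes[, covariates, drop = FALSE]) else NULL,
                       c1 = c1, c2 = c2)
  } else if (!length(covariates)) {
    res <- gwas_logistic_fast(G, y, c1 = c1, c2 = c2)
  } else {
    C <- as.matrix(x$phenotypes[, covariates, drop = FALSE])
    res <- t(apply(G, 2, function(g) {
      fit <- stats::glm.fit(cbind(1, g, C), y, family = stats::binomial())
      V <- chol2inv(chol(crossprod(cbind(1, g, C) * sqrt(fit$weights))))
      c(fit$coefficients[2], sqrt(V[2, 2]))
    }))
    res <- list(beta = res[, 1], se = res[, 2])
  }

  ea <- if (!is.null(x$coded_alleles)) unname(x$coded_alleles[snps_k]) else rep("A", length(snps_k))
  oa <- if (!is.null(attr(x$coded_alleles, "other"))) {
    unname(attr(x$coded_alleles, "other")[snps_k])
  } else {
    vapply(ea, function(a) setdiff(c("G", "A"), a)[1], character(1), USE.NAMES = FALSE)
  }
  out <- summary_set(data.frame(
    snp_id = snps_k, effect_allele = ea, other_allele = oa,
    eaf = c1 / (2 * n), beta = res$beta, se = res$se,
    pvalue = pmax(two_sided_p(res$beta / res$se), .Machine$double.xmin),
    n = n, stringsAsFactors = FALSE), trait_name = trait_col,
    trait_sd = trait_sd, per_sd = per_sd)
  attr(out, "skipped") <- rbind(attr(out, "skipped"), skipped)
  out
}

# simple regression per SNP; covariates handled by Frisch-Waugh
# residualisation of the trait and each dosage column. Centred cross
# products come from the cached class counts (sum(g^2) = c1 + 2*c2), so no
# centred copy of G is ever materialised.
gwas_linear <- function(G, y, C = NULL, c1 = colSums(G),
                        c2 = colSums(G * (G - 1)) / 2) {
  n <- nrow(G)
  q <- 0L
  if (!is.null(C)) {
    X <- cbind(1, C)
    q <- ncol(C)
    H <- solve(crossprod(X))
    y <- drop(y - X %*% (H %*% crossprod(X, y)))
    B <- H %*% crossprod(X, G)            # (1+q) x m projection coefficients
    sxx <- (c1 + 2 * c2) - colSums((crossprod(X) %*% B) * B)
    sxy <- drop(crossprod(G, y))          # residualised y is orthogonal to X
    syy <- sum(y^2)
  } else {
    y <- y - mean(y)
    sxx <- (c1 + 2 * c2) - c1^2 / n
    sxy <- drop(crossprod(G, y))          # y centred, so no mean correction
    syy <- sum(y^2)
  }
  beta <- sxy / sxx
  rss <- syy - beta^2 * sxx
  df <- n - 2L - q
  list(beta = beta, se = sqrt(pmax(rss, 0) / (df * sxx)))
}

# Vectorised intercept+dosage logistic regression. A hard-called dosage
# takes values {0,1,2}, so the per-SNP likelihood depends only on the
# genotype-class counts (n0,n1,n2) and case counts (s0,s1,s2): two passes
# over G collect them, then the Newton iterations run on length-m vectors.
# Identical to glm() to numerical precision on hard-called dosages.
gwas_logistic_fast <- function(G, y, c1 = NULL, c2 = NULL,
                               max_iter = 50L, tol = 1e-12) {
  n <- nrow(G)
  if (is.null(c1)) c1 <- colSums(G)
  if (is.null(c2)) c2 <- colSums(G * (G - 1)) / 2
  Gc <- G[y == 1, , drop = FALSE]         # case submatrix: counts among cases
  t1 <- colSums(Gc)
  t2 <- colSums(Gc * (Gc - 1)) / 2
  n2 <- c2; n1 <- c1 - 2 * c2; n0 <- n - n1 - n2
  s2 <- t2; s1 <- t1 - 2 * t2; s0 <- sum(y) - s1 - s2

  m <- ncol(G)
  a <- rep(stats::qlogis(mean(y)), m)
  b <- numeric(m)
  for (it in seq_len(max_iter)) {
    p0 <- stats::plogis(a); p1 <- stats::plogis(a + b); p2 <- stats::plogis(a + 2 * b)
    r0 <- s0 - n0 * p0; r1 <- s1 - n1 * p1; r2 <- s2 - n2 * p2
    U0 <- r0 + r1 + r2
    U1 <- r1 + 2 * r2
    w0 <- n0 * p0 * (1 - p0); w1 <- n1 * p1 * (1 - p1); w2 <- n2 * p2 * (1 - p2)
    S0 <- w0 + w1 + w2
    S1 <- w1 + 2 * w2
    S2 <- w1 + 4 * w2
    det <- S0 * S2 - S1^2
    da <- (S2 * U0 - S1 * U1) / det
    db <- (S0 * U1 - S1 * U0) / det
    a <- a + da; b <- b + db
    if (max(abs(da), abs(db)) < tol) break
  }
  list(beta = b, se = sqrt(S0 / det))
}
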