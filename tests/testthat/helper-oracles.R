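# Independent oracles and small fixture builders used across the suite.
# Every oracle is coded from the defining formula, not by calling the
# package's implementation path.

# weighted least squares of y on X (no intercept unless a 1-column is
# included) via explicitly solved normal equations
oracle_wls <- function(X, y, w) {
  X <- as.matrix(X)
  A <- t(X * w) %*% X
  b <- t(X * w) %*% y
  solve(A, b)[, 1]
}

# inverse-variance weighted mean of ratios, straight from the definition
oracle_ivw <- function(bx, sx, by, sy, se_order = "first") {
  r <- by / bx
  se_r <- if (se_order == "first") sy / abs(bx) else
    sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  w <- 1 / se_r^2
  list(beta = sum(w * r) / sum(w), se = sqrt(1 / sum(w)))
}

# weighted median by evaluating the interpolation definition on a fine grid
# of candidate values (brute force)
oracle_weighted_median <- function(ratios, weights, grid_n = 200001) {
  o <- order(ratios)
  r <- ratios[o]
  w <- weights[o] / sum(weights)
  q <- cumsum(w) - w / 2
  if (0.5 <= q[1]) return(r[1])
  if (0.5 >= q[length(q)]) return(r[length(r)])
  grid <- seq(min(r), max(r), length.out = grid_n)
  qq <- approx(r, q, xout = grid, ties = "ordered")$y
  grid[which.min(abs(qq - 0.5))]
}

# greedy clump oracle: literal restatement of the selection rule with
# explicit loops over the p-ordered SNP list
oracle_clump <- function(df, r2, chrom, pos, r2_threshold, window_kb) {
  ord <- order(df$pvalue, -abs(df$beta / df$se), df$snp_id)
  ids <- df$snp_id[ord]
  discarded <- character(0)
  kept <- character(0)
  for (id in ids) {
    if (id %in% discarded) next
    kept <- c(kept, id)
    for (other in ids) {
      if (other == id || other %in% discarded || other %in% kept) next
      if (chrom[[id]] != chrom[[other]]) next
      if (abs(pos[[id]] - pos[[other]]) / 1000 > window_kb) next
      if (r2[id, other] > r2_threshold) discarded <- c(discarded, other)
    }
  }
  kept
}

# minimal valid summary-statistic data.frame
make_summary_df <- function(k = 5, seed = 1, chrom = NULL, pos = NULL) {
  set.seed(seed)
  alleles <- c("A", "C", "G", "T")
  ea <- sample(alleles, k, replace = TRUE)
  oa <- vapply(ea, function(a) sample(setdiff(alleles, a), 1), character(1))
  data.frame(snp_id = sprintf("rs%03d", seq_len(k)),
             chrom = chrom %||% rep("1", k),
             pos = pos %||% (seq_len(k) * 1000L),
             effect_allele = ea, other_allele = oa,
             eaf = runif(k, 0.1, 0.9),
             beta = rnorm(k, 0, 0.05),
             se = runif(k, 0.005, 0.02),
             pvalue = runif(k, 1e-10, 0.05),
             n = 10000L, stringsAsFactors = FALSE)
}

make_hset <- function(k = 10, slope = 0.5, intercept = 0, noise = 0, seed = 1) {
  set.seed(seed)
  bx <- runif(k, 0.05, 0.3)
  sx <- runif(k, 0.005, 0.02)
  sy <- runif(k, 0.01, 0.05)
  by <- intercept + slope * bx + rnorm(k, 0, noise)
  harmonised_set(bx, sx, by, sy)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}
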