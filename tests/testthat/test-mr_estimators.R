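# Two-sample estimators: Wald ratio, IVW, MR-Egger, weighted median.

test_that("Wald ratio divides outcome by exposure effects with delta-method SEs of both orders", {
  e <- wald_ratio(0.1, 0.01, 0.05, 0.02, "first")
  expect_equal(e$beta, 0.5)
  expect_equal(e$se, 0.2)
  expect_equal(e$ci_low, 0.5 - 1.959964 * 0.2)
  expect_equal(e$ci_high, 0.5 + 1.959964 * 0.2)

  e0 <- wald_ratio(0.1, 0.01, 0, 0.02, "first")
  expect_equal(e0$beta, 0)
  expect_equal(e0$se, 0.2)

  # second-order: frozen value computed from the two-term delta formula
  # sqrt(sy^2/bx^2 + by^2 sx^2/bx^4) = sqrt(0.04 + 0.0025)
  e2 <- wald_ratio(0.1, 0.01, 0.05, 0.02, "second")
  expect_equal(e2$se, sqrt(0.0425))
  expect_equal(e2$se, 0.2061552813, tolerance = 1e-9)

  expect_error(wald_ratio(0, 0.01, 0.05, 0.02), "zero instrument")
})

test_that("fixed-effect IVW pools ratios by inverse variance and reduces to the Wald ratio at k = 1", {
  h1 <- harmonised_set(0.1, 0.01, 0.05, 0.02)
  expect_equal(ivw_fixed(h1)$beta, wald_ratio(0.1, 0.01, 0.05, 0.02)$beta)
  expect_equal(ivw_fixed(h1)$se, wald_ratio(0.1, 0.01, 0.05, 0.02)$se)

  # hand-computed weighted-mean oracle: ratios {0.2, 0.15, 0.3},
  # weights {100, 400, 100} -> beta 110/600, se sqrt(1/600)
  h3 <- harmonised_set(bx = c(0.1, 0.2, 0.15), sx = rep(0.01, 3),
                       by = c(0.02, 0.03, 0.045), sy = c(0.01, 0.01, 0.015))
  e <- ivw_fixed(h3)
  expect_equal(e$beta, 110 / 600, tolerance = 1e-12)
  expect_equal(e$beta, 0.1833333, tolerance = 1e-6)
  expect_equal(e$se, sqrt(1 / 600), tolerance = 1e-12)
  expect_equal(e$n_snps, 3L)

  # equal-weight pooling: three identical rows leave beta, shrink se by sqrt(3)
  hrep <- harmonised_set(rep(0.1, 3), rep(0.01, 3), rep(0.05, 3), rep(0.02, 3))
  expect_equal(ivw_fixed(hrep)$beta, 0.5)
  expect_equal(ivw_fixed(hrep)$se, 0.2 / sqrt(3))

  expect_error(ivw_fixed(harmonised_set(0, 0.01, 0.05, 0.02)), "bx = 0")
})

test_that("IVW from the ratio form equals origin-constrained weighted regression", {
  for (seed in 1:10) {
    h <- make_hset(k = 15, slope = 0.4, noise = 0.02, seed = seed)
    e <- ivw_fixed(h)
    wls <- oracle_wls(matrix(h$rows$bx), h$rows$by, 1 / h$rows$sy^2)
    expect_equal(e$beta, unname(wls), tolerance = 1e-10)
    orc <- oracle_ivw(h$rows$bx, h$rows$sx, h$rows$by, h$rows$sy)
    expect_equal(e$beta, orc$beta, tolerance = 1e-10)
    expect_equal(e$se, orc$se, tolerance = 1e-10)
  }
})

test_that("MR-Egger recovers exact linear and affine relations and matches the normal-equation oracle", {
  h_lin <- make_hset(k = 6, slope = 0.5, noise = 0)
  e <- mr_egger(h_lin)
  expect_equal(e$beta, 0.5, tolerance = 1e-12)
  expect_equal(e$extra$egger_intercept, 0, tolerance = 1e-12)

  h_aff <- make_hset(k = 6, slope = 0.5, intercept = 0.01, noise = 0)
  e2 <- mr_egger(h_aff)
  expect_equal(e2$beta, 0.5, tolerance = 1e-12)
  expect_equal(e2$extra$egger_intercept, 0.01, tolerance = 1e-12)

  # noisy instances vs explicitly solved 2x2 weighted normal equations
  for (seed in 1:8) {
    h <- make_hset(k = 4 + seed, slope = 0.3, intercept = 0.005,
                   noise = 0.01, seed = seed)
    w <- 1 / h$rows$sy^2
    ref <- oracle_wls(cbind(1, h$rows$bx), h$rows$by, w)
    e3 <- mr_egger(h)  # orient is a no-op here: all bx > 0 by construction
    expect_equal(e3$extra$egger_intercept, unname(ref[1]), tolerance = 1e-10)
    expect_equal(e3$beta, unname(ref[2]), tolerance = 1e-10)
  }

  expect_error(mr_egger(harmonised_set(c(0.1, 0.2), c(0.01, 0.01),
                                       c(0.05, 0.1), c(0.02, 0.02))),
               ">=3 instruments")
})

test_that("constraining the Egger intercept to zero reproduces the IVW slope under shared weights", {
  for (seed in 1:6) {
    h <- make_hset(k = 12, slope = 0.25, noise = 0.015, seed = seed)
    w <- 1 / h$rows$sy^2
    origin_slope <- sum(w * h$rows$bx * h$rows$by) / sum(w * h$rows$bx^2)
    expect_equal(ivw_fixed(h)$beta, origin_slope, tolerance = 1e-12)
  }
})

test_that("weighted median interpolates cumulative weight midpoints and matches a brute-force oracle", {
  wm <- mrmediate:::weighted_median_point
  # odd-k equal weights: the ordinary median
  expect_equal(wm(c(0.1, 0.2, 0.9), rep(1, 3)), 0.2)
  # all ratios equal: weights are irrelevant
  expect_equal(wm(rep(0.37, 4), c(1, 5, 2, 9)), 0.37)
  # two equal-weight ratios interpolate to the midpoint
  expect_equal(wm(c(0.1, 0.3), c(1, 1)), 0.2)
  expect_equal(wm(c(0.1, 0.3), c(1, 1)),
               oracle_weighted_median(c(0.1, 0.3), c(1, 1)), tolerance = 1e-5)
  # random instances vs the fine-grid interpolation oracle
  for (seed in 1:10) {
    set.seed(seed)
    k <- sample(3:9, 1)
    r <- rnorm(k); w <- runif(k, 0.5, 2)
    expect_equal(wm(r, w), oracle_weighted_median(r, w), tolerance = 1e-4)
  }
  # equal weights agree with the midpoint-interpolation sample median
  for (seed in 1:6) {
    set.seed(seed)
    r <- rnorm(5)
    expect_equal(wm(r, rep(1, 5)), median(r), tolerance = 1e-12)
  }
})

test_that("weighted median estimator is seed-reproducible and needs >=3 instruments and >=100 resamples", {
  h <- make_hset(k = 8, slope = 0.5, noise = 0.02)
  e1 <- weighted_median(h, n_boot = 200, seed = 11)
  e2 <- weighted_median(h, n_boot = 200, seed = 11)
  expect_identical(e1$beta, e2$beta)
  expect_identical(e1$se, e2$se)
  e3 <- weighted_median(h, n_boot = 200, seed = 12)
  expect_false(identical(e1$se, e3$se))
  expect_error(weighted_median(h, n_boot = 50, seed = 1), "n_boot")
  expect_error(weighted_median(make_hset(2), n_boot = 200, seed = 1),
               ">=3 instruments")
})

test_that("with directional pleiotropy in a minority of SNPs the weighted median is less biased than IVW", {
  # summary-level simulation: 25 instruments, slope 0.5; 20% of SNPs get a
  # positive direct outcome effect. Mean absolute bias over 250 replicates.
  slope <- 0.5
  bias <- with_seed_local(99, {
    t(vapply(seq_len(250), function(r) {
      k <- 25
      bx <- runif(k, 0.05, 0.3)
      sy <- rep(0.02, k)
      pleio <- c(rep(0.03, 5), rep(0, 20))
      by <- slope * bx + pleio + rnorm(k, 0, sy)
      h <- harmonised_set(bx, rep(1e-4, k), by, sy)
      c(ivw = ivw_fixed(h)$beta - slope,
        wm = mrmediate:::weighted_median_point(by / bx, (bx / sy)^2) - slope)
    }, numeric(2)))
  })
  expect_lt(mean(abs(bias[, "wm"])), mean(abs(bias[, "ivw"])))

  # without pleiotropy the three estimators agree within Monte-Carlo error
  ests <- with_seed_local(100, {
    t(vapply(seq_len(200), function(r) {
      k <- 25
      bx <- runif(k, 0.05, 0.3)
      sy <- rep(0.02, k)
      by <- slope * bx + rnorm(k, 0, sy)
      h <- harmonised_set(bx, rep(1e-4, k), by, sy)
      c(ivw_fixed(h)$beta, mr_egger(h)$beta,
        mrmediate:::weighted_median_point(by / bx, (bx / sy)^2))
    }, numeric(3)))
  })
  m <- colMeans(ests)
  expect_lt(max(abs(m - slope)), 0.01)
})

test_that("estimate_total_effect harmonises then dispatches, reducing to the Wald ratio for one SNP", {
  d <- make_summary_df(1)
  d$beta <- 0.1; d$se <- 0.01
  o <- d; o$beta <- 0.05; o$se <- 0.02
  e <- estimate_total_effect(summary_set(d, "edu"), summary_set(o, "chd"),
                             method = "wald_ratio")
  expect_equal(e$beta, 0.5)
  e_ivw <- estimate_total_effect(summary_set(d, "edu"), summary_set(o, "chd"),
                                 method = "ivw_fixed")
  expect_equal(e_ivw$beta, e$beta)
})
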