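# Multivariable MR and the mediation constructions.

test_that("MVMR solves exact systems and reduces to IVW for a single exposure", {
  # orthogonal design with exact by = 0.3*bx1 - 0.2*bx2
  bx <- cbind(e1 = c(1, 1, 0, 0, 2, -1), e2 = c(0, 0, 1, -1, 0, 0)) * 0.1
  by <- 0.3 * bx[, 1] - 0.2 * bx[, 2]
  m <- multi_harmonised_set(bx, bx * 0 + 0.01, by, rep(0.02, 6))
  fit <- mvmr_fit(m)
  expect_equal(fit$coefficients$beta, c(0.3, -0.2), tolerance = 1e-12)

  h <- make_hset(k = 10, slope = 0.4, noise = 0.02, seed = 2)
  m1 <- multi_harmonised_set(matrix(h$rows$bx, ncol = 1),
                             matrix(h$rows$sx, ncol = 1),
                             h$rows$by, h$rows$sy,
                             exposure_names = "edu")
  fit1 <- mvmr_fit(m1)
  ivw <- ivw_fixed(h)
  expect_equal(fit1$coefficients$beta, ivw$beta, tolerance = 1e-12)
  expect_equal(mvmr_fit(m1, overdispersion = "fixed")$coefficients$se,
               ivw$se, tolerance = 1e-12)
})

test_that("MVMR coefficients match the independent normal-equation oracle on random instances", {
  for (seed in 1:8) {
    set.seed(seed)
    k <- 8; p <- 2
    bx <- matrix(rnorm(k * p, 0, 0.1), k, p)
    by <- rnorm(k, bx %*% c(0.3, -0.1), 0.02)
    sy <- runif(k, 0.01, 0.03)
    m <- multi_harmonised_set(bx, bx * 0 + 0.01, by, sy,
                              exposure_names = c("edu", "bmi"))
    fit <- mvmr_fit(m)
    ref <- oracle_wls(bx, by, 1 / sy^2)
    expect_equal(fit$coefficients$beta, unname(ref), tolerance = 1e-10)
  }
})

test_that("MVMR rejects rank-deficient exposure matrices naming the collinear exposure", {
  bx <- cbind(edu = runif(6, 0.05, 0.2), bmi = 0)
  m <- multi_harmonised_set(bx, bx * 0 + 0.01, rnorm(6, 0, 0.05), rep(0.02, 6))
  expect_error(mvmr_fit(m), "rank deficient.*bmi")
})

test_that("product of coefficients and its Sobel SE follow the delta formula", {
  r <- product_indirect(list(beta = -0.2, se = 0.05), list(beta = 0.5, se = 0.1))
  expect_equal(r$beta, -0.1)
  expect_equal(r$se, sqrt(0.0004 + 0.000625))
  expect_equal(r$se, 0.03201562, tolerance = 1e-7)

  # numeric-differentiation check of the same instance: for f(a,b) = a*b,
  # grad = (b, a), se = sqrt(b^2 sa^2 + a^2 sb^2)
  fd <- function(a, b, sa, sb, eps = 1e-6) {
    ga <- ((a + eps) * b - (a - eps) * b) / (2 * eps)
    gb <- (a * (b + eps) - a * (b - eps)) / (2 * eps)
    sqrt(ga^2 * sa^2 + gb^2 * sb^2)
  }
  expect_equal(r$se, fd(-0.2, 0.5, 0.05, 0.1), tolerance = 1e-6)

  r0 <- product_indirect(list(beta = 0, se = 0.05), list(beta = 0.5, se = 0.1))
  expect_equal(r0$beta, 0)
  expect_equal(r0$se, 0.5 * 0.05)

  rid <- product_indirect(list(beta = -0.2, se = 0.05), list(beta = 1, se = 0))
  expect_equal(rid$beta, -0.2)
  expect_equal(rid$se, 0.05)
})

test_that("proportion mediated is the indirect/total ratio with an unclipped delta CI", {
  p <- proportion_mediated(list(beta = -0.1, se = 0.02),
                           list(beta = -0.5, se = 0.05))
  expect_equal(p$point, 0.2)

  # indirect = total forces P = 1 with se sqrt(2)*(se/beta) when ses match
  p1 <- proportion_mediated(list(beta = -0.5, se = 0.05),
                            list(beta = -0.5, se = 0.05))
  expect_equal(p1$point, 1)
  expect_equal(p1$se, sqrt(2) * 0.05 / 0.5)

  expect_error(proportion_mediated(list(beta = 0.1, se = 0.01),
                                   list(beta = 0, se = 0.01)),
               "null total effect")

  # scale invariance: scaling both pieces by any c != 0 changes nothing
  for (c_ in c(-3, 0.01, 7)) {
    ps <- proportion_mediated(list(beta = -0.1 * c_, se = 0.02 * abs(c_)),
                              list(beta = -0.5 * c_, se = 0.05 * abs(c_)))
    expect_equal(ps$point, p$point, tolerance = 1e-12)
    expect_equal(ps$se, p$se, tolerance = 1e-12)
  }

  # intervals may extend outside [0, 1], as printed intervals do
  pw <- proportion_mediated(list(beta = -0.18, se = 0.08),
                            list(beta = -0.5, se = 0.3))
  expect_lt(pw$ci_low, 0)
})

test_that("difference-method mediation computes (T - D)/T with frozen arithmetic cases", {
  expect_equal(combined_difference(list(beta = -0.5, se = 0.03),
                                   list(beta = -0.5, se = 0.05))$proportion$point, 0)
  expect_equal(combined_difference(list(beta = -0.5, se = 0.03),
                                   list(beta = 0, se = 0.05))$proportion$point, 1)
  cd <- combined_difference(list(beta = -0.462, se = 0.02),
                            list(beta = -0.296, se = 0.06))
  expect_equal(cd$proportion$point, (-0.462 + 0.296) / -0.462)
  expect_equal(cd$proportion$point, 0.3593074, tolerance = 1e-6)
  expect_error(combined_difference(list(beta = 0, se = 0.02),
                                   list(beta = -0.2, se = 0.06)),
               "null total effect")
})

test_that("two-step MR recovers a known product mediation from simulated summary statistics", {
  # summary-level generator with a = -0.3 (exposure -> mediator),
  # b = 0.4 (mediator -> outcome | exposure), direct = -0.2:
  # total = -0.2 + (-0.3 * 0.4) = -0.32, true P = 0.12/0.32 = 0.375
  mk <- function(seed, a = -0.3, b = 0.4, direct = -0.2) {
    set.seed(seed)
    ke <- 60; km <- 60
    alpha_e <- runif(ke, 0.03, 0.12)       # exposure-panel effects on exposure
    alpha_m <- runif(km, 0.03, 0.12)       # mediator-panel effects on mediator
    se_x <- 0.004; se_m <- 0.006; se_y <- 0.008
    ids <- c(sprintf("e%02d", 1:ke), sprintf("m%02d", 1:km))
    bx_e <- c(alpha_e, rep(0, km)) + rnorm(ke + km, 0, se_x)
    bx_m <- c(a * alpha_e, alpha_m) + rnorm(ke + km, 0, se_m)
    by <- c((direct + a * b) * alpha_e, b * alpha_m) + rnorm(ke + km, 0, se_y)
    al <- rep("A", ke + km); ol <- rep("G", ke + km)
    list(
      exposure = summary_set(data.frame(snp_id = ids, effect_allele = al,
                                        other_allele = ol, beta = bx_e,
                                        se = se_x), "edu"),
      mediator = summary_set(data.frame(snp_id = ids, effect_allele = al,
                                        other_allele = ol, beta = bx_m,
                                        se = se_m), "bmi"),
      outcome = summary_set(data.frame(snp_id = ids, effect_allele = al,
                                       other_allele = ol, beta = by,
                                       se = se_y), "chd"),
      epanel = ids[1:ke], mpanel = ids[ke + 1:km])
  }
  props <- vapply(1:12, function(s) {
    d <- mk(s)
    two_step_mediation(d$exposure, d$mediator, d$outcome,
                       exposure_snps = d$epanel,
                       mediator_snps = d$mpanel)$proportion$point
  }, numeric(1))
  expect_equal(mean(props), 0.375, tolerance = 0.02)

  # null pathway: mediator generated independent of the exposure (a = 0)
  props0 <- vapply(13:18, function(s) {
    d <- mk(s, a = 0)
    m <- two_step_mediation(d$exposure, d$mediator, d$outcome,
                            exposure_snps = d$epanel, mediator_snps = d$mpanel)
    expect_true(m$proportion$ci_low <= 0 && m$proportion$ci_high >= 0)
    m$proportion$point
  }, numeric(1))
  expect_lt(abs(mean(props0)), 0.05)
})

test_that("product and difference methods agree in a linear system without interactions", {
  # same summary-level system, single mediator: P_product vs P_difference
  set.seed(5)
  diffs <- vapply(seq_len(200), function(r) {
    ke <- 40; km <- 40
    a <- -0.3; b <- 0.4; direct <- -0.2
    alpha_e <- runif(ke, 0.04, 0.12); alpha_m <- runif(km, 0.04, 0.12)
    se_x <- 0.004; se_m <- 0.006; se_y <- 0.008
    bx_e <- c(alpha_e, rep(0, km)) + rnorm(ke + km, 0, se_x)
    bx_m <- c(a * alpha_e, alpha_m) + rnorm(ke + km, 0, se_m)
    by <- c((direct + a * b) * alpha_e, b * alpha_m) + rnorm(ke + km, 0, se_y)
    h_t <- harmonised_set(bx_e[1:ke], rep(se_x, ke), by[1:ke], rep(se_y, ke))
    h_a <- harmonised_set(bx_e[1:ke], rep(se_x, ke), bx_m[1:ke], rep(se_m, ke))
    tot <- ivw_fixed(h_t); aa <- ivw_fixed(h_a)
    m <- multi_harmonised_set(cbind(edu = bx_e, med = bx_m),
                              cbind(rep(se_x, ke + km), rep(se_m, ke + km)),
                              by, rep(se_y, ke + km))
    fit <- mvmr_fit(m)
    bb <- mvmr_coef(fit, "med")
    p_prod <- aa$beta * bb$beta / tot$beta
    p_diff <- (tot$beta - mvmr_coef(fit, "edu")$beta) / tot$beta
    p_prod - p_diff
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.01)
})
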