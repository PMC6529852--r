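# Allele scores, one-sample MR, phenotype derivations, observational arm.

small_cohort <- function(n = 5, G = NULL, phen = NULL, coded = NULL) {
  G <- G %||% matrix(c(0, 1, 2, 1, 0,
                       2, 2, 1, 0, 1), n, 2,
                     dimnames = list(NULL, c("s1", "s2")))
  phen <- phen %||% data.frame(y = seq_len(nrow(G)))
  cohort(G, phen, coded_alleles = coded)
}

test_that("allele scores are oriented, additive dot products and linear in the weights", {
  x <- small_cohort()
  expect_equal(build_allele_score(x, score_definition("s1", 1)),
               x$genotypes[, "s1"])
  # all weights 0.5, all dosages 2 -> score = number of SNPs
  x2 <- cohort(matrix(2, 4, 3, dimnames = list(NULL, paste0("s", 1:3))),
               data.frame(y = 1:4))
  expect_equal(build_allele_score(x2, score_definition(paste0("s", 1:3), rep(0.5, 3))),
               rep(3, 4))
  # by-hand dot product on 5 individuals, 2 SNPs
  def <- score_definition(c("s1", "s2"), c(0.2, -0.4))
  expect_equal(build_allele_score(x, def),
               0.2 * x$genotypes[, "s1"] - 0.4 * x$genotypes[, "s2"])
  # linearity: score(w1 + w2) = score(w1) + score(w2)
  d1 <- score_definition(c("s1", "s2"), c(0.2, -0.4))
  d2 <- score_definition(c("s1", "s2"), c(0.1, 0.3))
  d12 <- score_definition(c("s1", "s2"), c(0.3, -0.1))
  expect_equal(build_allele_score(x, d12),
               build_allele_score(x, d1) + build_allele_score(x, d2))
  # orientation: weight on the opposite allele flips the dosage to 2 - g
  coded <- c(s1 = "A", s2 = "C")
  xo <- small_cohort(coded = coded)
  def_flip <- score_definition("s1", 1, effect_allele = "G")
  expect_equal(build_allele_score(xo, def_flip), 2 - xo$genotypes[, "s1"])
  expect_error(build_allele_score(x, score_definition("s9", 1)), "s9")
  expect_error(score_definition("s1", 0), "nonzero")
})

test_that("blood pressure medication adjustment adds 10 mm Hg for treated participants only", {
  expect_equal(adjust_sbp_for_medication(140, 1), 150)
  expect_equal(adjust_sbp_for_medication(140, 0), 140)
  expect_equal(adjust_sbp_for_medication(c(120, 140, 160), c(0, 1, 0)),
               c(120, 150, 160))
  expect_error(adjust_sbp_for_medication(-5, 0), "positive")
})

test_that("qualification categories map to years of schooling with hard errors for unknown codes", {
  expect_equal(map_qualifications_to_years("none of the above"), 7L)
  expect_equal(map_qualifications_to_years("College or University degree"), 20L)
  expect_equal(map_qualifications_to_years(c("CSEs", "A levels or AS levels")),
               c(10L, 13L))
  expect_error(map_qualifications_to_years("apprenticeship"), "apprenticeship")
})

test_that("a perfect instrument reduces one-sample MR to ordinary regression", {
  set.seed(21)
  n <- 500
  e <- rnorm(n)
  y <- 0.3 * e + rnorm(n)
  x <- cohort(matrix(1, n, 1, dimnames = list(NULL, "s1")),
              data.frame(exposure = e, outcome = y))
  est <- one_sample_mr(x, score = e, "exposure", "outcome",
                       binary_outcome = FALSE)
  expect_equal(est$beta, unname(coef(lm(y ~ e))[2]), tolerance = 1e-10)
})

test_that("one-sample MR resists planted confounding that biases naive regression", {
  set.seed(31)
  true_effect <- 0.25
  res <- t(replicate(40, {
    n <- 2500
    g <- rbinom(n, 2, 0.3)
    u <- rnorm(n)
    e <- 0.4 * g + 0.8 * u + rnorm(n)
    y <- true_effect * e - 0.9 * u + rnorm(n)
    x <- cohort(matrix(g, ncol = 1, dimnames = list(NULL, "s1")),
                data.frame(exposure = e, outcome = y))
    mr <- one_sample_mr(x, build_allele_score(x, score_definition("s1", 1)),
                        "exposure", "outcome", binary_outcome = FALSE)
    c(mr = mr$beta, naive = unname(coef(lm(y ~ e))[2]))
  }))
  expect_lt(abs(mean(res[, "mr"]) - true_effect), 0.03)
  expect_gt(abs(mean(res[, "naive"]) - true_effect), 0.15)
})

test_that("under a null causal effect the 2SLS interval covers zero at the nominal rate", {
  set.seed(77)
  cover <- replicate(200, {
    n <- 800
    g <- rbinom(n, 2, 0.3)
    e <- 0.5 * g + rnorm(n)
    y <- rnorm(n)                      # no effect of exposure
    x <- cohort(matrix(g, ncol = 1, dimnames = list(NULL, "s1")),
                data.frame(exposure = e, outcome = y))
    est <- one_sample_mr(x, g, "exposure", "outcome", binary_outcome = FALSE)
    est$ci_low <= 0 && est$ci_high >= 0
  })
  expect_gt(mean(cover), 0.91)
  expect_lt(mean(cover), 0.99)
})

test_that("observational totals recover planted log odds ratios and confounder adjustment helps", {
  set.seed(41)
  # null: odds ratio near 1
  n <- 8000
  e <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0 * e))
  x <- cohort(matrix(0, n, 1, dimnames = list(NULL, "s1")),
              data.frame(education = e, outcome = y))
  est0 <- observational_total(x, "education", "outcome")
  expect_lt(abs(est0$beta), 0.08)

  # planted effect, no confounding
  betas <- replicate(15, {
    e <- rnorm(n)
    y <- rbinom(n, 1, plogis(-2 - 0.15 * e))
    x <- cohort(matrix(0, n, 1, dimnames = list(NULL, "s1")),
                data.frame(education = e, outcome = y))
    observational_total(x, "education", "outcome")$beta
  })
  expect_lt(abs(mean(betas) + 0.15), 0.02)

  # measured confounder: adjusted estimate is closer to truth
  res <- t(replicate(15, {
    u <- rnorm(n)
    e <- 0.7 * u + rnorm(n)
    y <- rbinom(n, 1, plogis(-2 - 0.15 * e + 0.5 * u))
    x <- cohort(matrix(0, n, 1, dimnames = list(NULL, "s1")),
                data.frame(education = e, outcome = y, u = u))
    c(adj = observational_total(x, "education", "outcome", "u")$beta,
      unadj = observational_total(x, "education", "outcome")$beta)
  }))
  expect_lt(abs(mean(res[, "adj"]) + 0.15), abs(mean(res[, "unadj"]) + 0.15))
})

test_that("observational mediation finds a null proportion for an unrelated mediator and is seed-stable", {
  set.seed(51)
  n <- 6000
  e <- rnorm(n)
  m <- rnorm(n)                        # independent of the exposure
  y <- rbinom(n, 1, plogis(-2 - 0.3 * e + 0.4 * m))
  x <- cohort(matrix(0, n, 1, dimnames = list(NULL, "s1")),
              data.frame(education = e, med = m, outcome = y))
  est <- observational_mediation(x, "education", "med", "outcome",
                                 n_boot = 150, seed = 9)
  expect_lt(abs(est$proportion$point), 0.05)
  expect_true(est$proportion$ci_low <= 0 && est$proportion$ci_high >= 0)

  est2 <- observational_mediation(x, "education", "med", "outcome",
                                  n_boot = 150, seed = 9)
  expect_identical(est$proportion, est2$proportion)
  est3 <- observational_mediation(x, "education", "med", "outcome",
                                  n_boot = 150, seed = 10)
  expect_false(identical(est$proportion$se, est3$proportion$se))
})

test_that("observational mediation recovers a planted proportion without measurement error", {
  # exact generator, reliability 1, no confounding, rare outcome: the
  # product-of-coefficients on log odds matches the generating proportion
  cfg <- synth_config(n = 30000, m_instruments = 20,
                      gamma_u = 0, delta_u = c(bmi = 0, sbp = 0, smoking = 0),
                      phi_u = 0,
                      reliability = c(bmi = 1, sbp = 1, smoking = 1),
                      true_proportions = c(bmi = 0.25, sbp = 0.1, smoking = 0.1),
                      outcome_prevalence = 0.02, seed = 61)
  props <- vapply(1:6, function(s) {
    cfg$seed <- 60 + s
    sim <- simulate_cohort(cfg)
    x <- standardise_phenotypes(sim$cohort)
    observational_mediation(x, "education_std", "bmi_std", "outcome",
                            confounders = c("age", "sex"), n_boot = 0)$proportion$point
  }, numeric(1))
  expect_lt(abs(mean(props) - 0.25), 0.03)
})

test_that("sample splitting is disjoint, exhaustive and reproducible", {
  x <- small_cohort(n = 5)
  sim <- simulate_cohort(synth_config(n = 1000, m_instruments = 5, seed = 5))
  halves <- split_sample(sim$cohort, 0.5, seed = 3)
  i1 <- attr(halves[[1]], "index"); i2 <- attr(halves[[2]], "index")
  expect_equal(halves[[1]]$n, 500)
  expect_equal(halves[[2]]$n, 500)
  expect_length(intersect(i1, i2), 0)
  expect_setequal(c(i1, i2), seq_len(1000))
  halves_b <- split_sample(sim$cohort, 0.5, seed = 3)
  expect_identical(attr(halves_b[[1]], "index"), i1)
  # union of halves reassembles the cohort
  reunited <- rbind(halves[[1]]$genotypes, halves[[2]]$genotypes)
  expect_equal(reunited[order(c(i1, i2)), ], sim$cohort$genotypes)
  expect_error(split_sample(sim$cohort, 1.2), "fraction")
})
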