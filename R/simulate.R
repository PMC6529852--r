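# Genotype-phenotype cohort simulator with closed-form mediation truth.
#
# Causal structure mirrored from the analysis assumptions: independent
# dosages -> continuous exposure (education, unit variance) -> three
# mediators (unit variance latent, classically mismeasured) -> binary
# outcome through a logistic link, with one unobserved confounder U loading
# on exposure, mediators and outcome. Mediator instrument panels are SNP
# blocks disjoint from the exposure panel, so there is no pleiotropy unless
# the pleiotropy knob is turned on.

MEDIATORS <- c("bmi", "sbp", "smoking")

#' Default simulation configuration
#'
#' The defaults encode the study conditions the package is designed around:
#' a cohort of 100 000, 100 SNPs per trait panel, instruments explaining 12%
#' of exposure variance (education) and 10% of each mediator's variance,
#' education effects on the mediators of (-0.22, -0.15, -0.32) SD/SD, a
#' total exposure log odds ratio of `ln 0.63` per SD with proportions
#' (0.18, 0.21, 0.34) flowing through BMI, systolic blood pressure and
#' lifetime smoking, 5% outcome prevalence, and mediator measurement
#' reliabilities (0.95, 0.7, 0.7).
#'
#' @param n cohort size.
#' @param m_instruments SNPs per trait panel (4 panels: exposure + 3
#'   mediators).
#' @param maf_range minor-allele-frequency range, within (0, 0.5\].
#' @param instrument_r2 exposure variance explained by the exposure panel.
#' @param mediator_r2 direct mediator variance explained by each mediator
#'   panel.
#' @param theta education -> mediator effects (SD/SD), named after
#'   `MEDIATORS`.
#' @param true_total total exposure -> outcome effect, log odds per SD.
#' @param true_proportions proportion of `true_total` mediated through each
#'   mediator (used to derive the mediator -> outcome effects
#'   `beta = prop * total / theta` and the direct effect
#'   `total * (1 - sum(prop))`).
#' @param gamma_u,delta_u,phi_u confounder loadings on exposure, mediators
#'   and outcome (log odds).
#' @param reliability classical measurement reliability of each observed
#'   mediator, in (0, 1\].
#' @param outcome_prevalence baseline outcome probability.
#' @param pleiotropy_fraction fraction of exposure-panel SNPs given direct
#'   outcome effects (default 0 = valid instruments).
#' @param pleiotropy_mean,pleiotropy_sd distribution of those direct log
#'   odds effects per allele.
#' @param education_mean_years,education_sd_years,sbp_mean_mmhg,sbp_sd_mmhg
#'   native-unit anchors used to emit `education_years` and the measured
#'   mm Hg blood pressure column.
#' @param seed integer seed; every random draw flows from it.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n = 100000,
                         m_instruments = 100,
                         maf_range = c(0.05, 0.45),
                         instrument_r2 = 0.12,
                         mediator_r2 = 0.10,
                         theta = c(bmi = -0.22, sbp = -0.15, smoking = -0.32),
                         true_total = log(0.63),
                         true_proportions = c(bmi = 0.18, sbp = 0.21, smoking = 0.34),
                         gamma_u = 0.3,
                         delta_u = c(bmi = 0.2, sbp = 0.2, smoking = 0.2),
                         phi_u = 0.3,
                         reliability = c(bmi = 0.95, sbp = 0.7, smoking = 0.7),
                         outcome_prevalence = 0.05,
                         pleiotropy_fraction = 0,
                         pleiotropy_mean = 0, pleiotropy_sd = 0,
                         education_mean_years = 14.9, education_sd_years = 3.6,
                         sbp_mean_mmhg = 137, sbp_sd_mmhg = 18.68,
                         seed = 1L) {
  theta <- theta[MEDIATORS]; delta_u <- delta_u[MEDIATORS]
  reliability <- reliability[MEDIATORS]
  true_proportions <- true_proportions[MEDIATORS]
  assert_that(maf_range[1] > 0 && maf_range[2] <= 0.5 &&
                maf_range[1] <= maf_range[2], "maf_range must lie in (0, 0.5]")
  assert_that(instrument_r2 > 0 && instrument_r2 < 1, "instrument_r2 must be in (0,1)")
  assert_that(mediator_r2 >= 0 && mediator_r2 < 1, "mediator_r2 must be in [0,1)")
  assert_that(all(reliability > 0 & reliability <= 1), "reliabilities must be in (0,1]")
  assert_that(outcome_prevalence > 0 && outcome_prevalence < 1,
              "outcome_prevalence must be in (0,1)")
  assert_that(all(theta != 0) || all(true_proportions == 0),
              "theta must be nonzero wherever a mediated proportion is nonzero")

  beta_mediator <- ifelse(theta != 0, true_proportions * true_total / theta, 0)
  beta_direct <- true_total * (1 - sum(true_proportions))

  # variance feasibility on the unit-variance scales
  resid_e <- 1 - instrument_r2 - gamma_u^2
  assert_that(resid_e > 0, "infeasible exposure variance budget (residual %g)", resid_e)
  resid_m <- 1 - theta^2 - mediator_r2 - delta_u^2
  assert_that(all(resid_m > 0), "infeasible mediator variance budget: %s",
              paste(MEDIATORS[resid_m <= 0], collapse = ", "))

  structure(list(n = as.integer(n), m_instruments = as.integer(m_instruments),
                 maf_range = maf_range, instrument_r2 = instrument_r2,
                 mediator_r2 = mediator_r2, theta = theta,
                 beta_mediator = beta_mediator, beta_direct = beta_direct,
                 gamma_u = gamma_u, delta_u = delta_u, phi_u = phi_u,
                 reliability = reliability,
                 outcome_prevalence = outcome_prevalence,
                 pleiotropy_fraction = pleiotropy_fraction,
                 pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
                 education_mean_years = education_mean_years,
                 education_sd_years = education_sd_years,
                 sbp_mean_mmhg = sbp_mean_mmhg, sbp_sd_mmhg = sbp_sd_mmhg,
                 seed = as.integer(seed),
                 resid_e = resid_e, resid_m = resid_m),
            class = "synth_config")
}

#' Closed-form ground truth implied by a configuration
#'
#' On the log-odds-linear system the generator uses, the total effect
#' decomposes exactly: `total = direct + sum(theta_i * beta_i)`, each
#' mediator's indirect effect is `theta_i * beta_i`, and proportions are
#' indirect/total. The combined (difference-method) proportion equals the
#' sum of the per-mediator proportions because the mediators are
#' conditionally independent given exposure and confounder.
#'
#' @param config a `synth_config`.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  indirect <- config$theta * config$beta_mediator
  total <- config$beta_direct + sum(indirect)
  prop <- if (total != 0) indirect / total else indirect * NA
  structure(list(true_total = total,
                 true_direct = config$beta_direct,
                 true_indirect = indirect,
                 true_proportion = prop,
                 true_proportion_combined = if (total != 0) sum(prop) else NA_real_),
            class = "simulation_truth")
}

# non-palindromic pairs only, so synthetic panels never lose SNPs to
# strand-ambiguity drops during harmonisation
random_alleles <- function(m) {
  effect <- sample(VALID_ALLELES, m, replace = TRUE)
  other <- vapply(effect, function(a) {
    sample(setdiff(VALID_ALLELES, c(a, COMPLEMENT[[a]])), 1)
  }, character(1), USE.NAMES = FALSE)
  list(effect = effect, other = other)
}

#' Simulate an individual-level cohort with known mediation truth
#'
#' Dosages are independent `Binomial(2, maf)` draws; per-SNP effects on
#' their panel's trait are Normal draws rescaled so the panel explains
#' exactly the configured variance fraction. The latent exposure and
#' mediators have unit variance by construction; observed mediators add
#' classical measurement noise with the configured reliability. The outcome
#' is Bernoulli with a logistic link on the *latent* mediators, the
#' exposure, the unobserved confounder, and benign age/sex covariates.
#' The measured blood pressure column is emitted in mm Hg with 10 mm Hg
#' subtracted for (blood-pressure-dependent) medication users, so the
#' analysis pipeline must re-apply [adjust_sbp_for_medication()].
#'
#' All randomness flows from `config$seed`: equal configs give bit-identical
#' cohorts.
#'
#' @param config a [synth_config()].
#' @return List with elements `cohort` (a [cohort()] with panels
#'   `education`, `bmi`, `sbp`, `smoking`), `truth`
#'   (a [simulation_truth()]), and `params` (the per-SNP effect draws).
#' @export
simulate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n; m <- config$m_instruments
  panels <- c("education", MEDIATORS)
  total_m <- m * length(panels)
  maf <- stats::runif(total_m, config$maf_range[1], config$maf_range[2])
  snp_ids <- sprintf("rs%s%04d", rep(c("e", "b", "s", "k"), each = m),
                     rep(seq_len(m), times = 4))
  G <- matrix(stats::rbinom(n * total_m, 2L, rep(maf, each = n)), n, total_m,
              dimnames = list(NULL, snp_ids))
  al <- random_alleles(total_m)

  panel_idx <- split(seq_len(total_m), rep(panels, each = m))[panels]
  scale_effects <- function(idx, target_r2) {
    raw <- stats::rnorm(length(idx))
    v <- 2 * maf[idx] * (1 - maf[idx])
    raw * sqrt(target_r2 / sum(raw^2 * v))
  }
  alpha_e <- scale_effects(panel_idx$education, config$instrument_r2)
  alpha_m <- lapply(MEDIATORS, function(tr) {
    if (config$mediator_r2 > 0) scale_effects(panel_idx[[tr]], config$mediator_r2)
    else numeric(m)
  })
  names(alpha_m) <- MEDIATORS

  U <- stats::rnorm(n)
  Ge <- G[, panel_idx$education, drop = FALSE]
  gc_e <- sweep(Ge, 2, 2 * maf[panel_idx$education])   # centred dosages
  E <- drop(gc_e %*% alpha_e) + config$gamma_u * U +
    stats::rnorm(n, sd = sqrt(config$resid_e))

  M_star <- matrix(0, n, 3, dimnames = list(NULL, MEDIATORS))
  M_obs <- M_star
  for (j in seq_along(MEDIATORS)) {
    tr <- MEDIATORS[j]
    Gm <- sweep(G[, panel_idx[[tr]], drop = FALSE], 2, 2 * maf[panel_idx[[tr]]])
    M_star[, j] <- config$theta[j] * E + drop(Gm %*% alpha_m[[j]]) +
      config$delta_u[j] * U + stats::rnorm(n, sd = sqrt(config$resid_m[j]))
    noise_var <- (1 - config$reliability[j]) / config$reliability[j]
    M_obs[, j] <- M_star[, j] +
      if (noise_var > 0) stats::rnorm(n, sd = sqrt(noise_var)) else 0
  }

  age <- stats::runif(n, 40, 70)
  sex <- stats::rbinom(n, 1L, 0.5)
  lp <- stats::qlogis(config$outcome_prevalence) +
    config$beta_direct * E + drop(M_star %*% config$beta_mediator) +
    config$phi_u * U + 0.02 * (age - 55) + 0.25 * (sex - 0.5)
  if (config$pleiotropy_fraction > 0) {
    k_ple <- max(1L, round(config$pleiotropy_fraction * m))
    ple_idx <- sample(panel_idx$education, k_ple)
    ple_eff <- stats::rnorm(k_ple, config$pleiotropy_mean, config$pleiotropy_sd)
    lp <- lp + drop(sweep(G[, ple_idx, drop = FALSE], 2, 2 * maf[ple_idx]) %*% ple_eff)
  } else {
    ple_idx <- integer(0); ple_eff <- numeric(0)
  }
  outcome <- stats::rbinom(n, 1L, stats::plogis(lp))

  sbp_medication <- stats::rbinom(n, 1L, stats::plogis(-2.2 + 0.8 * M_star[, "sbp"]))
  sbp_measured <- config$sbp_mean_mmhg + config$sbp_sd_mmhg * M_obs[, "sbp"] -
    10 * sbp_medication

  phen <- data.frame(
    education = E,
    education_years = config$education_mean_years + config$education_sd_years * E,
    bmi = M_obs[, "bmi"],
    sbp = M_obs[, "sbp"],
    smoking_index = M_obs[, "smoking"],
    sbp_measured_mmhg = sbp_measured,
    sbp_medication = sbp_medication,
    outcome = outcome,
    age = age, sex = sex)

  coded <- stats::setNames(al$effect, snp_ids)
  attr(coded, "other") <- stats::setNames(al$other, snp_ids)
  co <- cohort(G, phen, snp_ids,
               panels = lapply(panel_idx, function(i) snp_ids[i]),
               coded_alleles = coded)
  list(cohort = co,
       truth = simulation_truth(config),
       params = list(maf = stats::setNames(maf, snp_ids),
                     alpha_education = stats::setNames(alpha_e, snp_ids[panel_idx$education]),
                     alpha_mediator = lapply(seq_along(MEDIATORS), function(j) {
                       stats::setNames(alpha_m[[j]], snp_ids[panel_idx[[MEDIATORS[j]]]])
                     }),
                     pleiotropy = list(snp = snp_ids[ple_idx], effect = ple_eff),
                     effect_allele = stats::setNames(al$effect, snp_ids),
                     other_allele = stats::setNames(al$other, snp_ids)))
}
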