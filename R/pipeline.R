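# End-to-end orchestration of the three analysis arms on a simulated (or
# user-supplied) study, plus report rendering.

MED_COLS <- c(bmi = "bmi_std", sbp = "sbp_std", smoking = "smoking_std")

#' Derive the standardised analysis phenotypes
#'
#' Reconstructs the analysis columns a real study would derive: education in
#' years standardised per SD, measured blood pressure adjusted for
#' antihypertensive medication (+10 mm Hg) then standardised, and the other
#' mediators standardised, each by its empirical SD. Adds columns
#' `education_std`, `bmi_std`, `sbp_std`, `smoking_std`.
#'
#' @param x a `cohort` with the simulator's phenotype layout.
#' @return The `cohort` with added standardised columns; empirical SDs are
#'   attached as `attr(., "trait_sds")`.
#' @export
standardise_phenotypes <- function(x) {
  stopifnot(inherits(x, "cohort"))
  ph <- x$phenotypes
  std <- function(v) (v - mean(v)) / stats::sd(v)
  sbp_adj <- adjust_sbp_for_medication(ph$sbp_measured_mmhg, ph$sbp_medication)
  ph$education_std <- std(ph$education_years)
  ph$bmi_std <- std(ph$bmi)
  ph$sbp_std <- std(sbp_adj)
  ph$smoking_std <- std(ph$smoking_index)
  sds <- c(education = stats::sd(ph$education_years), bmi = stats::sd(ph$bmi),
           sbp = stats::sd(sbp_adj), smoking = stats::sd(ph$smoking_index))
  x$phenotypes <- ph   # keep the genotype matrix and its cached statistics
  attr(x, "trait_sds") <- sds
  x
}

#' Two-sample MR arm on a simulated cohort
#'
#' Computes GWAS summary statistics within the cohort for the standardised
#' exposure, the three mediators and the binary outcome, then runs the full
#' two-sample machinery: total effects by IVW, MR-Egger and the weighted
#' median; per-mediator two-step (product-of-coefficients) mediation; and
#' combined difference-method mediation from a four-exposure multivariable
#' MR.
#'
#' @param x a standardised `cohort` (see [standardise_phenotypes()]).
#' @param seed integer seed for the weighted-median bootstrap.
#' @param n_boot weighted-median bootstrap resamples (default 200 in the
#'   pipeline for speed; the standalone estimator defaults to 1000).
#' @param sensitivity also run Egger and weighted median (default TRUE).
#' @return List with `totals` (list of `mr_estimate`), `mediation` (list of
#'   `mediation_estimate` per mediator), `combined`
#'   (a `mediation_estimate`), `summaries` (the generated `summary_set`s).
#' @export
run_two_sample <- function(x, seed = 1L, n_boot = 200, sensitivity = TRUE) {
  stopifnot(inherits(x, "cohort"))
  assert_that(!is.null(x$panels), "cohort carries no instrument panels")
  scan <- function(col, name) {
    s <- compute_gwas_summaries(x, col, per_sd = TRUE)
    s$trait_name <- name
    s
  }
  edu <- scan("education_std", "education")
  meds <- lapply(names(MED_COLS), function(tr) scan(MED_COLS[[tr]], tr))
  names(meds) <- names(MED_COLS)
  out <- scan("outcome", "outcome")

  edu_panel <- subset_snps(edu, x$panels$education, require_all = TRUE)
  h_total <- harmonise(edu_panel, out)
  totals <- list(ivw = ivw_fixed(h_total))
  if (sensitivity) {
    totals$egger <- mr_egger(h_total)
    totals$weighted_median <- weighted_median(h_total, n_boot = max(100, n_boot),
                                              seed = seed)
  }

  mediation <- lapply(names(MED_COLS), function(tr) {
    two_step_mediation(edu, meds[[tr]], out,
                       exposure_snps = x$panels$education,
                       mediator_snps = x$panels[[tr]])
  })
  names(mediation) <- names(MED_COLS)

  all_snps <- unlist(x$panels[c("education", names(MED_COLS))], use.names = FALSE)
  mh <- multi_harmonise(c(list(education = edu), meds), out, snps = all_snps)
  mvmr <- mvmr_fit(mh)
  combined <- combined_difference(totals$ivw, mvmr, exposure = "education",
                                  labels = list(exposure = "education",
                                                mediator = "bmi+sbp+smoking",
                                                outcome = "outcome"))
  list(totals = totals, mediation = mediation, combined = combined,
       mvmr = mvmr,
       summaries = c(list(education = edu, outcome = out), meds))
}

#' One-sample MR arm with split-sample allele scores
#'
#' Splits the cohort in half; estimates per-SNP score weights for each trait
#' panel in the first half; builds weighted allele scores and runs the
#' score-based estimators in the second half (avoiding winner's-curse
#' overlap between weight discovery and analysis). Total effects by the
#' reduced-form/first-stage ratio (plus Egger and weighted-median
#' sensitivity estimates on the per-SNP associations of the analysis half),
#' per-mediator product-of-coefficients mediation and combined
#' difference-method mediation via the multivariable score estimator.
#'
#' @param x a standardised `cohort`.
#' @param seed integer seed (sample split and bootstraps).
#' @param n_boot bootstrap resamples for mediation CIs (0 = point estimates
#'   only).
#' @param covariates adjusted-for phenotype columns (default age, sex).
#' @param risk_difference also compute the linear-probability-scale
#'   replication of the mediation estimates.
#' @return List with `total`, `sensitivity`, `mediation`, `combined`,
#'   optional `risk_difference`, and the `scores`.
#' @export
run_one_sample <- function(x, seed = 1L, n_boot = 0,
                           covariates = c("age", "sex"),
                           risk_difference = FALSE) {
  stopifnot(inherits(x, "cohort"))
  halves <- split_sample(x, 0.5, seed = seed)
  disc <- halves[[1]]; ana <- halves[[2]]

  defs <- lapply(c("education", names(MED_COLS)), function(tr) {
    col <- if (tr == "education") "education_std" else MED_COLS[[tr]]
    s <- compute_gwas_summaries(disc, col, snps = x$panels[[tr]], per_sd = TRUE)
    score_definition(s$data$snp_id, s$data$beta, s$data$effect_allele,
                     source_label = sprintf("split-sample GWAS of %s", tr))
  })
  names(defs) <- c("education", names(MED_COLS))
  scores <- vapply(defs, function(d) build_allele_score(ana, d),
                   numeric(ana$n))

  total <- one_sample_mr(ana, scores[, "education"], "education_std", "outcome",
                         covariates = covariates)

  mediation <- lapply(names(MED_COLS), function(tr) {
    one_sample_mediation(ana, scores[, c("education", tr)],
                         "education_std", MED_COLS[[tr]], "outcome",
                         covariates = covariates, n_boot = n_boot, seed = seed)
  })
  names(mediation) <- names(MED_COLS)
  combined <- one_sample_mediation(ana, scores, "education_std",
                                   unname(MED_COLS), "outcome",
                                   covariates = covariates, n_boot = n_boot,
                                   seed = seed)
  out <- list(total = total, mediation = mediation, combined = combined,
              scores = scores, score_definitions = defs)
  if (risk_difference) {
    out$risk_difference <- list(
      total = one_sample_mr(ana, scores[, "education"], "education_std",
                            "outcome", covariates = covariates,
                            binary_outcome = FALSE),
      combined = one_sample_mediation(ana, scores, "education_std",
                                      unname(MED_COLS), "outcome",
                                      covariates = covariates, n_boot = n_boot,
                                      seed = seed, scale = "risk_difference"))
  }
  out
}

#' Observational arm
#'
#' Multivariable logistic regression total effect and regression-based
#' mediation (product of coefficients per mediator, difference method for
#' all three jointly), adjusted for the observed covariates. The unobserved
#' simulated confounder stays unobserved, as in a real study.
#'
#' @param x a standardised `cohort`.
#' @param n_boot bootstrap resamples for mediation CIs (0 = point estimates
#'   only, delta-method proportion se).
#' @param seed integer seed for the bootstrap.
#' @param confounders adjusted-for phenotype columns (default age, sex).
#' @return List with `total`, `mediation`, `combined`.
#' @export
run_observational <- function(x, n_boot = 0, seed = 1L,
                              confounders = c("age", "sex")) {
  stopifnot(inherits(x, "cohort"))
  total <- observational_total(x, "education_std", "outcome", confounders)
  mediation <- lapply(names(MED_COLS), function(tr) {
    observational_mediation(x, "education_std", MED_COLS[[tr]], "outcome",
                            confounders, n_boot = n_boot, seed = seed)
  })
  names(mediation) <- names(MED_COLS)
  combined <- observational_mediation(x, "education_std", unname(MED_COLS),
                                      "outcome", confounders, n_boot = n_boot,
                                      seed = seed)
  list(total = total, mediation = mediation, combined = combined)
}

#' Simulate a study and check recovery of every estimand
#'
#' Runs the full loop: simulate a cohort from `config`, derive the analysis
#' phenotypes, run the two-sample, one-sample and observational arms, and
#' tabulate estimated against true total effects and proportions mediated.
#'
#' @param config a [synth_config()].
#' @param n_boot bootstrap resamples for the individual-level CIs (0 =
#'   point estimates only; recovery checks only need points).
#' @param arms which arms to run.
#' @return List of class `recovery_report`: `truth`, `two_sample`,
#'   `one_sample`, `observational` (the arm bundles) and `table`, a
#'   data.frame of estimand / truth / per-arm estimates.
#' @export
end_to_end_truth_check <- function(config = synth_config(), n_boot = 0,
                                   arms = c("two_sample", "one_sample",
                                            "observational")) {
  sim <- simulate_cohort(config)
  x <- standardise_phenotypes(sim$cohort)
  truth <- sim$truth
  res <- list(truth = truth, config = config)
  if ("two_sample" %in% arms)
    res$two_sample <- run_two_sample(x, seed = config$seed, sensitivity = FALSE)
  if ("one_sample" %in% arms)
    res$one_sample <- run_one_sample(x, seed = config$seed, n_boot = n_boot)
  if ("observational" %in% arms)
    res$observational <- run_observational(x, n_boot = n_boot, seed = config$seed)

  est <- function(arm) {
    a <- res[[arm]]
    if (is.null(a)) return(rep(NA_real_, 5))
    tot <- if (arm == "two_sample") a$totals$ivw else a$total
    c(tot$beta,
      vapply(MEDIATORS, function(tr) a$mediation[[tr]]$proportion$point,
             numeric(1)),
      a$combined$proportion$point)
  }
  res$table <- data.frame(
    estimand = c("total_log_or", paste0("proportion_", MEDIATORS),
                 "proportion_combined"),
    truth = c(truth$true_total, truth$true_proportion,
              truth$true_proportion_combined),
    two_sample = est("two_sample"),
    one_sample = est("one_sample"),
    observational = est("observational"),
    stringsAsFactors = FALSE)
  class(res) <- "recovery_report"
  res
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Render a results bundle as a human-readable report
#'
#' Odds ratios are shown as `exp(beta)` with 95% CIs in the
#' `"0.63 (0.60 to 0.67)"` style; proportions mediated as whole percents.
#' A machine-readable twin (nested list, suitable for JSON serialisation)
#' is attached as `attr(., "machine")`.
#'
#' @param bundle a nonempty list as returned by [run_two_sample()],
#'   [run_one_sample()], [run_observational()] or a named list of such
#'   bundles.
#' @return Character vector of report lines.
#' @export
render_report <- function(bundle) {
  assert_that(is.list(bundle) && length(bundle) > 0, "empty results bundle")
  lines <- character(0)
  machine <- list()
  emit <- function(...) lines <<- c(lines, sprintf(...))

  render_arm <- function(arm, name) {
    emit("== %s ==", name)
    tots <- if (!is.null(arm$totals)) arm$totals else
      if (!is.null(arm$total)) list(total = arm$total) else list()
    for (nm in names(tots)) {
      e <- tots[[nm]]
      emit("  total effect [%s]: OR %s, p %.3g", e$method,
           format_or_ci(e$beta, e$se), e$pvalue)
      machine[[name]]$totals[[nm]] <<- unclass(e)
    }
    for (nm in names(arm$mediation)) {
      m <- arm$mediation[[nm]]
      pr <- m$proportion
      emit("  mediated via %s: %s", nm,
           format_pct_ci(pr$point, pr$ci_low %||% NA, pr$ci_high %||% NA))
      machine[[name]]$mediation[[nm]] <<- unclass(m)
    }
    if (!is.null(arm$combined)) {
      pr <- arm$combined$proportion
      emit("  all mediators combined: %s",
           format_pct_ci(pr$point, pr$ci_low %||% NA, pr$ci_high %||% NA))
      machine[[name]]$combined <<- unclass(arm$combined)
    }
  }

  if (any(c("totals", "total", "mediation") %in% names(bundle))) {
    render_arm(bundle, "results")
  } else {
    for (nm in names(bundle)) {
      if (is.list(bundle[[nm]]) &&
          any(c("totals", "total", "mediation") %in% names(bundle[[nm]]))) {
        render_arm(bundle[[nm]], nm)
      }
    }
    assert_that(length(lines) > 0, "empty results bundle")
  }
  attr(lines, "machine") <- machine
  lines
}

#' Re-run the two-sample analyses on published per-SNP association tables
#'
#' Expects a directory of tab-delimited summary-statistic files in the
#' standard `SNP CHR BP EA OA EAF BETA SE P N` layout: `education.tsv`,
#' `bmi.tsv`, `sbp.tsv`, `smoking.tsv` (association estimates for the
#' instruments with each trait), outcome files (`chd.tsv`, `stroke.tsv`,
#' `mi.tsv` as available), and optional `<trait>.instruments` files listing
#' the instrument SNP ids one per line (defaults to all SNPs in the trait
#' file). Runs total-effect IVW/Egger/weighted-median and the two-step and
#' combined mediation grids against each outcome.
#'
#' @param dir directory of input tables.
#' @param outcomes outcome file stems to analyse (default those present).
#' @param seed seed for the weighted-median bootstrap.
#' @return Named list per outcome with `totals`, `mediation`, `combined`.
#' @export
reproduce_published_two_sample <- function(dir, outcomes = NULL, seed = 1L) {
  assert_that(dir.exists(dir), "input directory '%s' does not exist", dir)
  need <- c("education", "bmi", "sbp", "smoking")
  paths <- file.path(dir, paste0(need, ".tsv"))
  missing <- need[!file.exists(paths)]
  assert_that(length(missing) == 0,
              "missing required summary tables in '%s': %s", dir,
              paste(paste0(missing, ".tsv"), collapse = ", "))
  sets <- lapply(seq_along(need), function(i) {
    read_summary_stats(paths[i], trait_name = need[i], per_sd = TRUE)
  })
  names(sets) <- need
  instruments <- lapply(need, function(tr) {
    f <- file.path(dir, paste0(tr, ".instruments"))
    if (file.exists(f)) readLines(f) else sets[[tr]]$data$snp_id
  })
  names(instruments) <- need

  outcomes <- outcomes %||% {
    all <- sub("\\.tsv$", "", basename(Sys.glob(file.path(dir, "*.tsv"))))
    setdiff(all, need)
  }
  assert_that(length(outcomes) > 0, "no outcome tables found in '%s'", dir)

  lapply(stats::setNames(outcomes, outcomes), function(oc) {
    out <- read_summary_stats(file.path(dir, paste0(oc, ".tsv")),
                              trait_name = oc, per_sd = TRUE)
    edu_panel <- subset_snps(sets$education, instruments$education)
    h <- harmonise(edu_panel, out)
    totals <- list(ivw = ivw_fixed(h), egger = mr_egger(h),
                   weighted_median = weighted_median(h, seed = seed))
    mediation <- lapply(c("bmi", "sbp", "smoking"), function(tr) {
      two_step_mediation(sets$education, sets[[tr]], out,
                         exposure_snps = instruments$education,
                         mediator_snps = instruments[[tr]])
    })
    names(mediation) <- c("bmi", "sbp", "smoking")
    mh <- multi_harmonise(sets, out,
                          snps = unique(unlist(instruments, use.names = FALSE)))
    combined <- combined_difference(totals$ivw, mvmr_fit(mh),
                                    exposure = "education")
    list(totals = totals, mediation = mediation, combined = combined)
  })
}
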