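# Individual-level cohort container, allele scores and phenotype derivations.

#' Construct a cohort object
#'
#' Couples an n x m genotype dosage matrix (values in \[0, 2\], columns =
#' SNPs) with a participant phenotype table. Optionally records which SNP
#' block instruments which trait (`panels`) and the allele each dosage
#' column counts (`coded_alleles`), used to orient allele-score weights.
#'
#' @param genotypes numeric matrix, participants x SNPs, dosages in \[0, 2\].
#' @param phenotypes data.frame with one row per participant; column names
#'   must be unique and rows complete (no missing values).
#' @param snp_ids SNP identifiers (default `colnames(genotypes)`).
#' @param panels optional named list mapping trait -> character vector of
#'   instrument SNP ids.
#' @param coded_alleles optional named character vector: the counted allele
#'   per SNP.
#' @param validate re-check the dosage range and phenotype completeness
#'   (default TRUE; internal callers re-wrapping an already validated matrix
#'   skip it).
#' @return An object of class `cohort`.
#' @export
cohort <- function(genotypes, phenotypes, snp_ids = colnames(genotypes),
                   panels = NULL, coded_alleles = NULL, validate = TRUE) {
  genotypes <- as.matrix(genotypes)
  assert_that(!is.null(snp_ids), "snp_ids required (or colnames on genotypes)")
  assert_that(length(snp_ids) == ncol(genotypes),
              "snp_ids must match genotype columns")
  assert_that(nrow(phenotypes) == nrow(genotypes),
              "phenotype rows must match genotype rows")
  assert_that(!anyDuplicated(names(phenotypes)), "phenotype columns must be unique")
  if (validate) {
    assert_that(min(genotypes) >= 0 && max(genotypes) <= 2,
                "dosages must lie in [0, 2]")
    assert_that(!anyNA(phenotypes), "phenotypes must be complete (no missing values)")
  }
  colnames(genotypes) <- snp_ids
  structure(list(n = nrow(genotypes), genotypes = genotypes,
                 phenotypes = as.data.frame(phenotypes),
                 snp_ids = as.character(snp_ids),
                 panels = panels, coded_alleles = coded_alleles,
                 .cache = new.env(parent = emptyenv())),
            class = "cohort")
}

# Per-column dosage sufficient statistics, computed once per cohort and
# cached: c1 = sum(g), c2 = #\{g = 2\} per SNP. For hard-called dosages these
# determine column means, variances and sums of squares without repeated
# passes over the genotype matrix.
dosage_suffstats <- function(x) {
  env <- x$.cache
  if (is.null(env$c1)) {
    G <- x$genotypes
    env$c1 <- colSums(G)
    env$c2 <- colSums(G * (G - 1)) / 2
  }
  list(c1 = env$c1, c2 = env$c2)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d participants, %d SNPs, phenotypes: %s\n",
              x$n, length(x$snp_ids),
              paste(names(x$phenotypes), collapse = ", ")))
  invisible(x)
}

#' Subset a cohort by participant index
#'
#' @param x a `cohort`.
#' @param i integer or logical participant index.
#' @return The subsetted `cohort`.
#' @export
cohort_subset <- function(x, i) {
  stopifnot(inherits(x, "cohort"))
  cohort(x$genotypes[i, , drop = FALSE], x$phenotypes[i, , drop = FALSE],
         x$snp_ids, x$panels, x$coded_alleles, validate = FALSE)
}

#' Define a weighted allele score
#'
#' @param snp_id SNP identifiers.
#' @param weight per-effect-allele weights (betas from an external discovery
#'   study); finite, at least one nonzero.
#' @param effect_allele optional allele each weight refers to; used to flip
#'   dosages coded on the opposite allele.
#' @param source_label provenance string.
#' @return Object of class `score_definition`.
#' @export
score_definition <- function(snp_id, weight, effect_allele = NULL,
                             source_label = "") {
  assert_that(all(is.finite(weight)), "weights must be finite")
  assert_that(any(weight != 0), "at least one weight must be nonzero")
  stopifnot(length(snp_id) == length(weight))
  structure(list(snp_id = as.character(snp_id), weight = as.numeric(weight),
                 effect_allele = effect_allele, source_label = source_label),
            class = "score_definition")
}

#' Build a weighted allele score for every participant
#'
#' `score_i = sum_k w_k * dosage_ik`, after orienting each dosage column to
#' the weight's effect allele (dosage becomes `2 - g` when the cohort codes
#' the opposite allele). Linear in the weights by construction.
#'
#' @param x a `cohort` containing every scored SNP.
#' @param def a `score_definition`.
#' @return Numeric vector of length `x$n`.
#' @export
build_allele_score <- function(x, def) {
  stopifnot(inherits(x, "cohort"), inherits(def, "score_definition"))
  idx <- match(def$snp_id, x$snp_ids)
  assert_that(!anyNA(idx), "SNPs missing from cohort: %s",
              paste(def$snp_id[is.na(idx)], collapse = ", "))
  G <- x$genotypes[, idx, drop = FALSE]
  if (!is.null(def$effect_allele) && !is.null(x$coded_alleles)) {
    coded <- x$coded_alleles[def$snp_id]
    flip <- !is.na(coded) & coded != def$effect_allele
    if (any(flip)) G[, flip] <- 2 - G[, flip]
  }
  drop(G %*% def$weight)
}

#' Adjust measured systolic blood pressure for antihypertensive treatment
#'
#' Participants on blood-pressure-lowering medication have 10 mm Hg added to
#' their measured systolic blood pressure, approximating the untreated
#' value.
#'
#' @param sbp measured systolic blood pressure in mm Hg (> 0).
#' @param on_medication logical/0-1 vector, recycled against `sbp`.
#' @param offset mm Hg added for treated participants (default 10).
#' @return Adjusted mm Hg vector, order preserved.
#' @export
adjust_sbp_for_medication <- function(sbp, on_medication, offset = 10) {
  assert_that(all(sbp > 0), "sbp must be positive mm Hg")
  sbp + offset * as.numeric(on_medication)
}

#' Default mapping from UK qualification categories to years of schooling
#'
#' ISCED-style conversion: university degree 20 years, NVQ/HND/HNC 19,
#' other professional qualification 15, A levels 13, GCSE/O levels 10,
#' CSEs 10, no formal qualifications 7.
#'
#' @return Named integer vector (qualification -> years).
#' @export
isced_years_table <- function() {
  c("college or university degree" = 20L,
    "nvq or hnd or hnc" = 19L,
    "other professional qualifications" = 15L,
    "a levels or as levels" = 13L,
    "o levels or gcses" = 10L,
    "cses" = 10L,
    "none of the above" = 7L)
}

#' Convert a qualification category to years of schooling
#'
#' @param qualification character vector of qualification labels
#'   (case-insensitive).
#' @param table named years table (default [isced_years_table()]).
#' @return Integer years of schooling; unknown categories are an error, not
#'   a silent default.
#' @export
map_qualifications_to_years <- function(qualification,
                                        table = isced_years_table()) {
  key <- tolower(trimws(qualification))
  idx <- match(key, names(table))
  assert_that(!anyNA(idx), "unknown qualification category: %s",
              paste(unique(qualification[is.na(idx)]), collapse = ", "))
  unname(table[idx])
}

#' Randomly split a cohort into two disjoint subsamples
#'
#' Disjoint, exhaustive partition, reproducible under `seed`; used for
#' split-sample allele-score weighting (weights estimated in one half,
#' scores analysed in the other) to avoid winner's-curse overlap.
#'
#' @param x a `cohort`.
#' @param fraction proportion assigned to the first half (0 < fraction < 1).
#' @param seed optional integer seed.
#' @return List of two `cohort` objects; participant indices are attached
#'   as `attr(., "index")`.
#' @export
split_sample <- function(x, fraction = 0.5, seed = NULL) {
  stopifnot(inherits(x, "cohort"))
  assert_that(fraction > 0 && fraction < 1, "fraction must be in (0, 1)")
  idx1 <- with_seed(seed, sort(sample.int(x$n, size = round(x$n * fraction))))
  idx2 <- setdiff(seq_len(x$n), idx1)
  halves <- list(cohort_subset(x, idx1), cohort_subset(x, idx2))
  attr(halves[[1]], "index") <- idx1
  attr(halves[[2]], "index") <- idx2
  halves
}
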