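# GWAS summary-statistic container, readers/writers and per-SD rescaling.

STANDARD_COLUMNS <- c(snp_id = "SNP", chrom = "CHR", pos = "BP",
                      effect_allele = "EA", other_allele = "OA",
                      eaf = "EAF", beta = "BETA", se = "SE",
                      pvalue = "P", n = "N")
MANDATORY_FIELDS <- c("snp_id", "effect_allele", "other_allele", "beta", "se")
VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct a GWAS summary-statistic set
#'
#' A `summary_set` holds one instrument panel (or full association table) for
#' one trait: one row per SNP with the estimated per-allele association
#' (`beta`, `se`), the effect/other alleles, and optional frequency, p-value
#' and sample size. It is the input unit of harmonisation, clumping and the
#' two-sample estimators.
#'
#' Rows violating the per-SNP invariants (identical alleles, non-positive
#' `se`, `pvalue` outside (0, 1], `eaf` outside \[0, 1\]) are removed and
#' recorded in `attr(x, "skipped")`; duplicate `snp_id`s are an error.
#'
#' @param data data.frame with columns `snp_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se` and optionally `chrom`, `pos`, `eaf`,
#'   `pvalue`, `n`. A missing `pvalue` column is filled from the Wald
#'   statistic `2*pnorm(-|beta/se|)`.
#' @param trait_name label for the measured trait.
#' @param trait_sd standard deviation of the trait in its native units, if
#'   known (used by [rescale_per_sd()]).
#' @param per_sd logical; `TRUE` once betas are on the per-SD-of-trait scale.
#' @return An object of class `summary_set`.
#' @export
summary_set <- function(data, trait_name, trait_sd = NA_real_, per_sd = FALSE) {
  assert_that(is.data.frame(data), "`data` must be a data.frame")
  for (f in MANDATORY_FIELDS) {
    assert_that(f %in% names(data), "mandatory column '%s' is missing", f)
  }
  d <- data.frame(
    snp_id = as.character(data$snp_id),
    chrom = if ("chrom" %in% names(data)) as.character(data$chrom) else NA_character_,
    pos = if ("pos" %in% names(data)) as.integer(data$pos) else NA_integer_,
    effect_allele = toupper(as.character(data$effect_allele)),
    other_allele = toupper(as.character(data$other_allele)),
    eaf = if ("eaf" %in% names(data)) as.numeric(data$eaf) else NA_real_,
    beta = as.numeric(data$beta),
    se = as.numeric(data$se),
    pvalue = if ("pvalue" %in% names(data)) as.numeric(data$pvalue) else NA_real_,
    n = if ("n" %in% names(data)) as.numeric(data$n) else NA_real_,
    stringsAsFactors = FALSE
  )
  miss_p <- is.na(d$pvalue) & !is.na(d$beta) & !is.na(d$se) & d$se > 0
  d$pvalue[miss_p] <- pmax(two_sided_p(d$beta[miss_p] / d$se[miss_p]),
                           .Machine$double.xmin)

  reason <- rep(NA_character_, nrow(d))
  bad <- function(cond, why) reason[is.na(reason) & cond] <<- why
  bad(is.na(d$snp_id) | d$snp_id == "", "missing_snp_id")
  bad(!(d$effect_allele %in% VALID_ALLELES) |
        !(d$other_allele %in% VALID_ALLELES), "invalid_allele")
  bad(d$effect_allele == d$other_allele, "identical_alleles")
  bad(!is.finite(d$beta), "missing_beta")
  bad(!is.finite(d$se) | d$se <= 0, "nonpositive_se")
  bad(!is.na(d$pvalue) & (d$pvalue <= 0 | d$pvalue > 1), "pvalue_out_of_range")
  bad(!is.na(d$eaf) & (d$eaf < 0 | d$eaf > 1), "eaf_out_of_range")

  skipped <- data.frame(snp_id = d$snp_id[!is.na(reason)],
                        reason = reason[!is.na(reason)],
                        stringsAsFactors = FALSE)
  d <- d[is.na(reason), , drop = FALSE]
  dup <- duplicated(d$snp_id)
  assert_that(!any(dup), "duplicate snp_id in summary set: %s",
              paste(unique(d$snp_id[dup]), collapse = ", "))
  rownames(d) <- NULL

  structure(
    list(trait_name = as.character(trait_name),
         trait_sd = as.numeric(trait_sd),
         per_sd = isTRUE(per_sd),
         data = d),
    skipped = skipped,
    class = "summary_set"
  )
}

#' @export
print.summary_set <- function(x, ...) {
  cat(sprintf("<summary_set> trait '%s': %d SNPs%s%s\n",
              x$trait_name, nrow(x$data),
              if (x$per_sd) " (per-SD units)" else "",
              if (is.finite(x$trait_sd)) sprintf(", trait SD %.4g", x$trait_sd) else ""))
  invisible(x)
}

#' @export
length.summary_set <- function(x) nrow(x$data)

#' Restrict a summary set to a set of SNP identifiers
#'
#' @param x a `summary_set`.
#' @param snp_ids character vector of identifiers to keep.
#' @param require_all error if any identifier is absent (default `FALSE`).
#' @return A `summary_set` with the matching rows, in `snp_ids` order.
#' @export
subset_snps <- function(x, snp_ids, require_all = FALSE) {
  stopifnot(inherits(x, "summary_set"))
  idx <- match(snp_ids, x$data$snp_id)
  if (require_all && anyNA(idx)) {
    stop_f("SNPs absent from '%s': %s", x$trait_name,
           paste(snp_ids[is.na(idx)], collapse = ", "))
  }
  x$data <- x$data[idx[!is.na(idx)], , drop = FALSE]
  rownames(x$data) <- NULL
  x
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Expects a header row. The standard layout is tab-delimited with columns
#' `SNP CHR BP EA OA EAF BETA SE P N` and `NA` for missing values; arbitrary
#' column names are supported through `column_map`.
#'
#' Rows failing the per-SNP invariants are skipped (not an error) and are
#' available with their reasons in `attr(result, "skipped")`.
#'
#' @param path file path.
#' @param trait_name trait label for the resulting set.
#' @param column_map named character vector mapping standard field names
#'   (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to the file's column names. Defaults to the
#'   standard layout.
#' @param sep field separator (default tab).
#' @param trait_sd,per_sd passed to [summary_set()].
#' @return A `summary_set`.
#' @export
read_summary_stats <- function(path, trait_name, column_map = NULL, sep = "\t",
                               trait_sd = NA_real_, per_sd = FALSE) {
  map <- STANDARD_COLUMNS
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = "NA",
                           check.names = FALSE, comment.char = "")
  for (f in MANDATORY_FIELDS) {
    assert_that(map[[f]] %in% names(raw),
                "mandatory column '%s' (mapped from field '%s') not found in %s",
                map[[f]], f, path)
  }
  present <- names(map)[map %in% names(raw)]
  d <- stats::setNames(raw[, map[present], drop = FALSE], present)
  summary_set(d, trait_name = trait_name, trait_sd = trait_sd, per_sd = per_sd)
}

#' Write a summary set to the standard tab-delimited layout
#'
#' Columns `SNP CHR BP EA OA EAF BETA SE P N`, missing values as `NA`,
#' numeric fields at full precision (round-trips bit-for-bit through
#' [read_summary_stats()] for finite values).
#'
#' @param x a `summary_set` (may be empty: a header-only file is written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_set"))
  d <- x$data
  out <- data.frame(SNP = d$snp_id, CHR = d$chrom, BP = d$pos,
                    EA = d$effect_allele, OA = d$other_allele,
                    EAF = format_full(d$eaf), BETA = format_full(d$beta),
                    SE = format_full(d$se), P = format_full(d$pvalue),
                    N = format_full(d$n), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

format_full <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) NA_character_ else format(v, digits = 17, scientific = TRUE)
  }, character(1))
  out
}

#' Rescale per-allele effects to per-SD-of-trait units
#'
#' Multiplies every `beta` and `se` by the trait's standard deviation so that
#' downstream causal estimates are expressed per SD of the exposure (e.g.
#' education effects per 3.6 years). Guarded by the set's unit flag: a set
#' already on the per-SD scale cannot be rescaled again.
#'
#' @param x a `summary_set` in native trait units.
#' @param sd positive trait standard deviation.
#' @param force apply the scaling even if the set is already flagged per-SD
#'   (e.g. to undo a scaling with `1/sd`).
#' @return The rescaled `summary_set` with `per_sd = TRUE` and `trait_sd`
#'   recorded.
#' @export
rescale_per_sd <- function(x, sd, force = FALSE) {
  stopifnot(inherits(x, "summary_set"))
  assert_that(is_number(sd) && sd > 0, "`sd` must be a positive number")
  assert_that(!x$per_sd || force,
              "set '%s' is already on the per-SD scale", x$trait_name)
  x$data$beta <- x$data$beta * sd
  x$data$se <- x$data$se * sd
  x$trait_sd <- sd
  x$per_sd <- TRUE
  x
}
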