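# Allele harmonisation of exposure and outcome summary statistics.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonise exposure and outcome summary statistics to a common effect allele
#'
#' For each SNP shared between the two sets, reorients the outcome
#' association so it refers to the exposure's effect allele:
#' * identical allele pairs are copied;
#' * swapped pairs have the outcome beta negated and `eaf` complemented;
#' * non-palindromic pairs matching after strand complementation are aligned
#'   the same way;
#' * palindromic pairs (A/T or G/C) are strand-ambiguous and handled by
#'   `palindrome_policy`;
#' * irreconcilable allele pairs are dropped with a recorded reason.
#'
#' Palindrome policies: `"drop_ambiguous"` (default) drops palindromic SNPs
#' whose effect-allele frequency in either study is missing or within
#' `eaf_ambiguity_window` of 0.5, keeps the literal alignment when both
#' frequencies fall on the same side of 0.5, and drops on frequency
#' disagreement; `"infer_by_eaf"` instead strand-flips on disagreement
#' (still dropping the ambiguous/missing cases); `"keep"` trusts the literal
#' allele letters for all SNPs.
#'
#' Harmonisation never changes `|beta|` of a retained SNP; only signs and
#' frequency complements change.
#'
#' @param exposure,outcome `summary_set` objects with a nonempty `snp_id`
#'   intersection.
#' @param palindrome_policy one of `"drop_ambiguous"`, `"infer_by_eaf"`,
#'   `"keep"`.
#' @param eaf_ambiguity_window half-width around eaf 0.5 within which a
#'   palindromic SNP's strand is considered unidentifiable (default 0.08,
#'   i.e. drop when `min(eaf, 1-eaf) > 0.42`).
#' @return An object of class `harmonised_set`: list with `exposure_name`,
#'   `outcome_name`, `rows` (data.frame `snp_id, bx, sx, by, sy, eaf`) and
#'   `dropped` (data.frame `snp_id, reason`).
#' @export
harmonise <- function(exposure, outcome,
                      palindrome_policy = c("drop_ambiguous", "infer_by_eaf", "keep"),
                      eaf_ambiguity_window = 0.08) {
  stopifnot(inherits(exposure, "summary_set"), inherits(outcome, "summary_set"))
  palindrome_policy <- match.arg(palindrome_policy)
  ex <- exposure$data
  ou <- outcome$data
  shared <- intersect(ex$snp_id, ou$snp_id)
  assert_that(length(shared) > 0,
              "no shared SNPs between '%s' and '%s'",
              exposure$trait_name, outcome$trait_name)
  ex <- ex[match(shared, ex$snp_id), ]
  ou <- ou[match(shared, ou$snp_id), ]

  n <- length(shared)
  by <- ou$beta; oeaf <- ou$eaf
  keep <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  ambiguous_window <- 0.5 - eaf_ambiguity_window

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    pal <- is_palindromic(ea_x, oa_x)

    same    <- ea_y == ea_x && oa_y == oa_x
    swapped <- ea_y == oa_x && oa_y == ea_x
    csame   <- COMPLEMENT[ea_y] == ea_x && COMPLEMENT[oa_y] == oa_x
    cswap   <- COMPLEMENT[ea_y] == oa_x && COMPLEMENT[oa_y] == ea_x

    if (!pal) {
      if (same) {
        # aligned, nothing to do
      } else if (swapped) {
        by[i] <- -by[i]; oeaf[i] <- 1 - oeaf[i]
      } else if (csame) {
        # reported on the opposite strand, same orientation
      } else if (cswap) {
        by[i] <- -by[i]; oeaf[i] <- 1 - oeaf[i]
      } else {
        keep[i] <- FALSE; reason[i] <- "allele_mismatch"
      }
      next
    }

    # palindromic: letters cannot identify the strand
    if (!(same || swapped)) {
      keep[i] <- FALSE; reason[i] <- "allele_mismatch"
      next
    }
    if (swapped) { by[i] <- -by[i]; oeaf[i] <- 1 - oeaf[i] }
    if (palindrome_policy == "keep") next

    fx <- ex$eaf[i]; fy <- oeaf[i]
    ambiguous <- is.na(fx) || is.na(fy) ||
      min(fx, 1 - fx) > ambiguous_window || min(fy, 1 - fy) > ambiguous_window
    if (ambiguous) {
      keep[i] <- FALSE; reason[i] <- "palindromic_ambiguous"
      next
    }
    agree <- (fx < 0.5) == (fy < 0.5)
    if (!agree) {
      if (palindrome_policy == "infer_by_eaf") {
        by[i] <- -by[i]; oeaf[i] <- 1 - oeaf[i]
      } else {
        keep[i] <- FALSE; reason[i] <- "palindromic_eaf_mismatch"
      }
    }
  }

  rows <- data.frame(snp_id = shared[keep],
                     bx = ex$beta[keep], sx = ex$se[keep],
                     by = by[keep], sy = ou$se[keep],
                     eaf = ex$eaf[keep],
                     stringsAsFactors = FALSE)
  rownames(rows) <- NULL
  dropped <- data.frame(snp_id = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  structure(list(exposure_name = exposure$trait_name,
                 outcome_name = outcome$trait_name,
                 rows = rows, dropped = dropped),
            class = "harmonised_set")
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("<harmonised_set> %s -> %s: %d SNPs retained, %d dropped\n",
              x$exposure_name, x$outcome_name, nrow(x$rows), nrow(x$dropped)))
  invisible(x)
}

#' Build a harmonised set directly from aligned effect vectors
#'
#' Convenience constructor for simulated or already-aligned inputs.
#'
#' @param bx,sx exposure betas and standard errors.
#' @param by,sy outcome betas and standard errors.
#' @param snp_id optional identifiers (default `snp1..snpk`).
#' @param eaf optional effect-allele frequencies.
#' @param exposure_name,outcome_name labels.
#' @return A `harmonised_set`.
#' @export
harmonised_set <- function(bx, sx, by, sy, snp_id = NULL, eaf = NA_real_,
                           exposure_name = "exposure", outcome_name = "outcome") {
  k <- length(bx)
  stopifnot(length(sx) == k, length(by) == k, length(sy) == k)
  assert_that(all(sx > 0) && all(sy > 0), "standard errors must be positive")
  structure(list(
    exposure_name = exposure_name, outcome_name = outcome_name,
    rows = data.frame(snp_id = snp_id %||% paste0("snp", seq_len(k)),
                      bx = bx, sx = sx, by = by, sy = sy, eaf = eaf,
                      stringsAsFactors = FALSE),
    dropped = data.frame(snp_id = character(), reason = character(),
                         stringsAsFactors = FALSE)),
    class = "harmonised_set")
}
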