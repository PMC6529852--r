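# Greedy LD clumping of summary statistics.

#' Construct an LD matrix object
#'
#' Squared-correlation (r²) matrix between SNPs plus their genomic
#' positions, as needed by [clump()].
#'
#' @param r2 symmetric numeric matrix of squared correlations in \[0, 1\]
#'   with unit diagonal; dimnames may carry the SNP ids.
#' @param snp_ids SNP identifiers in matrix order (defaults to rownames).
#' @param chrom,pos chromosome labels and 1-based positions aligned to
#'   `snp_ids`.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r2, snp_ids = rownames(r2), chrom, pos) {
  r2 <- as.matrix(r2)
  assert_that(!is.null(snp_ids), "snp_ids required (or rownames on r2)")
  assert_that(nrow(r2) == ncol(r2) && nrow(r2) == length(snp_ids),
              "r2 must be square and match snp_ids")
  assert_that(max(abs(r2 - t(r2))) < 1e-8, "r2 matrix must be symmetric")
  assert_that(all(abs(diag(r2) - 1) < 1e-8), "r2 diagonal must be 1")
  assert_that(all(r2 >= -1e-12 & r2 <= 1 + 1e-12), "r2 values must lie in [0,1]")
  stopifnot(length(chrom) == length(snp_ids), length(pos) == length(snp_ids))
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = as.character(snp_ids), r2 = r2,
                 chrom = stats::setNames(as.character(chrom), snp_ids),
                 pos = stats::setNames(as.numeric(pos), snp_ids)),
            class = "ld_matrix")
}

#' Read an LD matrix and companion positions file
#'
#' The matrix file is a square tab-delimited table with the SNP ids as
#' header row and first column; the positions file has columns `SNP CHR BP`.
#'
#' @param matrix_path path to the r² matrix file.
#' @param positions_path path to the positions file.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(matrix_path, positions_path) {
  m <- utils::read.table(matrix_path, header = TRUE, sep = "\t",
                         row.names = 1, check.names = FALSE)
  p <- utils::read.table(positions_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  for (col in c("SNP", "CHR", "BP")) {
    assert_that(col %in% names(p), "positions file lacks column '%s'", col)
  }
  idx <- match(rownames(m), p$SNP)
  assert_that(!anyNA(idx), "positions missing for: %s",
              paste(setdiff(rownames(m), p$SNP), collapse = ", "))
  ld_matrix(as.matrix(m), rownames(m), p$CHR[idx], p$BP[idx])
}

#' Greedy LD clumping by p-value
#'
#' Selects an approximately independent instrument panel: SNPs are ranked by
#' ascending p-value (ties broken by larger `|beta/se|`, then by `snp_id`);
#' the best remaining SNP is accepted and every remaining SNP on the same
#' chromosome within `window_kb` kilobases whose r² with it exceeds
#' `r2_threshold` is discarded, until no SNPs remain. The returned panel
#' therefore contains no pair violating the (r², window) constraint.
#'
#' The two regimes used for instrument construction in this field — a
#' lenient pairwise `r2 < 0.1` panel and a strict `r2 < 0.001`,
#' `window_kb = 10000` panel — are both reachable via the parameters.
#'
#' @param x a `summary_set`; every SNP must be present in `ld`.
#' @param ld an [ld_matrix()].
#' @param r2_threshold maximum tolerated squared correlation (default 0.001).
#' @param window_kb distance in kb within which the r² constraint applies
#'   (default 10000); SNPs on different chromosomes are never compared.
#' @return The clumped `summary_set`, ordered by the selection rank.
#' @export
clump <- function(x, ld, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(x, "summary_set"), inherits(ld, "ld_matrix"))
  d <- x$data
  missing <- setdiff(d$snp_id, ld$snp_ids)
  assert_that(length(missing) == 0, "SNPs absent from LD matrix: %s",
              paste(missing, collapse = ", "))
  ord <- order(d$pvalue, -abs(d$beta / d$se), d$snp_id)
  ids <- d$snp_id[ord]
  chrom <- ld$chrom[ids]
  pos <- ld$pos[ids]

  alive <- rep(TRUE, length(ids))
  accepted <- character(0)
  for (i in seq_along(ids)) {
    if (!alive[i]) next
    accepted <- c(accepted, ids[i])
    if (i == length(ids)) break
    later <- which(alive & seq_along(ids) > i)
    if (!length(later)) next
    same_chr <- chrom[later] == chrom[i]
    near <- abs(pos[later] - pos[i]) / 1000 <= window_kb
    hi_r2 <- ld$r2[ids[i], ids[later]] > r2_threshold
    alive[later[same_chr & near & hi_r2]] <- FALSE
  }
  subset_snps(x, accepted, require_all = TRUE)
}
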