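# Internal helpers shared across estimators.

# 95% Wald interval multiplier used throughout (Normal, not t).
Z95 <- 1.959964

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
two_sided_p <- function(z) 2 * stats::pnorm(-abs(z))

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so package functions never disturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

stop_f <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(ok, fmt, ...) if (!ok) stop_f(fmt, ...)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Format a log odds ratio estimate as an odds ratio with 95% CI
#'
#' Renders `exp(beta)` and its Wald interval in the conventional
#' `"0.63 (0.60 to 0.67)"` display style used in epidemiological reports.
#'
#' @param beta log odds ratio.
#' @param se its standard error.
#' @param digits decimal places (default 2).
#' @return A single character string.
#' @export
#' @examples
#' format_or_ci(-0.462, 0.0283)
format_or_ci <- function(beta, se, digits = 2) {
  sprintf(paste0("%.", digits, "f (%.", digits, "f to %.", digits, "f)"),
          exp(beta), exp(beta - Z95 * se), exp(beta + Z95 * se))
}

#' Format a proportion mediated as a percentage with 95% CI
#'
#' @param p point estimate of the proportion (not percent).
#' @param ci_low,ci_high interval bounds on the proportion scale.
#' @return A string such as `"18% (14% to 23%)"`.
#' @export
format_pct_ci <- function(p, ci_low, ci_high) {
  sprintf("%.0f%% (%.0f%% to %.0f%%)", 100 * p, 100 * ci_low, 100 * ci_high)
}

#' Recover a log odds ratio from a rendered odds ratio string
#'
#' Inverse of [format_or_ci()] to 3 decimals: parses `"OR (lo to hi)"` and
#' returns the implied beta and se.
#'
#' @param s string produced by [format_or_ci()].
#' @return list with `beta` and `se`.
#' @export
parse_or_ci <- function(s) {
  m <- regmatches(s, regexec("^([0-9.]+) \\(([0-9.]+) to ([0-9.]+)\\)$", s))[[1]]
  assert_that(length(m) == 4L, "cannot parse odds-ratio string '%s'", s)
  v <- as.numeric(m[2:4])
  list(beta = log(v[1]), se = (log(v[3]) - log(v[2])) / (2 * Z95))
}
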