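#' Standard error of a log odds ratio from its confidence interval
#'
#' Inverts the conventional `OR (low-high)` reporting format: on the log
#' scale the interval is symmetric around the point estimate, so
#' `se = (log(ci_high) - log(ci_low)) / (2 * z)` with `z` the two-sided
#' normal quantile for the interval level.
#'
#' @param ci_low,ci_high Positive odds-ratio interval bounds, `ci_low < ci_high`.
#' @param level Interval coverage, default `0.95`.
#' @return Standard error of the log odds ratio (scalar or vector).
#' @examples
#' se_from_ci(1.12, 1.29)
#' @export
se_from_ci <- function(ci_low, ci_high, level = 0.95) {
  stop_if_not(all(ci_low > 0) && all(ci_high > 0), "CI bounds must be positive")
  stop_if_not(all(ci_low < ci_high), "ci_low must be < ci_high")
  stop_if_not(level > 0 && level < 1, "level must be in (0,1)")
  z <- stats::qnorm((1 + level) / 2)
  (log(ci_high) - log(ci_low)) / (2 * z)
}

#' Confidence interval for a log odds ratio
#'
#' Companion to [se_from_ci()]: returns the odds-ratio scale interval
#' `exp(beta +/- z * se)`.
#'
#' @param beta Log odds ratio.
#' @param se Standard error of `beta`.
#' @param level Interval coverage.
#' @return Named vector `c(ci_low, ci_high)` (or two-column matrix).
#' @export
ci_from_beta <- function(beta, se, level = 0.95) {
  z <- stats::qnorm((1 + level) / 2)
  cbind(ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Combines per-study log odds ratios by classical fixed-effect
#' inverse-variance weighting (the `STDERR` scheme of standard GWAS
#' meta-analysis tools): `beta = sum(b_i/se_i^2) / sum(1/se_i^2)`,
#' `se = sqrt(1/sum(1/se_i^2))`. Cochran's Q is computed for logging only.
#'
#' @param beta Numeric vector of study log odds ratios.
#' @param se Numeric vector of their standard errors (all `> 0`).
#' @param labels Optional study labels.
#' @param level Confidence level for the combined interval.
#' @return An object of class `meta_result`: list with `beta`, `se`,
#'   `or_point`, `ci_low`, `ci_high`, `z`, `p`, `q`, `q_df`, `n_studies`.
#' @examples
#' ivw_fixed_meta(beta = log(c(1.20, 1.42)),
#'                se = se_from_ci(c(1.12, 1.21), c(1.29, 1.65)))
#' @export
ivw_fixed_meta <- function(beta, se, labels = NULL, level = 0.95) {
  stop_if_not(length(beta) >= 1, "at least one study required")
  stop_if_not(length(beta) == length(se), "beta and se lengths differ")
  stop_if_not(all(is.finite(beta)) && all(is.finite(se)) && all(se > 0),
              "all se must be finite and > 0")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- sqrt(1 / sum(w))
  z <- b / s
  ci <- ci_from_beta(b, s, level)
  q <- sum(w * (beta - b)^2)
  structure(list(beta = b, se = s, or_point = exp(b),
                 ci_low = unname(ci[1, "ci_low"]), ci_high = unname(ci[1, "ci_high"]),
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 q = q, q_df = length(beta) - 1L,
                 n_studies = length(beta), labels = labels, level = level),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, digits = 3, ...) {
  cat(sprintf("Fixed-effect IVW meta-analysis of %d studies\n", x$n_studies))
  cat(sprintf("  OR %.*f (%.*f-%.*f), z = %.2f, p = %.3g\n",
              digits, x$or_point, digits, x$ci_low, digits, x$ci_high, x$z, x$p))
  cat(sprintf("  Cochran's Q = %.2f on %d df\n", x$q, x$q_df))
  invisible(x)
}

#' Crude allelic odds ratio from minor-allele frequencies
#'
#' Reconstructs the 2x2 allele-count table from case/control minor-allele
#' frequencies and sample sizes (allele counts `2*n*maf`, rounded half-up to
#' integers since published MAFs are printed to limited precision), then
#' returns the allelic odds ratio with a Woolf standard error
#' (`sqrt(sum(1/cell))`) and normal-theory interval on the log scale.
#' Any empty cell triggers the Haldane-Anscombe 0.5 continuity correction
#' and sets `corrected = TRUE`.
#'
#' @param maf_case,maf_control Minor-allele frequencies in `(0,1)`.
#' @param n_case,n_control Subject counts (`> 0`).
#' @param level Confidence level.
#' @return List with `or`, `beta`, `se`, `ci_low`, `ci_high`, `table`
#'   (the 2x2 allele counts), and `corrected`.
#' @examples
#' allelic_or_from_maf(0.14, 0.10, 2497, 4611)
#' @export
allelic_or_from_maf <- function(maf_case, maf_control, n_case, n_control,
                                level = 0.95) {
  stop_if_not(maf_case > 0 && maf_case < 1 && maf_control > 0 && maf_control < 1,
              "frequencies must be in (0,1)")
  stop_if_not(n_case > 0 && n_control > 0, "sample sizes must be positive")
  a <- round(2 * n_case * maf_case)        # case minor alleles
  b <- 2 * n_case - a                      # case major alleles
  c_ <- round(2 * n_control * maf_control) # control minor alleles
  d <- 2 * n_control - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("case", "control"), c("minor", "major")))
  corrected <- any(tab == 0)
  if (corrected) tab <- tab + 0.5
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  se <- sqrt(sum(1 / tab))
  ci <- ci_from_beta(log(or), se, level)
  list(or = or, beta = log(or), se = se,
       ci_low = unname(ci[1, "ci_low"]), ci_high = unname(ci[1, "ci_high"]),
       table = tab, corrected = corrected)
}

#' Meta-analyse a study summary table
#'
#' Convenience wrapper: takes a data frame in the package's study-table
#' format (columns `label`, `or`, `ci_low`, `ci_high`, optionally `p`,
#' `n_case`, `n_control`, `maf_case`, `maf_control`), converts ORs and
#' intervals to log-odds and standard errors, and runs [ivw_fixed_meta()].
#'
#' @param studies Data frame of study summaries.
#' @param use Optional character vector of `label`s to include.
#' @return A `meta_result`.
#' @export
meta_analyse_studies <- function(studies, use = NULL) {
  need <- c("label", "or", "ci_low", "ci_high")
  miss <- setdiff(need, names(studies))
  stop_if_not(length(miss) == 0,
              paste("study table missing columns:", paste(miss, collapse = ", ")))
  if (!is.null(use)) studies <- studies[studies$label %in% use, , drop = FALSE]
  stop_if_not(nrow(studies) >= 1, "no studies selected")
  ivw_fixed_meta(beta = log(studies$or),
                 se = se_from_ci(studies$ci_low, studies$ci_high),
                 labels = studies$label)
}
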