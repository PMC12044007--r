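#' Fit a qPCR standard curve
#'
#' Least-squares fit of Ct against `log10(quantity)`. The amplification
#' efficiency is `E = 10^(-1/slope) - 1`, so a slope of `-3.3219` Ct per
#' decade corresponds to perfect doubling (`E = 1`). A non-negative slope
#' flags the curve as invalid rather than erroring, since downstream
#' quantification must refuse it explicitly.
#'
#' @param quantities Positive input quantities (>= 3 distinct values).
#' @param cts Observed Ct values, same length.
#' @return Object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `efficiency`, `valid`.
#' @export
fit_standard_curve <- function(quantities, cts) {
  stop_if_not(length(quantities) == length(cts), "lengths differ")
  stop_if_not(all(quantities > 0), "quantities must be positive")
  stop_if_not(length(unique(quantities)) >= 3, "need >= 3 distinct quantities")
  x <- log10(quantities)
  fit <- stats::lm(cts ~ x)
  slope <- unname(stats::coef(fit)[2])
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 efficiency = 10^(-1 / slope) - 1,
                 valid = slope < 0),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve: slope %.4f, intercept %.2f, R^2 %.4f, E = %.3f%s\n",
              x$slope, x$intercept, x$r_squared, x$efficiency,
              if (x$valid) "" else "  [INVALID: non-negative slope]"))
  invisible(x)
}

#' Percent input from ChIP-qPCR Ct values via a standard curve
#'
#' Quantities are interpolated from the curve
#' (`q = 10^((ct - intercept)/slope)`), and the immunoprecipitated
#' quantity is expressed as a percentage of the input quantity after
#' correcting the input for the fraction of chromatin it represents.
#'
#' @param ct_ip Ct value(s) of the IP sample.
#' @param ct_input Ct value(s) of the input sample.
#' @param curve A valid [fit_standard_curve()] object.
#' @param input_dilution_factor Factor by which the input underrepresents
#'   the IP chromatin (e.g. a 1% input has factor 100); default 1.
#' @return Percent input values.
#' @export
percent_input <- function(ct_ip, ct_input, curve, input_dilution_factor = 1) {
  stop_if_not(inherits(curve, "standard_curve") && curve$valid,
              "a valid standard curve is required")
  q <- function(ct) 10^((ct - curve$intercept) / curve$slope)
  100 * q(ct_ip) / (q(ct_input) * input_dilution_factor)
}

#' Allelic enrichment of ChIP DNA relative to input
#'
#' Compares per-replicate A/G (or any allele-pair) signal ratios between
#' immunoprecipitated and input DNA: enrichment is the ratio of the mean
#' IP ratio to the mean input ratio, and significance is an unpaired
#' two-tailed t-test of the per-replicate ratios. Mean-of-ratios is used
#' because the significance test operates on per-replicate ratios.
#'
#' @param ip_ratios,input_ratios Positive per-replicate allele ratios
#'   (>= 2 each).
#' @return List with `enrichment`, `ratio_ip`, `ratio_input`, `p`.
#' @export
allelic_enrichment <- function(ip_ratios, input_ratios) {
  stop_if_not(all(ip_ratios > 0) && all(input_ratios > 0),
              "allele ratios must be positive")
  stop_if_not(length(ip_ratios) >= 2 && length(input_ratios) >= 2,
              "need >= 2 replicates per group")
  p <- two_group_t(ip_ratios, input_ratios)
  list(enrichment = mean(ip_ratios) / mean(input_ratios),
       ratio_ip = mean(ip_ratios), ratio_input = mean(input_ratios), p = p)
}

#' Luciferase fold change over the empty vector, with allele comparison
#'
#' Normalizes each well's firefly signal by its Renilla co-transfection
#' control and reports fold change relative to the mean empty-vector
#' F/R ratio. When two allele groups are given, an unpaired two-tailed
#' t-test compares their fold values.
#'
#' @param firefly,renilla Per-well construct signals (`renilla > 0`).
#' @param ev_firefly,ev_renilla Per-well empty-vector signals.
#' @param group Optional factor/character splitting construct wells into
#'   two allele groups for the comparison test.
#' @return List with `fold` (per well), `fold_by_group` (means, when
#'   grouped), `p_allele` (when grouped).
#' @export
luciferase_fold <- function(firefly, renilla, ev_firefly, ev_renilla,
                            group = NULL) {
  stop_if_not(all(renilla > 0) && all(ev_renilla > 0), "zero Renilla signal")
  ev_fr <- mean(ev_firefly / ev_renilla)
  fold <- (firefly / renilla) / ev_fr
  out <- list(fold = fold)
  if (!is.null(group)) {
    g <- as.factor(group)
    stop_if_not(nlevels(g) == 2, "group must have exactly 2 levels")
    a <- fold[g == levels(g)[1]]
    b <- fold[g == levels(g)[2]]
    out$fold_by_group <- stats::setNames(c(mean(a), mean(b)), levels(g))
    out$p_allele <- stats::t.test(a, b, var.equal = TRUE)$p.value
  }
  out
}

#' Normalize a growth time series to its first timepoint
#'
#' @param counts Cell counts over time; `counts[1]` (the 0-h count) must
#'   be positive.
#' @return Fold changes relative to the first timepoint.
#' @export
growth_normalize <- function(counts) {
  stop_if_not(length(counts) >= 1 && counts[1] > 0,
              "count at the first timepoint must be positive")
  counts / counts[1]
}
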