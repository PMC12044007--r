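#' Per-protein spectral-count enrichment of bait over control
#'
#' Implements the pseudo-count spectral enrichment scheme: a pseudo count
#' of 1 is added to every PSM count, the per-condition medians of the +1
#' counts are taken, and the fold change is the ratio of bait to control
#' medians. The p-value is an unpaired, two-tailed, equal-variance t-test
#' on the +1 counts (no log transform). Proteins whose +1 counts are
#' constant and identical across both conditions get `p = 1`.
#'
#' @param psm Proteins x samples integer matrix of PSM counts.
#' @param conditions Named character vector mapping each sample (column)
#'   to `"bait"` or `"control"`.
#' @return Data frame `protein_id, fc, p, median_bait, median_control`.
#' @export
psm_enrichment <- function(psm, conditions) {
  stop_if_not(all(colnames(psm) %in% names(conditions)),
              "every sample column must be mapped to a condition")
  cond <- conditions[colnames(psm)]
  stop_if_not(all(cond %in% c("bait", "control")),
              "conditions must be 'bait' or 'control'")
  bait <- psm[, cond == "bait", drop = FALSE] + 1
  ctrl <- psm[, cond == "control", drop = FALSE] + 1
  stop_if_not(ncol(bait) >= 2 && ncol(ctrl) >= 2,
              "need >= 2 samples per condition")
  mb <- apply(bait, 1, stats::median)
  mc <- apply(ctrl, 1, stats::median)
  p <- vapply(seq_len(nrow(psm)), function(i) {
    x <- bait[i, ]; y <- ctrl[i, ]
    two_group_t(x, y)
  }, numeric(1))
  data.frame(protein_id = rownames(psm) %||% as.character(seq_len(nrow(psm))),
             fc = mb / mc, p = p, median_bait = mb, median_control = mc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Significance and fold-change filter on enrichment calls
#'
#' Keeps proteins significantly enriched (`p < p_max`) with fold change
#' strictly above `fc_min` (both strict, so a protein at exactly 1.5-fold
#' is excluded).
#'
#' @param calls Data frame from [psm_enrichment()].
#' @param fc_min Minimum fold change, strict (default 1.5).
#' @param p_max Maximum p-value, strict (default 0.05).
#' @return Character vector of passing protein ids, ordered by descending
#'   fold change.
#' @export
enrichment_filter <- function(calls, fc_min = 1.5, p_max = 0.05) {
  keep <- calls[calls$p < p_max & calls$fc > fc_min, , drop = FALSE]
  keep$protein_id[order(-keep$fc)]
}

#' Intersection with an independent pilot enrichment list
#'
#' @param primary Character vector of enriched proteins, in ranking order.
#' @param pilot Character vector from the pilot experiment.
#' @return The intersection, keeping `primary`'s order.
#' @export
pilot_overlap <- function(primary, pilot) {
  primary[primary %in% pilot]
}

#' Dose-dependent-decrease filter on candidate substrates
#'
#' Fits, per protein, a least-squares line of mean abundance per dose
#' against `log10(dose)` and calls a dose-dependent decrease when the
#' slope is negative with one-sided `p < p_max`. An endpoint test
#' (lowest- vs highest-dose replicates, unpaired two-tailed t) is also
#' reported; the trend test gates the verdict.
#'
#' @param dose_table Long data frame `protein_id, dose, replicate,
#'   abundance` with at least 3 distinct doses.
#' @param candidates Protein ids to test (must be present in the table).
#' @param p_max One-sided significance threshold (default 0.05).
#' @return Data frame `protein_id, dose_slope, p_dose, p_endpoint,
#'   passed_dose`.
#' @export
dose_decrease_filter <- function(dose_table, candidates, p_max = 0.05) {
  doses <- sort(unique(dose_table$dose))
  stop_if_not(length(doses) >= 3, "need >= 3 distinct doses for trend testing")
  miss <- setdiff(candidates, unique(dose_table$protein_id))
  stop_if_not(length(miss) == 0,
              paste("candidates absent from dose table:", paste(miss, collapse = ", ")))
  rows <- lapply(candidates, function(id) {
    sub <- dose_table[dose_table$protein_id == id, , drop = FALSE]
    means <- tapply(sub$abundance, sub$dose, mean)
    x <- log10(as.numeric(names(means)))
    fit <- stats::lm(as.numeric(means) ~ x)
    cf <- summary(fit)$coefficients
    slope <- cf["x", "Estimate"]
    # one-sided p for slope < 0
    p_one <- stats::pt(cf["x", "t value"], df = fit$df.residual)
    lo <- sub$abundance[sub$dose == doses[1]]
    hi <- sub$abundance[sub$dose == doses[length(doses)]]
    p_end <- if (length(lo) >= 2 && length(hi) >= 2 && stats::var(c(lo, hi)) > 0) {
      stats::t.test(lo, hi, var.equal = TRUE)$p.value
    } else NA_real_
    data.frame(protein_id = id, dose_slope = slope, p_dose = p_one,
               p_endpoint = p_end,
               passed_dose = slope < 0 && p_one < p_max,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Full substrate-triage funnel
#'
#' Chains spectral-count enrichment, the significance/fold-change filter,
#' the pilot-list intersection, and the dose-dependent-decrease filter
#' into per-protein substrate calls. Every protein in the PSM table gets a
#' row; `final_candidate` implies all upstream flags.
#'
#' @param psm,conditions As in [psm_enrichment()].
#' @param dose_table As in [dose_decrease_filter()].
#' @param pilot Pilot enrichment list; `NULL` skips the overlap stage
#'   (all enriched proteins move forward).
#' @param fc_min,p_max Enrichment filter thresholds.
#' @return Data frame of substrate calls: `protein_id, fc_enrichment,
#'   p_enrichment, passed_enrichment, in_pilot_overlap, dose_slope,
#'   p_dose, passed_dose, final_candidate`.
#' @export
substrate_triage <- function(psm, conditions, dose_table, pilot = NULL,
                             fc_min = 1.5, p_max = 0.05) {
  enr <- psm_enrichment(psm, conditions)
  passed <- enrichment_filter(enr, fc_min = fc_min, p_max = p_max)
  overlap <- if (is.null(pilot)) passed else pilot_overlap(passed, pilot)
  calls <- data.frame(protein_id = enr$protein_id,
                      fc_enrichment = enr$fc, p_enrichment = enr$p,
                      passed_enrichment = enr$protein_id %in% passed,
                      in_pilot_overlap = enr$protein_id %in% overlap,
                      dose_slope = NA_real_, p_dose = NA_real_,
                      passed_dose = FALSE, final_candidate = FALSE,
                      stringsAsFactors = FALSE)
  testable <- intersect(overlap, unique(dose_table$protein_id))
  if (length(testable)) {
    dd <- dose_decrease_filter(dose_table, testable, p_max = p_max)
    i <- match(dd$protein_id, calls$protein_id)
    calls$dose_slope[i] <- dd$dose_slope
    calls$p_dose[i] <- dd$p_dose
    calls$passed_dose[i] <- dd$passed_dose
  }
  calls$final_candidate <- calls$passed_enrichment & calls$in_pilot_overlap &
    calls$passed_dose
  calls
}
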