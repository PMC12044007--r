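#' Chi-squared statistic (1 df) from a two-sided p-value
#'
#' Inverts a two-sided normal p-value to its 1-df chi-squared statistic,
#' `chisq = qnorm(p/2)^2`. Computed through the log-scale normal quantile
#' (AS241), which keeps the relative error below 1e-6 down to p = 1e-300;
#' inverting the upper-tail chi-squared CDF naively loses precision long
#' before that.
#'
#' @param p Vector of p-values in `(0, 1]`.
#' @return Chi-squared statistics (`>= 0`).
#' @examples
#' p_to_chisq1(0.05)   # 3.8415
#' @export
p_to_chisq1 <- function(p) {
  stop_if_not(all(p > 0) && all(p <= 1), "p must be in (0, 1]")
  stats::qnorm(log(p) - log(2), log.p = TRUE)^2
}

#' Likelihood ratios of each variant's association relative to the tag SNP
#'
#' For 1-df association statistics the likelihood ratio between the tag
#' model and variant i's model is `exp((chisq_tag - chisq_i)/2)`, computed
#' from the GWAS p-values. The tag (smallest p) has LLR 1; larger values
#' mean the variant's model is that many times less likely than the tag's.
#'
#' @param records Data frame with columns `variant_id` and `p`.
#' @param tag_id The tag SNP's `variant_id` (must be present; a warning is
#'   issued if it does not carry the smallest p).
#' @return Named numeric vector of LLRs, one per record.
#' @export
llr_from_pvalues <- function(records, tag_id) {
  stop_if_not(all(c("variant_id", "p") %in% names(records)),
              "records need columns variant_id, p")
  i <- match(tag_id, records$variant_id)
  stop_if_not(!is.na(i), sprintf("tag variant '%s' not found", tag_id))
  if (records$p[i] > min(records$p)) {
    warning("tag variant does not have the smallest p-value", call. = FALSE)
  }
  chisq <- p_to_chisq1(records$p)
  stats::setNames(exp((chisq[i] - chisq) / 2), records$variant_id)
}

#' LD r-squared of every variant with a tag variant
#'
#' Accepts either a dosage matrix (individuals x variants; r^2 is the
#' squared Pearson correlation of dosage columns) or a precomputed square
#' r^2 matrix with variant ids as dimnames. Zero-variance columns yield
#' `NA`.
#'
#' @param x Dosage matrix or square r^2 matrix.
#' @param tag_id Column name of the tag variant.
#' @return Named vector of r^2 with the tag (tag itself 1).
#' @export
ld_r2 <- function(x, tag_id) {
  stop_if_not(tag_id %in% colnames(x), sprintf("tag '%s' not in columns", tag_id))
  is_r2 <- nrow(x) == ncol(x) && !is.null(rownames(x)) &&
    identical(rownames(x), colnames(x)) && all(x >= 0, na.rm = TRUE) &&
    all(x <= 1 + 1e-12, na.rm = TRUE)
  if (is_r2) return(stats::setNames(as.numeric(x[tag_id, ]), colnames(x)))
  g <- x[, tag_id]
  stop_if_not(stats::sd(g) > 0, "tag column has zero variance")
  r <- suppressWarnings(as.numeric(stats::cor(x, g)))
  stats::setNames(r^2, colnames(x))
}

#' Likelihood-ratio / LD filter for credible causal variants
#'
#' Retains variants whose likelihood ratio relative to the tag is at most
#' `llr_max` (the "1:100" rule) and whose LD with the tag exceeds
#' `r2_min`. The tag is always retained.
#'
#' @param llr Named LLR vector from [llr_from_pvalues()].
#' @param r2 Named r^2 vector from [ld_r2()] (same ids).
#' @param tag_id Tag variant id.
#' @param llr_max Maximum LLR (default 100).
#' @param r2_min Minimum r^2, strict (default 0.8).
#' @return Data frame `variant_id, llr, r2, pass` sorted by LLR.
#' @export
llr_ld_filter <- function(llr, r2, tag_id, llr_max = 100, r2_min = 0.8) {
  ids <- names(llr)
  r2 <- r2[ids]
  pass <- (llr <= llr_max) & !is.na(r2) & (r2 > r2_min)
  pass[ids == tag_id] <- TRUE
  out <- data.frame(variant_id = ids, llr = as.numeric(llr),
                    r2 = as.numeric(r2), pass = as.logical(pass),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$llr), , drop = FALSE]
}
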