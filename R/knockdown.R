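#' Drop genes with too many zero-count samples
#'
#' Removes genes with no reads in more than `max_zero_fraction` of the
#' samples (strict inequality: a gene at exactly the threshold is kept).
#'
#' @param counts Genes x samples count matrix.
#' @param max_zero_fraction Maximum tolerated zero fraction (default 0.20).
#' @return The filtered count matrix.
#' @export
filter_expressed <- function(counts, max_zero_fraction = 0.20) {
  zf <- rowMeans(counts == 0)
  counts[zf <= max_zero_fraction, , drop = FALSE]
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Between-library composition normalization by the trimmed mean of
#' M-values: per-gene log2 ratios to a reference library are doubly
#' trimmed (30% on M, 5% on A) and combined with precision weights; the
#' resulting per-sample factors are rescaled so their log-mean is zero.
#' Delegates to the standard edgeR implementation of this scheme.
#'
#' @param counts Genes x samples count matrix (no all-zero sample).
#' @param trim_m,trim_a Trim fractions on M and A values.
#' @return Named per-sample scaling factors, `sum(log(f)) == 0`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  stop_if_not(ncol(counts) >= 2, "need >= 2 samples")
  stop_if_not(all(colSums(counts) > 0), "sample with all-zero counts")
  f <- edgeR::calcNormFactors(as.matrix(counts), method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  stats::setNames(f / exp(mean(log(f))), colnames(counts))
}

#' Normalized expression on the effective-library scale
#'
#' Counts per million over the TMM-effective library size
#' (`lib.size * factor`), used for ranking samples by driver expression.
#'
#' @param counts Count matrix.
#' @param factors Factors from [tmm_factors()] (computed if missing).
#' @return Matrix of normalized expression values.
#' @export
normalized_counts <- function(counts, factors = NULL) {
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- colSums(counts) * factors[colnames(counts)]
  sweep(counts, 2, eff / 1e6, "/")
}

#' Split samples into driver-expression extreme quartiles
#'
#' Orders samples by the normalized expression of the driver gene and
#' returns the bottom and top `floor(N/4)` samples. Ties are broken by
#' stable input order.
#'
#' @param normalized Normalized expression matrix (genes x samples).
#' @param driver_gene Row name of the driver gene.
#' @return List with `low`, `high` (character sample ids) and `k`.
#' @export
quartile_split <- function(normalized, driver_gene) {
  stop_if_not(driver_gene %in% rownames(normalized),
              sprintf("driver gene '%s' not in matrix", driver_gene))
  n <- ncol(normalized)
  stop_if_not(n >= 8, "need >= 8 samples for a quartile split")
  k <- floor(n / 4)
  expr <- normalized[driver_gene, ]
  o <- order(expr)                       # stable for ties
  ids <- colnames(normalized)
  list(low = ids[o[seq_len(k)]], high = ids[o[(n - k + 1):n]], k = k)
}

# Conditional log-likelihood of a common dispersion given group sums,
# summed over genes and groups; counts must be on a common library scale.
common_cond_loglik <- function(phi, count_groups) {
  r <- 1 / phi
  ll <- 0
  for (y in count_groups) {
    # y: genes x samples matrix of one group
    n <- ncol(y)
    z <- rowSums(y)
    ll <- ll + sum(lgamma(y + r)) - n * nrow(y) * lgamma(r) +
      nrow(y) * lgamma(n * r) - sum(lgamma(z + n * r))
  }
  ll
}

golden_max <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c_ <- b - gr * (b - a); d <- a + gr * (b - a)
  fc <- f(c_); fd <- f(d)
  while (abs(b - a) > tol) {
    if (fc > fd) { b <- d; d <- c_; fd <- fc; c_ <- b - gr * (b - a); fc <- f(c_) }
    else { a <- c_; c_ <- d; fc <- fd; d <- a + gr * (b - a); fd <- f(d) }
  }
  (a + b) / 2
}

# Mid-p quantile-to-quantile NB mapping of counts to a common library size.
q2q_pseudo_counts <- function(counts, lib, lib_out, phi) {
  p_g <- rowSums(counts) / sum(lib)
  out <- counts
  r <- 1 / phi
  for (s in seq_len(ncol(counts))) {
    mu_in <- pmax(p_g * lib[s], 1e-8)
    mu_out <- pmax(p_g * lib_out, 1e-8)
    y <- counts[, s]
    u <- stats::pnbinom(y - 1, mu = mu_in, size = r) +
      0.5 * stats::dnbinom(y, mu = mu_in, size = r)
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
    out[, s] <- stats::qnbinom(u, mu = mu_out, size = r)
  }
  out
}

# Conditional NB exact test for one gene: group sums s1, s2 from n1, n2
# equal-library samples, common dispersion phi. Two-sided p: sum of
# conditional outcome probabilities <= the observed outcome's.
nb_exact_gene <- function(s1, s2, n1, n2, phi) {
  s <- s1 + s2
  if (s == 0) return(1)
  r <- 1 / phi
  m <- s / (n1 + n2)
  k <- 0:s
  lp <- stats::dnbinom(k, size = n1 * r, mu = n1 * m, log = TRUE) +
    stats::dnbinom(s - k, size = n2 * r, mu = n2 * m, log = TRUE)
  lp <- lp - logsumexp(lp)
  obs <- lp[s1 + 1]
  min(1, sum(exp(lp[lp <= obs + 1e-12])))
}

#' Quartile-contrast negative-binomial exact test
#'
#' Differential expression between two sample groups under a common-
#' dispersion negative-binomial model, following the quantile-adjusted
#' conditional maximum-likelihood scheme: counts are mapped to pseudo-counts
#' at the geometric-mean library size by a mid-p quantile-to-quantile NB
#' transformation; the common dispersion maximizes the conditional
#' log-likelihood of the pseudo-counts (golden-section search over log
#' dispersion in `[1e-4, 10]`, with one re-adjustment round); and each
#' gene gets a two-sided conditional NB exact test on its group sums.
#' The log2 fold change (`groupA` over `groupB`) uses group mean
#' pseudo-counts with a prior count of 0.125.
#'
#' @param counts Genes x samples count matrix.
#' @param groupA,groupB Character vectors of sample ids (each `>= 2`).
#'   Conventionally `groupA` is the driver-low (bottom-quartile) group so
#'   the fold change reads "bottom over top".
#' @return Object of class `de_result`: data frame `gene, logFC, PValue,
#'   FDR` with attributes `dispersion` and `lib_out`.
#' @export
nb_exact_test <- function(counts, groupA, groupB) {
  stop_if_not(length(groupA) >= 2 && length(groupB) >= 2,
              "both groups need >= 2 samples")
  stop_if_not(all(c(groupA, groupB) %in% colnames(counts)),
              "group sample ids must be columns of counts")
  sub <- as.matrix(counts[, c(groupA, groupB), drop = FALSE])
  lib <- colSums(sub)
  lib_out <- exp(mean(log(pmax(lib, 1))))
  phi <- 0.1
  for (round in 1:2) {
    pseudo <- q2q_pseudo_counts(sub, lib, lib_out, phi)
    grpA <- pseudo[, groupA, drop = FALSE]
    grpB <- pseudo[, groupB, drop = FALSE]
    phi <- exp(golden_max(function(lphi) {
      common_cond_loglik(exp(lphi), list(grpA, grpB))
    }, log(1e-4), log(10)))
  }
  s1 <- rowSums(grpA); s2 <- rowSums(grpB)
  n1 <- length(groupA); n2 <- length(groupB)
  pv <- vapply(seq_len(nrow(sub)), function(i) {
    nb_exact_gene(s1[i], s2[i], n1, n2, phi)
  }, numeric(1))
  pv[s1 + s2 == 0] <- 1
  lfc <- log2((s1 / n1 + 0.125) / (s2 / n2 + 0.125))
  lfc[s1 + s2 == 0] <- 0
  out <- data.frame(gene = rownames(sub) %||% as.character(seq_len(nrow(sub))),
                    logFC = lfc, PValue = pv, FDR = bh_fdr(pv),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- phi
  attr(out, "lib_out") <- lib_out
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment with monotonicity enforcement (a thin wrapper
#' over `stats::p.adjust(method = "BH")`).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of FDR-adjusted values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  stop_if_not(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must be in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' Select differentially expressed genes
#'
#' Filters a DE table at an FDR threshold and, when `log2fc_min` is
#' given, additionally at a strict absolute log2 fold-change threshold.
#'
#' @param de A `de_result` (or data frame with `gene`, `logFC`, `FDR`).
#' @param fdr_max FDR threshold, strict (default 0.05).
#' @param log2fc_min Optional |log2FC| threshold, strict.
#' @return Character vector of selected gene ids.
#' @export
de_gene_selection <- function(de, fdr_max = 0.05, log2fc_min = NULL) {
  keep <- de$FDR < fdr_max
  if (!is.null(log2fc_min)) keep <- keep & abs(de$logFC) > log2fc_min
  de$gene[keep]
}

#' Run the full in-silico knockdown analysis
#'
#' Filters low-coverage genes, TMM-normalizes, splits samples into
#' driver-expression extreme quartiles, runs the NB exact test
#' (bottom over top), and optionally preranked GSEA on the
#' FDR-significant genes ranked by log2 fold change.
#'
#' @param counts Genes x samples count matrix.
#' @param driver_gene Driver gene id.
#' @param gene_sets Optional named list of gene sets for GSEA.
#' @param fdr_max FDR threshold for the GSEA input list.
#' @param n_perm,seed GSEA permutation controls.
#' @return List with `de`, `split`, `factors`, `selected`, and (when
#'   `gene_sets` given) `gsea`.
#' @export
insilico_knockdown <- function(counts, driver_gene, gene_sets = NULL,
                               fdr_max = 0.05, n_perm = 1000, seed = 1L) {
  kept <- filter_expressed(counts)
  stop_if_not(driver_gene %in% rownames(kept),
              "driver gene filtered out or absent")
  f <- tmm_factors(kept)
  norm <- normalized_counts(kept, f)
  sp <- quartile_split(norm, driver_gene)
  de <- nb_exact_test(kept, groupA = sp$low, groupB = sp$high)
  sel <- de_gene_selection(de, fdr_max = fdr_max)
  out <- list(de = de, split = sp, factors = f, selected = sel)
  if (!is.null(gene_sets)) {
    ranked <- stats::setNames(de$logFC, de$gene)[sel]
    out$gsea <- gsea_preranked(ranked, gene_sets, n_perm = n_perm, seed = seed)
  }
  out
}
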