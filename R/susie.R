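#' Sum-of-single-effects Bayesian fine-mapping
#'
#' Fits the additive sum of `L` single-effect regressions to a phenotype
#' (Gaussian working model; a 0/1 case-control phenotype is accepted and
#' treated as Gaussian, as is conventional for this model class) by
#' iterative Bayesian stepwise selection. Each single-effect regression
#' computes per-variant Wakefield-style Bayes factors
#' `BF_j = sqrt(s_j^2/(s_j^2 + s0^2)) * exp(z_j^2/2 * s0^2/(s_j^2 + s0^2))`
#' on the residualized phenotype and normalizes them (uniform prior over
#' variants) into the effect's posterior inclusion vector `alpha_l`. The
#' per-effect prior variance `s0^2` is chosen by maximizing the
#' single-effect marginal likelihood over a fixed grid of fractions of
#' `var(y)`. Per-variant posterior inclusion probabilities are
#' `PIP_j = 1 - prod_l (1 - alpha_lj)`.
#'
#' A level-`coverage` credible set is reported for each effect as the
#' smallest prefix of variants by descending `alpha_l` whose mass reaches
#' `coverage`, kept only if its purity (minimum pairwise absolute dosage
#' correlation) is at least `purity_min`; duplicate sets are collapsed.
#'
#' @param dosages Individuals x variants numeric matrix (columns named).
#' @param phenotype Numeric vector (quantitative or 0/1).
#' @param L Maximum number of single effects (default 10).
#' @param coverage Credible-set coverage target (default 0.9).
#' @param purity_min Minimum credible-set purity (default 0.5).
#' @param max_iter,tol IBSS convergence controls: stop when the largest
#'   absolute change in any `alpha` falls below `tol`.
#' @param prior_grid Grid of prior-variance fractions of `var(y)`.
#' @return Object of class `susie_fit`: list with `alpha` (L x m), `pip`,
#'   `credible_sets` (list of lists with `members`, `coverage`, `purity`),
#'   `sigma2`, `prior_variances`, `converged`, `n_iter`, `purity_min`.
#' @export
susie_fit <- function(dosages, phenotype, L = 10, coverage = 0.9,
                      purity_min = 0.5, max_iter = 100, tol = 1e-3,
                      prior_grid = c(0.001, 0.005, 0.01, 0.05, 0.1, 0.2, 0.5, 1)) {
  stop_if_not(all(is.finite(dosages)) && all(is.finite(phenotype)),
              "non-finite inputs")
  stop_if_not(nrow(dosages) == length(phenotype),
              "dosages and phenotype dimensions differ")
  n <- nrow(dosages); m <- ncol(dosages)
  ids <- colnames(dosages) %||% paste0("v", seq_len(m))
  sds <- apply(dosages, 2, stats::sd)
  keep_sd <- ifelse(sds > 0, sds, 1)
  X <- scale(dosages, center = TRUE, scale = keep_sd)
  X[, sds == 0] <- 0
  y <- phenotype - mean(phenotype)
  vy <- stats::var(y)
  if (vy == 0) vy <- 1
  d <- colSums(X^2)
  d[d == 0] <- Inf                       # zero-variance columns never selected
  sigma2 <- vy
  alpha <- matrix(1 / m, L, m)
  mu1 <- matrix(0, L, m)                 # posterior means given inclusion
  fitted <- rep(0, n)
  b_l <- alpha * mu1                     # L x m posterior mean effects
  prior_v <- rep(NA_real_, L)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    alpha_old <- alpha
    for (l in seq_len(L)) {
      fitted <- fitted - drop(X %*% b_l[l, ])
      r <- y - fitted
      xtr <- drop(crossprod(X, r))
      bhat <- xtr / d
      s2 <- sigma2 / d
      z2 <- bhat^2 / s2
      best <- NULL; best_ll <- -Inf
      for (frac in prior_grid) {
        s0sq <- frac * vy
        lbf <- 0.5 * log(s2 / (s2 + s0sq)) + 0.5 * z2 * s0sq / (s2 + s0sq)
        ll <- logsumexp(lbf - log(m))
        if (ll > best_ll) {
          best_ll <- ll
          best <- list(lbf = lbf, s0sq = s0sq)
        }
      }
      lbf <- best$lbf
      prior_v[l] <- best$s0sq
      a <- exp(lbf - logsumexp(lbf))
      post_shrink <- best$s0sq / (best$s0sq + s2)
      mu1[l, ] <- post_shrink * bhat
      alpha[l, ] <- a
      b_l[l, ] <- a * mu1[l, ]
      fitted <- fitted + drop(X %*% b_l[l, ])
    }
    sigma2 <- max(sum((y - fitted)^2) / n, 1e-8)
    if (max(abs(alpha - alpha_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  pip <- 1 - apply(1 - alpha, 2, prod)
  cs <- list()
  cors <- suppressWarnings(stats::cor(dosages))
  for (l in seq_len(L)) {
    o <- order(alpha[l, ], decreasing = TRUE)
    csum <- cumsum(alpha[l, o])
    k <- which(csum >= coverage)[1]
    if (is.na(k)) next
    members <- o[seq_len(k)]
    purity <- if (length(members) == 1) 1 else {
      sub <- abs(cors[members, members])
      min(sub[upper.tri(sub)], na.rm = TRUE)
    }
    if (!is.finite(purity) || purity < purity_min) next
    key <- paste(sort(members), collapse = ",")
    if (key %in% vapply(cs, function(s) paste(sort(s$member_idx), collapse = ","), ""))
      next
    cs[[length(cs) + 1]] <- list(effect = l,
                                 members = ids[members],
                                 member_idx = members,
                                 coverage = csum[k],
                                 purity = purity)
  }
  structure(list(alpha = alpha, pip = stats::setNames(pip, ids),
                 credible_sets = cs, sigma2 = sigma2,
                 prior_variances = prior_v, converged = converged,
                 n_iter = it, coverage = coverage, purity_min = purity_min,
                 L = L),
            class = "susie_fit")
}

#' @export
print.susie_fit <- function(x, ...) {
  cat(sprintf("Sum-of-single-effects fit: L = %d, %s after %d iterations\n",
              x$L, if (x$converged) "converged" else "NOT converged", x$n_iter))
  cat(sprintf("  %d credible set(s) at coverage %.2f (purity >= %.2f)\n",
              length(x$credible_sets), x$coverage, x$purity_min))
  for (s in x$credible_sets) {
    cat(sprintf("  set (effect %d): {%s}  coverage %.3f purity %.3f\n",
                s$effect, paste(s$members, collapse = ", "), s$coverage, s$purity))
  }
  top <- sort(x$pip, decreasing = TRUE)
  top <- top[seq_len(min(5, length(top)))]
  cat("  top PIPs:", paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Full fine-mapping of a locus
#'
#' Convenience wrapper combining the likelihood-ratio/LD filter with the
#' Bayesian credible-set engine on the same locus.
#'
#' @param records Association records (columns `variant_id`, `p`).
#' @param dosages Dosage matrix for LD and the Bayesian model.
#' @param phenotype Phenotype vector for the Bayesian model.
#' @param tag_id Tag variant; defaults to the smallest-p variant.
#' @param llr_max,r2_min,L,coverage,purity_min Thresholds passed through.
#' @return List with `table` (per-variant `llr`, `r2`, `pip`, `pass`) and
#'   `susie` (the `susie_fit`).
#' @export
fine_map_locus <- function(records, dosages, phenotype, tag_id = NULL,
                           llr_max = 100, r2_min = 0.8, L = 10,
                           coverage = 0.9, purity_min = 0.5) {
  if (is.null(tag_id)) tag_id <- records$variant_id[which.min(records$p)]
  llr <- llr_from_pvalues(records, tag_id)
  r2 <- ld_r2(dosages, tag_id)
  filt <- llr_ld_filter(llr, r2, tag_id, llr_max = llr_max, r2_min = r2_min)
  fit <- susie_fit(dosages, phenotype, L = L, coverage = coverage,
                   purity_min = purity_min)
  filt$pip <- as.numeric(fit$pip[filt$variant_id])
  list(table = filt, susie = fit, tag_id = tag_id)
}
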