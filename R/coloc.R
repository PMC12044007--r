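#' Wakefield log approximate Bayes factor for association
#'
#' For an effect estimate `beta` with standard error `se` and a normal
#' effect prior with standard deviation `prior_sd`,
#' `log ABF = 0.5*log(se^2/(se^2 + W)) + 0.5*z^2*W/(se^2 + W)` with
#' `W = prior_sd^2` and `z = beta/se`. The default prior standard
#' deviations follow the usual convention for this family of methods:
#' 0.15 for quantitative traits and 0.2 for case-control log odds ratios.
#'
#' @param beta,se Effect estimates and standard errors (`se > 0`).
#' @param prior_sd Prior standard deviation of the true effect.
#' @return Log Bayes factors (association vs null), vectorized.
#' @export
wakefield_abf <- function(beta, se, prior_sd = 0.15) {
  stop_if_not(all(se > 0), "se must be > 0")
  w <- prior_sd^2
  z2 <- (beta / se)^2
  0.5 * log(se^2 / (se^2 + w)) + 0.5 * z2 * w / (se^2 + w)
}

# Harmonize two summary tables: inner join on variant_id; when both carry
# ref/alt alleles, align trait 2 effects to trait 1's allele orientation,
# dropping unresolvable (palindromic-mismatch) variants with a warning.
harmonize_traits <- function(t1, t2) {
  shared <- intersect(t1$variant_id, t2$variant_id)
  dropped <- length(union(t1$variant_id, t2$variant_id)) - length(shared)
  a <- t1[match(shared, t1$variant_id), , drop = FALSE]
  b <- t2[match(shared, t2$variant_id), , drop = FALSE]
  if (all(c("ref", "alt") %in% names(a)) && all(c("ref", "alt") %in% names(b))) {
    comp <- function(x) chartr("ACGT", "TGCA", x)
    same <- toupper(a$ref) == toupper(b$ref) & toupper(a$alt) == toupper(b$alt)
    flipped <- toupper(a$ref) == toupper(b$alt) & toupper(a$alt) == toupper(b$ref)
    strand <- toupper(a$ref) == comp(toupper(b$ref)) &
      toupper(a$alt) == comp(toupper(b$alt))
    palindromic <- toupper(b$ref) == comp(toupper(b$alt))
    resolvable <- same | ((flipped | strand) & !palindromic)
    b$beta[flipped & !palindromic] <- -b$beta[flipped & !palindromic]
    if (any(!resolvable)) {
      warning(sprintf("dropping %d allele-ambiguous variant(s)", sum(!resolvable)),
              call. = FALSE)
      a <- a[resolvable, , drop = FALSE]
      b <- b[resolvable, , drop = FALSE]
      dropped <- dropped + sum(!resolvable)
    }
  }
  list(t1 = a, t2 = b, n_dropped = dropped)
}

#' Colocalization of two association signals by Bayes-factor enumeration
#'
#' Standard five-hypothesis enumeration over single-causal-variant
#' configurations: H0 no association; H1/H2 one trait associated; H3 both,
#' distinct causal variants; H4 both, one shared causal variant. Sums of
#' per-variant approximate Bayes factors are accumulated with log-sum-exp
#' throughout.
#'
#' @param trait1,trait2 Data frames with columns `variant_id`, `beta`,
#'   `se` (and optionally `ref`/`alt` for allele harmonization). Joined on
#'   shared variant ids; the number dropped is reported.
#' @param p1,p2,p12 Prior probabilities that a variant is causal for trait
#'   1 only, trait 2 only, or both (defaults 1e-4, 1e-4, 1e-5).
#' @param prior_sd1,prior_sd2 Effect-prior SDs for the two traits
#'   (defaults 0.2 for a case-control trait 1, 0.15 for a quantitative
#'   trait 2).
#' @return Object of class `coloc_result`: list with `pp` (named PP0..PP4,
#'   summing to 1), `n_variants`, `n_dropped`, `priors`, `prior_sd`,
#'   `abf1`, `abf2` (per-variant log ABFs).
#' @export
coloc_posteriors <- function(trait1, trait2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                             prior_sd1 = 0.2, prior_sd2 = 0.15) {
  h <- harmonize_traits(trait1, trait2)
  m <- nrow(h$t1)
  stop_if_not(m >= 2, "need at least 2 shared variants")
  l1 <- wakefield_abf(h$t1$beta, h$t1$se, prior_sd1)
  l2 <- wakefield_abf(h$t2$beta, h$t2$se, prior_sd2)
  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  # sum over ordered pairs (i != j) of BF1_i * BF2_j
  s3 <- logdiffexp(s1 + s2, s12)
  lh <- c(h0 = 0,
          h1 = log(p1) + s1,
          h2 = log(p2) + s2,
          h3 = log(p1) + log(p2) + s3,
          h4 = log(p12) + s12)
  pp <- exp(lh - logsumexp(lh))
  names(pp) <- paste0("PP", 0:4)
  structure(list(pp = pp, n_variants = m, n_dropped = h$n_dropped,
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 prior_sd = c(trait1 = prior_sd1, trait2 = prior_sd2),
                 abf1 = stats::setNames(l1, h$t1$variant_id),
                 abf2 = stats::setNames(l2, h$t1$variant_id)),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("Colocalization over %d shared variants (%d dropped)\n",
              x$n_variants, x$n_dropped))
  cat(paste(sprintf("  %s = %.3f", names(x$pp), x$pp), collapse = "\n"), "\n")
  invisible(x)
}
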