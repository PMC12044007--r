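#' Configuration for the synthetic GWAS locus generator
#'
#' Bundles and validates the parameters of the haplotype/phenotype
#' simulator. All generators in the package are pure functions of their
#' configuration and a single integer seed; per-stage random streams are
#' derived from that seed by fixed offsets (see `stream_seed()` in the
#' package source), so a fixed seed reproduces every byte of output.
#'
#' @param seed Integer seed.
#' @param n_individuals Number of diploid individuals (`>= 2`).
#' @param n_variants Number of variants in the LD block.
#' @param ld_decay Adjacent-variant haplotype correlation in `[0, 1)`;
#'   correlation between variants `k` apart decays as `ld_decay^k`.
#' @param causal_index Index of the causal variant (default: middle of the
#'   block).
#' @param causal_beta Log-odds effect per standardized dosage unit.
#' @param case_fraction Expected case proportion under the null intercept.
#' @param maf_range Length-2 vector of minor-allele frequency bounds, each
#'   in `(0, 0.5]`.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_individuals = 2000L, n_variants = 50L,
                       ld_decay = 0.9, causal_index = NULL, causal_beta = 0.4,
                       case_fraction = 0.5, maf_range = c(0.1, 0.5)) {
  if (is.null(causal_index)) causal_index <- max(1L, ceiling(n_variants / 2))
  stop_if_not(n_individuals >= 2, "invalid config: n_individuals must be >= 2")
  stop_if_not(n_variants >= 1, "invalid config: n_variants must be >= 1")
  stop_if_not(ld_decay >= 0 && ld_decay < 1, "invalid config: ld_decay must be in [0,1)")
  stop_if_not(causal_index >= 1 && causal_index <= n_variants,
              "invalid config: causal_index out of range")
  stop_if_not(case_fraction > 0 && case_fraction < 1,
              "invalid config: case_fraction must be in (0,1)")
  stop_if_not(length(maf_range) == 2 && all(maf_range > 0) && all(maf_range <= 0.5)
              && maf_range[1] <= maf_range[2],
              "invalid config: maf_range must be within (0, 0.5]")
  structure(list(seed = as.integer(seed), n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants), ld_decay = ld_decay,
                 causal_index = as.integer(causal_index), causal_beta = causal_beta,
                 case_fraction = case_fraction, maf_range = maf_range),
            class = "sim_config")
}

#' Simulate genotype dosages over an LD block
#'
#' Haplotypes follow a first-order Markov chain of allele indicators: each
#' variant's allele frequency is drawn from `maf_range` and the chain's
#' transition probabilities are chosen so that the correlation between
#' adjacent allele indicators equals `ld_decay` (clipped to valid
#' probabilities when marginal frequencies differ strongly). Because the
#' conditional expectation is linear in the previous allele, correlation
#' between variants `k` apart is exactly `ld_decay^k` at the haplotype
#' level; dosages (sums of two independent haplotypes) inherit it.
#'
#' @param config A [sim_config()].
#' @return List with `dosages` (individuals x variants integer matrix of
#'   0/1/2, columns `v1..vm`), `ld` (squared Pearson correlation matrix of
#'   the dosage columns), and `maf` (the simulated allele frequencies).
#' @export
simulate_ld_genotypes <- function(config) {
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(stream_seed(config$seed, "genotypes"))
  m <- config$n_variants
  n <- config$n_individuals
  # allele frequencies drift slowly along the block (bounded random walk),
  # keeping adjacent marginals close so the Markov transition probabilities
  # stay in [0,1] and the target adjacent correlation is attained exactly
  rho <- config$ld_decay
  feasible <- function(f_prev, f_new) {
    # transition probabilities exist for correlation rho between
    # Bernoulli(f_prev) and Bernoulli(f_new)
    ratio <- sqrt(f_new * (1 - f_new) / (f_prev * (1 - f_prev)))
    (f_new - rho * ratio * f_prev >= 0) &&
      (f_new + rho * ratio * (1 - f_prev) <= 1)
  }
  f <- numeric(m)
  f[1] <- stats::runif(1, config$maf_range[1], config$maf_range[2])
  if (m > 1) {
    for (j in 2:m) {
      cand <- min(max(f[j - 1] + stats::rnorm(1, 0, 0.02),
                      config$maf_range[1]), config$maf_range[2])
      for (k in 1:50) {
        if (feasible(f[j - 1], cand)) break
        cand <- f[j - 1] + 0.8 * (cand - f[j - 1])
      }
      f[j] <- if (feasible(f[j - 1], cand)) cand else f[j - 1]
    }
  }
  nh <- 2L * n
  hap <- matrix(0L, nh, m)
  hap[, 1] <- stats::rbinom(nh, 1L, f[1])
  if (m > 1) {
    for (j in 2:m) {
      # linear-in-previous-allele transition giving corr rho between
      # adjacent indicators (exact when probabilities stay in [0,1])
      ratio <- sqrt(f[j] * (1 - f[j]) / (f[j - 1] * (1 - f[j - 1])))
      p <- f[j] + rho * ratio * (hap[, j - 1] - f[j - 1])
      p <- pmin(pmax(p, 0), 1)
      hap[, j] <- stats::rbinom(nh, 1L, p)
    }
  }
  dos <- hap[seq(1, nh, by = 2), , drop = FALSE] + hap[seq(2, nh, by = 2), , drop = FALSE]
  colnames(dos) <- paste0("v", seq_len(m))
  ld <- suppressWarnings(stats::cor(dos))^2
  ld[!is.finite(ld)] <- NA_real_
  list(dosages = dos, ld = ld, maf = f)
}

# Single-variant logistic score test against an intercept-only null.
# Returns beta (one-step estimate U/V), se = 1/sqrt(V), p, and a
# separation/degenerate flag. Avoids iterative fitting instability.
score_test_binary <- function(g, y) {
  ybar <- mean(y)
  gc <- g - mean(g)
  u <- sum(gc * y)
  v <- ybar * (1 - ybar) * sum(gc^2)
  if (!is.finite(v) || v <= 0) {
    return(c(beta = NA_real_, se = NA_real_, z = 0, p = 1, flagged = 1))
  }
  z <- u / sqrt(v)
  # separation: one allele class absent within cases or controls entirely
  flagged <- as.numeric(length(unique(g[y == 1])) == 1 || length(unique(g[y == 0])) == 1)
  c(beta = u / v, se = 1 / sqrt(v), z = z, p = 2 * stats::pnorm(-abs(z)),
    flagged = flagged)
}

#' Simulate case-control summary statistics over a dosage matrix
#'
#' Phenotypes are drawn from a logistic model on the standardized causal
#' dosage (`logit P(y=1) = qlogis(case_fraction) + causal_beta * g_std`).
#' Per-variant association statistics come from the single-variant logistic
#' score test against an intercept-only null, which is exact to first order
#' and avoids iterative-fit instability; records with quasi-separation are
#' flagged, not dropped.
#'
#' @param dosages Individuals x variants dosage matrix from
#'   [simulate_ld_genotypes()].
#' @param config A [sim_config()].
#' @return Data frame (one row per variant) with columns `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`, `beta`, `se`, `z`, `p`, `flagged`, plus
#'   attribute `phenotype` (the 0/1 vector used).
#' @export
simulate_case_control_summary <- function(dosages, config) {
  set.seed(stream_seed(config$seed, "phenotype"))
  g <- dosages[, config$causal_index]
  gs <- if (stats::sd(g) > 0) (g - mean(g)) / stats::sd(g) else g * 0
  eta <- stats::qlogis(config$case_fraction) + config$causal_beta * gs
  y <- stats::rbinom(nrow(dosages), 1L, stats::plogis(eta))
  res <- t(apply(dosages, 2, score_test_binary, y = y))
  out <- data.frame(variant_id = colnames(dosages),
                    chrom = "1", pos = seq_len(ncol(dosages)) * 1000L,
                    ref = "G", alt = "A",
                    beta = res[, "beta"], se = res[, "se"], z = res[, "z"],
                    p = pmax(res[, "p"], .Machine$double.xmin),
                    flagged = res[, "flagged"] > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "phenotype") <- y
  out
}

#' Simulate two aligned association-summary tables for colocalization
#'
#' Trait 1 is a case-control GWAS (as in
#' [simulate_case_control_summary()]); trait 2 is a quantitative trait
#' (an eQTL-style expression phenotype) driven either by the same causal
#' variant (`shared = TRUE`) or by a second variant with `r^2 < 0.2` to the
#' first (`shared = FALSE`).
#'
#' @param dosages Dosage matrix.
#' @param shared Logical; do the two traits share their causal variant?
#' @param config A [sim_config()]; `causal_beta` is reused as the
#'   per-standardized-dosage effect for both traits.
#' @param beta2 Effect size for trait 2 (default `config$causal_beta`).
#' @return List with `trait1`, `trait2` (aligned data frames) and
#'   `causal_index2`.
#' @export
simulate_two_trait_summaries <- function(dosages, shared, config,
                                         beta2 = config$causal_beta) {
  trait1 <- simulate_case_control_summary(dosages, config)
  ld <- suppressWarnings(stats::cor(dosages))^2
  if (shared) {
    idx2 <- config$causal_index
  } else {
    r2_to_causal <- ld[, config$causal_index]
    ok <- which(r2_to_causal < 0.2)
    ok <- setdiff(ok, config$causal_index)
    if (!length(ok)) {
      stop(sprintf("no variant with r^2 < 0.2 to the causal variant (min available r^2 = %.3f)",
                   min(r2_to_causal[-config$causal_index])), call. = FALSE)
    }
    # farthest qualifying variant for a clean separation
    idx2 <- ok[which.max(abs(ok - config$causal_index))]
  }
  set.seed(stream_seed(config$seed, "eqtl"))
  g2 <- dosages[, idx2]
  gs2 <- if (stats::sd(g2) > 0) (g2 - mean(g2)) / stats::sd(g2) else g2 * 0
  yq <- beta2 * gs2 + stats::rnorm(nrow(dosages))
  fit1 <- function(g) {
    if (stats::sd(g) == 0) return(c(beta = 0, se = Inf, p = 1))
    sfit <- stats::lm.fit(cbind(1, g), yq)
    rdf <- length(yq) - 2L
    s2 <- sum(sfit$residuals^2) / rdf
    xtx <- sum((g - mean(g))^2)
    se <- sqrt(s2 / xtx)
    b <- unname(sfit$coefficients[2])
    c(beta = b, se = se, p = 2 * stats::pt(-abs(b / se), rdf))
  }
  res2 <- t(apply(dosages, 2, fit1))
  trait2 <- data.frame(variant_id = colnames(dosages),
                       beta = res2[, "beta"], se = res2[, "se"],
                       p = res2[, "p"], stringsAsFactors = FALSE,
                       row.names = NULL)
  list(trait1 = trait1, trait2 = trait2, causal_index2 = idx2)
}

#' Simulate a spectral-count IP-MS experiment with planted substrates
#'
#' PSM counts are Poisson with protein-specific background rates (matching
#' the low-count nature of spectral data). Planted substrates receive a
#' bait-condition rate `substrate_fold` times their control rate
#' (default 4, at least 3); non-substrates are exchangeable across
#' conditions. A matching dose-titration abundance table is produced in
#' which substrates halve in expected abundance per decade of inducer dose
#' and non-substrates are flat, with log-normal measurement noise.
#'
#' @param n_proteins,n_substrates Protein counts (`n_substrates <= n_proteins`).
#' @param bait_reps,ctrl_reps Replicate counts per condition.
#' @param doses Strictly increasing positive inducer doses (default
#'   `c(0.1, 1, 10, 100)` ng/mL with 3 replicates each).
#' @param dose_reps Replicates per dose.
#' @param substrate_fold Bait/control rate ratio for substrates (`>= 3`).
#' @param base_rate_mean Mean background Poisson rate.
#' @param seed Integer seed.
#' @return List with `psm` (matrix proteins x samples), `conditions`
#'   (named character vector sample -> "bait"/"control"), `dose_table`
#'   (long data frame `protein_id, dose, replicate, abundance`), and
#'   `truth` (list with `substrate_proteins`).
#' @export
simulate_psm_experiment <- function(n_proteins = 200L, n_substrates = 5L,
                                    bait_reps = 3L, ctrl_reps = 4L,
                                    doses = c(0.1, 1, 10, 100), dose_reps = 3L,
                                    substrate_fold = 4, base_rate_mean = 2,
                                    seed = 1L) {
  stop_if_not(n_substrates <= n_proteins, "n_substrates must be <= n_proteins")
  stop_if_not(all(diff(doses) > 0) && all(doses > 0),
              "doses must be strictly increasing and positive")
  stop_if_not(substrate_fold >= 3, "substrate_fold must be >= 3")
  set.seed(stream_seed(seed, "psm"))
  ids <- sprintf("P%04d", seq_len(n_proteins))
  substrates <- if (n_substrates > 0) ids[seq_len(n_substrates)] else character(0)
  lambda <- stats::rgamma(n_proteins, shape = 2, scale = base_rate_mean / 2)
  # substrates are genuinely pulled-down proteins: their baseline rate is
  # bounded below (reliably detected in every run) so the planted signal
  # is physically observable
  is_sub <- ids %in% substrates
  lambda[is_sub] <- pmax(lambda[is_sub], 2 * base_rate_mean)
  lam_bait <- lambda
  lam_bait[is_sub] <- lambda[is_sub] * substrate_fold
  samples <- c(paste0("bait", seq_len(bait_reps)), paste0("ctrl", seq_len(ctrl_reps)))
  conditions <- stats::setNames(rep(c("bait", "control"), c(bait_reps, ctrl_reps)), samples)
  psm <- matrix(0L, n_proteins, length(samples), dimnames = list(ids, samples))
  for (s in samples) {
    lam <- if (conditions[[s]] == "bait") lam_bait else lambda
    psm[, s] <- stats::rpois(n_proteins, lam)
  }
  # dose titration: substrates halve per decade of dose, others flat
  base_ab <- stats::rlnorm(n_proteins, meanlog = log(1000), sdlog = 0.5)
  rows <- expand.grid(protein_id = ids, dose = doses,
                      replicate = seq_len(dose_reps), stringsAsFactors = FALSE)
  slope <- ifelse(rows$protein_id %in% substrates, -1, 0) # log2 units per log10(dose)
  mu <- base_ab[match(rows$protein_id, ids)] *
    2^(slope * (log10(rows$dose) - log10(doses[1])))
  rows$abundance <- mu * stats::rlnorm(nrow(rows), 0, 0.1)
  list(psm = psm, conditions = conditions, dose_table = rows,
       truth = list(substrate_proteins = substrates))
}

#' Simulate an RNA-seq count matrix with a driver gene and planted gene sets
#'
#' Counts are negative binomial with gene-specific log-normal mean
#' abundances and a common dispersion. Each sample carries a latent driver
#' activity `a ~ N(0,1)`; the driver gene's expression follows
#' `2^a` (about a two-fold interquartile-extreme contrast, as seen for
#' modest-variance regulators in bulk tissue), and genes in planted sets
#' have their log2 mean shifted by `log2_effect * a / 2.54`, so the
#' expected contrast between bottom- and top-quartile driver samples is
#' `log2_effect` (2.54 is the expected standardized gap between the
#' extreme-quartile means of a standard normal).
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param driver_gene Name given to the driver gene (placed first).
#' @param planted_sets Named list of gene-set sizes, e.g.
#'   `list(setA = 50, setB = 40)`; sets are disjoint and exclude the driver.
#' @param log2_effect Expected log2 contrast of planted genes between
#'   driver-expression extreme quartiles.
#' @param dispersion Common NB dispersion (`> 0`).
#' @param mean_log,sd_log Log-normal parameters of baseline gene means.
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples integer matrix), `truth`
#'   (list with `driver_gene`, `enriched_gene_sets` mapping set id to
#'   member genes, `driver_activity`).
#' @export
simulate_rnaseq <- function(n_genes = 2000L, n_samples = 328L,
                            driver_gene = "DRIVER1",
                            planted_sets = list(set1 = 50L),
                            log2_effect = 1, dispersion = 0.1,
                            mean_log = log(100), sd_log = 1, seed = 1L) {
  stop_if_not(dispersion > 0, "invalid config: dispersion must be > 0")
  n_set_genes <- sum(unlist(planted_sets))
  stop_if_not(n_set_genes + 1 <= n_genes, "planted sets larger than gene universe")
  set.seed(stream_seed(seed, "rnaseq"))
  genes <- c(driver_gene, sprintf("G%05d", seq_len(n_genes - 1L)))
  sets <- list()
  nxt <- 2L
  for (nm in names(planted_sets)) {
    k <- planted_sets[[nm]]
    sets[[nm]] <- genes[nxt:(nxt + k - 1L)]
    nxt <- nxt + k
  }
  a <- stats::rnorm(n_samples)                     # latent driver activity
  mu0 <- stats::rlnorm(n_genes, mean_log, sd_log)
  shift <- matrix(0, n_genes, n_samples)
  shift[1, ] <- a                                  # driver: 2^a
  for (nm in names(sets)) {
    idx <- match(sets[[nm]], genes)
    shift[idx, ] <- matrix(log2_effect * a / 2.54, length(idx), n_samples, byrow = TRUE)
  }
  mu <- mu0 * 2^shift
  counts <- matrix(stats::rnbinom(n_genes * n_samples, mu = mu, size = 1 / dispersion),
                   n_genes, n_samples,
                   dimnames = list(genes, paste0("s", seq_len(n_samples))))
  list(counts = counts,
       truth = list(driver_gene = driver_gene, enriched_gene_sets = sets,
                    driver_activity = a))
}

#' Simulate qPCR dilution-series Ct values with known efficiency
#'
#' The generating model is the standard-curve relation
#' `Ct = intercept - log10(quantity) / log10(1 + E)` plus Gaussian noise,
#' where `E` is the amplification efficiency (`E = 1` is perfect doubling,
#' slope `-3.3219` Ct per decade).
#'
#' @param targets Character vector of target names.
#' @param efficiencies Per-target efficiencies in `(0.7, 1.1]`.
#' @param dilution_points Number of serial 10-fold dilutions (`>= 3`).
#' @param reps Technical replicates per point.
#' @param noise_sd Ct noise standard deviation.
#' @param intercept Ct at quantity 1.
#' @param seed Integer seed.
#' @return Data frame `target, quantity, replicate, ct` with attribute
#'   `truth` (named efficiency vector).
#' @export
simulate_qpcr <- function(targets = c("T1", "T2"), efficiencies = c(1.0, 0.9),
                          dilution_points = 5L, reps = 3L, noise_sd = 0.1,
                          intercept = 35, seed = 1L) {
  stop_if_not(length(targets) == length(efficiencies),
              "one efficiency per target required")
  stop_if_not(all(efficiencies > 0.7) && all(efficiencies <= 1.1),
              "efficiencies must be in (0.7, 1.1]")
  stop_if_not(dilution_points >= 3, "at least 3 dilution points required")
  set.seed(stream_seed(seed, "qpcr"))
  q <- 100 / 10^(seq_len(dilution_points) - 1)
  rows <- expand.grid(target = targets, quantity = q,
                      replicate = seq_len(reps), stringsAsFactors = FALSE)
  e <- efficiencies[match(rows$target, targets)]
  rows$ct <- intercept - log10(rows$quantity) / log10(1 + e) +
    stats::rnorm(nrow(rows), 0, noise_sd)
  attr(rows, "truth") <- stats::setNames(efficiencies, targets)
  rows
}
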