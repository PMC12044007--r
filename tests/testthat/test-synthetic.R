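test_that("genotype generator is deterministic and validates its config", {
  sc <- sim_config(seed = 42, n_individuals = 200, n_variants = 20)
  g1 <- simulate_ld_genotypes(sc)
  g2 <- simulate_ld_genotypes(sc)
  expect_identical(g1$dosages, g2$dosages)
  expect_identical(g1$ld, g2$ld)
  expect_true(all(g1$dosages %in% 0:2))
  expect_error(sim_config(n_individuals = 1), "n_individuals")
  expect_error(sim_config(ld_decay = 1), "ld_decay")
  expect_error(sim_config(maf_range = c(0.1, 0.7)), "maf_range")
})

test_that("LD decays geometrically with the configured adjacent correlation", {
  # independence at ld_decay = 0
  g0 <- simulate_ld_genotypes(sim_config(seed = 5, n_individuals = 1000,
                                         n_variants = 30, ld_decay = 0))
  r <- suppressWarnings(cor(g0$dosages))
  offdiag <- abs(r[upper.tri(r)])
  expect_lt(mean(offdiag), 3 / sqrt(1000))
  # geometric decay: r^2 at lag 10 with ld_decay 0.95 is about 0.95^20
  g <- simulate_ld_genotypes(sim_config(seed = 3, n_individuals = 5000,
                                        n_variants = 50, ld_decay = 0.95))
  lag10 <- mean(diag(g$ld[1:40, 11:50]))
  expect_equal(lag10, 0.95^20, tolerance = 0.15)
  # LD matrix is the squared dosage correlation
  expect_equal(g$ld, suppressWarnings(cor(g$dosages))^2, tolerance = 1e-12)
})

test_that("case-control summaries are calibrated under the null and powered otherwise", {
  # null: p-values uniform over 500 independent variants
  sc0 <- sim_config(seed = 9, n_individuals = 800, n_variants = 500,
                    ld_decay = 0, causal_beta = 0)
  g0 <- simulate_ld_genotypes(sc0)
  s0 <- simulate_case_control_summary(g0$dosages, sc0)
  expect_gt(ks.test(s0$p, "punif")$p.value, 0.01)
  # power: the causal variant beats its flank
  sc1 <- sim_config(seed = 10, n_individuals = 4000, n_variants = 21,
                    ld_decay = 0.5, causal_index = 11, causal_beta = 0.4)
  g1 <- simulate_ld_genotypes(sc1)
  s1 <- simulate_case_control_summary(g1$dosages, sc1)
  expect_gt(-log10(s1$p[11]), median(-log10(s1$p[-11])))
  # determinism of the whole record table
  expect_identical(s1, simulate_case_control_summary(g1$dosages, sc1))
})

test_that("degenerate monomorphic variants are flagged, not fatal", {
  sc <- sim_config(seed = 1, n_individuals = 100, n_variants = 3)
  g <- simulate_ld_genotypes(sc)
  g$dosages[, 2] <- 2L   # monomorphic column
  s <- simulate_case_control_summary(g$dosages, sc)
  expect_true(s$flagged[2] || s$p[2] == 1)
  expect_equal(nrow(s), 3)
})

test_that("two-trait generator shares or separates the causal variant on request", {
  sc <- sim_config(seed = 12, n_individuals = 1000, n_variants = 40,
                   ld_decay = 0.9, causal_index = 10, causal_beta = 0.5)
  g <- simulate_ld_genotypes(sc)
  sh <- simulate_two_trait_summaries(g$dosages, shared = TRUE, sc)
  expect_equal(sh$causal_index2, 10)
  expect_identical(sh$trait1$variant_id, sh$trait2$variant_id)
  di <- simulate_two_trait_summaries(g$dosages, shared = FALSE, sc)
  expect_lt(g$ld[10, di$causal_index2], 0.2)
  # impossible low-LD request errors informatively
  ghi <- simulate_ld_genotypes(sim_config(seed = 12, n_individuals = 3000,
                                          n_variants = 4, ld_decay = 0.999,
                                          causal_index = 2))
  expect_error(simulate_two_trait_summaries(ghi$dosages, shared = FALSE,
                                            sim_config(seed = 12, n_individuals = 3000,
                                                       n_variants = 4, ld_decay = 0.999,
                                                       causal_index = 2)),
               "r\\^2")
})

test_that("PSM experiment plants recoverable substrates with Poisson counts", {
  ps <- simulate_psm_experiment(n_proteins = 100, n_substrates = 4, seed = 21)
  expect_setequal(ps$truth$substrate_proteins, rownames(ps$psm)[1:4])
  expect_true(all(ps$truth$substrate_proteins %in% ps$dose_table$protein_id))
  expect_identical(ps$psm, simulate_psm_experiment(n_proteins = 100,
                                                   n_substrates = 4, seed = 21)$psm)
  expect_error(simulate_psm_experiment(n_substrates = 10, n_proteins = 5),
               "n_substrates")
  expect_error(simulate_psm_experiment(doses = c(10, 1)), "doses")
})

test_that("RNA-seq counts approach Poisson as dispersion vanishes", {
  rn <- simulate_rnaseq(n_genes = 300, n_samples = 200, dispersion = 1e-6,
                        planted_sets = list(), sd_log = 0, seed = 4)
  # variance/mean ratio near 1 for constant-mean background genes
  vm <- apply(rn$counts[-1, ], 1, var) / rowMeans(rn$counts[-1, ])
  expect_equal(mean(vm), 1, tolerance = 0.1)
  expect_error(simulate_rnaseq(dispersion = 0), "dispersion")
})

test_that("planted gene sets shift expression between driver quartiles", {
  rn <- simulate_rnaseq(n_genes = 500, n_samples = 240, log2_effect = 1,
                        planted_sets = list(up = 40), seed = 8)
  a <- rn$truth$driver_activity
  low <- a <= quantile(a, 0.25); high <- a >= quantile(a, 0.75)
  idx <- match(rn$truth$enriched_gene_sets$up, rownames(rn$counts))
  contrast <- log2(rowMeans(rn$counts[idx, high]) + 0.5) -
    log2(rowMeans(rn$counts[idx, low]) + 0.5)
  expect_equal(mean(contrast), 1, tolerance = 0.25)
})

test_that("qPCR generator follows the standard-curve model exactly at zero noise", {
  qp <- simulate_qpcr(targets = "T1", efficiencies = 1.0, noise_sd = 0, seed = 2)
  cv <- fit_standard_curve(qp$quantity, qp$ct)
  expect_equal(cv$slope, -1 / log10(2), tolerance = 1e-9)   # -3.3219
  expect_equal(cv$efficiency, 1.0, tolerance = 1e-9)
  expect_error(simulate_qpcr(efficiencies = 0.5, targets = "T1"), "efficiencies")
  expect_error(simulate_qpcr(dilution_points = 2, targets = "T1",
                             efficiencies = 1), "dilution")
})
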