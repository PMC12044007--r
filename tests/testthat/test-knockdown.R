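test_that("expression filter drops genes exceeding the zero fraction strictly", {
  counts <- rbind(a = c(rep(0, 21), rep(5, 79)),   # 21% zeros -> dropped
                  b = c(rep(0, 20), rep(5, 80)),   # exactly 20% -> kept
                  c = rep(3, 100))
  colnames(counts) <- paste0("s", 1:100)
  kept <- filter_expressed(counts)
  expect_setequal(rownames(kept), c("b", "c"))
  allpos <- matrix(1, 3, 4)
  expect_equal(filter_expressed(allpos), allpos)
})

test_that("TMM factors are unity for identical and purely scaled libraries", {
  set.seed(5)
  base <- rpois(400, 50)
  m <- cbind(s1 = base, s2 = base, s3 = base)
  f <- tmm_factors(m)
  expect_equal(unname(f), rep(1, 3), tolerance = 1e-9)
  # doubling a library changes depth, not composition
  m2 <- cbind(s1 = base, s2 = base * 2L)
  f2 <- tmm_factors(m2)
  expect_equal(unname(f2), c(1, 1), tolerance = 1e-6)
  expect_equal(sum(log(f2)), 0, tolerance = 1e-9)
  expect_error(tmm_factors(cbind(a = c(0, 0), b = c(1, 1))), "all-zero")
})

test_that("TMM trimming shrugs off a 5% planted DE fraction", {
  set.seed(6)
  mu <- rlnorm(2000, log(100), 1)
  y1 <- rnbinom(2000, mu = mu, size = 10)
  # composition-balanced 5% DE: expression-matched pairs, one up one down,
  # so the true between-library scaling stays 1
  o <- order(mu)
  pairs <- matrix(o[1001:1100], ncol = 2, byrow = TRUE)
  mu2 <- mu
  mu2[pairs[, 1]] <- mu2[pairs[, 1]] * 4
  mu2[pairs[, 2]] <- mu2[pairs[, 2]] / 4
  y2 <- rnbinom(2000, mu = mu2, size = 10)
  f <- tmm_factors(cbind(a = y1, b = y2))
  expect_lt(max(abs(f - 1)), 0.03)
})

test_that("quartile split takes floor(N/4) from each extreme with stable ties", {
  mk <- function(n) {
    m <- matrix(1, 2, n, dimnames = list(c("DRV", "g"), paste0("s", 1:n)))
    m["DRV", ] <- seq_len(n)
    m
  }
  sp <- quartile_split(mk(328), "DRV")
  expect_equal(sp$k, 82)
  expect_length(sp$low, 82); expect_length(sp$high, 82)
  expect_length(intersect(sp$low, sp$high), 0)
  expect_equal(sp$low, paste0("s", 1:82))
  expect_equal(sp$high, paste0("s", 247:328))
  expect_equal(quartile_split(mk(9), "DRV")$k, 2)
  expect_error(quartile_split(mk(7), "DRV"), ">= 8 samples")
  expect_error(quartile_split(mk(20), "nope"), "driver")
})

test_that("the NB exact test is symmetric, handles empty genes, and nails obvious DE", {
  set.seed(11)
  counts <- matrix(rnbinom(50 * 12, mu = 60, size = 10), 50, 12,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  counts[1, ] <- 0
  counts[2, 1:6] <- rnbinom(6, mu = 400, size = 10)   # strong DE
  counts[2, 7:12] <- rnbinom(6, mu = 40, size = 10)
  A <- paste0("s", 1:6); B <- paste0("s", 7:12)
  de <- nb_exact_test(counts, A, B)
  expect_equal(de$PValue[1], 1)
  expect_equal(de$logFC[1], 0)
  expect_lt(de$PValue[2], 1e-6)
  expect_gt(de$logFC[2], 1)
  # relabeling the groups flips the fold change but not the p-value
  de_swap <- nb_exact_test(counts, B, A)
  expect_equal(de$PValue, de_swap$PValue, tolerance = 1e-9)
  expect_equal(de$logFC, -de_swap$logFC, tolerance = 1e-9)
  expect_true(all(de$FDR >= de$PValue - 1e-12))
})

test_that("exact-test results track the reference qCML implementation", {
  skip_if_not_installed("edgeR")
  set.seed(12)
  mu <- rlnorm(150, log(80), 0.7)
  counts <- matrix(rnbinom(150 * 16, mu = mu, size = 8), 150, 16,
                   dimnames = list(paste0("g", 1:150), paste0("s", 1:16)))
  idx <- 1:10
  counts[idx, 1:8] <- matrix(rnbinom(80, mu = mu[idx] * 3, size = 8), 10, 8)
  A <- paste0("s", 1:8); B <- paste0("s", 9:16)
  de <- nb_exact_test(counts, A, B)
  y <- edgeR::DGEList(counts = counts,
                      group = rep(c("A", "B"), each = 8))
  y <- edgeR::estimateCommonDisp(y)
  et <- edgeR::exactTest(y, pair = c("B", "A"))$table
  expect_equal(attr(de, "dispersion"), y$common.dispersion, tolerance = 0.25)
  expect_gt(cor(-log10(de$PValue), -log10(et$PValue), method = "spearman"), 0.95)
  # both routes flag the planted genes
  expect_true(all(de$FDR[idx] < 0.05))
  expect_true(all(p.adjust(et$PValue, "BH")[idx] < 0.05))
})

test_that("null type-I error of the exact test is near nominal", {
  set.seed(13)
  counts <- matrix(rnbinom(400 * 20, mu = 50, size = 10), 400, 20,
                   dimnames = list(paste0("g", 1:400), paste0("s", 1:20)))
  de <- nb_exact_test(counts, paste0("s", 1:10), paste0("s", 11:20))
  rate <- mean(de$PValue < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("BH adjustment equals a brute-force step-up oracle", {
  bh_oracle <- function(p) {
    n <- length(p); o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    out <- numeric(n); out[o] <- pmin(adj, 1); out
  }
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(14)
  for (i in 1:5) {
    p <- runif(50)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("gene selection applies FDR-only or FDR-plus-fold filters strictly", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   logFC = c(0.5, 0.6, -0.7, 2),
                   FDR = c(0.01, 0.01, 0.01, 0.2))
  expect_setequal(de_gene_selection(de), c("a", "b", "c"))
  expect_setequal(de_gene_selection(de, log2fc_min = 0.5), c("b", "c"))
  expect_setequal(de_gene_selection(de, fdr_max = 1), c("a", "b", "c", "d"))
})

test_that("the full in-silico knockdown recovers planted covariation", {
  rn <- simulate_rnaseq(n_genes = 600, n_samples = 160, log2_effect = 1.2,
                        planted_sets = list(up = 40), seed = 31)
  kd <- insilico_knockdown(rn$counts, "DRIVER1",
                          gene_sets = rn$truth$enriched_gene_sets,
                          n_perm = 200, seed = 31)
  expect_equal(kd$split$k, 40)
  planted <- rn$truth$enriched_gene_sets$up
  expect_gt(mean(planted %in% kd$selected), 0.5)
  expect_lt(kd$gsea$fdr[kd$gsea$set == "up"], 0.1)
})
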