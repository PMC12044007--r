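test_that("pseudo-count enrichment follows the stated median-ratio and t-test recipe", {
  psm <- rbind(hit = c(10, 12, 11, 1, 0, 1, 1),
               flat = c(2, 2, 2, 2, 2, 2, 2),
               zero = c(0, 0, 0, 0, 0, 0, 0))
  colnames(psm) <- c(paste0("b", 1:3), paste0("c", 1:4))
  cond <- setNames(rep(c("bait", "control"), c(3, 4)), colnames(psm))
  e <- psm_enrichment(psm, cond)
  expect_equal(e$fc[e$protein_id == "hit"], 12 / 2)       # medians of +1 counts
  expect_equal(e$fc[e$protein_id == "flat"], 1)
  expect_equal(e$p[e$protein_id == "flat"], 1)
  expect_equal(e$fc[e$protein_id == "zero"], 1)
  expect_equal(e$p[e$protein_id == "zero"], 1)
  # oracle: equal-variance t-test on the +1 counts
  expect_equal(e$p[e$protein_id == "hit"],
               t.test(c(11, 13, 12), c(2, 1, 2, 2), var.equal = TRUE)$p.value)
  expect_error(psm_enrichment(psm[, c(1, 4, 5, 6)], cond[c(1, 4, 5, 6)]),
               "2 samples")
})

test_that("the enrichment filter is strict at both thresholds", {
  calls <- data.frame(protein_id = c("a", "b", "c", "d"),
                      fc = c(1.5, 1.6, 3.0, 3.0),
                      p = c(0.01, 0.01, 0.05, 0.001))
  expect_setequal(enrichment_filter(calls), c("b", "d"))
  expect_length(enrichment_filter(calls[0, ]), 0)
})

test_that("planted substrates pass triage; false passes respect the binomial bound", {
  ps <- simulate_psm_experiment(n_proteins = 200, n_substrates = 5, seed = 77)
  calls <- substrate_triage(ps$psm, ps$conditions, ps$dose_table,
                            pilot = rownames(ps$psm))
  truth <- ps$truth$substrate_proteins
  found <- calls$protein_id[calls$final_candidate]
  expect_true(all(truth %in% found))
  bg_pass <- sum(calls$passed_enrichment[!calls$protein_id %in% truth])
  expect_lte(bg_pass, qbinom(0.99, 195, 0.05))
  # final_candidate implies every upstream flag
  fc <- calls[calls$final_candidate, ]
  expect_true(all(fc$passed_enrichment & fc$in_pilot_overlap & fc$passed_dose))
})

test_that("pilot overlap is an order-stable intersection", {
  expect_equal(pilot_overlap(c("x", "y", "z"), c("z", "x")), c("x", "z"))
  expect_length(pilot_overlap(c("x"), c("y")), 0)
  expect_equal(pilot_overlap(c("a", "b"), c("a", "b")), c("a", "b"))
})

test_that("dose filter demands a significantly negative trend", {
  mk <- function(mult) {
    expand.grid(dose = c(0.1, 1, 10, 100), replicate = 1:3) |>
      transform(protein_id = "p1",
                abundance = 1000 * mult^(log10(dose) + 1) *
                  exp(rnorm(12, 0, 0.01)))
  }
  set.seed(1)
  dec <- dose_decrease_filter(mk(0.5), "p1")     # halves per decade
  expect_true(dec$passed_dose)
  expect_lt(dec$dose_slope, 0)
  flat <- dose_decrease_filter(mk(1), "p1")
  expect_false(flat$passed_dose)
  inc <- dose_decrease_filter(mk(2), "p1")
  expect_false(inc$passed_dose)
  expect_gt(inc$dose_slope, 0)
  two <- mk(0.5); two <- two[two$dose < 10, ]
  expect_error(dose_decrease_filter(two, "p1"), "3 distinct doses")
  expect_error(dose_decrease_filter(mk(0.5), "absent"), "absent")
})

test_that("count scaling preserves enrichment decisions and ranking", {
  ps <- simulate_psm_experiment(n_proteins = 120, n_substrates = 4, seed = 13)
  e1 <- psm_enrichment(ps$psm, ps$conditions)
  e10 <- psm_enrichment(ps$psm * 10L, ps$conditions)
  # pseudo-count dilution shifts low-count fold changes, but the planted
  # substrates pass the filter either way and the ranking is stable
  expect_true(all(ps$truth$substrate_proteins %in% enrichment_filter(e1)))
  expect_true(all(ps$truth$substrate_proteins %in% enrichment_filter(e10)))
  expect_gt(cor(e1$fc, e10$fc, method = "spearman"), 0.95)
  # at well-measured proteins the median ratio is pseudo-count-stable
  deep <- simulate_psm_experiment(n_proteins = 120, n_substrates = 4,
                                  base_rate_mean = 20, seed = 13)
  d1 <- psm_enrichment(deep$psm, deep$conditions)
  d10 <- psm_enrichment(deep$psm * 10L, deep$conditions)
  hi <- pmin(d1$median_bait, d1$median_control) >= 10
  expect_gt(sum(hi), 50)
  expect_lt(max(abs(d10$fc[hi] / d1$fc[hi] - 1)), 0.10)
  expect_identical(substrate_triage(ps$psm, ps$conditions, ps$dose_table),
                   substrate_triage(ps$psm, ps$conditions, ps$dose_table))
})

test_that("a null experiment yields almost no final candidates", {
  passes <- vapply(1:10, function(s) {
    ps <- simulate_psm_experiment(n_proteins = 150, n_substrates = 0, seed = 900 + s)
    calls <- substrate_triage(ps$psm, ps$conditions, ps$dose_table,
                              pilot = rownames(ps$psm))
    sum(calls$final_candidate)
  }, numeric(1))
  # two independent 5% filters bound the expected pass count
  expect_lt(mean(passes), 0.05 * 0.05 * 150 + 1)
})
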