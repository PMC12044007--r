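test_that("log-odds construction follows the smoothed-probability formula", {
  # uniform counts against a uniform background score zero everywhere
  u <- matrix(10, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  pwm <- pfm_to_pwm(u)
  expect_true(all(abs(pwm$log_odds) < 1e-9))
  # single-sequence PFM puts its maximum on the observed base
  single <- matrix(0, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  single["A", 1] <- 1; single["C", 2] <- 1; single["G", 3] <- 1
  pwm1 <- pfm_to_pwm(single)
  expect_equal(unname(apply(pwm1$log_odds, 1, which.max)), c(1, 2, 3))
  # hand-computed 2-mer: counts A=3,C=1 at pos 1 (others 0), uniform bg
  cnt <- matrix(0, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  cnt[, 1] <- c(3, 1, 0, 0); cnt[, 2] <- c(0, 0, 4, 0)
  pwm2 <- pfm_to_pwm(cnt, pseudocount = 1)
  expect_equal(unname(pwm2$log_odds[1, "A"]), log((3 + 0.25) / 5) - log(0.25),
               tolerance = pwm2$delta)
  expect_equal(unname(pwm2$log_odds[2, "T"]), log(0.25 / 5) - log(0.25),
               tolerance = pwm2$delta)
  expect_error(pfm_to_pwm(matrix(0, 4, 2)), "all-zero")
})

test_that("DP tail probabilities equal exhaustive enumeration", {
  for (seed in c(11, 12)) {
    pwm <- pfm_to_pwm(random_pfm(6, seed), background = c(0.3, 0.2, 0.2, 0.3))
    sc_min <- sum(apply(pwm$log_odds, 1, min))
    sc_max <- sum(apply(pwm$log_odds, 1, max))
    expect_equal(as.numeric(score_pvalue(pwm, sc_min)), 1.0)
    expect_equal(as.numeric(score_pvalue(pwm, sc_max + 1)), 0.0)
    for (q in c(0.2, 0.6, 0.9)) {
      s <- sc_min + q * (sc_max - sc_min)
      expect_equal(as.numeric(score_pvalue(pwm, s)),
                   brute_force_pwm_pvalue(pwm, s), tolerance = 1e-9)
    }
  }
})

test_that("score_pvalue is monotone non-increasing in the threshold", {
  pwm <- pfm_to_pwm(random_pfm(7, 3))
  ss <- seq(sum(apply(pwm$log_odds, 1, min)), sum(apply(pwm$log_odds, 1, max)),
            length.out = 40)
  ps <- vapply(ss, function(s) as.numeric(score_pvalue(pwm, s)), numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("best SNP hit agrees with a window-by-window brute force on both strands", {
  pwm <- pfm_to_pwm(random_pfm(5, 9))
  seqc <- random_dna(25, 99)
  pos <- 12
  for (allele in c("A", "G")) {
    h <- snp_best_hit(pwm, seqc, pos, allele)
    # brute force
    b <- strsplit(seqc, "")[[1]]; b[pos] <- allele
    best <- -Inf
    for (st in (pos - 4):pos) {
      w <- paste(b[st:(st + 4)], collapse = "")
      fw <- sum(pwm$log_odds[cbind(1:5, match(strsplit(w, "")[[1]],
                                              c("A", "C", "G", "T")))])
      rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(w, "")[[1]]), collapse = ""))
      rv <- sum(pwm$log_odds[cbind(1:5, match(strsplit(rc, "")[[1]],
                                              c("A", "C", "G", "T")))])
      best <- max(best, fw, rv)
    }
    expect_equal(h$score, best, tolerance = 1e-9)
  }
  expect_error(snp_best_hit(pwm, "ACGTACGT", 2, "A"), "flank too short")
})

test_that("strand handling is symmetric for palindromic motifs and under revcomp", {
  # palindromic motif: positions read the same on both strands
  pal <- matrix(0, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  pal["A", 1] <- 8; pal["C", 2] <- 8; pal["G", 3] <- 8; pal["T", 4] <- 8  # ACGT
  pwm <- pfm_to_pwm(pal)
  seqc <- random_dna(20, 7)
  h <- snp_best_hit(pwm, seqc, 10, "C")
  # reverse-complementing the sequence leaves the best score unchanged
  rc <- chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(seqc, "")[[1]]),
                                             collapse = ""))
  h_rc <- snp_best_hit(pwm, rc, nchar(seqc) - 10 + 1, "G")
  expect_equal(h$score, h_rc$score, tolerance = 1e-9)
  expect_equal(h$p, h_rc$p, tolerance = 1e-12)
})

test_that("p-value fold changes reproduce the published allele-preference table", {
  tab <- read.delim(fixture_path("chr1p36_motif_pvalues.tsv"))
  fc <- mapply(function(p1, p2) fold_change_from_pvalues(p1, p2)$fold_change,
               tab$p_allele1, tab$p_allele2)
  elf2 <- tab$motif == "ELF2"
  expect_equal(round(fc[elf2], 2), 23.91)
  fosl2 <- tab$motif == "FOSL2"
  expect_equal(fc[fosl2], 37.93, tolerance = 0.001)
  expect_equal(fold_change_from_pvalues(0.3, 0.3)$fold_change, 1.0)
  expect_equal(fold_change_from_pvalues(1e-3, 1e-2)$stronger_allele, "1")
  expect_error(fold_change_from_pvalues(0, 0.1), "\\(0,1\\]")
})

test_that("motif ranking orders the strongest allelic disruption first", {
  tab <- read.delim(fixture_path("chr1p36_motif_pvalues.tsv"))
  tab <- tab[tab$snp_id == "rs13303160" & tab$motif != "FOSB", ]
  rep_ <- data.frame(snp_id = tab$snp_id, motif = tab$motif,
                     p_allele1 = tab$p_allele1, p_allele2 = tab$p_allele2,
                     fold_change = mapply(function(a, b)
                       fold_change_from_pvalues(a, b)$fold_change,
                       tab$p_allele1, tab$p_allele2),
                     stronger_allele = "A")
  ranked <- rank_disrupted_motifs(rep_)
  expect_equal(ranked$motif[1], "FOSL1")
  expect_identical(rank_disrupted_motifs(rep_[0, ]), rep_[0, ])
  expect_equal(nrow(rank_disrupted_motifs(rep_, fold_min = 1)), nrow(rep_))
})

test_that("allele reports from PWMs carry coherent best hits and fold changes", {
  pwms <- read_jaspar_pfms(fixture_path("synthetic_motifs.jaspar"))
  expect_named(pwms, c("SYN_ETS", "SYN_AP1"))
  seqc <- paste0(random_dna(10, 5), "CCGGAA", random_dna(10, 6))
  rep_ <- allele_motif_report(pwms, seqc, 16, "A", "G", snp_id = "s1")
  expect_equal(nrow(rep_), 2)
  expect_true(all(rep_$fold_change >= 1))
  expect_true(all(rep_$p_allele1 > 0 & rep_$p_allele1 <= 1))
  # the ETS-like motif prefers the A allele that completes its GGAA core
  ets <- rep_[rep_$motif == "SYN_ETS", ]
  expect_equal(ets$stronger_allele, "A")
})
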