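# Shared fixture builders; everything is generated in code.

fixture_path <- function(file) {
  system.file("extdata", file, package = "locusfunnel")
}

# small random position frequency matrix (counts), 4 x L with ACGT rows
random_pfm <- function(L, seed) {
  set.seed(seed)
  matrix(stats::rpois(4 * L, 20) + 1, 4, L,
         dimnames = list(c("A", "C", "G", "T"), NULL))
}

# brute-force tail probability of a PWM score over all 4^L sequences
brute_force_pwm_pvalue <- function(pwm, s) {
  L <- pwm$length
  seqs <- as.matrix(expand.grid(rep(list(1:4), L)))
  sc <- rowSums(matrix(pwm$log_odds[cbind(rep(seq_len(L), each = nrow(seqs)),
                                          as.vector(seqs))],
                       nrow(seqs), L))
  pr <- apply(seqs, 1, function(x) prod(pwm$background[x]))
  sum(pr[sc >= s - 1e-9])
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent single-effect Bayesian regression: normalized Wakefield-type
# Bayes factors computed through normal densities (not the package's formula)
ser_alpha_oracle <- function(X, y, s0sq, sigma2) {
  Xs <- scale(X)
  yc <- y - mean(y)
  d <- colSums(Xs^2)
  bhat <- drop(crossprod(Xs, yc)) / d
  s2 <- sigma2 / d
  bf <- stats::dnorm(bhat, 0, sqrt(s0sq + s2)) / stats::dnorm(bhat, 0, sqrt(s2))
  bf / sum(bf)
}
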