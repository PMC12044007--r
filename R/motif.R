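DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a log-odds position weight matrix from a count matrix
#'
#' Converts a position frequency matrix of base counts into log-odds
#' scores against a background distribution:
#' `log((c + pc*bg_b) / (colsum + pc)) - log(bg_b)` per position and base,
#' i.e. a Dirichlet-smoothed probability model over the background.
#' Scores are quantized at construction to a per-matrix resolution of
#' (largest per-position score range)/10000, so that downstream exact
#' p-value computation by integer dynamic programming represents the
#' stored matrix without further rounding; the resolution is recorded in
#' the object and bounds the quantization error at `L * delta / 2` per
#' window score.
#'
#' @param counts 4 x L or L x 4 non-negative count matrix; if 4 rows (or
#'   columns) are named they must be A, C, G, T.
#' @param background Base probabilities (A, C, G, T), summing to 1.
#' @param pseudocount Positive smoothing mass (default 1).
#' @param name Motif name.
#' @return Object of class `pwm`: list with `name`, `length`, `log_odds`
#'   (L x 4), `int_scores` (integer L x 4), `delta` (score units per
#'   integer), `background`, `pseudocount`.
#' @export
pfm_to_pwm <- function(counts, background = rep(0.25, 4), pseudocount = 1,
                       name = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) == 4 && ncol(counts) != 4) counts <- t(counts)
  if (ncol(counts) != 4) stop("counts must be 4 x L or L x 4", call. = FALSE)
  stop_if_not(all(counts >= 0), "counts must be non-negative")
  stop_if_not(all(rowSums(counts) > 0), "all-zero position in count matrix")
  stop_if_not(abs(sum(background) - 1) < 1e-8, "background must sum to 1")
  stop_if_not(pseudocount > 0, "pseudocount must be positive")
  L <- nrow(counts)
  bg <- matrix(background, L, 4, byrow = TRUE)
  prob <- (counts + pseudocount * bg) / (rowSums(counts) + pseudocount)
  lo <- log(prob) - log(bg)
  rng <- apply(lo, 1, function(r) diff(range(r)))
  delta <- max(rng) / 10000
  if (delta == 0) delta <- 1e-4
  int_scores <- round(lo / delta)
  lo_q <- int_scores * delta
  colnames(lo_q) <- colnames(int_scores) <- DNA_BASES
  structure(list(name = name, length = L, log_odds = lo_q,
                 int_scores = int_scores, delta = delta,
                 background = background, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("PWM '%s': %d positions, score resolution %.3g\n",
              x$name, x$length, x$delta))
  print(round(x$log_odds, 3))
  invisible(x)
}

# reverse-complement a PWM (reverse positions, swap complementary bases)
pwm_revcomp <- function(pwm) {
  flip <- function(m) m[rev(seq_len(nrow(m))), c("T", "G", "C", "A"), drop = FALSE]
  out <- pwm
  out$log_odds <- flip(pwm$log_odds)
  out$int_scores <- flip(pwm$int_scores)
  colnames(out$log_odds) <- colnames(out$int_scores) <- DNA_BASES
  out
}

# score one window (character vector of bases, length L); NA if non-ACGT
pwm_score_window <- function(pwm, bases) {
  idx <- match(bases, DNA_BASES)
  if (anyNA(idx)) return(NA_real_)
  sum(pwm$log_odds[cbind(seq_len(pwm$length), idx)])
}

# Exact distribution of the integer window score under the background,
# by convolution over positions. Returns list(support_offset, probs).
pwm_score_distribution <- function(pwm) {
  ints <- pwm$int_scores
  lo <- sum(apply(ints, 1, min))
  hi <- sum(apply(ints, 1, max))
  if (hi - lo + 1 > 5e7) {
    stop("score range overflow: reduce matrix length or resolution", call. = FALSE)
  }
  cur <- c(1)
  cur_lo <- 0
  for (i in seq_len(pwm$length)) {
    row <- ints[i, ]
    rlo <- min(row)
    new_lo <- cur_lo + rlo
    new_len <- length(cur) + (max(row) - rlo)
    nxt <- numeric(new_len)
    for (b in 1:4) {
      off <- row[b] - rlo
      idx <- seq_along(cur) + off
      nxt[idx] <- nxt[idx] + cur * pwm$background[b]
    }
    cur <- nxt
    cur_lo <- new_lo
  }
  list(offset = cur_lo, probs = cur)
}

#' Exact p-value of a PWM score under the background model
#'
#' Computes `P(score >= s)` for a random background sequence of the
#' motif's length by exact dynamic programming over the integer score
#' lattice (the matrix stores quantized scores, so the computation is
#' exact for the stored matrix). The attribute `error_bound` reports the
#' p-value slack attributable to score quantization relative to an
#' unquantized matrix, obtained by shifting the threshold by the maximal
#' accumulated rounding error `L * delta / 2` in both directions.
#'
#' @param pwm A [pfm_to_pwm()] object.
#' @param s Score threshold (typically an observed window score).
#' @return p-value in `[0, 1]` with attributes `error_bound`, `p_lower`,
#'   `p_upper`.
#' @export
score_pvalue <- function(pwm, s) {
  dist <- pwm_score_distribution(pwm)
  tail_p <- function(t_int) {
    i <- t_int - dist$offset + 1
    if (i <= 1) return(1)
    if (i > length(dist$probs)) return(0)
    sum(dist$probs[i:length(dist$probs)])
  }
  ratio <- s / pwm$delta
  t_int <- if (abs(ratio - round(ratio)) < 1e-6) round(ratio) else ceiling(ratio)
  p <- tail_p(t_int)
  shift <- ceiling(pwm$length / 2)     # L * delta/2 in integer units
  p_lo <- tail_p(t_int + shift)
  p_hi <- tail_p(t_int - shift)
  attr(p, "p_lower") <- p_lo
  attr(p, "p_upper") <- p_hi
  attr(p, "error_bound") <- p_hi - p_lo
  p
}

#' Best motif hit over all windows covering a SNP, on both strands
#'
#' Substitutes the given allele at the marked position, slides the motif
#' across every window of the motif's length that overlaps the SNP,
#' scores both strands (via the reverse-complement matrix, so minus-strand
#' hits are reported in plus-strand coordinates), and returns the hit with
#' the smallest background p-value (equivalently the largest score).
#'
#' @param pwm A `pwm` object.
#' @param sequence Character scalar, the SNP's flanking sequence.
#' @param snp_pos 1-based position of the SNP within `sequence`; at least
#'   `L - 1` bases of flank are required on each side.
#' @param allele Single base to place at `snp_pos`.
#' @return List with `score`, `p`, `strand` (`"+"`/`"-"`), `offset`
#'   (1-based plus-strand start of the best window).
#' @export
snp_best_hit <- function(pwm, sequence, snp_pos, allele) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  L <- pwm$length
  stop_if_not(snp_pos >= 1 && snp_pos <= length(bases), "snp_pos outside sequence")
  if (snp_pos - 1 < L - 1 || length(bases) - snp_pos < L - 1) {
    stop(sprintf("flank too short: need >= %d bases on each side of the SNP", L - 1),
         call. = FALSE)
  }
  stop_if_not(toupper(allele) %in% DNA_BASES, "allele must be one of A/C/G/T")
  bases[snp_pos] <- toupper(allele)
  starts <- (snp_pos - L + 1):snp_pos
  pwm_rc <- pwm_revcomp(pwm)
  best <- list(score = -Inf, strand = NA_character_, offset = NA_integer_)
  for (st in starts) {
    w <- bases[st:(st + L - 1)]
    for (strand in c("+", "-")) {
      sc <- pwm_score_window(if (strand == "+") pwm else pwm_rc, w)
      if (!is.na(sc) && sc > best$score) {
        best <- list(score = sc, strand = strand, offset = st)
      }
    }
  }
  stop_if_not(is.finite(best$score), "no scorable window (non-ACGT bases?)")
  p <- score_pvalue(pwm, best$score)
  list(score = best$score, p = as.numeric(p), strand = best$strand,
       offset = best$offset, error_bound = attr(p, "error_bound"))
}

#' Fold change between two per-allele binding p-values
#'
#' The allele-differential binding proxy: `fold = max(p1, p2)/min(p1, p2)`
#' with the stronger (more significant) allele carried separately.
#'
#' @param p1,p2 Best-hit p-values for allele 1 and allele 2, in `(0, 1]`.
#' @param alleles Optional length-2 character labels.
#' @return List `fold_change`, `stronger_allele` (index 1/2 or its label).
#' @examples
#' fold_change_from_pvalues(2.08e-3, 8.70e-5)   # 23.91, allele 2 stronger
#' @export
fold_change_from_pvalues <- function(p1, p2, alleles = c("1", "2")) {
  stop_if_not(p1 > 0 && p1 <= 1 && p2 > 0 && p2 <= 1, "p-values must be in (0,1]")
  list(fold_change = max(p1, p2) / min(p1, p2),
       stronger_allele = alleles[[if (p1 <= p2) 1 else 2]])
}

#' Allele-differential motif report for one SNP against a motif set
#'
#' For each motif, computes the best hit for each allele and the p-value
#' fold change between them.
#'
#' @param pwms List of `pwm` objects.
#' @param sequence,snp_pos SNP flanking sequence and 1-based SNP position.
#' @param allele1,allele2 The two alleles.
#' @param snp_id Identifier carried into the report.
#' @return Data frame with one row per motif: `snp_id`, `motif`,
#'   `p_allele1`, `p_allele2`, `fold_change`, `stronger_allele`,
#'   `strand1`, `offset1`, `strand2`, `offset2`.
#' @export
allele_motif_report <- function(pwms, sequence, snp_pos, allele1, allele2,
                                snp_id = "snp") {
  rows <- lapply(pwms, function(pwm) {
    h1 <- snp_best_hit(pwm, sequence, snp_pos, allele1)
    h2 <- snp_best_hit(pwm, sequence, snp_pos, allele2)
    fc <- fold_change_from_pvalues(h1$p, h2$p, alleles = c(allele1, allele2))
    data.frame(snp_id = snp_id, motif = pwm$name,
               p_allele1 = h1$p, p_allele2 = h2$p,
               fold_change = fc$fold_change, stronger_allele = fc$stronger_allele,
               strand1 = h1$strand, offset1 = h1$offset,
               strand2 = h2$strand, offset2 = h2$offset,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Rank allele-disrupted motifs by p-value fold change
#'
#' @param reports Data frame from [allele_motif_report()] (possibly row-bound
#'   over SNPs).
#' @param fold_min Keep motifs with `fold_change >= fold_min` (default 1).
#' @return The filtered report sorted by descending `fold_change`.
#' @export
rank_disrupted_motifs <- function(reports, fold_min = 1) {
  if (!nrow(reports)) return(reports)
  out <- reports[reports$fold_change >= fold_min, , drop = FALSE]
  out[order(-out$fold_change), , drop = FALSE]
}
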