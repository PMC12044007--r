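# Weighted Kolmogorov-Smirnov enrichment score for a gene set given
# ranked (decreasing) statistics. `pos` are member positions in the
# ranking, `w` the |stat|^weight values at those positions. The running
# sum jumps up at hits and drifts down across misses; the extreme of
# larger magnitude is the ES.
es_from_positions <- function(pos, w, n_genes) {
  o <- order(pos)
  pos <- pos[o]; w <- w[o]
  k <- length(pos)
  nr <- sum(w)
  if (nr == 0) w <- rep(1, k) / k else w <- w / nr
  miss_step <- 1 / (n_genes - k)
  cum_hit <- cumsum(w)
  # deviation just after each hit, and just before each hit
  dev_after <- cum_hit - (pos - seq_len(k)) * miss_step
  dev_before <- c(0, cum_hit[-k]) - (pos - seq_len(k)) * miss_step
  hi <- max(dev_after)
  lo <- min(dev_before)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment analysis
#'
#' Classic preranked GSEA: genes are ordered by a signed ranking statistic
#' (here conventionally log2 fold change); each set's enrichment score is
#' the extreme of a weighted Kolmogorov-Smirnov running sum with weight
#' `|stat|^weight` (default exponent 1); the null is gene-label
#' permutation (equivalently random sets of the same size) under a fixed
#' seed; `NES = ES / mean(|null ES| of the same sign)`; the permutation
#' p-value uses the same-sign null tail with add-one smoothing; and FDR
#' follows the positive/negative pooled-null convention (fraction of
#' pooled null NES at least as extreme, divided by the fraction of
#' observed NES at least as extreme, capped at 1).
#'
#' @param stats Named numeric vector of ranking statistics (names are gene
#'   ids; ties broken by input order).
#' @param gene_sets Named list of character vectors.
#' @param n_perm Permutations per set (default 1000).
#' @param seed Integer seed (mandatory for reproducibility).
#' @param min_size,max_size Set-size bounds after intersecting with the
#'   ranked universe (defaults 5, 500); sets outside are skipped and
#'   reported in the `skipped` attribute.
#' @param weight Weight exponent on `|stat|` (default 1).
#' @return Data frame `set, size, es, nes, p_perm, fdr` with attributes
#'   `n_perm`, `seed`, `skipped`.
#' @export
gsea_preranked <- function(stats, gene_sets, n_perm = 1000, seed,
                           min_size = 5, max_size = 500, weight = 1) {
  stop_if_not(!missing(seed), "seed is required")
  stop_if_not(!is.null(names(stats)), "stats must be a named vector")
  o <- order(stats, decreasing = TRUE)
  ranked <- stats[o]
  genes <- names(ranked)
  n <- length(genes)
  wvec <- abs(ranked)^weight
  sizes <- vapply(gene_sets, function(s) sum(s %in% genes), integer(1))
  ok <- sizes >= min_size & sizes <= max_size
  skipped <- names(gene_sets)[!ok]
  gene_sets <- gene_sets[ok]
  sizes <- sizes[ok]
  if (!length(gene_sets)) {
    out <- data.frame(set = character(0), size = integer(0), es = numeric(0),
                      nes = numeric(0), p_perm = numeric(0), fdr = numeric(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  set.seed(stream_seed(seed, "gsea"))
  es <- numeric(length(gene_sets))
  null_es <- vector("list", length(gene_sets))
  for (i in seq_along(gene_sets)) {
    pos <- which(genes %in% gene_sets[[i]])
    es[i] <- es_from_positions(pos, wvec[pos], n)
    k <- length(pos)
    null_es[[i]] <- vapply(seq_len(n_perm), function(p) {
      rpos <- sample.int(n, k)
      es_from_positions(rpos, wvec[rpos], n)
    }, numeric(1))
  }
  nes <- numeric(length(es))
  p_perm <- numeric(length(es))
  for (i in seq_along(es)) {
    nul <- null_es[[i]]
    same <- if (es[i] >= 0) nul[nul >= 0] else nul[nul < 0]
    denom <- mean(abs(same))
    nes[i] <- if (length(same) && denom > 0) es[i] / denom else 0
    p_perm[i] <- (1 + sum(abs(same) >= abs(es[i]))) / (1 + length(same))
  }
  # pooled-null FDR per sign
  null_nes <- unlist(lapply(seq_along(es), function(i) {
    nul <- null_es[[i]]
    pos <- nul[nul >= 0]; neg <- nul[nul < 0]
    c(if (length(pos) && mean(pos) > 0) pos / mean(pos) else numeric(0),
      if (length(neg) && mean(-neg) > 0) neg / mean(-neg) else numeric(0))
  }))
  fdr <- vapply(seq_along(nes), function(i) {
    v <- nes[i]
    if (v >= 0) {
      nn <- null_nes[null_nes >= 0]
      num <- if (length(nn)) mean(nn >= v) else 0
      den <- mean(nes[nes >= 0] >= v)
    } else {
      nn <- null_nes[null_nes < 0]
      num <- if (length(nn)) mean(nn <= v) else 0
      den <- mean(nes[nes < 0] <= v)
    }
    if (den == 0) return(0)
    min(1, num / den)
  }, numeric(1))
  out <- data.frame(set = names(gene_sets), size = sizes, es = es, nes = nes,
                    p_perm = p_perm, fdr = fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p_perm, -abs(out$nes)), , drop = FALSE]
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "skipped") <- skipped
  out
}
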