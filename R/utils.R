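# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

#' @keywords internal
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when equal within machine precision
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

# Deterministic per-stream seeds derived from one global seed.
# Offsets are fixed and documented here; keep results < 2^31.
stream_seed <- function(seed, stream = c("genotypes", "phenotype", "eqtl",
                                         "psm", "rnaseq", "qpcr", "gsea",
                                         "assay")) {
  stream <- match.arg(stream)
  offset <- c(genotypes = 0L, phenotype = 1L, eqtl = 2L, psm = 3L,
              rnaseq = 4L, qpcr = 5L, gsea = 6L, assay = 7L)[[stream]]
  (as.integer(seed) %% 2000000000L) + offset * 1000L
}

# Unpaired equal-variance two-tailed t-test that degrades gracefully on
# constant data: identical constant groups give p = 1, distinct constant
# groups give p = 0 (the pooled variance is zero, so the difference is
# certain under the model).
two_group_t <- function(x, y) {
  if (stats::var(c(x, y)) == 0) return(1)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    return(if (mean(x) == mean(y)) 1 else 0)
  }
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
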