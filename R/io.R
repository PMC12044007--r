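#' Read an association summary-statistics TSV
#'
#' Expects a tab-separated file with header columns `variant_id`, `beta`,
#' `se`, `p` (extra columns such as `chrom`, `pos`, `ref`, `alt` are kept).
#' Malformed rows (non-finite `beta`/`se`, `se <= 0`, `p` outside `(0,1]`)
#' are rejected with their line numbers reported in a warning and the
#' `rejected` attribute.
#'
#' @param path Path to the TSV.
#' @return Data frame of typed association records.
#' @export
read_summary_stats <- function(path) {
  x <- read_tsv(path)
  need <- c("variant_id", "beta", "se", "p")
  miss <- setdiff(need, names(x))
  stop_if_not(length(miss) == 0,
              paste("summary-stat file missing column(s):", paste(miss, collapse = ", ")))
  for (col in c("beta", "se", "p")) x[[col]] <- as.numeric(x[[col]])
  bad <- !is.finite(x$beta) | !is.finite(x$se) | x$se <= 0 |
    !is.finite(x$p) | x$p <= 0 | x$p > 1
  if (any(bad)) {
    warning(sprintf("rejected %d malformed row(s) at line(s): %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")),
            call. = FALSE)
  }
  out <- x[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- which(bad) + 1L
  out
}

#' Read a square LD matrix TSV (header row and first column are variant ids)
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with matching dimnames.
#' @export
read_ld_matrix <- function(path) {
  x <- read_tsv(path)
  ids <- as.character(x[[1]])
  m <- as.matrix(x[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  stop_if_not(nrow(m) == ncol(m), "LD matrix must be square")
  stop_if_not(identical(rownames(m), colnames(m)),
              "LD matrix row and column ids differ")
  m
}

#' Read motif count matrices in JASPAR text format
#'
#' Parses the conventional format: a `>identifier name` line followed by
#' four rows `A [ 1 2 3 ]` ... `T [ ... ]` (brackets optional). Multiple
#' motifs per file are supported.
#'
#' @param path Path to the PFM text file.
#' @param background,pseudocount Passed to [pfm_to_pwm()].
#' @return Named list of `pwm` objects.
#' @export
read_jaspar_pfms <- function(path, background = rep(0.25, 4), pseudocount = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  stop_if_not(length(starts) > 0, "no motif headers ('>') found")
  out <- list()
  for (i in seq_along(starts)) {
    from <- starts[i]
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    hdr <- sub("^>\\s*", "", lines[from])
    name <- strsplit(hdr, "\\s+")[[1]]
    name <- name[length(name)]
    rows <- lines[(from + 1):to]
    stop_if_not(length(rows) == 4, sprintf("motif '%s': expected 4 base rows", name))
    counts <- matrix(0, 4, 0)
    parsed <- lapply(rows, function(r) {
      base <- sub("^\\s*([ACGTacgt]).*", "\\1", r)
      nums <- gsub("[^0-9eE+. -]", " ", sub("^\\s*[ACGTacgt]", "", r))
      list(base = toupper(base), vals = as.numeric(strsplit(trimws(nums), "\\s+")[[1]]))
    })
    bases <- vapply(parsed, `[[`, "", "base")
    stop_if_not(setequal(bases, DNA_BASES), sprintf("motif '%s': need rows A,C,G,T", name))
    L <- length(parsed[[1]]$vals)
    counts <- matrix(NA_real_, 4, L, dimnames = list(DNA_BASES, NULL))
    for (pr in parsed) counts[pr$base, ] <- pr$vals
    out[[name]] <- pfm_to_pwm(counts, background = background,
                              pseudocount = pseudocount, name = name)
  }
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: `set_name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t")[[1]]
    stop_if_not(length(parts) >= 3, "GMT line with fewer than 3 fields")
    out[[parts[1]]] <- unique(parts[-(1:2)])
  }
  out
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over Biostrings when available, with a plain-text
#' fallback reader.
#'
#' @param path Path to the FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readDNAStringSet(path)
    return(stats::setNames(as.character(x), sub("\\s.*", "", names(x))))
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  seqs <- tapply(lines[!hdr], id[!hdr], paste, collapse = "")
  stats::setNames(as.character(seqs), sub("^>\\s*(\\S+).*", "\\1", lines[hdr]))
}

#' Write a named character vector of sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(c(paste0(">", nm), seqs[[nm]]), con)
  }
  invisible(path)
}
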