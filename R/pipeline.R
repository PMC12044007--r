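pipeline_defaults <- function() {
  list(
    seed = 1L,
    stages = c("simulate", "meta", "finemap", "motif", "coloc",
               "substrates", "knockdown", "assays"),
    # analysis thresholds (documented defaults of the published funnel)
    llr_max = 100, r2_min = 0.8, coverage = 0.9, L = 10,
    fold_min = 1, fc_min = 1.5, p_max = 0.05,
    fdr_max = 0.05, log2fc_min = 0.5, n_perm = 1000,
    # synthetic-locus shape
    n_individuals = 2000L, n_variants = 50L, ld_decay = 0.9,
    causal_index = 25L, causal_beta = 0.4, case_fraction = 0.5,
    n_genes = 2000L, n_samples = 328L,
    # optional file inputs
    study_file = NULL, pfm_file = NULL, gmt_file = NULL, out_dir = NULL
  )
}

#' Build and validate a pipeline configuration
#'
#' Starts from the documented defaults (thresholds 100, 0.8, 0.9, 10,
#' 1.5, 0.05, 0.05, 0.5 for the LLR, LD, credible-set coverage, number of
#' effects, enrichment fold, enrichment p, DE FDR, and |log2FC| filters)
#' and overrides them with the supplied values; unknown keys are a
#' validation error naming the key. Configurations round-trip losslessly
#' through YAML (see [read_pipeline_config()]).
#'
#' @param ... Named overrides of the default configuration.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  unknown <- setdiff(names(over), names(cfg))
  stop_if_not(length(unknown) == 0,
              paste("unknown configuration key(s):", paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  stop_if_not(cfg$llr_max > 0, "llr_max must be > 0")
  stop_if_not(cfg$r2_min >= 0 && cfg$r2_min <= 1, "r2_min must be in [0,1]")
  stop_if_not(cfg$coverage > 0 && cfg$coverage < 1, "coverage must be in (0,1)")
  stop_if_not(cfg$L >= 1, "L must be >= 1")
  stop_if_not(cfg$fc_min > 0, "fc_min must be > 0")
  stop_if_not(cfg$p_max > 0 && cfg$p_max < 1, "p_max must be in (0,1)")
  stop_if_not(cfg$fdr_max > 0 && cfg$fdr_max <= 1, "fdr_max must be in (0,1]")
  stop_if_not(cfg$n_perm >= 10, "n_perm must be >= 10")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_hash <- function(config) {
  s <- yaml::as.yaml(unclass(config))
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the locus-to-function pipeline
#'
#' Executes the configured stages in dependency order on a synthetic
#' locus (and any configured file inputs) and assembles a locus report.
#' A failed stage is recorded in `report$status` and its downstream
#' dependents are skipped rather than crashing the run. With a fixed
#' configuration and seed the report is reproducible byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `locus_report`: list of per-stage results plus
#'   `status` and `provenance`; written as JSON and TSVs under
#'   `config$out_dir` when set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stop_if_not(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  report <- list(status = list(), provenance = list(
    package = "locusfunnel",
    version = as.character(utils::packageVersion("locusfunnel")),
    seed = config$seed, config_hash = config_hash(config)))
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  run_stage <- function(stage, deps, fun) {
    if (!(stage %in% config$stages)) {
      report$status[[stage]] <<- "disabled"
      return(invisible(NULL))
    }
    failed_dep <- deps[vapply(deps, function(d)
      !identical(report$status[[d]], "ok"), logical(1))]
    if (length(failed_dep)) {
      report$status[[stage]] <<- paste0("skipped (needs ", failed_dep[1], ")")
      return(invisible(NULL))
    }
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      report$status[[stage]] <<- paste("failed:", conditionMessage(res))
    } else {
      report$status[[stage]] <<- "ok"
      report[[stage]] <<- res
    }
    invisible(NULL)
  }

  run_stage("simulate", character(0), function() {
    sc <- sim_config(seed = config$seed, n_individuals = config$n_individuals,
                     n_variants = config$n_variants, ld_decay = config$ld_decay,
                     causal_index = config$causal_index,
                     causal_beta = config$causal_beta,
                     case_fraction = config$case_fraction)
    geno <- simulate_ld_genotypes(sc)
    gwas <- simulate_case_control_summary(geno$dosages, sc)
    traits <- simulate_two_trait_summaries(geno$dosages, shared = TRUE, sc)
    psm <- simulate_psm_experiment(seed = config$seed)
    rna <- simulate_rnaseq(seed = config$seed, n_genes = config$n_genes,
                           n_samples = config$n_samples)
    qpcr <- simulate_qpcr(seed = config$seed)
    log_stage("simulate", sprintf("%d individuals x %d variants; %d proteins; %d genes x %d samples",
                                  nrow(geno$dosages), ncol(geno$dosages),
                                  nrow(psm$psm), nrow(rna$counts), ncol(rna$counts)))
    list(sim_config = sc, genotypes = geno, gwas = gwas, traits = traits,
         psm = psm, rnaseq = rna, qpcr = qpcr)
  })

  run_stage("meta", character(0), function() {
    path <- config$study_file %||%
      system.file("extdata", "chr1p36_studies.tsv", package = "locusfunnel")
    studies <- read_tsv(path)
    res <- meta_analyse_studies(studies)
    log_stage("meta", sprintf("%d studies in -> OR %.3f (%.3f-%.3f)",
                              res$n_studies, res$or_point, res$ci_low, res$ci_high))
    list(studies = studies, result = res)
  })

  run_stage("finemap", "simulate", function() {
    sim <- report$simulate
    fm <- fine_map_locus(sim$gwas, sim$genotypes$dosages,
                         attr(sim$gwas, "phenotype"),
                         llr_max = config$llr_max, r2_min = config$r2_min,
                         L = config$L, coverage = config$coverage)
    log_stage("finemap", sprintf("%d variants in -> %d pass LLR/LD, %d credible set(s)",
                                 nrow(fm$table), sum(fm$table$pass),
                                 length(fm$susie$credible_sets)))
    fm
  })

  run_stage("motif", character(0), function() {
    path <- config$pfm_file %||%
      system.file("extdata", "synthetic_motifs.jaspar", package = "locusfunnel")
    pwms <- read_jaspar_pfms(path)
    # deterministic synthetic flank carrying an ETS-like core around the SNP
    L <- max(vapply(pwms, `[[`, 0L, "length"))
    set.seed(stream_seed(config$seed, "assay"))
    flank <- paste(sample(DNA_BASES, 2 * L + 20, replace = TRUE), collapse = "")
    pos <- L + 10L
    seqc <- strsplit(flank, "")[[1]]
    core_start <- pos - 3L
    seqc[core_start:(core_start + 3L)] <- c("G", "G", "A", "A")
    pos <- core_start + 3L               # SNP at the last core base
    flank <- paste(seqc, collapse = "")
    rep_ <- allele_motif_report(pwms, flank, pos, "A", "G", snp_id = "snp1")
    ranked <- rank_disrupted_motifs(rep_, fold_min = config$fold_min)
    log_stage("motif", sprintf("%d motifs scanned -> %d at fold >= %.2g",
                               nrow(rep_), nrow(ranked), config$fold_min))
    list(report = rep_, ranked = ranked, sequence = flank, snp_pos = pos)
  })

  run_stage("coloc", "simulate", function() {
    tr <- report$simulate$traits
    res <- coloc_posteriors(tr$trait1, tr$trait2)
    log_stage("coloc", sprintf("%d shared variants -> PP4 %.3f", res$n_variants,
                               res$pp["PP4"]))
    res
  })

  run_stage("substrates", "simulate", function() {
    psm <- report$simulate$psm
    calls <- substrate_triage(psm$psm, psm$conditions, psm$dose_table,
                              fc_min = config$fc_min, p_max = config$p_max)
    log_stage("substrates", sprintf("%d proteins -> %d enriched -> %d final candidates",
                                    nrow(calls), sum(calls$passed_enrichment),
                                    sum(calls$final_candidate)))
    calls
  })

  run_stage("knockdown", "simulate", function() {
    rna <- report$simulate$rnaseq
    sets <- if (!is.null(config$gmt_file)) read_gmt(config$gmt_file) else
      rna$truth$enriched_gene_sets
    res <- insilico_knockdown(rna$counts, rna$truth$driver_gene,
                              gene_sets = sets, fdr_max = config$fdr_max,
                              n_perm = config$n_perm, seed = config$seed)
    log_stage("knockdown", sprintf("%d genes tested (quartiles n=%d) -> %d at FDR < %.2g",
                                   nrow(res$de), res$split$k, length(res$selected),
                                   config$fdr_max))
    res[c("de", "split", "selected", "gsea")]
  })

  run_stage("assays", "simulate", function() {
    qp <- report$simulate$qpcr
    curves <- lapply(split(qp, qp$target), function(d)
      fit_standard_curve(d$quantity, d$ct))
    log_stage("assays", sprintf("%d standard curve(s): E = %s", length(curves),
                                paste(sprintf("%.3f", vapply(curves, `[[`, 0, "efficiency")),
                                      collapse = ", ")))
    list(curves = curves)
  })

  class(report) <- "locus_report"
  if (!is.null(config$out_dir)) write_locus_report(report, config$out_dir)
  report
}

#' Write a locus report as JSON plus human-readable TSVs
#'
#' @param report A `locus_report`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_locus_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summarize <- list(
    status = report$status,
    provenance = report$provenance,
    meta = if (!is.null(report$meta))
      report$meta$result[c("or_point", "ci_low", "ci_high", "z", "p")],
    finemap = if (!is.null(report$finemap)) list(
      n_pass = sum(report$finemap$table$pass),
      credible_sets = lapply(report$finemap$susie$credible_sets,
                             function(s) s[c("members", "coverage", "purity")])),
    coloc = if (!is.null(report$coloc)) as.list(report$coloc$pp),
    substrates = if (!is.null(report$substrates)) list(
      n_enriched = sum(report$substrates$passed_enrichment),
      final_candidates = report$substrates$protein_id[report$substrates$final_candidate]),
    knockdown = if (!is.null(report$knockdown)) list(
      quartile_n = report$knockdown$split$k,
      n_selected = length(report$knockdown$selected)),
    assays = if (!is.null(report$assays))
      lapply(report$assays$curves, function(cv) cv[c("slope", "efficiency", "r_squared")])
  )
  jsonlite::write_json(summarize, file.path(dir, "locus_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if (!is.null(report$finemap)) write_tsv(report$finemap$table,
                                          file.path(dir, "finemap.tsv"))
  if (!is.null(report$motif)) write_tsv(report$motif$report,
                                        file.path(dir, "motifs.tsv"))
  if (!is.null(report$substrates)) write_tsv(report$substrates,
                                             file.path(dir, "substrates.tsv"))
  if (!is.null(report$knockdown)) write_tsv(report$knockdown$de,
                                            file.path(dir, "de_results.tsv"))
  invisible(dir)
}

#' @export
print.locus_report <- function(x, ...) {
  cat("Locus report (seed", x$provenance$seed, ")\n")
  for (nm in names(x$status)) cat(sprintf("  %-10s %s\n", nm, x$status[[nm]]))
  invisible(x)
}
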