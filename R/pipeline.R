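#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow with its conventional
#' default: candidate length > 200 nt, coding potential < 0 on both strands,
#' conservation retention above 0.5 (0.25 for common candidates), presence
#' in at least half the samples per condition (5 samples for co-expression),
#' significance at p < 0.05, variant QC at MAF >= 0.005 and HWE p >= 1e-8,
#' and a 10 kb partition window. The demo simulation sizes keep an
#' end-to-end run on a laptop scale; raise them for larger experiments.
#'
#' @param ... named overrides of any default.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    min_len = 200L,
    cpc_cutoff = 0,
    conservation_cutoff_all = 0.5,
    conservation_cutoff_common = 0.25,
    presence_min_samples = 5L,
    alpha = 0.05,
    alpha_var = 0.05,
    maf_min = 0.005,
    hwe_p_min = 1e-8,
    window = 10000L,
    # demo simulation sizes
    sim = list(
      n_genes = 12L, n_genic = 12L, n_short = 6L, n_coding = 12L,
      n_domain = 6L, n_homolog = 6L, n_lncrna = 24L,
      design = c(dry = 30L, lactating = 30L),
      n_ind = 300L, n_var = 1200L, m1 = 100L
    )
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "PipelineConfig")
}

#' Read and write pipeline configurations
#'
#' Configurations serialize to YAML and round-trip losslessly, so a run can
#' be reproduced from its config file alone.
#'
#' @param config a `PipelineConfig`.
#' @param path YAML file path.
#' @return `read_pipeline_config()` a `PipelineConfig`.
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  # named vectors serialize as YAML maps, not bare sequences
  cfg$sim$design <- as.list(cfg$sim$design)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$sim$design <- unlist(cfg$sim$design)
  do.call(pipeline_config, cfg)
}

#' Run the full synthetic-data pipeline
#'
#' Executes simulate -> filter -> profile -> differential expression ->
#' conservation -> co-expression -> enrichment on generated inputs, writing
#' per-stage TSV outputs and a machine-readable `summary.json` of headline
#' counts into `outdir`. Identical configurations (including the seed)
#' produce byte-identical summaries.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @return the summary list, invisibly; side effect: files under `outdir`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- config$sim
  seed <- config$seed

  log_path <- file.path(outdir, "run.log")
  logf <- function(fmt, ...) {
    cat(sprintf("[%s] %s\n", "run", sprintf(fmt, ...)), file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  logf("seed = %d", seed)
  logf(
    "thresholds: len>%d cpc<%g cons>%g/%g alpha=%g maf>=%g hwe>=%g window=%d",
    config$min_len, config$cpc_cutoff, config$conservation_cutoff_all,
    config$conservation_cutoff_common, config$alpha, config$maf_min,
    config$hwe_p_min, config$window
  )

  # two conditions share the reference annotation layout but not transcripts
  gen_dry <- sim_annotation(
    n_genes = sim$n_genes, n_genic = sim$n_genic, n_short = sim$n_short,
    n_coding = sim$n_coding, n_domain = sim$n_domain,
    n_homolog = sim$n_homolog, n_lncrna = sim$n_lncrna,
    condition = "dry", seed = seed
  )
  gen_lact <- sim_annotation(
    n_genes = sim$n_genes, n_genic = sim$n_genic, n_short = sim$n_short,
    n_coding = sim$n_coding, n_domain = sim$n_domain,
    n_homolog = sim$n_homolog, n_lncrna = sim$n_lncrna,
    condition = "lactating", seed = seed + 1L
  )

  cascade <- list(
    dry = run_cascade(
      gen_dry$transcripts, gen_dry$annotation, gen_dry$motifs, gen_dry$known,
      min_len = config$min_len
    ),
    lactating = run_cascade(
      gen_lact$transcripts, gen_lact$annotation, gen_lact$motifs, gen_lact$known,
      min_len = config$min_len
    )
  )
  for (cd in names(cascade)) {
    utils::write.table(
      cascade[[cd]]$report, file.path(outdir, sprintf("filter_report_%s.tsv", cd)),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }

  # expression over the union of surviving candidates (overlap-matched pairs
  # share their dry baseline so planted effects are recoverable)
  dry_m <- cascade$dry$merged[["dry"]]
  lact_m <- cascade$lactating$merged[["lactating"]]
  names(dry_m) <- sprintf("dry_c%02d", seq_along(dry_m))
  names(lact_m) <- sprintf("lact_c%02d", seq_along(lact_m))
  pairs <- match_common(dry_m, lact_m)
  all_ids <- c(names(dry_m), names(lact_m))
  ex <- sim_expression(all_ids,
    design = sim$design, units = "FPKM", seed = seed + 2L
  )
  pairs_kept <- presence_filter_pairs(pairs, ex$expr)
  de <- if (nrow(pairs_kept)) {
    run_de(pairs_kept, ex$expr, alpha = config$alpha, alpha_var = config$alpha_var)
  } else {
    NULL
  }
  de_summary <- if (is.null(de)) {
    list(total = 0L, significant = 0L, up_dry = 0L, up_lact = 0L, ns = 0L)
  } else {
    summarize_de(de, alpha = config$alpha)
  }
  if (!is.null(de)) {
    utils::write.table(de, file.path(outdir, "differential_expression.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }

  profiles <- rbind(
    summarize_group(gen_dry$transcripts, ex$expr, label = "all_dry"),
    summarize_group(gen_lact$transcripts, ex$expr, label = "all_lactating"),
    if (!is.null(cascade$dry$candidates)) {
      summarize_group(cascade$dry$candidates, ex$expr, label = "lncrna_dry")
    },
    if (!is.null(cascade$lactating$candidates)) {
      summarize_group(cascade$lactating$candidates, ex$expr, label = "lncrna_lactating")
    }
  )
  utils::write.table(profiles, file.path(outdir, "profiles.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  # conservation over the merged candidates
  genome <- c(chr1 = 1e6, chr2 = 1e6, chr3 = 1e6)
  cands <- c(dry_m, lact_m)
  cons <- sim_conservation(genome, cands, seed = seed + 3L)
  scores <- data.frame(
    id = names(cands),
    group = "lncRNA",
    score = interval_mean_score(cons$track, cands),
    stringsAsFactors = FALSE
  )
  ranked <- rank_and_threshold(scores,
    cutoff_all = config$conservation_cutoff_all,
    cutoff_common = config$conservation_cutoff_common
  )
  utils::write.table(ranked$table, file.path(outdir, "conservation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  # co-expression of lncRNA candidates against simulated coding genes
  gene_ids <- sprintf("gene_expr_%03d", seq_len(50))
  co_ex <- sim_expression(c(names(dry_m), gene_ids),
    design = sim$design, units = "TPM", seed = seed + 4L
  )
  co_f <- presence_filter_matrix(co_ex$expr, min_samples = config$presence_min_samples)
  co <- correlate_lnc_genes(co_f, lnc_ids = names(dry_m))
  clust <- coexpression_clusters(co, alpha = config$alpha)
  utils::write.table(co, file.path(outdir, "coexpression.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(clust$top, file.path(outdir, "top_correlates.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  # heritability enrichment on simulated genotypes/phenotypes
  gp <- sim_genetics(
    n = sim$n_ind, m = sim$n_var, m1 = sim$m1, seed = seed + 5L
  )
  enr <- fit_enrichment(gp$geno, gp$pheno, gp$lnc,
    window = config$window, maf_min = config$maf_min, hwe_p_min = config$hwe_p_min
  )
  utils::write.table(
    data.frame(
      partition = "lnc", m1 = enr$m1, m2 = enr$m2,
      enrichment = enr$rho, se = enr$se, p = enr$p
    ),
    file.path(outdir, "enrichment.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  summary <- list(
    seed = seed,
    filter = lapply(cascade, function(cs) {
      stats::setNames(as.list(cs$report$survivors), cs$report$stage)
    }),
    merged_candidates = list(dry = length(dry_m), lactating = length(lact_m)),
    common_pairs = nrow(pairs),
    pairs_after_presence = nrow(pairs_kept),
    de = de_summary,
    conservation_retained = length(ranked$retained),
    conservation_unmapped = ranked$n_unmapped,
    coexpression_pairs = nrow(co),
    lnc_with_association = sum(!clust$top$no_association),
    enrichment = list(
      m1 = enr$m1, m2 = enr$m2,
      rho = round(enr$rho, 6), se = round(enr$se, 6), p = round(enr$p, 6)
    )
  )
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  logf("done")
  invisible(summary)
}
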