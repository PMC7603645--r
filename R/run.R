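# End-to-end run with on-disk outputs and a run manifest.

threshold_header <- function(config) {
  c(sprintf("detectability: FPKM > %g in >= %d%% samples; log2(FPKM + %g)",
            config$min_fpkm, round(100 * config$min_sample_frac),
            config$pseudocount),
    sprintf("aging correlation: |r| > %g & P < %g", config$r_aging,
            config$p_aging),
    sprintf("AR calling: |log2FC| > %g & FDR < %g (two oldest vs youngest)",
            config$fc_min, config$fdr_max),
    sprintf("edges: r > %g & FDR < %g (%s, consensus %s); partners: r > %g & q < %g",
            config$edge_r, config$edge_q,
            if (config$signed_edges) "signed" else "absolute",
            config$consensus_mode, config$partner_r, config$partner_q),
    sprintf("modules: walktrap %d steps, > %d genes; enrichment: term %d..%d, overlap >= %d, FDR < %g",
            config$walktrap_steps, config$module_min_size,
            config$enrich_min_term, config$enrich_max_term,
            config$enrich_min_query, config$enrich_fdr))
}

#' Run the pipeline and write all result tables
#'
#' Runs [aging_landscape()] on loaded or synthetic inputs and writes the
#' per-tissue and cross-tissue result TSVs (each with the generating
#' thresholds in `#` header lines), a GraphML + edge-list export of each
#' consensus network, and a YAML run manifest. Output is deterministic for
#' a fixed seed.
#'
#' @param counts,samples,genes inputs (e.g. from [load_inputs()] or
#'   [generate_study()]).
#' @param outdir output directory.
#' @param gmt optional gene-set collection.
#' @param config a [pipeline_config()].
#' @param truth optional planted truth; adds a recovery report.
#' @return the `aging_landscape` fit, invisibly.
#' @export
run_pipeline <- function(counts, samples, genes, outdir, gmt = NULL,
                         config = pipeline_config(), truth = NULL) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  fit <- aging_landscape(counts, samples, genes, gmt = gmt, config = config,
                         truth = truth)
  hdr <- threshold_header(config)
  files <- character(0)
  put <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv_commented(df, path, hdr)
    files <<- c(files, name)
  }

  for (t in fit$tissues) {
    pt <- fit$per_tissue[[t]]
    put(pt$correlation[pt$correlation$called & !pt$correlation$degenerate, ],
        sprintf("%s_aging_correlated.tsv", t))
    put(do.call(rbind, pt$de), sprintf("%s_differential_expression.tsv", t))
    put(pt$ar$members, sprintf("%s_ar_genes.tsv", t))
    if (!is.null(pt$network)) {
      put(pt$network$edges, sprintf("%s_network_edges.tsv", t))
      igraph::write_graph(pt$network$graph,
                          file.path(outdir, sprintf("%s_network.graphml", t)),
                          format = "graphml")
      files <- c(files, sprintf("%s_network.graphml", t))
      put(pt$modules$membership, sprintf("%s_modules.tsv", t))
      put(pt$growth$per_stage, sprintf("%s_network_growth.tsv", t))
    }
    if (length(pt$partners)) {
      put(data.frame(lnc_id = rep(names(pt$partners), lengths(pt$partners)),
                     mrna_id = unlist(pt$partners, use.names = FALSE)),
          sprintf("%s_lnc_partners.tsv", t))
    }
    if (!is.null(pt$enrichment)) {
      put(pt$enrichment$ar_mrna_up, sprintf("%s_enrichment_up.tsv", t))
      put(pt$enrichment$ar_mrna_down, sprintf("%s_enrichment_down.tsv", t))
    }
  }

  if (!is.null(fit$overlap)) put(fit$overlap$per_gene, "ar_sharing.tsv")
  if (!is.null(fit$similarity)) {
    for (b in names(fit$similarity)) {
      m <- fit$similarity[[b]]
      put(data.frame(tissue = rownames(m), m, check.names = FALSE),
          sprintf("similarity_%s.tsv", b))
    }
  }
  if (!is.null(fit$tissue_specificity)) {
    for (a in names(fit$tissue_specificity)) {
      put(fit$tissue_specificity[[a]],
          sprintf("tissue_specificity_%sw.tsv", a))
    }
  }
  for (t in names(fit$age_specificity)) {
    put(fit$age_specificity[[t]], sprintf("%s_age_specificity.tsv", t))
  }
  if (!is.null(fit$recovery)) {
    rec <- fit$recovery
    lines <- c(
      if (!is.null(rec$ar))
        sprintf("ar_sensitivity\t%.4f\nar_fdp\t%.4f", rec$ar$sensitivity,
                rec$ar$fdp),
      if (!is.null(rec$specificity))
        sprintf("specificity_top_decile_planted\t%.4f",
                rec$specificity$top_decile_planted_frac),
      if (!is.null(rec$modules))
        vapply(rec$modules, function(m)
          sprintf("module_%s_jaccard\t%.4f", m$module_id, m$jaccard),
          character(1)))
    writeLines(c("metric\tvalue", lines), file.path(outdir, "recovery.tsv"))
    files <- c(files, "recovery.tsv")
  }

  manifest <- list(package = "lncage",
                   version = as.character(utils::packageVersion("lncage")),
                   config = unclass(config),
                   tissues = fit$tissues,
                   n_samples = nrow(fit$samples),
                   n_genes = nrow(fit$genes),
                   files = sort(files))
  yaml::write_yaml(manifest, file.path(outdir, "run_manifest.yaml"))
  invisible(fit)
}
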