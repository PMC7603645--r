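# Validated input loading, configuration and end-to-end orchestration.

#' Load and validate pipeline inputs
#'
#' Reads the counts TSV (first column `gene_id`, one column per sample),
#' sample metadata TSV (`sample_id`, `tissue`, `age_weeks`, `replicate`)
#' and gene annotation TSV (`gene_id`, `biotype`, `length_bp`, `n_exons`,
#' `n_isoforms`), cross-checks ids in both directions, rejects negative
#' counts, and restricts biotypes to lncRNA/mRNA (unknown biotypes are
#' dropped with a warning in lenient mode, an error otherwise).
#'
#' @param counts_path,samples_path,genes_path input files.
#' @param lenient drop genes with unknown biotype instead of failing.
#' @return list with `counts` (integer matrix), `samples`, `genes`.
#' @export
load_inputs <- function(counts_path, samples_path, genes_path,
                        lenient = TRUE) {
  for (p in c(counts_path, samples_path, genes_path))
    assert_that(file.exists(p), sprintf("no such file: '%s'", p))
  counts_df <- read_tsv_plain(counts_path)
  assert_that(colnames(counts_df)[1] == "gene_id",
              "counts file must start with a gene_id column")
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  rownames(counts) <- counts_df$gene_id
  assert_that(!anyDuplicated(rownames(counts)), "duplicate gene ids in counts")
  assert_that(!anyNA(counts) && all(counts >= 0),
              "counts must be non-negative and complete")
  samples <- read_tsv_plain(samples_path)
  genes <- read_tsv_plain(genes_path)
  need_s <- c("sample_id", "tissue", "age_weeks", "replicate")
  assert_that(all(need_s %in% colnames(samples)),
              sprintf("sample table needs columns: %s",
                      paste(need_s, collapse = ", ")))
  need_g <- c("gene_id", "biotype", "length_bp")
  assert_that(all(need_g %in% colnames(genes)),
              sprintf("gene table needs columns: %s",
                      paste(need_g, collapse = ", ")))

  no_meta <- setdiff(colnames(counts), samples$sample_id)
  assert_that(length(no_meta) == 0,
              sprintf("sample(s) in counts without metadata: %s",
                      first_offenders(no_meta)))
  no_counts <- setdiff(samples$sample_id, colnames(counts))
  assert_that(length(no_counts) == 0,
              sprintf("sample(s) in metadata without counts: %s",
                      first_offenders(no_counts)))
  no_anno <- setdiff(rownames(counts), genes$gene_id)
  assert_that(length(no_anno) == 0,
              sprintf("gene(s) in counts without annotation: %s",
                      first_offenders(no_anno)))

  unknown <- !(genes$biotype %in% c("lncRNA", "mRNA"))
  if (any(unknown)) {
    if (!lenient) {
      stop_ctx(sprintf("unknown biotype(s): %s",
                       first_offenders(unique(genes$biotype[unknown]))))
    }
    warning(sprintf("dropping %d gene(s) with unknown biotype (%s)",
                    sum(unknown),
                    first_offenders(unique(genes$biotype[unknown]))))
    genes <- genes[!unknown, , drop = FALSE]
    counts <- counts[rownames(counts) %in% genes$gene_id, , drop = FALSE]
  }
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  list(counts = counts, samples = samples, genes = genes)
}

#' Pipeline thresholds and switches
#'
#' All analysis thresholds with their study defaults: detectability
#' FPKM > 0.5 in >= 20% of samples; aging correlation r > 0.9, P < 0.05;
#' AR calling |log2FC| > 0.75, FDR < 0.1 in the 78w or 104w vs 8w contrast;
#' partner lists r > 0.8, adjusted P < 0.05; network edges r > 0.9,
#' FDR < 0.05; walktrap 10 steps, modules > 30 genes; enrichment term size
#' 10..400, overlap >= 5, FDR < 0.1; specificity thresholds 0.25..0.5 and
#' top/bottom 20% quantile groups.
#'
#' @param min_fpkm,min_sample_frac,pseudocount detectability/log transform.
#' @param r_aging,p_aging aging-correlation calling.
#' @param fc_min,fdr_max AR calling.
#' @param partner_r,partner_q guilt-by-association partner thresholds.
#' @param edge_r,edge_q network edge thresholds.
#' @param signed_edges signed (`r > edge_r`) or absolute edge rule.
#' @param consensus_mode `"union"` or `"intersection"` of stages 1 and 4.
#' @param walktrap_steps,module_min_size module detection.
#' @param enrich_min_term,enrich_max_term,enrich_min_query,enrich_fdr
#'   enrichment filters.
#' @param specificity_thresholds,top_frac,bottom_frac specificity analysis.
#' @param similarity_weight_u,similarity_weight_i tissue-similarity weights.
#' @param detect_scope `"tissue"` (filter per tissue) or `"global"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(min_fpkm = 0.5, min_sample_frac = 0.2,
                            pseudocount = 1,
                            r_aging = 0.9, p_aging = 0.05,
                            fc_min = 0.75, fdr_max = 0.1,
                            partner_r = 0.8, partner_q = 0.05,
                            edge_r = 0.9, edge_q = 0.05,
                            signed_edges = TRUE,
                            consensus_mode = "union",
                            walktrap_steps = 10, module_min_size = 30,
                            enrich_min_term = 10, enrich_max_term = 400,
                            enrich_min_query = 5, enrich_fdr = 0.1,
                            specificity_thresholds = c(0.25, 0.3, 0.35,
                                                       0.4, 0.45, 0.5),
                            top_frac = 0.2, bottom_frac = 0.2,
                            similarity_weight_u = 0.8,
                            similarity_weight_i = 0.2,
                            detect_scope = c("tissue", "global")) {
  detect_scope <- match.arg(detect_scope)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full multi-tissue aging-transcriptome analysis
#'
#' Orchestrates, per tissue (alphabetical order): detectability filtering,
#' aging correlation, differential expression against the youngest age, AR
#' calling from the two oldest contrasts, guilt-by-association partner
#' lists, stage-binned co-expression networks with walktrap modules and
#' growth metrics, and (given a gene-set collection) enrichment. Across
#' tissues: AR sharing, tissue-similarity matrices, tissue/age specificity
#' profiles, specificity classification and the tissue-specific vs control
#' regulation shift. When truth labels from [generate_study()] are
#' supplied, a recovery report is attached.
#'
#' @param counts gene x sample count matrix.
#' @param samples,genes metadata and annotation (see [load_inputs()]).
#' @param gmt optional `gene_set_collection` for enrichment.
#' @param config a [pipeline_config()].
#' @param truth optional truth list from an `aging_study`.
#' @return object of class `aging_landscape`.
#' @export
aging_landscape <- function(counts, samples, genes, gmt = NULL,
                            config = pipeline_config(), truth = NULL) {
  assert_that(inherits(config, "pipeline_config"),
              "config must come from pipeline_config()")
  tissues <- sort(unique(samples$tissue))
  tmm <- tmm_normalization_factors(counts)
  fpkm <- compute_fpkm(counts, genes, tmm)
  lnc_all <- genes$gene_id[genes$biotype == "lncRNA"]
  mrna_all <- genes$gene_id[genes$biotype == "mRNA"]
  age_points <- sort(unique(samples$age_weeks))
  young <- min(age_points)
  old_ages <- utils::tail(age_points, 2)
  canonical <- length(age_points) == 5

  global_expr <- filter_detectable(fpkm, config$min_fpkm,
                                   config$min_sample_frac,
                                   config$pseudocount, tmm)

  per_tissue <- list()
  for (t in tissues) {
    ids <- samples$sample_id[samples$tissue == t]
    expr <- if (config$detect_scope == "tissue") {
      filter_detectable(fpkm[, ids, drop = FALSE], config$min_fpkm,
                        config$min_sample_frac, config$pseudocount, tmm[ids])
    } else {
      structure(list(values = global_expr$values[, ids, drop = FALSE],
                     fpkm = global_expr$fpkm[, ids, drop = FALSE],
                     detectable = global_expr$detectable,
                     pseudocount = config$pseudocount,
                     min_fpkm = config$min_fpkm,
                     min_sample_frac = config$min_sample_frac,
                     tmm_factors = tmm[ids]),
                class = "expr_matrix")
    }
    res <- list(expr = expr)

    res$correlation <- aging_correlation(expr, samples, t,
                                         r_min = config$r_aging,
                                         p_max = config$p_aging)
    res$de <- lapply(setdiff(age_points, young), function(a)
      differential_expression(expr, samples, t, old_age = a,
                              young_age = young))
    names(res$de) <- sprintf("%gv%g", setdiff(age_points, young), young)
    old_de <- res$de[sprintf("%gv%g", old_ages, young)]
    res$ar <- call_aging_regulated(old_de, genes, fc_min = config$fc_min,
                                   fdr_max = config$fdr_max)

    det_mrna <- intersect(mrna_all, rownames(expr$values))
    ar_lnc <- ar_ids(res$ar, "lncRNA")
    ar_mrna <- ar_ids(res$ar, "mRNA")
    res$partners <- lapply(stats::setNames(ar_lnc, ar_lnc), function(l)
      coexpressed_partners(expr$values, l, det_mrna,
                           r_min = config$partner_r,
                           q_max = config$partner_q))

    if (canonical && length(ar_lnc) > 0 && length(ar_mrna) > 0) {
      stages <- bin_stages(samples, t, age_points)
      edge_list <- lapply(stages, function(s)
        stage_edges(expr$values, ar_lnc, ar_mrna, s,
                    r_min = config$edge_r, q_max = config$edge_q,
                    signed = config$signed_edges))
      res$stages <- stages
      res$network <- suppressWarnings(
        consensus_network(edge_list, mode = config$consensus_mode))
      res$modules <- detect_modules(res$network,
                                    steps = config$walktrap_steps,
                                    min_size = config$module_min_size)
      res$growth <- growth_metrics(expr$values, ar_lnc, ar_mrna, stages,
                                   modules = res$modules$modules,
                                   r_edge = config$edge_r)
    }

    if (!is.null(gmt)) {
      background <- rownames(expr$values)
      res$enrichment <- list()
      for (dir in c("up", "down")) {
        q <- res$ar$members$gene_id[res$ar$members$biotype == "mRNA" &
                                      res$ar$members$direction == dir]
        res$enrichment[[paste0("ar_mrna_", dir)]] <-
          enrich(q, background, gmt, config$enrich_min_term,
                 config$enrich_max_term, config$enrich_min_query,
                 config$enrich_fdr)
      }
      res$enrichment$lnc_partner_terms <- lapply(res$partners, function(p) {
        if (length(p) < config$enrich_min_query) return(character(0))
        e <- enrich(p, background, gmt, config$enrich_min_term,
                    config$enrich_max_term, config$enrich_min_query,
                    config$enrich_fdr)
        e$term[e$significant]
      })
    }
    per_tissue[[t]] <- res
  }

  out <- list(tissues = tissues, per_tissue = per_tissue, config = config,
              genes = genes, samples = samples, tmm = tmm)

  ar_sets <- lapply(per_tissue, `[[`, "ar")
  if (length(tissues) >= 2) {
    nonempty <- vapply(ar_sets, function(a) nrow(a$members) > 0, logical(1))
    if (sum(nonempty) >= 2) {
      out$overlap <- cross_tissue_overlap(ar_sets[nonempty])
    }
    out$similarity <- list(
      lncRNA = suppressWarnings(
        pairwise_similarity(ar_sets, "lncRNA",
                            config$similarity_weight_u,
                            config$similarity_weight_i)),
      mRNA = suppressWarnings(
        pairwise_similarity(ar_sets, "mRNA",
                            config$similarity_weight_u,
                            config$similarity_weight_i)))

    det_any <- rownames(global_expr$fpkm)
    out$tissue_specificity <- lapply(stats::setNames(age_points, age_points),
                                     function(a)
      fractional_profile(fpkm[det_any, , drop = FALSE], samples,
                         axis = "tissue", at = a))
    prof_young <- out$tissue_specificity[[as.character(young)]]
    lnc_scored <- prof_young[prof_young$gene_id %in% lnc_all, ]
    if (nrow(lnc_scored) >= 5) {
      scores <- stats::setNames(lnc_scored$score, lnc_scored$gene_id)
      out$specificity_groups <- quantile_groups(scores, config$top_frac,
                                                config$bottom_frac)
      out$classification <- list()
      out$regulation_shift <- list()
      for (t in tissues) {
        ar_l <- intersect(ar_ids(ar_sets[[t]], "lncRNA"), names(scores))
        anr_l <- setdiff(intersect(rownames(per_tissue[[t]]$expr$values),
                                   names(scores)), ar_l)
        if (length(ar_l) && length(anr_l)) {
          out$classification[[t]] <-
            classify_specific(prof_young,
                              list(AR = ar_l, ANR = anr_l),
                              config$specificity_thresholds)
        }
        fc <- ar_sets[[t]]$fc_all
        sp <- intersect(out$specificity_groups$specific, names(fc))
        ct <- intersect(out$specificity_groups$control, names(fc))
        if (length(sp) && length(ct)) {
          out$regulation_shift[[t]] <-
            regulation_shift(fc, sp, ct, ar_sets[[t]])
        }
      }
    }
  }

  out$age_specificity <- lapply(stats::setNames(tissues, tissues), function(t)
    fractional_profile(per_tissue[[t]]$expr$fpkm, samples, axis = "age",
                       at = t))

  out$features <- lapply(stats::setNames(tissues, tissues), function(t) {
    ar_l <- ar_ids(ar_sets[[t]], "lncRNA")
    anr_l <- setdiff(intersect(lnc_all,
                               rownames(per_tissue[[t]]$expr$values)), ar_l)
    if (length(ar_l) == 0 || length(anr_l) == 0) return(NULL)
    compare_gene_features(genes, ar_l, anr_l, expr = per_tissue[[t]]$expr)
  })

  out <- structure(out, class = "aging_landscape")
  if (!is.null(truth)) out$recovery <- recovery_report(out, truth)
  out
}

#' @export
print.aging_landscape <- function(x, ...) {
  cat(sprintf("aging_landscape: %d tissue(s), %d samples, %d genes\n",
              length(x$tissues), nrow(x$samples), nrow(x$genes)))
  print(summary(x))
  invisible(x)
}

#' @export
summary.aging_landscape <- function(object, ...) {
  do.call(rbind, lapply(object$tissues, function(t) {
    pt <- object$per_tissue[[t]]
    m <- pt$ar$members
    data.frame(tissue = t,
               detectable = sum(pt$expr$detectable),
               aging_correlated = sum(pt$correlation$called),
               ar_lncRNA = sum(m$biotype == "lncRNA"),
               ar_mRNA = sum(m$biotype == "mRNA"),
               network_edges = if (!is.null(pt$network)) nrow(pt$network$edges) else NA_integer_,
               modules = if (!is.null(pt$modules)) length(pt$modules$modules) else NA_integer_,
               stringsAsFactors = FALSE)
  }))
}

#' Recovery report against planted truth
#'
#' Compares pipeline calls with the generator's planted labels: AR
#' sensitivity and false-discovery proportion (pooled over tissues), the
#' fraction of the top decile of tissue-specificity scores occupied by
#' planted tissue-specific genes, and per planted module the best Jaccard
#' overlap with a detected module plus the stage-wise within-module mean
#' absolute correlation and its strict-increase flag.
#'
#' @param fit an `aging_landscape`.
#' @param truth truth list from [generate_study()] (`$truth`).
#' @return list with `ar`, `specificity`, `modules` components.
#' @export
recovery_report <- function(fit, truth) {
  planted <- truth$aging
  rep_ar <- NULL
  if (nrow(planted) > 0) {
    tp <- 0L; called_total <- 0L; fp <- 0L
    for (t in fit$tissues) {
      called <- fit$per_tissue[[t]]$ar$members$gene_id
      true_t <- planted$gene_id[planted$tissue == t]
      tp <- tp + length(intersect(called, true_t))
      fp <- fp + length(setdiff(called, true_t))
      called_total <- called_total + length(called)
    }
    n_planted <- nrow(planted[planted$tissue %in% fit$tissues, ])
    rep_ar <- list(sensitivity = tp / n_planted,
                   fdp = if (called_total > 0) fp / called_total else 0,
                   n_planted = n_planted, n_called = called_total)
  }

  rep_spec <- NULL
  spec_genes <- truth$genes$gene_id[!is.na(truth$genes$specific_tissue)]
  if (length(spec_genes) > 0 && !is.null(fit$tissue_specificity)) {
    prof <- fit$tissue_specificity[[1]]
    ord <- order(-prof$score, prof$gene_id)
    top <- prof$gene_id[ord[seq_len(max(1, floor(0.1 * nrow(prof))))]]
    rep_spec <- list(top_decile_planted_frac = mean(top %in% spec_genes),
                     n_top = length(top), n_planted = length(spec_genes))
  }

  rep_mod <- NULL
  mods <- unique(truth$modules[, c("module_id", "tissue")])
  if (nrow(mods) > 0) {
    rep_mod <- lapply(seq_len(nrow(mods)), function(i) {
      mid <- mods$module_id[i]; t <- mods$tissue[i]
      gids <- truth$genes$gene_id[!is.na(truth$genes$module_id) &
                                    truth$genes$module_id == mid]
      pt <- fit$per_tissue[[t]]
      if (is.null(pt) || is.null(pt$modules)) {
        return(list(module_id = mid, tissue = t, jaccard = NA_real_))
      }
      jac <- if (length(pt$modules$modules) == 0) 0 else
        max(vapply(pt$modules$modules, function(d)
          length(intersect(d, gids)) / length(union(d, gids)), numeric(1)))
      stage_r <- growth_metrics(pt$expr$values, gids, gids, pt$stages,
                                modules = stats::setNames(list(gids), mid))
      within <- stage_r$module_mean_abs_r[1, ]
      list(module_id = mid, tissue = t, jaccard = jac,
           stage_mean_abs_r = within,
           strictly_increasing = all(diff(within) > 0))
    })
    names(rep_mod) <- mods$module_id
  }
  list(ar = rep_ar, specificity = rep_spec, modules = rep_mod)
}
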