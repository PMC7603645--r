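# Stage-binned AR-lncRNA~AR-mRNA co-expression networks, consensus
# construction, walktrap modules, growth metrics and partner lists.

#' Bin samples of one tissue into four age stages
#'
#' Adjacent age points are pooled: stage 1 = 8 & 26 weeks, stage 2 = 26 &
#' 60, stage 3 = 60 & 78, stage 4 = 78 & 104. Every canonical age must be
#' present and no other age may occur.
#'
#' @param meta sample metadata (`sample_id`, `tissue`, `age_weeks`).
#' @param tissue tissue to bin.
#' @param age_points the canonical ages, strictly increasing.
#' @return named list `stage1`..`stage4` of sample id vectors, with the
#'   stage definition in `attr(, "definition")`.
#' @export
bin_stages <- function(meta, tissue, age_points = c(8, 26, 60, 78, 104)) {
  sub <- meta[meta$tissue == tissue, , drop = FALSE]
  assert_that(nrow(sub) > 0, sprintf("no samples for tissue '%s'", tissue))
  extra <- setdiff(unique(sub$age_weeks), age_points)
  assert_that(length(extra) == 0,
              sprintf("non-canonical age point(s) in tissue '%s': %s",
                      tissue, paste(extra, collapse = ", ")))
  missing <- setdiff(age_points, unique(sub$age_weeks))
  assert_that(length(missing) == 0,
              sprintf("tissue '%s' is missing age point(s): %s", tissue,
                      paste(missing, collapse = ", ")))
  stages <- lapply(seq_len(length(age_points) - 1), function(s)
    sub$sample_id[sub$age_weeks %in% age_points[c(s, s + 1)]])
  names(stages) <- paste0("stage", seq_along(stages))
  attr(stages, "definition") <- vapply(seq_along(stages), function(s)
    sprintf("%gw&%gw", age_points[s], age_points[s + 1]), character(1))
  stages
}

#' lncRNA~mRNA correlation edges within one stage
#'
#' Pearson correlation between every lncRNA and every mRNA over the stage's
#' samples (per-gene z-scoring within the stage is applied; it does not
#' change Pearson r), p-values from the t-transform, and BH adjustment over
#' all tested pairs of the tissue x stage. An edge is significant iff
#' `r > r_min` (signed by default) and `q < q_max`. Zero-variance genes are
#' skipped and recorded in `attr(, "skipped")`.
#'
#' @param values log2 expression matrix (genes x samples).
#' @param lnc_ids,mrna_ids node candidate sets (non-empty).
#' @param sample_ids the stage's samples (>= 4).
#' @param r_min,q_max edge thresholds.
#' @param signed apply the threshold to signed r (`r > r_min`); if `FALSE`,
#'   to `|r|`.
#' @return data frame of all tested pairs: lnc_id, mrna_id, r, p, q,
#'   significant.
#' @export
stage_edges <- function(values, lnc_ids, mrna_ids, sample_ids,
                        r_min = 0.9, q_max = 0.05, signed = TRUE) {
  assert_that(length(sample_ids) >= 4, "need >= 4 samples in a stage")
  assert_that(length(lnc_ids) > 0 && length(mrna_ids) > 0,
              "both node sets must be non-empty")
  lnc_ids <- intersect(lnc_ids, rownames(values))
  mrna_ids <- intersect(mrna_ids, rownames(values))
  x <- values[lnc_ids, sample_ids, drop = FALSE]
  y <- values[mrna_ids, sample_ids, drop = FALSE]
  sd_x <- apply(x, 1, stats::sd); sd_y <- apply(y, 1, stats::sd)
  skipped <- c(rownames(x)[sd_x == 0], rownames(y)[sd_y == 0])
  zscore <- function(m, s) {
    z <- (m - rowMeans(m)) / ifelse(s > 0, s, 1)
    z[s == 0, ] <- NA_real_  # degenerate genes: pairs reported but untested
    z
  }
  n <- length(sample_ids)
  r <- suppressWarnings(stats::cor(t(zscore(x, sd_x)), t(zscore(y, sd_y))))
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(r) == 1] <- 0
  out <- data.frame(lnc_id = rep(rownames(r), times = ncol(r)),
                    mrna_id = rep(colnames(r), each = nrow(r)),
                    r = as.vector(r), p = as.vector(p),
                    stringsAsFactors = FALSE)
  tested <- is.finite(out$p)
  out$q <- NA_real_
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  r_eff <- if (signed) out$r else abs(out$r)
  out$significant <- tested & !is.na(r_eff) & r_eff > r_min &
    out$q < q_max
  if (length(skipped)) {
    message(sprintf("%d zero-variance gene(s) skipped in stage edge scan",
                    length(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Consensus AR-lncRNA~AR-mRNA network
#'
#' Builds the per-tissue consensus graph from the youngest and oldest
#' stages: the edge set is the union (default) of pairs significant in
#' stage 1 or stage 4 (an intersection mode is available), and every edge
#' carries its correlation at all four stages so network growth can be
#' tracked. The graph is bipartite (lncRNA~mRNA edges only).
#'
#' @param edge_list list of four data frames from [stage_edges()], one per
#'   stage (all covering the same pairs).
#' @param mode `"union"` (significant in stage 1 or 4) or `"intersection"`.
#' @return object of class `consensus_network`: list with `edges` (lnc_id,
#'   mrna_id, r1..r4, q1..q4, stages_significant), `graph` (igraph),
#'   `nodes`, `lnc`, `mrna`, `mode`. Empty networks are returned with a
#'   warning, not an error.
#' @export
consensus_network <- function(edge_list, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  assert_that(length(edge_list) == 4, "need edges for all four stages")
  key <- paste(edge_list[[1]]$lnc_id, edge_list[[1]]$mrna_id)
  for (e in edge_list[-1]) {
    assert_that(identical(paste(e$lnc_id, e$mrna_id), key),
                "stage edge tables must cover the same pairs in the same order")
  }
  sig <- vapply(edge_list, function(e) e$significant, logical(length(key)))
  if (length(key) == 0) sig <- matrix(FALSE, 0, 4)
  keep <- if (mode == "union") sig[, 1] | sig[, 4] else sig[, 1] & sig[, 4]
  edges <- data.frame(lnc_id = edge_list[[1]]$lnc_id[keep],
                      mrna_id = edge_list[[1]]$mrna_id[keep],
                      stringsAsFactors = FALSE)
  for (s in 1:4) {
    edges[[paste0("r", s)]] <- edge_list[[s]]$r[keep]
    edges[[paste0("q", s)]] <- edge_list[[s]]$q[keep]
  }
  edges$stages_significant <- apply(sig[keep, , drop = FALSE], 1, function(z)
    paste(which(z), collapse = ";"))
  if (nrow(edges) == 0) warning("consensus network has no edges")
  lnc <- unique(edges$lnc_id); mrna <- unique(edges$mrna_id)
  g <- igraph::graph_from_data_frame(
    edges[, c("lnc_id", "mrna_id", "r1", "r2", "r3", "r4")],
    directed = FALSE,
    vertices = data.frame(name = c(lnc, mrna),
                          biotype = rep(c("lncRNA", "mRNA"),
                                        c(length(lnc), length(mrna)))))
  structure(list(edges = edges, graph = g, nodes = c(lnc, mrna),
                 lnc = lnc, mrna = mrna, mode = mode),
            class = "consensus_network")
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf("consensus_network (%s of stages 1/4): %d edges, %d lncRNAs ~ %d mRNAs\n",
              x$mode, nrow(x$edges), length(x$lnc), length(x$mrna)))
  invisible(x)
}

#' Walktrap module detection on a consensus network
#'
#' Random-walk community detection (`igraph::cluster_walktrap`, 10-step
#' walks by default) on the unweighted consensus graph; communities with
#' more than `min_size` genes are retained.
#'
#' @param network a `consensus_network`.
#' @param steps walk length.
#' @param min_size retain modules with strictly more genes than this.
#' @param weighted weight the walk by the stage-4 correlation.
#' @return object of class `module_set`: list with `membership` (data frame
#'   module_id, gene_id, biotype), `modules` (named list of gene id
#'   vectors), `steps`, `min_size`. Edge-less networks yield zero modules.
#' @export
detect_modules <- function(network, steps = 10, min_size = 30,
                           weighted = FALSE) {
  assert_that(inherits(network, "consensus_network"),
              "network must be a consensus_network")
  empty <- structure(list(membership = data.frame(module_id = character(),
                                                  gene_id = character(),
                                                  biotype = character()),
                          modules = list(), steps = steps,
                          min_size = min_size),
                     class = "module_set")
  if (nrow(network$edges) == 0) return(empty)
  w <- if (weighted) abs(igraph::E(network$graph)$r4) else NULL
  wt <- igraph::cluster_walktrap(network$graph, steps = steps, weights = w)
  memb <- igraph::membership(wt)
  sizes <- table(memb)
  keep_comm <- names(sizes)[sizes > min_size]
  if (length(keep_comm) == 0) return(empty)
  keep_comm <- keep_comm[order(-sizes[keep_comm])]
  modules <- lapply(keep_comm, function(cc) sort(names(memb)[memb == cc]))
  names(modules) <- sprintf("M%02d", seq_along(modules))
  biotype_of <- stats::setNames(igraph::V(network$graph)$biotype,
                                igraph::V(network$graph)$name)
  membership <- data.frame(
    module_id = rep(names(modules), lengths(modules)),
    gene_id = unlist(modules, use.names = FALSE),
    stringsAsFactors = FALSE)
  membership$biotype <- biotype_of[membership$gene_id]
  structure(list(membership = membership, modules = modules,
                 steps = steps, min_size = min_size),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d module(s) > %d genes (walktrap, %d steps)\n",
              length(x$modules), x$min_size, x$steps))
  if (length(x$modules)) {
    for (m in names(x$modules))
      cat(sprintf("  %s: %d genes\n", m, length(x$modules[[m]])))
  }
  invisible(x)
}

#' Stage-wise network growth metrics
#'
#' Per stage: the mean absolute Pearson correlation over all
#' AR-lncRNA x AR-mRNA pairs, the count of pairs above the edge threshold,
#' and (optionally) the mean absolute within-module correlation over all
#' gene pairs of each supplied module. The monotone flag records whether
#' the global mean |r| increases strictly from stage 1 to 4.
#'
#' @param values log2 expression matrix.
#' @param lnc_ids,mrna_ids AR node sets.
#' @param stages stage binning from [bin_stages()].
#' @param modules optional named list of gene id vectors (e.g. detected or
#'   planted modules).
#' @param r_edge threshold for the strong-pair count.
#' @return list: `per_stage` (data frame stage, n_pairs, mean_abs_r,
#'   n_strong), `module_mean_abs_r` (module x stage matrix or NULL),
#'   `monotone_increase`.
#' @export
growth_metrics <- function(values, lnc_ids, mrna_ids, stages,
                           modules = NULL, r_edge = 0.9) {
  lnc_ids <- intersect(lnc_ids, rownames(values))
  mrna_ids <- intersect(mrna_ids, rownames(values))
  per_stage <- do.call(rbind, lapply(seq_along(stages), function(s) {
    ids <- stages[[s]]
    r <- suppressWarnings(stats::cor(t(values[lnc_ids, ids, drop = FALSE]),
                                     t(values[mrna_ids, ids, drop = FALSE])))
    r <- r[is.finite(r)]
    data.frame(stage = s, n_pairs = length(r),
               mean_abs_r = mean(abs(r)), n_strong = sum(r > r_edge))
  }))
  module_r <- NULL
  if (!is.null(modules) && length(modules)) {
    module_r <- t(vapply(modules, function(gids) {
      gids <- intersect(gids, rownames(values))
      vapply(stages, function(ids) {
        r <- suppressWarnings(stats::cor(t(values[gids, ids, drop = FALSE])))
        mean(abs(r[upper.tri(r)]), na.rm = TRUE)
      }, numeric(1))
    }, numeric(length(stages))))
    colnames(module_r) <- names(stages)
  }
  list(per_stage = per_stage,
       module_mean_abs_r = module_r,
       monotone_increase = all(diff(per_stage$mean_abs_r) > 0))
}

#' Co-expressed mRNA partners of one lncRNA
#'
#' All detectable mRNAs whose Pearson correlation with the lncRNA over the
#' tissue's samples (all ages pooled) exceeds `r_min` (signed) at BH
#' adjusted p < `q_max`; the basis of guilt-by-association annotation.
#'
#' @param values log2 expression matrix (detectable genes of the tissue).
#' @param lnc_id the lncRNA (must be detectable, i.e. a row of `values`).
#' @param mrna_ids candidate mRNA ids.
#' @param sample_ids samples to correlate over (default: all columns).
#' @param r_min,q_max partner thresholds.
#' @return character vector of partner mRNA ids; the full correlation table
#'   in `attr(, "table")`.
#' @export
coexpressed_partners <- function(values, lnc_id, mrna_ids,
                                 sample_ids = colnames(values),
                                 r_min = 0.8, q_max = 0.05) {
  assert_that(lnc_id %in% rownames(values),
              sprintf("lncRNA '%s' is not detectable here", lnc_id))
  mrna_ids <- intersect(mrna_ids, rownames(values))
  assert_that(length(mrna_ids) > 0, "no detectable candidate mRNAs")
  y <- values[lnc_id, sample_ids]
  assert_that(stats::sd(y) > 0,
              sprintf("lncRNA '%s' has zero variance", lnc_id))
  tab <- row_cor_test(values[mrna_ids, sample_ids, drop = FALSE], y)
  ok <- !is.na(tab$r)
  tab$q <- NA_real_
  tab$q[ok] <- stats::p.adjust(tab$p[ok], method = "BH")
  partners <- rownames(tab)[ok & tab$r > r_min & tab$q < q_max]
  tab <- data.frame(mrna_id = rownames(tab), r = tab$r, p = tab$p, q = tab$q,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(partners, "table") <- tab
  partners
}
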