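# Aging-correlated genes, differential expression, AR gene sets, cross-tissue
# sharing and feature comparisons.

subset_tissue <- function(expr, meta, tissue) {
  ids <- meta$sample_id[meta$tissue == tissue]
  assert_that(length(ids) > 0, sprintf("no samples for tissue '%s'", tissue))
  ids <- intersect(colnames(expr$values), ids)
  list(values = expr$values[, ids, drop = FALSE],
       meta = meta[match(ids, meta$sample_id), , drop = FALSE])
}

#' Aging-correlated genes in one tissue
#'
#' Pearson correlation of log2 expression against log2(age in weeks) over
#' all samples of a tissue, with the t-transform p-value
#' (`t = r * sqrt((n - 2) / (1 - r^2))`, n - 2 df). A gene is called
#' aging-correlated iff `|r| > r_min` and `p < p_max`; both signs are
#' reported. Zero-variance genes are excluded and flagged, not an error.
#'
#' @param expr an `expr_matrix` (log2 values used).
#' @param meta sample metadata with `sample_id`, `tissue`, `age_weeks`.
#' @param tissue tissue to analyse.
#' @param r_min,p_max calling thresholds (strict inequalities).
#' @param per_age_means correlate per-age replicate means instead of all
#'   replicate samples.
#' @return data frame: gene_id, tissue, r, p, direction, called, degenerate.
#' @export
aging_correlation <- function(expr, meta, tissue, r_min = 0.9, p_max = 0.05,
                              per_age_means = FALSE) {
  sub <- subset_tissue(expr, meta, tissue)
  vals <- sub$values
  age <- sub$meta$age_weeks
  assert_that(length(unique(age)) >= 3,
              sprintf("tissue '%s' needs >= 3 distinct ages", tissue))
  if (per_age_means) {
    uages <- sort(unique(age))
    vals <- vapply(uages, function(a)
      rowMeans(vals[, age == a, drop = FALSE]), numeric(nrow(vals)))
    colnames(vals) <- as.character(uages)
    age <- uages
  }
  x <- log2(age)
  degenerate <- apply(vals, 1, stats::sd) == 0
  res <- data.frame(gene_id = rownames(vals), tissue = tissue,
                    r = NA_real_, p = NA_real_,
                    direction = NA_character_, called = FALSE,
                    degenerate = degenerate, stringsAsFactors = FALSE)
  ok <- !degenerate
  if (any(ok)) {
    ct <- row_cor_test(vals[ok, , drop = FALSE], x)
    res$r[ok] <- ct$r
    res$p[ok] <- ct$p
    res$direction[ok] <- ifelse(ct$r >= 0, "positive", "negative")
    res$called[ok] <- abs(ct$r) > r_min & ct$p < p_max
  }
  rownames(res) <- NULL
  res
}

#' Differential expression between two age groups of one tissue
#'
#' Per-gene Welch t-test on log2 expression (old minus young), with
#' Benjamini-Hochberg FDR within the (tissue, contrast) family.
#'
#' @inheritParams aging_correlation
#' @param old_age,young_age ages (weeks) defining the contrast.
#' @return data frame: gene_id, tissue, old_age, young_age, log2FC, t, p, fdr.
#' @export
differential_expression <- function(expr, meta, tissue, old_age, young_age) {
  sub <- subset_tissue(expr, meta, tissue)
  idx_old <- which(sub$meta$age_weeks == old_age)
  idx_young <- which(sub$meta$age_weeks == young_age)
  assert_that(length(idx_old) > 0,
              sprintf("tissue '%s': no samples at %g weeks", tissue, old_age))
  assert_that(length(idx_young) > 0,
              sprintf("tissue '%s': no samples at %g weeks", tissue, young_age))
  w <- row_welch(sub$values, idx_old, idx_young)
  data.frame(gene_id = rownames(sub$values), tissue = tissue,
             old_age = old_age, young_age = young_age,
             log2FC = w$log2FC, t = w$t, p = w$p,
             fdr = stats::p.adjust(w$p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Call aging-regulated (AR) genes of one tissue
#'
#' A gene is AR iff `|log2FC| > fc_min` and `FDR < fdr_max` (strict) in at
#' least one of the two old-age contrasts (78 vs 8 or 104 vs 8 weeks in the
#' canonical design). The reported `log2FC_old_young` is the signed fold
#' change of larger magnitude among the two old contrasts (computed for
#' every tested gene, AR or not). Genes qualifying in both contrasts with
#' opposite signs are kept with direction `"discordant"`.
#'
#' @param de_list list of data frames from [differential_expression()], one
#'   per old contrast (typically 78 vs 8 and 104 vs 8).
#' @param genes gene annotation with `gene_id` and `biotype`.
#' @param fc_min,fdr_max calling thresholds (strict inequalities).
#' @return object of class `ar_set`: list with `tissue`, `members` (data
#'   frame: gene_id, biotype, direction, contrasts, log2FC_old_young),
#'   `fc_all` (log2FC_old_young for every tested gene) and thresholds.
#' @export
call_aging_regulated <- function(de_list, genes, fc_min = 0.75,
                                 fdr_max = 0.1) {
  assert_that(length(de_list) >= 2,
              "both old-age contrasts are required to call AR genes")
  tissue <- unique(vapply(de_list, function(d) d$tissue[1], character(1)))
  assert_that(length(tissue) == 1, "all contrasts must come from one tissue")
  ids <- de_list[[1]]$gene_id
  for (d in de_list) assert_that(identical(d$gene_id, ids),
                                 "contrasts must cover the same genes")
  fc <- vapply(de_list, function(d) d$log2FC, numeric(length(ids)))
  fdr <- vapply(de_list, function(d) d$fdr, numeric(length(ids)))
  contrast_lab <- vapply(de_list, function(d)
    sprintf("%gv%g", d$old_age[1], d$young_age[1]), character(1))

  pass <- abs(fc) > fc_min & fdr < fdr_max
  which_larger <- max.col(abs(fc), ties.method = "first")
  fc_old_young <- fc[cbind(seq_along(ids), which_larger)]
  is_ar <- rowSums(pass) > 0

  dir_of <- function(i) {
    signs <- unique(sign(fc[i, pass[i, ]]))
    if (length(signs) > 1) "discordant" else if (signs > 0) "up" else "down"
  }
  members <- data.frame(gene_id = ids[is_ar], stringsAsFactors = FALSE)
  if (nrow(members)) {
    members$biotype <- genes$biotype[match(members$gene_id, genes$gene_id)]
    members$direction <- vapply(which(is_ar), dir_of, character(1))
    members$contrasts <- vapply(which(is_ar), function(i)
      paste(contrast_lab[pass[i, ]], collapse = ";"), character(1))
    members$log2FC_old_young <- fc_old_young[is_ar]
  } else {
    members$biotype <- character(0); members$direction <- character(0)
    members$contrasts <- character(0); members$log2FC_old_young <- numeric(0)
  }
  n_disc <- sum(members$direction == "discordant")
  if (n_disc > 0) {
    message(sprintf("tissue '%s': %d AR gene(s) with discordant directions kept",
                    tissue, n_disc))
  }
  structure(list(tissue = tissue, members = members,
                 fc_all = stats::setNames(fc_old_young, ids),
                 fc_min = fc_min, fdr_max = fdr_max,
                 contrasts = contrast_lab),
            class = "ar_set")
}

#' @export
print.ar_set <- function(x, ...) {
  tab <- table(factor(x$members$biotype, levels = c("lncRNA", "mRNA")))
  cat(sprintf("AR set [%s]: %d genes (%d lncRNA, %d mRNA); |log2FC| > %g & FDR < %g in %s\n",
              x$tissue, nrow(x$members), tab["lncRNA"], tab["mRNA"],
              x$fc_min, x$fdr_max, paste(x$contrasts, collapse = " or ")))
  invisible(x)
}

ar_ids <- function(ar, biotype = NULL) {
  m <- ar$members
  if (!is.null(biotype)) m <- m[m$biotype == biotype, , drop = FALSE]
  m$gene_id
}

#' Cross-tissue sharing of AR genes
#'
#' Counts, per gene, in how many tissues it was called AR, and summarises
#' the percentage of AR genes found in exactly 1, 2, 3, or more than 3
#' tissues, split by biotype.
#'
#' @param ar_sets named list of `ar_set` objects (>= 2 tissues).
#' @return list with `per_gene` (gene_id, biotype, n_tissues, tissues) and
#'   `summary` (biotype x sharing-class percentage table).
#' @export
cross_tissue_overlap <- function(ar_sets) {
  assert_that(length(ar_sets) >= 2, "need AR sets from >= 2 tissues")
  long <- do.call(rbind, lapply(ar_sets, function(a)
    a$members[, c("gene_id", "biotype")]))
  tissue_of <- rep(vapply(ar_sets, function(a) a$tissue, character(1)),
                   vapply(ar_sets, function(a) nrow(a$members), integer(1)))
  per_gene <- stats::aggregate(list(n_tissues = tissue_of),
                               by = list(gene_id = long$gene_id),
                               FUN = length)
  per_gene$biotype <- long$biotype[match(per_gene$gene_id, long$gene_id)]
  per_gene$tissues <- vapply(per_gene$gene_id, function(g)
    paste(sort(tissue_of[long$gene_id == g]), collapse = ";"), character(1))
  cls <- cut(per_gene$n_tissues, breaks = c(0, 1, 2, 3, Inf),
             labels = c("1", "2", "3", ">3"))
  tab <- table(per_gene$biotype, cls)
  pct <- prop.table(tab, margin = 1) * 100
  list(per_gene = per_gene[, c("gene_id", "biotype", "n_tissues", "tissues")],
       summary = pct)
}

#' Compare structural features of two gene sets
#'
#' Two-sided Mann-Whitney tests on gene length, isoform number, exon number
#' (and mean expression when an expression matrix is supplied), reporting
#' group medians and p-values. Typical use: AR-lncRNAs vs aging
#' non-regulated lncRNAs.
#'
#' @param genes gene annotation with the feature columns.
#' @param setA,setB gene id vectors (both non-empty).
#' @param features annotation columns to test.
#' @param expr optional `expr_matrix`; adds a `mean_expr` feature.
#' @return data frame: feature, median_A, median_B, p.
#' @export
compare_gene_features <- function(genes, setA, setB,
                                  features = c("length_bp", "n_isoforms",
                                               "n_exons"),
                                  expr = NULL) {
  assert_that(length(setA) > 0 && length(setB) > 0,
              "both gene sets must be non-empty")
  missing <- setdiff(features, colnames(genes))
  assert_that(length(missing) == 0,
              sprintf("missing feature column(s): %s",
                      paste(missing, collapse = ", ")))
  feat <- genes[, c("gene_id", features), drop = FALSE]
  if (!is.null(expr)) {
    me <- rowMeans(expr$values)
    feat$mean_expr <- me[match(feat$gene_id, names(me))]
    features <- c(features, "mean_expr")
  }
  a <- feat[match(setA, feat$gene_id), , drop = FALSE]
  b <- feat[match(setB, feat$gene_id), , drop = FALSE]
  do.call(rbind, lapply(features, function(f) {
    xa <- stats::na.omit(a[[f]]); xb <- stats::na.omit(b[[f]])
    p <- suppressWarnings(stats::wilcox.test(xa, xb,
                                             alternative = "two.sided")$p.value)
    data.frame(feature = f, median_A = stats::median(xa),
               median_B = stats::median(xb), p = p,
               stringsAsFactors = FALSE)
  }))
}
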