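# Fractional-expression specificity over tissues and ages, threshold
# classification, quantile grouping and the regulation-shift comparison.

#' Fractional expression profiles
#'
#' For each gene, the fraction of its expression falling in each category
#' (tissue at a fixed age, or age within a fixed tissue), computed on
#' replicate means of linear FPKM. The specificity score is the maximum
#' fraction: 1 = exclusive to one category, 1/k = uniform over k categories.
#' For the age axis the standard deviation of the fractions is also
#' reported. Genes with zero total expression are excluded and recorded in
#' the `"excluded"` attribute.
#'
#' @param fpkm linear FPKM matrix (genes x samples).
#' @param meta sample metadata (`sample_id`, `tissue`, `age_weeks`).
#' @param axis `"tissue"` (across tissues at one age) or `"age"` (across
#'   ages within one tissue).
#' @param at the fixed level: an age in weeks for `axis = "tissue"`, a
#'   tissue name for `axis = "age"`.
#' @return data frame: gene_id, one fraction column per category, `score`,
#'   and `sd_fractions` for the age axis; excluded gene ids in
#'   `attr(, "excluded")`.
#' @export
fractional_profile <- function(fpkm, meta, axis = c("tissue", "age"), at) {
  axis <- match.arg(axis)
  fpkm <- as.matrix(fpkm)
  if (axis == "tissue") {
    meta_use <- meta[meta$age_weeks == at, , drop = FALSE]
    assert_that(nrow(meta_use) > 0, sprintf("no samples at %s weeks", at))
    category <- meta_use$tissue
  } else {
    meta_use <- meta[meta$tissue == at, , drop = FALSE]
    assert_that(nrow(meta_use) > 0, sprintf("no samples for tissue '%s'", at))
    category <- as.character(meta_use$age_weeks)
  }
  ids <- intersect(meta_use$sample_id, colnames(fpkm))
  assert_that(length(ids) > 0, "no matching sample columns")
  category <- category[match(ids, meta_use$sample_id)]
  cats <- if (axis == "age") {
    as.character(sort(unique(meta_use$age_weeks)))
  } else sort(unique(category))
  means <- vapply(cats, function(cc)
    rowMeans(fpkm[, ids[category == cc], drop = FALSE]),
    numeric(nrow(fpkm)))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1,
                    dimnames = list(rownames(fpkm), cats))
  }
  total <- rowSums(means)
  excluded <- rownames(fpkm)[total == 0]
  keep <- total > 0
  frac <- means[keep, , drop = FALSE] / total[keep]
  out <- data.frame(gene_id = rownames(fpkm)[keep], frac,
                    score = apply(frac, 1, max),
                    check.names = FALSE, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (axis == "age") out$sd_fractions <- apply(frac, 1, stats::sd)
  attr(out, "excluded") <- excluded
  attr(out, "axis") <- axis
  attr(out, "at") <- at
  out
}

#' Percentage of specific genes per threshold and group
#'
#' For each score threshold, the percentage of each gene group (e.g.
#' AR-lncRNAs vs ANR-lncRNAs) whose specificity score strictly exceeds it.
#'
#' @param profiles output of [fractional_profile()] (tissue axis).
#' @param groups named list of gene id vectors.
#' @param thresholds score cutoffs.
#' @return data frame: group, threshold, n, pct_specific.
#' @export
classify_specific <- function(profiles, groups,
                              thresholds = c(0.25, 0.3, 0.35, 0.4, 0.45, 0.5)) {
  assert_that(length(groups) > 0 && !is.null(names(groups)),
              "groups must be a named list")
  scores <- stats::setNames(profiles$score, profiles$gene_id)
  do.call(rbind, lapply(names(groups), function(gname) {
    s <- scores[intersect(groups[[gname]], names(scores))]
    assert_that(length(s) > 0, sprintf("empty gene group '%s'", gname))
    data.frame(group = gname, threshold = thresholds,
               n = length(s),
               pct_specific = vapply(thresholds, function(th)
                 100 * mean(s > th), numeric(1)),
               stringsAsFactors = FALSE)
  }))
}

#' Top/bottom quantile groups by specificity score
#'
#' Ranks genes by score (descending) and returns the top fraction as the
#' specific set and the bottom fraction as the control set. Ties are broken
#' by gene id so that both sets have exactly `floor(frac * n)` members.
#'
#' @param scores named numeric vector (gene id -> score), >= 5 genes.
#' @param top_frac,bottom_frac quantile fractions (sum must be <= 1).
#' @return list with `specific` and `control` gene id vectors.
#' @export
quantile_groups <- function(scores, top_frac = 0.2, bottom_frac = 0.2) {
  assert_that(length(scores) >= 5, "need >= 5 scored genes")
  assert_that(top_frac > 0 && bottom_frac > 0 && top_frac + bottom_frac <= 1,
              "overlapping quantiles: top_frac + bottom_frac must be <= 1")
  ord <- order(-scores, names(scores))
  n_top <- floor(top_frac * length(scores))
  n_bot <- floor(bottom_frac * length(scores))
  list(specific = names(scores)[ord[seq_len(n_top)]],
       control = names(scores)[rev(ord)[seq_len(n_bot)]])
}

#' Aging-regulation shift between tissue-specific and control genes
#'
#' Compares the old-vs-young log2 fold changes of the tissue-specific and
#' control groups: empirical CDFs over signed and absolute fold change,
#' two-sided Mann-Whitney p-values, and the percentage of each group called
#' aging-regulated.
#'
#' @param fc named numeric vector of log2FC(old/young) per gene (the signed
#'   larger-magnitude fold change among the two old contrasts).
#' @param specific,control gene id vectors (non-empty, fold changes
#'   available for all members).
#' @param ar_set an `ar_set` or a vector of AR gene ids.
#' @return list: `ecdf_signed`/`ecdf_abs` (per-group ECDF functions),
#'   `fc` (long data frame for plotting), `p_abs`, `p_signed`,
#'   `ar_rate` (percentages per group).
#' @export
regulation_shift <- function(fc, specific, control, ar_set) {
  assert_that(length(specific) > 0 && length(control) > 0,
              "both groups must be non-empty")
  missing <- setdiff(c(specific, control), names(fc))
  assert_that(length(missing) == 0,
              sprintf("no fold change for gene(s): %s",
                      first_offenders(missing)))
  ar_ids_vec <- if (inherits(ar_set, "ar_set")) ar_set$members$gene_id else ar_set
  fs <- fc[specific]; fcn <- fc[control]
  p_signed <- suppressWarnings(stats::wilcox.test(fs, fcn)$p.value)
  p_abs <- suppressWarnings(stats::wilcox.test(abs(fs), abs(fcn))$p.value)
  list(ecdf_signed = list(specific = stats::ecdf(fs),
                          control = stats::ecdf(fcn)),
       ecdf_abs = list(specific = stats::ecdf(abs(fs)),
                       control = stats::ecdf(abs(fcn))),
       fc = data.frame(gene_id = c(specific, control),
                       group = rep(c("specific", "control"),
                                   c(length(specific), length(control))),
                       log2FC = c(fs, fcn), row.names = NULL,
                       stringsAsFactors = FALSE),
       p_signed = p_signed, p_abs = p_abs,
       ar_rate = c(specific = 100 * mean(specific %in% ar_ids_vec),
                   control = 100 * mean(control %in% ar_ids_vec)))
}
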