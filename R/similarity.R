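# Tissue-similarity scores between AR gene sets and abundance matching.

#' Similarity score between two gene sets
#'
#' Weighted combination of the Jaccard index (union term, weight 0.8) and
#' the overlap coefficient (intersection term, weight 0.2), following the
#' enrichment-map style combined set-similarity coefficient:
#' `score = w_u * |A n B| / |A u B| + w_i * |A n B| / min(|A|, |B|)`.
#' Bounded in `[0, 1]`, symmetric, 1 iff the (non-empty) sets are equal and
#' 0 iff they are disjoint. `mode = "raw"` exposes the literal
#' raw-cardinality reading `w_u * |A u B| + w_i * |A n B|` for audit only
#' (unbounded; not used by the pipeline).
#'
#' @param setA,setB gene id vectors (at least one non-empty).
#' @param weight_u,weight_i weights of the union (Jaccard) and intersection
#'   (overlap-coefficient) terms.
#' @param mode `"combined"` (default) or `"raw"`.
#' @return numeric score.
#' @export
similarity_score <- function(setA, setB, weight_u = 0.8, weight_i = 0.2,
                             mode = c("combined", "raw")) {
  mode <- match.arg(mode)
  setA <- unique(setA); setB <- unique(setB)
  assert_that(length(setA) > 0 || length(setB) > 0,
              "similarity of two empty sets is undefined")
  n_int <- length(intersect(setA, setB))
  n_uni <- length(union(setA, setB))
  if (mode == "raw") return(weight_u * n_uni + weight_i * n_int)
  if (length(setA) == 0 || length(setB) == 0) return(0)
  weight_u * n_int / n_uni + weight_i * n_int / min(length(setA), length(setB))
}

#' Pairwise tissue-similarity matrix of AR sets
#'
#' Scores every unordered tissue pair with [similarity_score()], separately
#' per biotype (AR-lncRNA and AR-mRNA matrices are compared triangle against
#' triangle). Tissues with an empty AR set score 0 against every other
#' tissue, with a warning.
#'
#' @param ar_sets named list of `ar_set` objects (>= 2 tissues).
#' @param biotype `"lncRNA"` or `"mRNA"`.
#' @inheritParams similarity_score
#' @return symmetric matrix of scores with tissue dimnames; diagonal 1 for
#'   non-empty sets.
#' @export
pairwise_similarity <- function(ar_sets, biotype = c("lncRNA", "mRNA"),
                                weight_u = 0.8, weight_i = 0.2) {
  biotype <- match.arg(biotype)
  assert_that(length(ar_sets) >= 2, "need >= 2 tissues")
  tissues <- vapply(ar_sets, function(a) a$tissue, character(1))
  sets <- lapply(ar_sets, ar_ids, biotype = biotype)
  names(sets) <- tissues
  empty <- vapply(sets, length, integer(1)) == 0
  if (any(empty)) {
    warning(sprintf("empty AR-%s set(s) in: %s; scored 0", biotype,
                    paste(tissues[empty], collapse = ", ")))
  }
  k <- length(sets)
  m <- matrix(0, k, k, dimnames = list(tissues, tissues))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (length(sets[[i]]) == 0 && length(sets[[j]]) == 0) {
        m[i, j] <- 0
      } else {
        m[i, j] <- similarity_score(sets[[i]], sets[[j]],
                                    weight_u = weight_u, weight_i = weight_i)
      }
    }
  }
  m
}

#' Abundance-matched lncRNA and mRNA subsets
#'
#' Removes the abundance gap between lncRNAs and mRNAs before comparing
#' them: mean log2 expression is cut into quantile bins on the pooled
#' distribution and, within each bin, equal numbers of genes are sampled
#' without replacement from both biotypes (bin capacity = the smaller of the
#' two counts). Deterministic for a fixed seed.
#'
#' @param lnc_ids,mrna_ids candidate gene ids (both non-empty).
#' @param mean_expr named numeric vector of mean log2 expression.
#' @param n_bins number of quantile bins on the pooled abundance.
#' @param seed integer seed for the within-bin sampling.
#' @return list with `lnc` and `mrna` matched gene id vectors.
#' @export
abundance_matched_subsets <- function(lnc_ids, mrna_ids, mean_expr,
                                      n_bins = 10, seed = 1L) {
  assert_that(length(lnc_ids) > 0 && length(mrna_ids) > 0,
              "both biotype lists must be non-empty")
  missing <- setdiff(c(lnc_ids, mrna_ids), names(mean_expr))
  assert_that(length(missing) == 0,
              sprintf("no expression for gene(s): %s",
                      first_offenders(missing)))
  pooled <- mean_expr[c(lnc_ids, mrna_ids)]
  brks <- unique(stats::quantile(pooled, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(pooled, breaks = brks, include.lowest = TRUE)
  bin_l <- bin[seq_along(lnc_ids)]
  bin_m <- bin[length(lnc_ids) + seq_along(mrna_ids)]
  shared <- intersect(levels(droplevels(bin_l)), levels(droplevels(bin_m)))
  assert_that(length(shared) > 0, "no abundance bin holds both biotypes")
  set.seed(seed)
  pick <- function(ids, b, lev, n) {
    cand <- sort(ids[b == lev])
    if (length(cand) == n) cand else sample(cand, n)
  }
  out_l <- character(0); out_m <- character(0)
  for (lev in shared) {
    n <- min(sum(bin_l == lev), sum(bin_m == lev))
    if (n == 0) next
    out_l <- c(out_l, pick(lnc_ids, bin_l, lev, n))
    out_m <- c(out_m, pick(mrna_ids, bin_m, lev, n))
  }
  list(lnc = out_l, mrna = out_m)
}
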