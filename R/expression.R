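# Normalization, FPKM conversion and the detectability filter.

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values between-sample normalization (Robinson-Oshlack),
#' computed by edgeR: the reference is the sample whose upper quartile is
#' closest to the mean upper quartile, M-values are trimmed 30% and
#' A-values 5% by default, and the factors are rescaled to geometric mean 1.
#'
#' @param counts non-negative gene x sample count matrix (>= 2 samples).
#' @param trim_M,trim_A two-sided trim proportions on log-ratios (M) and
#'   average log-abundance (A).
#' @return named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_normalization_factors <- function(counts, trim_M = 0.3, trim_A = 0.05) {
  counts <- as.matrix(counts)
  assert_that(ncol(counts) >= 2,
              "TMM needs >= 2 samples (single-sample input)")
  assert_that(all(counts >= 0), "counts must be non-negative")
  zero <- colSums(counts) == 0
  if (any(zero)) {
    stop_ctx(sprintf("all-zero sample(s): %s",
                     first_offenders(colnames(counts)[zero] %||% which(zero))))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM",
                              logratioTrim = trim_M, sumTrim = trim_A)
  names(f) <- colnames(counts)
  f
}

#' FPKM from counts
#'
#' `FPKM[g, s] = count[g, s] / (length_kb[g] * effective_library_millions[s])`
#' with effective library = column sum x TMM factor.
#'
#' @param counts gene x sample count matrix with gene ids as rownames.
#' @param genes gene annotation data frame with `gene_id` and `length_bp`.
#' @param factors per-sample normalization factors (default all 1).
#' @return FPKM matrix with the same dimnames as `counts`.
#' @export
compute_fpkm <- function(counts, genes, factors = NULL) {
  counts <- as.matrix(counts)
  assert_that(!is.null(rownames(counts)), "counts must have gene ids as rownames")
  len <- genes$length_bp[match(rownames(counts), genes$gene_id)]
  bad <- is.na(len) | len <= 0
  if (any(bad)) {
    stop_ctx(sprintf("missing or non-positive length for gene(s): %s",
                     first_offenders(rownames(counts)[bad])))
  }
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  assert_that(length(factors) == ncol(counts),
              "one normalization factor per sample required")
  eff_lib <- colSums(counts) * factors
  assert_that(all(eff_lib > 0), "zero effective library size")
  sweep(counts / (len / 1000), 2, eff_lib / 1e6, "/")
}

#' Detectability filter and log2 transform
#'
#' A gene is detectable iff its FPKM exceeds `min_fpkm` (strictly) in at
#' least `ceiling(min_sample_frac * n_samples)` samples. Detectable genes
#' are carried forward as `log2(FPKM + pseudocount)`.
#'
#' @param fpkm non-negative FPKM matrix.
#' @param min_fpkm detectability threshold (strict `>`).
#' @param min_sample_frac fraction of samples required (ceiling rule).
#' @param pseudocount added before the log2 transform.
#' @param tmm_factors optional per-sample factors carried for provenance.
#' @return object of class `expr_matrix`: list with `values` (log2, kept
#'   genes), `fpkm` (linear, kept genes), `detectable` (named logical over
#'   all input genes), `pseudocount`, `min_fpkm`, `min_sample_frac`,
#'   `tmm_factors`.
#' @export
filter_detectable <- function(fpkm, min_fpkm = 0.5, min_sample_frac = 0.2,
                              pseudocount = 1, tmm_factors = NULL) {
  fpkm <- as.matrix(fpkm)
  assert_that(nrow(fpkm) > 0 && ncol(fpkm) > 0, "empty FPKM matrix")
  assert_that(all(fpkm >= 0), "FPKM must be non-negative")
  assert_that(pseudocount > 0, "pseudocount must be positive")
  need <- ceiling(min_sample_frac * ncol(fpkm))
  keep <- rowSums(fpkm > min_fpkm) >= need
  names(keep) <- rownames(fpkm)
  structure(list(values = log2(fpkm[keep, , drop = FALSE] + pseudocount),
                 fpkm = fpkm[keep, , drop = FALSE],
                 detectable = keep,
                 pseudocount = pseudocount,
                 min_fpkm = min_fpkm,
                 min_sample_frac = min_sample_frac,
                 tmm_factors = tmm_factors),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d detectable of %d genes x %d samples (FPKM > %g in >= %d%% samples; log2(FPKM + %g))\n",
              sum(x$detectable), length(x$detectable), ncol(x$values),
              x$min_fpkm, round(100 * x$min_sample_frac), x$pseudocount))
  invisible(x)
}

#' Normalize, convert and filter in one step
#'
#' Convenience wrapper: TMM factors over all samples, FPKM conversion, then
#' the detectability filter, optionally restricted to one tissue's samples.
#'
#' @param counts gene x sample counts.
#' @param genes gene annotation with `length_bp`.
#' @param sample_ids optional subset of columns (e.g. one tissue) to filter
#'   on; TMM factors are still computed across all provided samples.
#' @inheritParams filter_detectable
#' @return an `expr_matrix` (see [filter_detectable()]).
#' @export
normalize_expression <- function(counts, genes, sample_ids = NULL,
                                 min_fpkm = 0.5, min_sample_frac = 0.2,
                                 pseudocount = 1) {
  f <- tmm_normalization_factors(counts)
  fpkm <- compute_fpkm(counts, genes, f)
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, colnames(fpkm))
    assert_that(length(missing) == 0,
                sprintf("unknown sample id(s): %s", first_offenders(missing)))
    fpkm <- fpkm[, sample_ids, drop = FALSE]
    f <- f[sample_ids]
  }
  filter_detectable(fpkm, min_fpkm = min_fpkm,
                    min_sample_frac = min_sample_frac,
                    pseudocount = pseudocount, tmm_factors = f)
}
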