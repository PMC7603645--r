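# Local gene-set enrichment: GMT parsing, hypergeometric tests with
# term-size/query filters, BH adjustment, cross-tissue recurrence.

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: term id, description, then member gene ids.
#' Duplicate members within a term are stored once.
#'
#' @param path GMT file.
#' @return object of class `gene_set_collection`: named list of gene id
#'   vectors with a `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), sprintf("no such file: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  assert_that(length(lines) > 0, sprintf("empty GMT file: '%s'", path))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    stop_ctx(sprintf("malformed GMT line(s) (< 3 fields): %s",
                     first_offenders(bad)))
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  assert_that(!anyDuplicated(ids), "duplicate term ids in GMT")
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- ids
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[[`, character(1), 2), ids)
  class(sets) <- "gene_set_collection"
  sets
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement (wraps
#' `stats::p.adjust(method = "BH")` after validating the input).
#'
#' @param p numeric p-values in `[0, 1]`.
#' @return adjusted q-values.
#' @export
bh_adjust <- function(p) {
  assert_that(is.numeric(p) && !anyNA(p) && all(p >= 0) && all(p <= 1),
              "p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric gene-set enrichment
#'
#' For each term, restricted to the background, the upper-tail
#' hypergeometric probability of observing at least the overlap between the
#' query and the term. Terms are tested only when their in-background size
#' lies in `[min_term, max_term]`, results are reported only for overlaps
#' of at least `min_query` genes, q-values are BH-adjusted over the
#' reported terms, and a term is significant iff `q < fdr_max`. With
#' `ease = TRUE` the overlap is deflated by one before the tail probability
#' (the DAVID EASE variant).
#'
#' @param query gene ids (must be a subset of the background).
#' @param background background gene ids (typically the tissue's detectable
#'   genes).
#' @param collection a `gene_set_collection` or named list of gene id
#'   vectors.
#' @param min_term,max_term in-background term-size window.
#' @param min_query minimum overlap for a term to be reported.
#' @param fdr_max significance threshold on q.
#' @param ease use the EASE-deflated overlap.
#' @return data frame: term, description, overlap, query_size, term_size,
#'   background_size, p, q, significant.
#' @export
enrich <- function(query, background, collection, min_term = 10,
                   max_term = 400, min_query = 5, fdr_max = 0.1,
                   ease = FALSE) {
  query <- unique(query); background <- unique(background)
  stray <- setdiff(query, background)
  assert_that(length(stray) == 0,
              sprintf("query gene(s) not in background: %s",
                      first_offenders(stray)))
  N <- length(background)
  n_query <- length(query)
  desc <- attr(collection, "descriptions") %||%
    stats::setNames(rep(NA_character_, length(collection)), names(collection))
  rows <- lapply(names(collection), function(term) {
    members <- intersect(collection[[term]], background)
    K <- length(members)
    if (K < min_term || K > max_term) return(NULL)
    k <- length(intersect(members, query))
    if (k < min_query) return(NULL)
    k_eff <- if (ease) max(k - 1, 0) else k
    p <- stats::phyper(k_eff - 1, K, N - K, n_query, lower.tail = FALSE)
    data.frame(term = term, description = unname(desc[term]),
               overlap = k, query_size = n_query, term_size = K,
               background_size = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(), description = character(),
                      overlap = integer(), query_size = integer(),
                      term_size = integer(), background_size = integer(),
                      p = numeric(), q = numeric(), significant = logical())
    return(out)
  }
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < fdr_max
  out[order(out$p), , drop = FALSE]
}

#' Terms recurrently enriched across tissues
#'
#' Counts, per term, the number of tissues in which it was significantly
#' enriched, and filters at a recurrence threshold (used both for AR-mRNA
#' biological processes and for guilt-by-association AR-lncRNA processes).
#'
#' @param sig_terms named list (one element per tissue) of significant term
#'   id vectors.
#' @param min_tissues minimum number of tissues.
#' @return data frame: term, n_tissues, tissues; filtered at
#'   `n_tissues >= min_tissues`, sorted by decreasing recurrence.
#' @export
recurrent_terms <- function(sig_terms, min_tissues = 2) {
  assert_that(length(sig_terms) >= 2 && !is.null(names(sig_terms)),
              "need a named list of >= 2 tissues")
  sig_terms <- lapply(sig_terms, unique)
  long <- data.frame(
    tissue = rep(names(sig_terms), lengths(sig_terms)),
    term = unlist(sig_terms, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(long) == 0) {
    return(data.frame(term = character(), n_tissues = integer(),
                      tissues = character()))
  }
  counts <- stats::aggregate(list(n_tissues = long$tissue),
                             by = list(term = long$term), FUN = length)
  counts$tissues <- vapply(counts$term, function(tt)
    paste(sort(long$tissue[long$term == tt]), collapse = ";"), character(1))
  counts <- counts[counts$n_tissues >= min_tissues, , drop = FALSE]
  counts[order(-counts$n_tissues, counts$term), , drop = FALSE]
}
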