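# Internal helpers shared across pipeline stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ctx <- function(..., call. = FALSE) stop(..., call. = call.)

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_ctx(msg)
  invisible(TRUE)
}

first_offenders <- function(x, n = 10) {
  x <- as.character(x)
  shown <- utils::head(x, n)
  extra <- length(x) - length(shown)
  paste0(paste(shown, collapse = ", "),
         if (extra > 0) sprintf(" ... and %d more", extra) else "")
}

# Row-wise Welch two-sample t-test on a numeric matrix.
# Groups are column index vectors. Zero pooled standard error is resolved as
# t = 0 (p = 1) when the mean difference is also zero, otherwise p = 0.
row_welch <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  assert_that(n1 >= 2 && n2 >= 2, "Welch test needs >= 2 replicates per group")
  x1 <- x[, idx1, drop = FALSE]; x2 <- x[, idx2, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  diff <- m1 - m2
  t <- diff / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  deg <- se2 == 0
  if (any(deg)) {
    t[deg] <- ifelse(diff[deg] == 0, 0, sign(diff[deg]) * Inf)
    p[deg] <- ifelse(diff[deg] == 0, 1, 0)
    df[deg] <- NA_real_
  }
  data.frame(log2FC = diff, t = t, df = df, p = p, row.names = rownames(x))
}

# Pearson correlation of every row of `x` against vector `y`, with the
# t-transform p-value (n - 2 df). Zero-variance rows come back NA.
row_cor_test <- function(x, y) {
  n <- length(y)
  assert_that(ncol(x) == n, "dimension mismatch between matrix and vector")
  r <- suppressWarnings(as.vector(stats::cor(t(x), y)))
  r[abs(r) > 1] <- sign(r[abs(r) > 1])  # guard rounding
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(r) == 1] <- 0
  data.frame(r = r, p = p, row.names = rownames(x))
}

# Write a TSV with '# key: value' header comment lines describing the
# thresholds that generated the table.
write_tsv_commented <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    comment.char = "#", check.names = FALSE, ...)
}
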