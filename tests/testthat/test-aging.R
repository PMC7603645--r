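# Aging correlation, differential expression, AR calling, sharing and
# feature comparisons.

test_that("a log-linear gene is perfectly aging-correlated", {
  meta <- make_meta(reps = 2)
  x <- log2(meta$age_weeks)
  vals <- rbind(linear = 1 + 2 * x,
                flat = rep(5, length(x)),
                noisy = 1 + 2 * x + c(0.2, -0.1, 0.3, -0.2, 0.1,
                                      -0.3, 0.2, 0.1, -0.1, 0.2))
  colnames(vals) <- meta$sample_id
  res <- aging_correlation(make_expr(vals), meta, "liver")
  expect_equal(res$r[res$gene_id == "linear"], 1)
  expect_true(res$called[res$gene_id == "linear"])
  expect_equal(res$direction[res$gene_id == "linear"], "positive")
  expect_true(res$degenerate[res$gene_id == "flat"])
  expect_false(res$called[res$gene_id == "flat"])
})

test_that("correlation p-values match a permutation oracle", {
  meta <- make_meta(reps = 5)
  x <- log2(meta$age_weeks)
  set.seed(10)
  y <- 0.25 * scale(x)[, 1] + rnorm(25, sd = 0.5)
  vals <- matrix(y, 1, dimnames = list("g1", meta$sample_id))
  res <- aging_correlation(make_expr(vals), meta, "liver", r_min = 0,
                           p_max = 1)
  r_obs <- res$r[1]
  set.seed(11)
  perm <- replicate(1e5, cor(sample(y), x))
  p_perm <- mean(abs(perm) >= abs(r_obs))
  expect_lt(abs(res$p[1] - p_perm), 0.01)
})

test_that("identical groups give zero fold change; planted effects are found", {
  meta <- make_meta(reps = 3)
  set.seed(12)
  vals <- matrix(rnorm(20 * nrow(meta), 5), 20,
                 dimnames = list(sprintf("g%02d", 1:20), meta$sample_id))
  young <- meta$sample_id[meta$age_weeks == 8]
  vals[, meta$sample_id[meta$age_weeks == 104]] <- vals[, young]
  de <- differential_expression(make_expr(vals), meta, "liver", 104, 8)
  expect_equal(de$log2FC, rep(0, 20))
  expect_error(differential_expression(make_expr(vals), meta, "liver",
                                       200, 8), "200")

  # Monte-Carlo power: delta = 2, sd = 0.3, n = 5/5 is called virtually always
  called <- vapply(1:200, function(i) {
    m <- matrix(rnorm(51 * 10, 0, 0.3), 51)
    m[1, 6:10] <- m[1, 6:10] + 2
    colnames(m) <- make_meta(ages = c(8, 104), reps = 5)$sample_id
    rownames(m) <- sprintf("g%02d", 1:51)
    d <- differential_expression(make_expr(m),
                                 make_meta(ages = c(8, 104), reps = 5),
                                 "liver", 104, 8)
    abs(d$log2FC[1]) > 0.75 && d$fdr[1] < 0.1
  }, logical(1))
  expect_gte(mean(called), 0.95)
})

test_that("AR calling pins the larger-magnitude fold change and strict cuts", {
  mk <- function(fc, fdr, old) {
    data.frame(gene_id = sprintf("g%d", seq_along(fc)), tissue = "liver",
               old_age = old, young_age = 8, log2FC = fc, t = 1,
               p = fdr, fdr = fdr, stringsAsFactors = FALSE)
  }
  # g1: qualifies both ways with opposite signs -> discordant, FC -2.0
  # g2: boundary |FC| = 0.75 -> excluded
  # g3: passes only one contrast, up
  # g4: fails everywhere
  # g5: FCs (0.3, -2.0), both FDR < 0.1 -> reported FC -2.0, down
  de78 <- mk(c(0.9, 0.75, 1.4, 0.1, 0.3), c(0.01, 0.01, 0.01, 0.9, 0.01), 78)
  de104 <- mk(c(-2.0, 0.75, 0.2, 0.2, -2.0), c(0.01, 0.01, 0.8, 0.8, 0.01),
              104)
  genes <- data.frame(gene_id = sprintf("g%d", 1:5),
                      biotype = c("lncRNA", "mRNA", "mRNA", "lncRNA",
                                  "lncRNA"))
  ar <- suppressMessages(call_aging_regulated(list(de78, de104), genes))
  m <- ar$members
  expect_setequal(m$gene_id, c("g1", "g3", "g5"))
  expect_equal(m$log2FC_old_young[m$gene_id == "g1"], -2.0)
  expect_equal(m$direction[m$gene_id == "g1"], "discordant")
  expect_equal(m$direction[m$gene_id == "g3"], "up")
  expect_equal(m$log2FC_old_young[m$gene_id == "g5"], -2.0)
  expect_equal(m$direction[m$gene_id == "g5"], "down")
  expect_false("g2" %in% m$gene_id)  # strict > 0.75
  # fold changes are reported for every tested gene
  expect_equal(unname(ar$fc_all["g4"]), 0.2)
})

test_that("AR calling equals a brute-force re-evaluation of the rule", {
  st <- small_study(seed = 21, n_tissues = 1, module_specs = list())
  expr <- normalize_expression(st$counts, st$genes)
  t1 <- st$config$tissue_names[1]
  de <- lapply(c(78, 104), function(a)
    differential_expression(expr, st$samples, t1, a, 8))
  ar <- call_aging_regulated(de, st$genes)
  brute <- unique(unlist(lapply(de, function(d)
    d$gene_id[abs(d$log2FC) > 0.75 & d$fdr < 0.1])))
  expect_setequal(ar$members$gene_id, brute)
})

test_that("benjamini-hochberg matches the textbook example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
})

test_that("cross-tissue sharing counts organs per gene", {
  mk_ar <- function(tissue, ids, biotype = "lncRNA") {
    structure(list(tissue = tissue,
                   members = data.frame(gene_id = ids, biotype = biotype,
                                        direction = "up", contrasts = "x",
                                        log2FC_old_young = 1,
                                        stringsAsFactors = FALSE),
                   fc_all = numeric(0), fc_min = 0.75, fdr_max = 0.1,
                   contrasts = "x"), class = "ar_set")
  }
  ov <- cross_tissue_overlap(list(mk_ar("T1", c("g1", "g2")),
                                  mk_ar("T2", "g1")))
  expect_equal(ov$per_gene$n_tissues[ov$per_gene$gene_id == "g1"], 2)
  expect_equal(ov$per_gene$n_tissues[ov$per_gene$gene_id == "g2"], 1)
  expect_equal(unname(ov$summary["lncRNA", "1"]), 50)
  # disjoint sets: all single-organ
  ov2 <- cross_tissue_overlap(list(mk_ar("T1", c("a", "b")),
                                   mk_ar("T2", c("c", "d"))))
  expect_equal(unname(ov2$summary["lncRNA", "1"]), 100)
  # identical sets over 3 tissues: none single-organ
  ov3 <- cross_tissue_overlap(list(mk_ar("T1", c("a", "b")),
                                   mk_ar("T2", c("a", "b")),
                                   mk_ar("T3", c("a", "b"))))
  expect_equal(unname(ov3$summary["lncRNA", "1"]), 0)
  expect_equal(unname(ov3$summary["lncRNA", "3"]), 100)
})

test_that("feature comparison reproduces the exact rank test", {
  genes <- data.frame(gene_id = sprintf("g%d", 1:6),
                      length_bp = c(1, 2, 3, 4, 5, 6),
                      n_isoforms = c(1, 2, 3, 4, 5, 6),
                      n_exons = c(1, 2, 3, 4, 5, 6))
  res <- compare_gene_features(genes, sprintf("g%d", 1:3),
                               sprintf("g%d", 4:6))
  expect_equal(res$p, rep(0.1, 3))  # exhaustive C(6,3) enumeration
  same <- compare_gene_features(genes, sprintf("g%d", 1:3),
                                sprintf("g%d", 1:3))
  expect_equal(same$p, rep(1, 3))
  # shifting one group's lengths makes p monotone in the shift
  set.seed(30)
  g2 <- data.frame(gene_id = sprintf("g%d", 1:40),
                   length_bp = rlnorm(40, 8, 0.3),
                   n_isoforms = 1, n_exons = 1)
  ps <- vapply(c(0, 2000, 10000), function(shift) {
    gs <- g2
    gs$length_bp[1:20] <- gs$length_bp[1:20] + shift
    compare_gene_features(gs, sprintf("g%d", 1:20),
                          sprintf("g%d", 21:40))$p[1]
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})
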