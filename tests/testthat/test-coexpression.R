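# Stage binning, edge calling, consensus construction, walktrap modules,
# growth metrics and partner lists.

test_that("stage binning pools adjacent ages and rejects strays", {
  meta <- make_meta(reps = 5)
  st <- bin_stages(meta, "liver")
  expect_equal(lengths(st), c(stage1 = 10, stage2 = 10, stage3 = 10,
                              stage4 = 10))
  shared <- intersect(st$stage1, st$stage2)
  expect_setequal(shared, meta$sample_id[meta$age_weeks == 26])
  expect_error(bin_stages(meta[meta$age_weeks != 60, ], "liver"), "60")
  odd <- rbind(meta, data.frame(sample_id = "liver_200w_r1",
                                tissue = "liver", age_weeks = 200,
                                replicate = 1))
  expect_error(bin_stages(odd, "liver"), "non-canonical")
})

test_that("edge calling flags exact copies and respects the signed rule", {
  meta <- make_meta(ages = c(8, 26), reps = 5)
  set.seed(50)
  lnc <- matrix(rnorm(2 * 10), 2, dimnames = list(c("l1", "l2"),
                                                  meta$sample_id))
  mrna <- rbind(copy = lnc["l1", ], anti = -lnc["l1", ],
                noise = rnorm(10))
  colnames(mrna) <- meta$sample_id
  vals <- rbind(lnc, mrna)
  e <- stage_edges(vals, c("l1", "l2"), c("copy", "anti", "noise"),
                   meta$sample_id)
  ecopy <- e[e$lnc_id == "l1" & e$mrna_id == "copy", ]
  expect_equal(ecopy$r, 1)
  expect_true(ecopy$significant)
  # anti-correlation fails the signed threshold even though |r| = 1
  eanti <- e[e$lnc_id == "l1" & e$mrna_id == "anti", ]
  expect_equal(eanti$r, -1)
  expect_false(eanti$significant)
  expect_true(stage_edges(vals, "l1", "anti", meta$sample_id,
                          signed = FALSE)$significant)
})

test_that("z-scoring is cosmetic for Pearson correlation", {
  meta <- make_meta(ages = c(8, 26), reps = 5)
  set.seed(51)
  vals <- matrix(rnorm(6 * 10, 5, 2), 6,
                 dimnames = list(sprintf("g%d", 1:6), meta$sample_id))
  e <- stage_edges(vals, sprintf("g%d", 1:3), sprintf("g%d", 4:6),
                   meta$sample_id, r_min = -1, q_max = 1)
  direct <- cor(t(vals[sprintf("g%d", 1:3), ]),
                t(vals[sprintf("g%d", 4:6), ]))
  expect_equal(e$r, as.vector(direct), tolerance = 1e-12)
})

test_that("null pairs are called at no more than the nominal rate", {
  set.seed(52)
  calls <- 0L; tested <- 0L
  for (i in 1:3) {
    vals <- matrix(rnorm(200 * 10), 200,
                   dimnames = list(sprintf("g%03d", 1:200),
                                   sprintf("s%d", 1:10)))
    e <- stage_edges(vals, sprintf("g%03d", 1:100),
                     sprintf("g%03d", 101:200), sprintf("s%d", 1:10))
    calls <- calls + sum(e$significant)
    tested <- tested + nrow(e)
  }
  expect_lte(calls / tested, 0.05)
})

test_that("consensus takes the union of stages 1 and 4 with r carried", {
  pairs <- biclique_pairs(c("l1", "l2"), c("m1", "m2"))
  sig <- list(c(TRUE, FALSE, FALSE, FALSE),   # stage 1: l1~m1
              rep(FALSE, 4),
              rep(FALSE, 4),
              c(FALSE, TRUE, FALSE, FALSE))   # stage 4: l2~m1
  net <- consensus_network(fake_stage_edges(pairs, sig))
  expect_equal(nrow(net$edges), 2)
  expect_setequal(paste(net$edges$lnc_id, net$edges$mrna_id),
                  c("l1 m1", "l2 m1"))
  # the late-emerging edge is present under the union rule
  late <- net$edges[net$edges$lnc_id == "l2", ]
  expect_equal(late$stages_significant, "4")
  expect_equal(late$r4, 0.95)
  expect_equal(late$r1, 0.1)
  # intersection mode discards it
  both <- suppressWarnings(consensus_network(fake_stage_edges(pairs, sig),
                                             mode = "intersection"))
  expect_equal(nrow(both$edges), 0)
  # an edge significant only in stages 2/3 is absent
  sig23 <- list(rep(FALSE, 4), c(TRUE, TRUE, TRUE, TRUE),
                c(TRUE, TRUE, TRUE, TRUE), rep(FALSE, 4))
  expect_warning(net23 <- consensus_network(fake_stage_edges(pairs, sig23)),
                 "no edges")
  expect_equal(nrow(net23$edges), 0)
  # nodes never exceed the candidate sets
  expect_true(all(net$nodes %in% c("l1", "l2", "m1", "m2")))
})

test_that("walktrap modules match the component oracle on bicliques", {
  lnc1 <- sprintf("A_l%02d", 1:18); mrna1 <- sprintf("A_m%02d", 1:17)
  lnc2 <- sprintf("B_l%02d", 1:18); mrna2 <- sprintf("B_m%02d", 1:17)
  pairs <- rbind(biclique_pairs(lnc1, mrna1), biclique_pairs(lnc2, mrna2))
  sig <- list(rep(TRUE, nrow(pairs)), rep(FALSE, nrow(pairs)),
              rep(FALSE, nrow(pairs)), rep(TRUE, nrow(pairs)))
  net <- consensus_network(fake_stage_edges(pairs, sig))
  ms <- detect_modules(net)
  expect_equal(length(ms$modules), 2)
  expect_equal(unname(sort(lengths(ms$modules))), c(35, 35))
  comp <- igraph::components(net$graph)$membership
  for (m in ms$modules) {
    expect_equal(length(unique(comp[m])), 1)
  }
  # partition: no gene in two modules
  expect_false(anyDuplicated(unlist(ms$modules)) > 0)
  # a 20-node biclique does not clear the > 30 size filter
  small <- consensus_network(fake_stage_edges(
    biclique_pairs(sprintf("l%02d", 1:10), sprintf("m%02d", 1:10)),
    list(rep(TRUE, 100), rep(FALSE, 100), rep(FALSE, 100),
         rep(TRUE, 100))))
  expect_equal(length(detect_modules(small)$modules), 0)
  expect_equal(length(detect_modules(small, min_size = 19)$modules), 1)
})

test_that("growth metrics rise with planted coupling and stay flat without", {
  st <- generate_study(study_config(
    n_tissues = 1, n_genes = 150, n_aging_up = 0, n_aging_down = 0,
    n_tissue_specific = 0,
    module_specs = list(module_spec(size = 40, aging_effect = 0)),
    seed = 60))
  expr <- normalize_expression(st$counts, st$genes)
  gids <- st$truth$genes$gene_id[!is.na(st$truth$genes$module_id)]
  glnc <- intersect(gids, st$genes$gene_id[st$genes$biotype == "lncRNA"])
  gmrna <- setdiff(gids, glnc)
  stages <- bin_stages(st$samples, st$config$tissue_names[1])
  gm <- growth_metrics(expr$values, glnc, gmrna, stages)
  expect_true(gm$monotone_increase)
  expect_true(all(gm$per_stage$mean_abs_r >= 0 &
                    gm$per_stage$mean_abs_r <= 1))
  # without coupling the strict-increase flag fires at roughly chance level
  set.seed(61)
  flags <- vapply(1:20, function(i) {
    vals <- matrix(rnorm(40 * 50), 40,
                   dimnames = list(sprintf("g%02d", 1:40),
                                   sprintf("s%02d", 1:50)))
    stages0 <- split(colnames(vals), rep(1:5, each = 10))
    stages0 <- lapply(1:4, function(s)
      c(stages0[[s]], stages0[[s + 1]]))
    growth_metrics(vals, sprintf("g%02d", 1:20), sprintf("g%02d", 21:40),
                   stages0)$monotone_increase
  }, logical(1))
  expect_lte(mean(flags), 0.25)
})

test_that("partner lists equal a brute-force correlation scan", {
  meta <- make_meta(reps = 5)
  set.seed(62)
  n <- nrow(meta)
  base <- rnorm(n)
  vals <- rbind(lnc = base,
                copy = base + rnorm(n, sd = 0.05),
                anti = -base + rnorm(n, sd = 0.05),
                matrix(rnorm(30 * n), 30,
                       dimnames = list(sprintf("m%02d", 1:30), NULL)))
  colnames(vals) <- meta$sample_id
  mrna <- setdiff(rownames(vals), "lnc")
  got <- coexpressed_partners(vals, "lnc", mrna)
  expect_true("copy" %in% got)
  expect_false("anti" %in% got)  # signed threshold
  # brute force re-scan
  r <- apply(vals[mrna, ], 1, cor, y = vals["lnc", ])
  p <- 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2)
  q <- p.adjust(p, "BH")
  expect_setequal(got, mrna[r > 0.8 & q < 0.05])
  expect_error(coexpressed_partners(vals, "absent", mrna), "detectable")
})
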