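# Synthetic study generator: design, determinism, planted structure and
# null calibration.

test_that("configuration is validated", {
  expect_error(study_config(n_tissues = 0), "non-positive")
  expect_error(study_config(tissue_names = c("a", "a"), n_tissues = 2),
               "duplicate")
  expect_error(study_config(age_points = c(26, 8)), "increasing")
  expect_error(study_config(n_genes = 50), "exceed")
  expect_error(module_spec(coupling = c(0.1, 0.3)), "4 values")
  expect_error(module_spec(coupling = c(0.1, 0.3, 0.6, 1.0)), "4 values")
})

test_that("full design yields one sample per tissue x age x replicate", {
  cfg <- study_config(n_genes = 500, n_aging_up = 5, n_aging_down = 5,
                      n_tissue_specific = 11, seed = 7)
  st <- generate_study(cfg)
  expect_equal(nrow(st$samples), 11 * 5 * 5)
  expect_equal(ncol(st$counts), 275)
  expect_false(anyDuplicated(st$samples$sample_id) > 0)
  tab <- table(st$samples$tissue, st$samples$age_weeks)
  expect_true(all(tab == 5))
  expect_true(all(st$counts >= 0))
})

test_that("same seed reproduces the study bit for bit", {
  cfg <- study_config(n_tissues = 2, n_genes = 300, n_aging_up = 10,
                      n_aging_down = 10, n_tissue_specific = 10,
                      module_specs = list(), seed = 42)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
})

test_that("truth labels are consistent with the configuration", {
  st <- small_study(seed = 5)
  expect_true(all(st$truth$aging$gene_id %in% st$genes$gene_id))
  expect_equal(sum(!is.na(st$truth$genes$module_id)), 24)
  expect_equal(sum(!is.na(st$truth$genes$specific_tissue)), 40)
  # per-tissue planted aging counts include specific and module genes
  for (t in unique(st$truth$aging$tissue)) {
    expect_gte(sum(st$truth$aging$tissue == t), 40)
  }
})

test_that("null genes match the t-distribution tail of the r-threshold rule", {
  cfg <- study_config(n_tissues = 1, n_replicates = 1, n_genes = 5000,
                      n_aging_up = 0, n_aging_down = 0,
                      n_tissue_specific = 0, module_specs = list(),
                      seed = 99)
  st <- generate_study(cfg)
  expr <- normalize_expression(st$counts, st$genes)
  res <- aging_correlation(expr, st$samples, st$config$tissue_names[1],
                           r_min = 0.9, p_max = 1)
  r <- res$r[!res$degenerate]
  expect_lt(abs(mean(r)), 0.03)
  n <- 5
  expected_tail <- 2 * pt(-0.9 * sqrt(n - 2) / sqrt(1 - 0.81), n - 2)
  expect_lt(abs(mean(abs(r) > 0.9) - expected_tail), 0.015)
})

test_that("planted aging-up genes correlate positively with log2 age", {
  cfg <- study_config(n_tissues = 1, n_genes = 300, n_aging_up = 50,
                      n_aging_down = 0, n_tissue_specific = 0,
                      module_specs = list(), aging_effect = 1, seed = 3)
  st <- generate_study(cfg)
  expr <- normalize_expression(st$counts, st$genes)
  res <- aging_correlation(expr, st$samples, st$config$tissue_names[1],
                           r_min = 0.9, p_max = 1)
  up <- st$truth$aging$gene_id[st$truth$aging$aging_direction == "up"]
  r_up <- res$r[match(up, res$gene_id)]
  r_up <- r_up[!is.na(r_up)]
  expect_lt(binom.test(sum(r_up > 0), length(r_up),
                       alternative = "greater")$p.value, 0.01)
})

test_that("module coupling produces strictly increasing stage correlations", {
  for (s in 1:3) {
    cfg <- study_config(n_tissues = 1, n_genes = 200, n_aging_up = 0,
                        n_aging_down = 0, n_tissue_specific = 0,
                        module_specs = list(module_spec(size = 40,
                                                        aging_effect = 0)),
                        seed = s)
    st <- generate_study(cfg)
    expr <- normalize_expression(st$counts, st$genes)
    gids <- st$truth$genes$gene_id[!is.na(st$truth$genes$module_id)]
    stages <- bin_stages(st$samples, st$config$tissue_names[1])
    gm <- growth_metrics(expr$values, gids, gids, stages,
                         modules = list(M = gids))
    within <- gm$module_mean_abs_r[1, ]
    expect_true(all(diff(within) > 0),
                info = sprintf("seed %d: %s", s,
                               paste(round(within, 3), collapse = ",")))
  }
})

test_that("fixtures round trip and the manifest guards its seed", {
  st <- small_study(seed = 8, n_genes = 120, n_aging_up = 5,
                    n_aging_down = 5, n_tissue_specific = 6,
                    module_specs = list())
  dir <- withr::local_tempdir()
  paths <- write_fixtures(st, dir)
  back <- read_fixtures(dir)
  expect_equal(back$counts, st$counts)
  expect_equal(back$samples$sample_id, st$samples$sample_id)
  expect_equal(back$genes$length_bp, st$genes$length_bp)
  expect_equal(back$manifest$config$seed, 8)
  expect_true(any(back$truth$aging_direction != "none"))

  # corrupt the manifest seed
  m <- yaml::read_yaml(paths["manifest"])
  m$seed <- 999L
  yaml::write_yaml(m, paths["manifest"])
  expect_error(read_fixtures(dir), "seed")

  # a negative count must be rejected on re-read
  m$seed <- 8L
  yaml::write_yaml(m, paths["manifest"])
  tab <- utils::read.delim(paths["counts"], check.names = FALSE)
  tab[2, 3] <- -4
  utils::write.table(tab, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_fixtures(dir), "non-negative")
})
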