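#' Canonical tissue panel of the study design
#'
#' Eleven mouse tissues sampled across the lifespan: brain, hypothalamus,
#' lung, bone marrow, gastric muscle, liver, kidney, heart, inguinal and
#' epididymal white adipose tissue, and brown adipose tissue.
#' @export
canonical_tissues <- function() {
  c("brain", "hypothalamus", "lung", "bone_marrow", "gastric_muscle",
    "liver", "kidney", "heart", "iWAT", "eWAT", "BAT")
}

#' Specify a planted lncRNA~mRNA co-expression module
#'
#' A module is a block of genes sharing a latent per-sample factor whose
#' variance grows along a stage-wise coupling schedule, so that the mean
#' within-module pairwise correlation rises across the four age stages
#' (8&26, 26&60, 60&78, 78&104 weeks). Module genes additionally carry a
#' late-onset aging trend so they qualify as aging-regulated and therefore
#' appear as nodes of the AR-lncRNA~AR-mRNA networks.
#'
#' @param size number of genes in the module.
#' @param lnc_frac fraction of module genes assigned the lncRNA biotype.
#' @param coupling length-4 vector in `[0, 1)`: target within-module
#'   correlation for stages 1..4.
#' @param aging_effect log2 fold change (oldest vs youngest age) of module
#'   genes; 0 plants a pure co-expression module with no aging trend.
#' @param direction +1 (up with age) or -1 (down); one sign per module.
#' @param tissue tissue the module lives in; `NULL` = first tissue of the
#'   study.
#' @return a `module_spec` list.
#' @export
module_spec <- function(size = 40, lnc_frac = 0.3,
                        coupling = c(0.1, 0.3, 0.6, 0.9),
                        aging_effect = 4, direction = 1, tissue = NULL) {
  assert_that(size >= 2, "module size must be >= 2")
  assert_that(lnc_frac >= 0 && lnc_frac <= 1, "lnc_frac must be in [0, 1]")
  assert_that(length(coupling) == 4 && all(coupling >= 0) && all(coupling < 1),
              "coupling must be 4 values in [0, 1)")
  assert_that(direction %in% c(-1, 1), "direction must be +1 or -1")
  structure(list(size = as.integer(size), lnc_frac = lnc_frac,
                 coupling = coupling, aging_effect = aging_effect,
                 direction = direction, tissue = tissue),
            class = "module_spec")
}

#' Configure a synthetic multi-tissue aging study
#'
#' Defaults mirror the full study design (11 tissues x 5 ages x 5 replicates,
#' ages 8/26/60/78/104 weeks) with negative-binomial counts on a log-normal
#' baseline, planted aging-up/down genes (log-linear trend in log2 weeks),
#' tissue-specific genes (multiplicative boost in one tissue, carrying an
#' amplified aging effect), and latent-factor co-expression modules.
#'
#' @param tissue_names tissue labels; must be unique.
#' @param n_tissues number of tissues; subsets `tissue_names` when smaller.
#' @param age_points ages in weeks, strictly increasing.
#' @param n_replicates replicates per tissue x age.
#' @param n_genes total genes.
#' @param frac_lncRNA fraction of genes assigned the lncRNA biotype.
#' @param n_aging_up,n_aging_down planted aging genes per tissue.
#' @param aging_effect log2 fold change at the oldest vs youngest age.
#' @param n_tissue_specific planted tissue-specific genes (round-robin over
#'   tissues).
#' @param specificity_boost multiplicative expression enrichment in the
#'   target tissue.
#' @param specific_aging_mult aging-effect multiplier for tissue-specific
#'   genes (tissue-specific genes are preferentially aging-regulated).
#' @param module_specs list of [module_spec()] objects.
#' @param nb_dispersion negative-binomial dispersion (0 = Poisson).
#' @param baseline_log2_mean,baseline_log2_sd log-normal baseline abundance
#'   parameters on the log2 scale.
#' @param lnc_baseline_shift additive log2 shift of lncRNA baselines
#'   (default -2, i.e. ~4x lower than mRNAs).
#' @param tissue_effect_sd sd (log2) of per-gene-per-tissue identity effects.
#' @param depth_mean,depth_sd_log2 sequencing depth location and log2 sd.
#' @param seed single integer governing all randomness.
#' @return a validated `study_config` list.
#' @export
study_config <- function(tissue_names = canonical_tissues(),
                         n_tissues = length(tissue_names),
                         age_points = c(8, 26, 60, 78, 104),
                         n_replicates = 5,
                         n_genes = 2000,
                         frac_lncRNA = 0.3,
                         n_aging_up = 100, n_aging_down = 100,
                         aging_effect = 2,
                         n_tissue_specific = 300,
                         specificity_boost = 8,
                         specific_aging_mult = 3,
                         module_specs = list(module_spec()),
                         nb_dispersion = 0.1,
                         baseline_log2_mean = 1, baseline_log2_sd = 2,
                         lnc_baseline_shift = -2,
                         tissue_effect_sd = 0.5,
                         depth_mean = 2e6, depth_sd_log2 = 0.25,
                         seed = 1L) {
  assert_that(n_tissues >= 1 && n_replicates >= 1 && n_genes >= 1,
              "configuration error: non-positive study dimensions")
  tissue_names <- tissue_names[seq_len(min(n_tissues, length(tissue_names)))]
  assert_that(length(tissue_names) == n_tissues,
              "configuration error: fewer tissue names than n_tissues")
  assert_that(!anyDuplicated(tissue_names),
              "configuration error: duplicate tissue names")
  assert_that(length(age_points) >= 2 && all(diff(age_points) > 0),
              "configuration error: age_points must be strictly increasing")
  assert_that(frac_lncRNA >= 0 && frac_lncRNA <= 1,
              "configuration error: frac_lncRNA must be in [0, 1]")
  assert_that(n_aging_up >= 0 && n_aging_down >= 0 && n_tissue_specific >= 0,
              "configuration error: negative planted-gene counts")
  assert_that(nb_dispersion >= 0, "configuration error: negative dispersion")
  assert_that(specificity_boost > 0, "configuration error: non-positive boost")
  for (m in module_specs)
    assert_that(inherits(m, "module_spec"),
                "module_specs must be a list of module_spec() objects")
  n_planted <- n_tissues * (n_aging_up + n_aging_down) + n_tissue_specific +
    sum(vapply(module_specs, function(m) m$size, integer(1)))
  assert_that(n_planted <= n_genes,
              sprintf("configuration error: %d planted genes exceed n_genes = %d",
                      n_planted, n_genes))
  structure(list(tissue_names = tissue_names, n_tissues = n_tissues,
                 age_points = age_points, n_replicates = n_replicates,
                 n_genes = as.integer(n_genes), frac_lncRNA = frac_lncRNA,
                 n_aging_up = as.integer(n_aging_up),
                 n_aging_down = as.integer(n_aging_down),
                 aging_effect = aging_effect,
                 n_tissue_specific = as.integer(n_tissue_specific),
                 specificity_boost = specificity_boost,
                 specific_aging_mult = specific_aging_mult,
                 module_specs = module_specs,
                 nb_dispersion = nb_dispersion,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 lnc_baseline_shift = lnc_baseline_shift,
                 tissue_effect_sd = tissue_effect_sd,
                 depth_mean = depth_mean, depth_sd_log2 = depth_sd_log2,
                 seed = as.integer(seed)),
            class = "study_config")
}

# Map a 4-stage coupling schedule to per-age latent-factor variances.
# The schedule value c_s sets the factor's shared variance in stage s
# (ages s and s+1) to 2 c_s / (1 - c_s) times the residual log2 noise
# variance sigma2, i.e. a within-module correlation of 2c/(1+c): ~0.95 at
# full coupling 0.9 (so a fully coupled module clears the r > 0.9 edge
# rule) down to ~0.18 at c = 0.1. Per-age variances are recovered by
# telescoping the stage averages (v1 = v_s1, then v_{j+1} = 2 v_sj - v_j),
# clamped at zero.
stage_coupling_variances <- function(coupling, sigma2, n_ages = 5) {
  vs <- sigma2 * 2 * coupling / (1 - pmin(coupling, 0.99))
  v <- numeric(n_ages)
  v[1] <- vs[1]
  for (j in seq_len(n_ages - 1)) v[j + 1] <- max(2 * vs[j] - v[j], 0)
  v
}

# Late-onset ramp (0..1 over ages) used for module-gene aging trends,
# following the shape of the coupling schedule so the full log2 fold change
# is realised between the youngest and the two oldest ages.
coupling_ramp <- function(coupling, n_ages = 5) {
  c_age <- c(coupling, coupling[length(coupling)])[seq_len(n_ages)]
  if (max(c_age) - min(c_age) < 1e-12) {
    seq(0, 1, length.out = n_ages)
  } else {
    (c_age - c_age[1]) / (max(c_age) - c_age[1])
  }
}

#' Generate a synthetic multi-tissue aging study
#'
#' Draws negative-binomial counts with mean = log-normal baseline x tissue
#' identity effect x tissue-specificity boost x aging trend (log-linear in
#' log2 weeks) x module latent factor, one sample per tissue x age x
#' replicate, and returns the count matrix, sample metadata, gene annotation
#' and the planted truth labels.
#'
#' @param config a [study_config()].
#' @return object of class `aging_study`: list with `counts` (genes x
#'   samples integer matrix), `samples`, `genes` (data frames), `truth`
#'   (list: `genes`, `aging`, `modules` data frames) and `config`.
#' @export
generate_study <- function(config) {
  assert_that(inherits(config, "study_config"), "config must be a study_config")
  set.seed(config$seed)
  G <- config$n_genes
  tissues <- config$tissue_names
  ages <- config$age_points
  n_ages <- length(ages)
  reps <- config$n_replicates

  samples <- expand.grid(replicate = seq_len(reps), age_weeks = ages,
                         tissue = tissues, KEEP.OUT.ATTRS = FALSE,
                         stringsAsFactors = FALSE)
  samples <- samples[, c("tissue", "age_weeks", "replicate")]
  samples$sample_id <- sprintf("%s_%03dw_r%d", samples$tissue,
                               samples$age_weeks, samples$replicate)
  S <- nrow(samples)

  gene_id <- sprintf("G%05d", seq_len(G))

  # --- role assignment (deterministic blocks) -------------------------------
  cursor <- 0L
  take <- function(n) {
    idx <- cursor + seq_len(n); cursor <<- cursor + n; idx
  }
  aging_idx <- list()
  for (t in tissues) {
    aging_idx[[t]] <- list(up = take(config$n_aging_up),
                           down = take(config$n_aging_down))
  }
  specific_idx <- take(config$n_tissue_specific)
  specific_tissue <- rep(tissues, length.out = config$n_tissue_specific)
  module_idx <- lapply(config$module_specs, function(m) take(m$size))
  module_tissue <- vapply(seq_along(config$module_specs), function(k) {
    config$module_specs[[k]]$tissue %||% tissues[1]
  }, character(1))
  assert_that(all(module_tissue %in% tissues),
              "configuration error: module tissue not in tissue_names")

  # --- biotype: exact split inside modules, Bernoulli elsewhere -------------
  biotype <- ifelse(stats::runif(G) < config$frac_lncRNA, "lncRNA", "mRNA")
  for (k in seq_along(module_idx)) {
    idx <- module_idx[[k]]
    n_lnc <- round(config$module_specs[[k]]$lnc_frac * length(idx))
    biotype[idx] <- c(rep("lncRNA", n_lnc), rep("mRNA", length(idx) - n_lnc))
  }
  is_lnc <- biotype == "lncRNA"

  # --- gene annotation ------------------------------------------------------
  length_bp <- ifelse(is_lnc,
                      round(2^stats::runif(G, log2(500), log2(5000))),
                      round(2^stats::runif(G, log2(800), log2(10000))))
  n_exons <- ifelse(is_lnc, 1L + stats::rpois(G, 1.5), 2L + stats::rpois(G, 7))
  n_isoforms <- ifelse(is_lnc, 1L + stats::rpois(G, 0.8),
                       1L + stats::rpois(G, 2.5))
  genes <- data.frame(gene_id = gene_id, biotype = biotype,
                      length_bp = as.integer(length_bp),
                      n_exons = as.integer(n_exons),
                      n_isoforms = as.integer(n_isoforms),
                      stringsAsFactors = FALSE)

  # --- baseline abundance (log2); planted genes floored above detectability -
  b <- stats::rnorm(G, config$baseline_log2_mean, config$baseline_log2_sd) +
    ifelse(is_lnc, config$lnc_baseline_shift, 0)
  planted <- unique(c(unlist(aging_idx, use.names = FALSE), specific_idx,
                      unlist(module_idx)))
  floor_log2 <- config$baseline_log2_mean - 1
  b[planted] <- pmax(b[planted], floor_log2)

  x_age <- log2(ages)
  x_centered <- x_age - mean(x_age)
  x_span <- max(x_age) - min(x_age)
  age_index <- match(samples$age_weeks, ages)
  tissue_of <- samples$tissue

  # log2 mean matrix: baseline + per-tissue identity effect
  M <- matrix(b, nrow = G, ncol = S)
  tissue_eff <- matrix(stats::rnorm(G * length(tissues), 0,
                                    config$tissue_effect_sd),
                       nrow = G, dimnames = list(NULL, tissues))
  M <- M + tissue_eff[, tissue_of]

  truth_aging <- list()
  add_trend <- function(M, idx, tissue, slope_log2) {
    cols <- which(tissue_of == tissue)
    M[idx, cols] <- M[idx, cols] +
      outer(slope_log2, x_centered[age_index[cols]])
    M
  }
  for (t in tissues) {
    up <- aging_idx[[t]]$up; down <- aging_idx[[t]]$down
    if (length(up)) {
      M <- add_trend(M, up, t, rep(config$aging_effect / x_span, length(up)))
      truth_aging[[length(truth_aging) + 1L]] <-
        data.frame(gene_id = gene_id[up], tissue = t, aging_direction = "up")
    }
    if (length(down)) {
      M <- add_trend(M, down, t, rep(-config$aging_effect / x_span, length(down)))
      truth_aging[[length(truth_aging) + 1L]] <-
        data.frame(gene_id = gene_id[down], tissue = t, aging_direction = "down")
    }
  }

  # tissue-specific genes: boost in target tissue + amplified aging trend.
  # The trend is anchored at the youngest age so the boost equals the
  # planted enrichment at baseline and aging modulates from there.
  if (length(specific_idx)) {
    spec_dir <- sample(c(-1, 1), length(specific_idx), replace = TRUE)
    spec_effect <- config$aging_effect * config$specific_aging_mult
    x_from_young <- x_age - x_age[1]
    for (i in seq_along(specific_idx)) {
      g <- specific_idx[i]; t <- specific_tissue[i]
      cols <- which(tissue_of == t)
      M[g, cols] <- M[g, cols] + log2(config$specificity_boost)
      if (spec_effect > 0) {
        M[g, cols] <- M[g, cols] +
          spec_dir[i] * spec_effect / x_span * x_from_young[age_index[cols]]
      }
    }
    if (spec_effect > 0) {
      truth_aging[[length(truth_aging) + 1L]] <-
        data.frame(gene_id = gene_id[specific_idx], tissue = specific_tissue,
                   aging_direction = ifelse(spec_dir > 0, "up", "down"))
    }
  }

  # modules: shared latent factor with stage-scheduled variance + late ramp
  sigma2_noise <- max(config$nb_dispersion, 0.02) / log(2)^2
  truth_modules <- list()
  for (k in seq_along(module_idx)) {
    spec <- config$module_specs[[k]]
    idx <- module_idx[[k]]
    t <- module_tissue[k]
    cols <- which(tissue_of == t)
    v_age <- stage_coupling_variances(spec$coupling, sigma2_noise, n_ages)
    # standardize the factor within each age group so the planted coupling
    # is realized exactly, not up to few-replicate sampling noise
    f <- numeric(length(cols))
    for (j in seq_len(n_ages)) {
      grp <- which(age_index[cols] == j)
      z <- stats::rnorm(length(grp))
      if (length(grp) >= 2) z <- as.numeric(scale(z))
      f[grp] <- z * sqrt(v_age[j])
    }
    loading <- stats::runif(length(idx), 0.9, 1.1)
    M[idx, cols] <- M[idx, cols] + outer(loading, f)
    if (spec$aging_effect > 0) {
      ramp <- coupling_ramp(spec$coupling, n_ages)
      shift <- spec$direction * spec$aging_effect * (ramp - mean(ramp))
      M[idx, cols] <- M[idx, cols] +
        matrix(shift[age_index[cols]], nrow = length(idx), ncol = length(cols),
               byrow = TRUE)
      truth_aging[[length(truth_aging) + 1L]] <-
        data.frame(gene_id = gene_id[idx], tissue = t,
                   aging_direction = if (spec$direction > 0) "up" else "down")
    }
    truth_modules[[k]] <-
      data.frame(module_id = sprintf("M%02d", k), tissue = t,
                 stage = 1:4, coupling = spec$coupling)
  }

  # --- counts: rescale each column to its sequencing depth, draw NB ---------
  mu0 <- 2^M * (length_bp / 1000)
  depth <- config$depth_mean * 2^stats::rnorm(S, 0, config$depth_sd_log2)
  mu <- sweep(mu0, 2, depth / colSums(mu0), "*")
  counts <- if (config$nb_dispersion > 0) {
    matrix(stats::rnbinom(G * S, mu = mu, size = 1 / config$nb_dispersion),
           nrow = G)
  } else {
    matrix(stats::rpois(G * S, lambda = mu), nrow = G)
  }
  dimnames(counts) <- list(gene_id, samples$sample_id)

  truth_genes <- data.frame(gene_id = gene_id,
                            specific_tissue = NA_character_,
                            module_id = NA_character_,
                            stringsAsFactors = FALSE)
  truth_genes$specific_tissue[specific_idx] <- specific_tissue
  for (k in seq_along(module_idx))
    truth_genes$module_id[module_idx[[k]]] <- sprintf("M%02d", k)

  truth_aging <- if (length(truth_aging)) {
    do.call(rbind, truth_aging)
  } else {
    data.frame(gene_id = character(), tissue = character(),
               aging_direction = character())
  }
  truth_modules <- if (length(truth_modules)) do.call(rbind, truth_modules) else
    data.frame(module_id = character(), tissue = character(),
               stage = integer(), coupling = numeric())

  structure(list(counts = counts,
                 samples = samples[, c("sample_id", "tissue", "age_weeks",
                                       "replicate")],
                 genes = genes,
                 truth = list(genes = truth_genes, aging = truth_aging,
                              modules = truth_modules),
                 config = config),
            class = "aging_study")
}

#' @export
print.aging_study <- function(x, ...) {
  cat(sprintf("Synthetic aging study: %d genes x %d samples (%d tissues x %d ages x %d reps)\n",
              nrow(x$counts), ncol(x$counts), x$config$n_tissues,
              length(x$config$age_points), x$config$n_replicates))
  cat(sprintf("  planted aging labels: %d; tissue-specific: %d; modules: %d\n",
              nrow(x$truth$aging), sum(!is.na(x$truth$genes$specific_tissue)),
              length(unique(stats::na.omit(x$truth$genes$module_id)))))
  invisible(x)
}

#' Write a synthetic study to plain-text fixtures
#'
#' Writes counts, sample metadata, gene annotation and truth labels as TSV
#' plus a YAML manifest holding the full configuration and seed, so the
#' fixtures can be regenerated exactly.
#'
#' @param study an `aging_study` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return named character vector of file paths, invisibly.
#' @export
write_fixtures <- function(study, dir) {
  assert_that(inherits(study, "aging_study"), "study must be an aging_study")
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    assert_that(ok, sprintf("I/O error: cannot create directory '%s'", dir))
  }
  paths <- c(counts = file.path(dir, "counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             genes = file.path(dir, "genes.tsv"),
             truth = file.path(dir, "truth.tsv"),
             manifest = file.path(dir, "manifest.yaml"))
  counts_df <- data.frame(gene_id = rownames(study$counts), study$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(counts_df, paths["counts"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(study$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$genes, paths["genes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  tg <- study$truth$genes
  ta <- study$truth$aging
  truth_long <- merge(tg, ta, by = "gene_id", all.x = TRUE)
  truth_long$aging_direction[is.na(truth_long$aging_direction)] <- "none"
  truth_long <- truth_long[order(truth_long$gene_id),
                           c("gene_id", "tissue", "aging_direction",
                             "specific_tissue", "module_id")]
  utils::write.table(truth_long, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")

  cfg <- study$config
  cfg_list <- unclass(cfg)
  cfg_list$module_specs <- lapply(cfg$module_specs, unclass)
  manifest <- list(generator = "lncage::generate_study",
                   seed = cfg$seed,
                   config = cfg_list,
                   files = as.list(basename(paths[c("counts", "samples",
                                                    "genes", "truth")])),
                   n_genes = nrow(study$counts),
                   n_samples = ncol(study$counts))
  yaml::write_yaml(manifest, paths["manifest"])
  invisible(paths)
}

#' Re-read fixtures written by [write_fixtures()]
#'
#' Validates the manifest (the recorded seed must match the embedded
#' configuration seed) and reloads counts, metadata, annotation and truth.
#'
#' @param dir fixture directory.
#' @return list with `counts`, `samples`, `genes`, `truth` and `manifest`.
#' @export
read_fixtures <- function(dir) {
  manifest_path <- file.path(dir, "manifest.yaml")
  assert_that(file.exists(manifest_path),
              sprintf("no manifest.yaml under '%s'", dir))
  manifest <- yaml::read_yaml(manifest_path)
  if (!is.null(manifest$seed) && !is.null(manifest$config$seed) &&
      manifest$seed != manifest$config$seed) {
    stop_ctx("manifest validation error: top-level seed differs from config seed")
  }
  loaded <- load_inputs(file.path(dir, "counts.tsv"),
                        file.path(dir, "samples.tsv"),
                        file.path(dir, "genes.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) read_tsv_plain(truth_path) else NULL
  c(loaded, list(truth = truth, manifest = manifest))
}
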