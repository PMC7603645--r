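# Shared fixture builders; everything is generated in code at test time.

# Small planted study used by several suites.
small_study <- function(seed = 1, n_tissues = 2, n_genes = 400,
                        n_aging_up = 20, n_aging_down = 20,
                        n_tissue_specific = 40, n_replicates = 5,
                        module_specs = list(module_spec(size = 24)), ...) {
  generate_study(study_config(
    n_tissues = n_tissues, n_genes = n_genes, n_aging_up = n_aging_up,
    n_aging_down = n_aging_down, n_tissue_specific = n_tissue_specific,
    n_replicates = n_replicates, module_specs = module_specs,
    seed = seed, ...))
}

# Minimal expression container around a hand-built log2 value matrix.
make_expr <- function(values, fpkm = 2^values - 1) {
  structure(list(values = values, fpkm = fpkm,
                 detectable = stats::setNames(rep(TRUE, nrow(values)),
                                              rownames(values)),
                 pseudocount = 1, min_fpkm = 0.5, min_sample_frac = 0.2,
                 tmm_factors = NULL),
            class = "expr_matrix")
}

# Metadata for one tissue over the canonical five ages.
make_meta <- function(tissue = "liver", ages = c(8, 26, 60, 78, 104),
                      reps = 5) {
  df <- expand.grid(replicate = seq_len(reps), age_weeks = ages,
                    stringsAsFactors = FALSE)
  df$tissue <- tissue
  df$sample_id <- sprintf("%s_%03dw_r%d", tissue, df$age_weeks, df$replicate)
  df[, c("sample_id", "tissue", "age_weeks", "replicate")]
}

# Definition-level O(m^2) Benjamini-Hochberg oracle:
# q_i = min over j with p_j >= p_i of m * p_j / rank(p_j), capped at 1.
bh_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    cand <- which(p >= p[i] - 1e-15)
    min(1, min(m * p[cand] / r[cand]))
  }, numeric(1))
}

# Stage-edge tables for a hand-crafted graph: 'sig' is a list of four
# logical vectors over the pair grid.
fake_stage_edges <- function(pairs, sig) {
  lapply(1:4, function(s) {
    data.frame(lnc_id = pairs$lnc_id, mrna_id = pairs$mrna_id,
               r = ifelse(sig[[s]], 0.95, 0.1),
               p = ifelse(sig[[s]], 1e-6, 0.5),
               q = ifelse(sig[[s]], 1e-5, 0.8),
               significant = sig[[s]], stringsAsFactors = FALSE)
  })
}

# Complete bipartite pair grid between two node sets.
biclique_pairs <- function(lnc, mrna) {
  expand.grid(lnc_id = lnc, mrna_id = mrna, stringsAsFactors = FALSE)
}
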