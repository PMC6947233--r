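# Small builders and a per-session cache for the heavier simulations shared
# across test files.

tiny_markers <- function(n = 3, chrom = "1", spacing = 1000L) {
  data.frame(marker_id = paste0("m", seq_len(n)), chrom = chrom,
             pos_bp = seq_len(n) * spacing, allele_ref = "A",
             allele_alt = "B", stringsAsFactors = FALSE)
}

tiny_ds <- function(g, chrom = "1") {
  g <- as.matrix(g)
  genotype_dataset(g, tiny_markers(ncol(g), chrom),
                   data.frame(sample_id = paste0("s", seq_len(nrow(g))),
                              stringsAsFactors = FALSE))
}

tiny_hs <- function(H, pops = NULL, spacing = 1000L) {
  H <- as.matrix(H)
  ids <- paste0("s", seq_len(nrow(H) / 2))
  if (is.null(pops)) pops <- rep("P1", length(ids))
  haplotype_set(H, rep(ids, each = 2), tiny_markers(ncol(H), spacing = spacing),
                pop_of = stats::setNames(pops, ids))
}

# random complete haplotype matrix with blocky LD-like columns
random_haps <- function(n_hap, m, seed) {
  set.seed(seed)
  base <- matrix(rbinom(4 * m, 1, 0.5), nrow = 4)
  H <- base[sample.int(4, n_hap, replace = TRUE), , drop = FALSE]
  flip <- matrix(rbinom(n_hap * m, 1, 0.15), nrow = n_hap)
  (H + flip) %% 2
}

.sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, cfg) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- simulate_divergence(cfg)
  .sim_cache[[key]]
}

# a small two-population cohort with one planted sweep, reused across files
small_sweep_sim <- function() {
  cached_sim("sweep", sim_config(
    n_pop = 60, n_chrom = 2, m_snps = 500, chrom_len_bp = 1e7,
    burn_in = 50, n_anc = 120, split_generations = 40,
    sweeps = data.frame(chrom = "1", pos_bp = 5e6, s = 0.25,
                        target_pop = "SJ"),
    seed = 11))
}

small_null_sim <- function() {
  cached_sim("null", sim_config(
    n_pop = 60, n_chrom = 2, m_snps = 500, chrom_len_bp = 1e7,
    burn_in = 50, n_anc = 120, split_generations = 40, seed = 12))
}
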