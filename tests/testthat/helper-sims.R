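# Shared simulated datasets, built once per test run and cached.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) assign(key, force(expr), .sim_cache)
  get(key, .sim_cache)
}

# tiny: fast smoke-scale experiment
tiny_cfg <- function(seed = 42, ...) {
  sim_config(n_genes = 12, gene_length_mean = 400, gene_length_sd = 40,
             library_sizes = list(p1 = 4e3, p2 = 4e3, allo = 8e3),
             n_deletion_clusters = 0, genes_per_supercontig = 6,
             seed = seed, ...)
}

# clean: error-free, deep, for truth-exactness properties
clean_cfg <- function(seed = 5, ...) {
  args <- list(n_genes = 60, gene_length_mean = 600, gene_length_sd = 60,
               library_sizes = list(p1 = 25e3, p2 = 25e3, allo = 6e4),
               n_deletion_clusters = 1, deletion_cluster_size = 2,
               genes_per_supercontig = 20, error_rate = 0, seed = seed)
  ov <- list(...)
  args[names(ov)] <- ov
  do.call(sim_config, args)
}

clean_sim <- function() cached("clean_sim", simulate_experiment(clean_cfg()))
clean_res <- function() cached("clean_res", analyze_experiment(clean_sim()))

# study: study-condition experiment (paper-like fate proportions, 4-fold
# effects, deep coverage, default error rate) for recovery properties
study_cfg <- function(seed = 11) {
  sim_config(n_genes = 300, gene_length_mean = 900, gene_length_sd = 150,
             library_sizes = list(p1 = 6e4, p2 = 6e4, allo = 15e4),
             n_deletion_clusters = 2, deletion_cluster_size = 3,
             genes_per_supercontig = 50, seed = seed)
}

study_sim <- function() cached("study_sim", simulate_experiment(study_cfg()))
study_res <- function() cached("study_res", analyze_experiment(study_sim()))

# lightweight stand-in gene set when only gene ids matter
fake_gene_set <- function(n) {
  ids <- sprintf("g%05d", seq_len(n))
  structure(list(seqs = setNames(rep("ACGTACGT", n), ids)),
            class = "gene_set")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_at <- function(seq, pos0, base) {
  substr(seq, pos0 + 1, pos0 + 1) <- base
  seq
}
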