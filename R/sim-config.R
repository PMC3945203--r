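#' Simulation configuration
#'
#' Builds and validates the configuration for the synthetic-data generator.
#' Defaults emulate the study system the package targets: a surrogate
#' reference gene set, one parent closely related to the reference and one
#' an order of magnitude more divergent, an allopolyploid carrying the
#' union of both parental genomes plus private post-hybridization
#' substitutions and clustered single-subgenome gene deletions, and per-gene
#' expression fates drawn from configurable category proportions.
#'
#' @param n_genes number of gene models.
#' @param gene_length_mean,gene_length_sd transcript length distribution
#'   (bp, normal, floored at \code{read_length}).
#' @param divergence_ancestral substitutions per site on the branch shared
#'   by both parents and the allopolyploid (relative to the reference).
#' @param divergence_close,divergence_far substitutions per site on the
#'   pre-hybridization branches of parent 1 (close to the reference) and
#'   parent 2 (divergent); these substitutions are inherited by the
#'   corresponding allopolyploid subgenome.
#' @param post_hyb_subs_p1,post_hyb_subs_p2 substitutions per site accrued
#'   after hybridization, applied independently at the same rate to the
#'   parent's private tip branch and to the allopolyploid subgenome branch
#'   (equal elapsed time on both sides of the split).
#' @param n_deletion_clusters,deletion_cluster_size number and size (genes)
#'   of clustered single-subgenome deletions in the allopolyploid.
#' @param fate_proportions nonnegative weights for the four expression
#'   outcomes (inheritance, blending, bias, reversal); normalized to sum 1.
#' @param inheritance_biased_frac fraction of inheritance genes carrying a
#'   parental expression bias (the rest are unbiased in both generations).
#' @param bias_log2_effect magnitude (log2) of "biased" expression.
#' @param expr_log2_mean,expr_log2_sd log2 base-expression distribution.
#' @param library_sizes named list with numeric vectors \code{p1},
#'   \code{p2}, \code{allo}: reads (fragments when paired) per replicate.
#' @param read_length read length in bp.
#' @param paired simulate the allopolyploid library as mate pairs.
#' @param fragment_length_mean,fragment_length_sd insert-size model for
#'   paired mode (bp).
#' @param error_rate per-base sequencing error probability.
#' @param genes_per_supercontig layout of gene models on synthetic
#'   supercontigs (used by the physical clustering analysis).
#' @param seed master seed; per-stage child seeds are derived
#'   deterministically so a fixed seed gives byte-identical outputs.
#'
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes = 1000,
                       gene_length_mean = 900,
                       gene_length_sd = 150,
                       divergence_ancestral = 0.002,
                       divergence_close = 0.004,
                       divergence_far = 0.04,
                       post_hyb_subs_p1 = 5e-4,
                       post_hyb_subs_p2 = 5e-4,
                       n_deletion_clusters = 3,
                       deletion_cluster_size = 3,
                       fate_proportions = c(inheritance = 0.561,
                                            blending = 0.251,
                                            bias = 0.156,
                                            reversal = 0.032),
                       inheritance_biased_frac = 0.25,
                       bias_log2_effect = 2.0,
                       expr_log2_mean = 5,
                       expr_log2_sd = 1.5,
                       library_sizes = list(p1 = c(2e5, 2e5),
                                            p2 = c(2e5, 2e5),
                                            allo = c(4e5, 4e5)),
                       read_length = 100,
                       paired = TRUE,
                       fragment_length_mean = 300,
                       fragment_length_sd = 30,
                       error_rate = 0.001,
                       genes_per_supercontig = 50,
                       seed = 1) {
  if (!is.numeric(n_genes) || n_genes < 1)
    stop("'n_genes' must be >= 1")
  n_genes <- as.integer(n_genes)
  if (gene_length_mean <= 0 || gene_length_sd < 0)
    stop("gene lengths must be positive")
  for (nm in c("divergence_ancestral", "divergence_close", "divergence_far",
               "post_hyb_subs_p1", "post_hyb_subs_p2", "error_rate"))
    stopifnot_prob(get(nm), nm)
  if (length(fate_proportions) != 4 || any(fate_proportions < 0) ||
      sum(fate_proportions) <= 0)
    stop("'fate_proportions' must be four nonnegative weights with positive sum")
  fate_proportions <- fate_proportions / sum(fate_proportions)
  names(fate_proportions) <- c("inheritance", "blending", "bias", "reversal")
  stopifnot_prob(inheritance_biased_frac, "inheritance_biased_frac",
                 allow_one = TRUE)
  if (bias_log2_effect <= 0) stop("'bias_log2_effect' must be > 0")
  if (n_deletion_clusters < 0 || deletion_cluster_size < 1)
    stop("deletion cluster settings invalid")
  if (n_genes < n_deletion_clusters * deletion_cluster_size)
    stop("'n_genes' must be >= n_deletion_clusters * deletion_cluster_size")
  if (!all(c("p1", "p2", "allo") %in% names(library_sizes)))
    stop("'library_sizes' needs elements p1, p2, allo")
  if (any(unlist(library_sizes) < 0)) stop("library sizes must be >= 0")
  if (read_length < 1) stop("'read_length' must be >= 1")
  structure(list(
    n_genes = n_genes,
    gene_length_mean = gene_length_mean,
    gene_length_sd = gene_length_sd,
    divergence_ancestral = divergence_ancestral,
    divergence_close = divergence_close,
    divergence_far = divergence_far,
    post_hyb_subs_p1 = post_hyb_subs_p1,
    post_hyb_subs_p2 = post_hyb_subs_p2,
    n_deletion_clusters = as.integer(n_deletion_clusters),
    deletion_cluster_size = as.integer(deletion_cluster_size),
    fate_proportions = fate_proportions,
    inheritance_biased_frac = inheritance_biased_frac,
    bias_log2_effect = bias_log2_effect,
    expr_log2_mean = expr_log2_mean,
    expr_log2_sd = expr_log2_sd,
    library_sizes = lapply(library_sizes, as.numeric),
    read_length = as.integer(read_length),
    paired = isTRUE(paired),
    fragment_length_mean = fragment_length_mean,
    fragment_length_sd = fragment_length_sd,
    error_rate = error_rate,
    genes_per_supercontig = as.integer(genes_per_supercontig),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genes, "genes;",
      "divergence (ancestral/close/far):",
      paste(x$divergence_ancestral, x$divergence_close, x$divergence_far,
            sep = "/"),
      "\n  fates:", paste(sprintf("%s=%.3f", names(x$fate_proportions),
                                  x$fate_proportions), collapse = " "),
      "\n  seed:", x$seed, "\n")
  invisible(x)
}
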