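#' Pipeline thresholds
#'
#' Collects every tunable of the analysis chain in one validated object.
#' Unknown settings are rejected.
#'
#' @param fold_de fold threshold of the differential-expression rule.
#' @param fold_ede extreme fold threshold for EDE genes.
#' @param min_parent_reads per-parent read minimum for gene retention.
#' @param min_ede_reads minimum allopolyploid reads for EDE eligibility.
#' @param min_informative_len minimum informative region length (bp).
#' @param q_thresh q-value threshold.
#' @param k_assign seed length for zero-mismatch assignment.
#' @param k_discovery seed length for low-stringency discovery mapping.
#' @param max_mismatch_discovery mismatch bound of discovery mapping;
#'   \code{NULL} means \code{ceiling(0.10 * read_length)}.
#' @param min_links,max_conflict_frac linkage-assignment thresholds.
#' @param min_cov_parent,min_alt_frac_parent parent variant calling.
#' @param min_alt_reads_allo,min_alt_frac_allo allopolyploid calling.
#' @param mu mutation rate per site per year for dating.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(fold_de = 2, fold_ede = 50,
                            min_parent_reads = 5, min_ede_reads = 5,
                            min_informative_len = 150, q_thresh = 0.05,
                            k_assign = 21, k_discovery = 9,
                            max_mismatch_discovery = NULL,
                            min_links = 3, max_conflict_frac = 0.05,
                            min_cov_parent = 5, min_alt_frac_parent = 0.9,
                            min_alt_reads_allo = 3, min_alt_frac_allo = 0.1,
                            mu = 1e-9) {
  vals <- as.list(environment())
  num <- vals[setdiff(names(vals), "max_mismatch_discovery")]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(unlist(num) <= 0 & !names(unlist(num)) %in% "max_conflict_frac"))
    stop("thresholds must be positive numbers")
  structure(vals, class = "pipeline_config")
}

cheap_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2^28
  sprintf("%07x", h)
}

output_header <- function(sim_cfg, pcfg) {
  sprintf("# homeofate %s | seed=%d | config=%s",
          as.character(packageVersion("homeofate")), sim_cfg$seed,
          cheap_hash(list(unclass(sim_cfg), unclass(pcfg))))
}

write_tsv <- function(x, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

concat_reads <- function(reps, paired) {
  r1 <- do.call(c, lapply(reps, `[[`, "reads"))
  if (paired) {
    r2 <- do.call(c, lapply(reps, `[[`, "reads2"))
    list(r1 = r1, r2 = r2,
         all = c(setNames(r1, paste0(names(r1), "/1")),
                 setNames(r2, paste0(names(r2), "/2"))))
  } else list(r1 = r1, r2 = NULL, all = r1)
}

#' Run the full homeolog-expression analysis on a simulated experiment
#'
#' Chains every stage: low-stringency discovery mapping of all three
#' samples against the surrogate reference; variant calling and
#' diagnostic classification (with linkage assignment of
#' allopolyploid-private SNPs); homeolog reference construction, masking
#' and gene culling; zero-mismatch parental counting and allopolyploid
#' homeolog assignment; expression statistics; fate, dominance, EDE, loss
#' and cluster classification; and dating.
#'
#' @param sim a \code{\link{simulate_experiment}} result (or an
#'   equivalently shaped list of real inputs).
#' @param pcfg a \code{\link{pipeline_config}}.
#' @return list with the results of every stage.
#' @export
analyze_experiment <- function(sim, pcfg = pipeline_config()) {
  cfg <- sim$cfg
  rl <- cfg$read_length
  mm_disc <- pcfg$max_mismatch_discovery %||% ceiling(0.10 * rl)
  ref <- sim$gene_set$seqs

  # --- discovery: map all samples to the surrogate reference ------------
  idx_disc <- build_index(ref, k = pcfg$k_discovery)
  p1 <- concat_reads(sim$reads$p1, paired = FALSE)
  p2 <- concat_reads(sim$reads$p2, paired = FALSE)
  al <- concat_reads(sim$reads$allo, paired = cfg$paired)
  map_u <- function(reads) {
    filter_unique_gene_hits(map_reads(reads, idx_disc, mm_disc))
  }
  h_p1 <- map_u(p1$all)
  h_p2 <- map_u(p2$all)
  h_al <- map_u(al$all)

  pu_p1 <- pileup(h_p1, p1$all, ref)
  pu_p2 <- pileup(h_p2, p2$all, ref)
  pu_al <- pileup(h_al, al$all, ref)
  v_p1 <- call_parent_variants(pu_p1, ref, pcfg$min_cov_parent,
                               pcfg$min_alt_frac_parent)
  v_p2 <- call_parent_variants(pu_p2, ref, pcfg$min_cov_parent,
                               pcfg$min_alt_frac_parent)
  v_al <- call_allo_variants(pu_al, ref, pcfg$min_alt_reads_allo,
                             pcfg$min_alt_frac_allo)
  snps <- classify_snps(v_p1, v_p2, v_al)
  snps <- assign_allo_unique_by_ld(h_al, al$all, snps,
                                   min_links = pcfg$min_links,
                                   max_conflict_frac = pcfg$max_conflict_frac)
  counts_cls <- class_counts(snps)

  # --- homeolog references ---------------------------------------------
  homref <- build_homeolog_references(sim$gene_set, snps)
  homref <- add_informative_regions(homref, rl)
  homref <- mask_noninformative(homref)

  # --- counting ---------------------------------------------------------
  pc_p1 <- lapply(sim$reads$p1, function(r)
    count_parent_reads(r$reads, homref, "p1", k = pcfg$k_assign))
  pc_p2 <- lapply(sim$reads$p2, function(r)
    count_parent_reads(r$reads, homref, "p2", k = pcfg$k_assign))
  parent_counts_rep <- list(
    p1 = vapply(pc_p1, `[[`, numeric(length(ref)), "counts"),
    p2 = vapply(pc_p2, `[[`, numeric(length(ref)), "counts"))
  parent_counts <- cbind(p1 = rowSums(parent_counts_rep$p1),
                         p2 = rowSums(parent_counts_rep$p2))
  rownames(parent_counts) <- names(ref)
  parent_totals <- c(p1 = sum(parent_counts[, "p1"]),
                     p2 = sum(parent_counts[, "p2"]))

  asg <- lapply(sim$reads$allo, function(r)
    assign_reads(r$reads, homref, reads2 = r$reads2, k = pcfg$k_assign))
  allo_counts <- Reduce(`+`, lapply(asg, `[[`, "counts"))
  allo_totals <- c(allo_p1 = sum(allo_counts[, 1]),
                   allo_p2 = sum(allo_counts[, 2]))
  assign_summary <- list(
    assigned = unname(sum(allo_totals)),
    ambiguous = sum(vapply(asg, `[[`, numeric(1), "ambiguous")),
    unassigned = sum(vapply(asg, `[[`, numeric(1), "unassigned")),
    n_fragments = sum(vapply(asg, `[[`, numeric(1), "n_fragments")))

  # --- culling ----------------------------------------------------------
  homref <- cull_genes(homref, parent_counts, pcfg$min_parent_reads,
                       pcfg$min_informative_len)
  retained <- names(homref$retained)[homref$retained]

  # --- statistics and fate ---------------------------------------------
  pc_r <- parent_counts[retained, , drop = FALSE]
  ac_r <- allo_counts[retained, , drop = FALSE]
  records <- expression_records(pc_r, parent_totals, ac_r, allo_totals,
                                pcfg$fold_de, pcfg$q_thresh)
  fates <- classify_fates(records)
  proportions <- outcome_proportions(fates)
  dominance <- dominance_classify(records, pc_r, parent_totals, ac_r,
                                  allo_totals, pcfg$fold_de, pcfg$q_thresh)
  ede <- find_ede(ac_r, allo_totals, pcfg$min_ede_reads, pcfg$fold_ede)
  loss <- loss_candidates(ac_r)
  clusters <- cluster_ede(sim$gene_set$coords, ede, retained)
  independence <- lapply(
    c("exclude_unbiased", "unbiased_as_independent",
      "unbiased_as_nonindependent"),
    function(tr) independence_proportions(fates, tr))
  names(independence) <- c("exclude_unbiased", "unbiased_as_independent",
                           "unbiased_as_nonindependent")

  dating <- date_upper_bound(shortest_branch_snps(counts_cls), homref$L,
                             pcfg$mu)

  list(snps = snps, class_counts = counts_cls,
       share_stats = snp_share_stats(counts_cls),
       homref = homref, retained = retained,
       parent_counts = parent_counts, parent_totals = parent_totals,
       allo_counts = allo_counts, allo_totals = allo_totals,
       assign_summary = assign_summary,
       records = records, fates = fates, proportions = proportions,
       dominance = dominance, ede = ede, loss = loss, clusters = clusters,
       independence = independence, dating = dating, pcfg = pcfg)
}

#' Run the pipeline end to end and write its outputs
#'
#' Simulates an experiment (unless one is supplied), analyzes it, and
#' writes the module outputs (diagnostic SNP VCF and class counts,
#' homeolog references and cull report, count and expression tables, fate
#' and cluster reports, JSON summaries) under \code{outdir}. Every table
#' carries a header comment with the tool version, configuration hash and
#' seed.
#'
#' @param sim_cfg a \code{\link{sim_config}}.
#' @param pcfg a \code{\link{pipeline_config}}.
#' @param outdir output directory, or \code{NULL} to skip writing.
#' @param sim optionally, a pre-built \code{\link{simulate_experiment}}.
#' @return the \code{\link{analyze_experiment}} result list, invisibly
#'   when writing.
#' @export
run_pipeline <- function(sim_cfg = sim_config(), pcfg = pipeline_config(),
                         outdir = NULL, sim = NULL) {
  if (is.null(sim)) sim <- simulate_experiment(sim_cfg)
  res <- analyze_experiment(sim, pcfg)
  if (is.null(outdir)) return(res)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hd <- output_header(sim$cfg, pcfg)
  write_snp_vcf(res$snps, file.path(outdir, "diagnostic_snps.vcf"))
  write_tsv(data.frame(class = names(res$class_counts),
                       count = as.integer(res$class_counts)),
            file.path(outdir, "snp_class_counts.tsv"), hd)
  write_homeolog_refs(res$homref, outdir)
  cm <- data.frame(gene_id = rownames(res$parent_counts),
                   p1_ortholog = res$parent_counts[, 1],
                   p2_ortholog = res$parent_counts[, 2],
                   allo_p1_homeolog = res$allo_counts[, 1],
                   allo_p2_homeolog = res$allo_counts[, 2])
  write_tsv(cm, file.path(outdir, "count_table.tsv"), hd)
  write_tsv(res$records, file.path(outdir, "expression_records.tsv"), hd)
  fate_tab <- res$fates
  fate_tab$dominance <- res$dominance$dominance[
    match(fate_tab$gene_id, res$dominance$gene_id)]
  fate_tab$driver <- res$dominance$driver[
    match(fate_tab$gene_id, res$dominance$gene_id)]
  fate_tab$ede <- res$ede[fate_tab$gene_id]
  fate_tab$loss <- res$loss$flag[fate_tab$gene_id]
  write_tsv(fate_tab, file.path(outdir, "fate_table.tsv"), hd)
  write_tsv(res$clusters$clusters, file.path(outdir, "ede_clusters.tsv"), hd)
  lr <- log_ratio_table(res$parent_counts[res$retained, , drop = FALSE],
                        res$parent_totals,
                        res$allo_counts[res$retained, , drop = FALSE],
                        res$allo_totals)
  write_tsv(lr, file.path(outdir, "log_ratios.tsv"), hd)
  summary <- list(
    seed = sim$cfg$seed,
    version = as.character(packageVersion("homeofate")),
    config_hash = cheap_hash(list(unclass(sim$cfg), unclass(res$pcfg))),
    n_genes = length(sim$gene_set$seqs),
    n_retained = length(res$retained),
    retention_pct = 100 * length(res$retained) /
      length(sim$gene_set$seqs),
    class_counts = as.list(res$class_counts),
    share_stats = res$share_stats,
    assign_summary = res$assign_summary,
    outcome_proportions = as.list(res$proportions),
    loss = res$loss[c("n_both_silent", "n_p1_only", "n_p2_only", "total",
                      "detection_rate_pct")],
    ede_clustering = res$clusters[c("n_clustered", "n_ede",
                                    "clustered_fraction_pct")],
    dating = res$dating)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
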