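test_that("gene set simulation validates inputs and degenerate settings", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(gene_length_mean = -5), "length")
  expect_error(sim_config(divergence_far = 1), "rate")
  expect_error(sim_config(fate_proportions = c(-1, 1, 1, 1)), "fate")
  expect_error(sim_config(n_genes = 5, n_deletion_clusters = 3,
                          deletion_cluster_size = 2), "deletion")
  cfg <- sim_config(n_genes = 100, gene_length_mean = 1000,
                    gene_length_sd = 0)
  gs <- simulate_gene_set(cfg)
  expect_true(all(Biostrings::width(gs$seqs) == 1000))
  expect_equal(nrow(gs$coords), 100)
  # 0-based half-open coordinates consistent with lengths and ordered
  expect_equal(gs$coords$end - gs$coords$start,
               unname(Biostrings::width(gs$seqs)))
  for (sc in unique(gs$coords$supercontig)) {
    co <- gs$coords[gs$coords$supercontig == sc, ]
    expect_true(all(diff(co$start) > 0))
    expect_true(all(co$start[-1] >= co$end[-nrow(co)]))
  }
})

test_that("a fixed seed reproduces the gene set FASTA byte for byte", {
  cfg <- sim_config(n_genes = 5, seed = 1, n_deletion_clusters = 0)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  Biostrings::writeXStringSet(simulate_gene_set(cfg)$seqs, f1)
  Biostrings::writeXStringSet(simulate_gene_set(cfg)$seqs, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("lineage evolution places branch-labelled substitutions", {
  cfg0 <- sim_config(n_genes = 4, divergence_ancestral = 0,
                     divergence_close = 0, divergence_far = 0,
                     post_hyb_subs_p1 = 0, post_hyb_subs_p2 = 0,
                     n_deletion_clusters = 0)
  gs0 <- simulate_gene_set(cfg0)
  lin0 <- evolve_lineages(gs0, cfg0)
  expect_equal(nrow(lin0$variants), 0)
  for (g in names(lin0$genomes))
    expect_identical(as.character(lin0$genomes[[g]]),
                     as.character(gs0$seqs))

  # binomial oracle on the divergent-parent branch count
  cfg <- sim_config(n_genes = 200, gene_length_mean = 1000,
                    gene_length_sd = 0, divergence_far = 0.03, seed = 3)
  gs <- simulate_gene_set(cfg)
  lin <- evolve_lineages(gs, cfg)
  L <- sum(Biostrings::width(gs$seqs))
  n_far <- sum(lin$variants$lineage == "p2_branch")
  expect_lt(abs(n_far - L * 0.03), 3 * sqrt(L * 0.03 * 0.97))

  # ancestral substitutions appear in both parents and both subgenomes
  anc <- lin$variants[lin$variants$lineage == "ancestral", ]
  anc <- anc[seq_len(min(50, nrow(anc))), ]
  for (i in seq_len(nrow(anc)))
    for (g in c("parent1", "parent2", "allo_p1", "allo_p2"))
      expect_identical(
        substr(as.character(lin$genomes[[g]][[anc$gene_id[i]]]),
               anc$pos[i] + 1, anc$pos[i] + 1), anc$alt[i])

  # sites are bi-allelic: one lineage per (gene, pos)
  expect_false(any(duplicated(paste(lin$variants$gene_id,
                                    lin$variants$pos))))
  expect_error(evolve_lineages(gs, within.list(cfg, divergence_far <- 1)))
})

test_that("deletions remove clustered adjacent genes from one subgenome", {
  cfg <- sim_config(n_genes = 40, n_deletion_clusters = 0, seed = 2,
                    genes_per_supercontig = 10)
  gs <- simulate_gene_set(cfg)
  lin <- evolve_lineages(gs, cfg)
  d0 <- apply_deletions(lin$genomes, gs, cfg)
  expect_equal(nrow(d0$deletions), 0)
  expect_identical(names(d0$genomes$allo_p1), names(gs$seqs))

  cfg2 <- sim_config(n_genes = 40, n_deletion_clusters = 2,
                     deletion_cluster_size = 3, seed = 2,
                     genes_per_supercontig = 10)
  d1 <- apply_deletions(lin$genomes, gs, cfg2)
  d2 <- apply_deletions(lin$genomes, gs, cfg2)
  expect_identical(d1$deletions, d2$deletions)  # seed-deterministic
  expect_equal(nrow(d1$deletions), 6)
  for (cl in unique(d1$deletions$cluster)) {
    genes <- d1$deletions$gene_id[d1$deletions$cluster == cl]
    side <- unique(d1$deletions$deleted_subgenome[d1$deletions$cluster == cl])
    expect_length(side, 1)
    co <- gs$coords[gs$coords$gene_id %in% genes, ]
    expect_length(unique(co$supercontig), 1)  # fits one supercontig
    slot <- if (side == "P1") "allo_p1" else "allo_p2"
    expect_false(any(genes %in% names(d1$genomes[[slot]])))
    other <- if (side == "P1") "allo_p2" else "allo_p1"
    expect_true(all(genes %in% names(d1$genomes[[other]])))
  }
})

test_that("expression fates follow the effect-size rules and proportions", {
  cfg1 <- sim_config(n_genes = 50,
                     fate_proportions = c(1, 0, 0, 0))
  tr1 <- assign_expression_fates(fake_gene_set(50), cfg1)
  expect_true(all(tr1$category == "inheritance"))
  expect_true(all(tr1$rho_h == tr1$rho_p))

  cfg <- sim_config(n_genes = 10000,
                    fate_proportions = c(0.4, 0.3, 0.2, 0.1), seed = 9)
  tr <- assign_expression_fates(fake_gene_set(10000), cfg)
  # rules per category
  bl <- tr[tr$category == "blending", ]
  expect_true(all(abs(bl$rho_p) >= 1 & bl$rho_h == 0))
  bi <- tr[tr$category == "bias", ]
  expect_true(all(bi$rho_p == 0 & abs(bi$rho_h) == cfg$bias_log2_effect))
  rv <- tr[tr$category == "reversal", ]
  expect_true(all(rv$rho_h == -rv$rho_p & abs(rv$rho_p) > 0))
  # multinomial oracle on category frequencies
  p <- c(inheritance = 0.4, blending = 0.3, bias = 0.2, reversal = 0.1)
  obs <- table(factor(tr$category, levels = names(p)))
  for (k in names(p))
    expect_lt(abs(obs[[k]] - 10000 * p[[k]]),
              3 * sqrt(10000 * p[[k]] * (1 - p[[k]])))
  expect_error(assign_expression_fates(fake_gene_set(5),
                                       within.list(cfg,
                                                   bias_log2_effect <- 0)))
})

test_that("read simulation respects truth, errors and the multinomial", {
  cfg <- sim_config(n_genes = 200, gene_length_mean = 700,
                    gene_length_sd = 100, error_rate = 0, paired = FALSE,
                    seed = 21)
  gs <- simulate_gene_set(cfg)
  tx <- as.character(gs$seqs)
  expr <- setNames(2^rnorm(200, 4, 1), names(tx))

  r0 <- simulate_reads(tx, expr, 0, cfg, paired = FALSE)
  expect_length(r0$reads, 0)

  set.seed(1)
  rr <- simulate_reads(tx, expr, 1e5, cfg, paired = FALSE)
  expect_equal(nrow(rr$origin), 1e5)
  # error-free reads are exact substrings of their origin (or its RC)
  idx <- sample.int(1e5, 300)
  for (i in idx) {
    o <- rr$origin[i, ]
    frag <- substr(tx[[o$transcript]], o$pos + 1, o$pos + cfg$read_length)
    expected <- if (o$strand == "+") frag
                else as.character(Biostrings::reverseComplement(
                  Biostrings::DNAString(frag)))
    expect_identical(unname(rr$reads[[o$read_id]]), expected)
  }
  # multinomial oracle on per-gene counts
  p <- expr * (nchar(tx) - cfg$read_length + 1)
  p <- p / sum(p)
  obs <- table(factor(rr$origin$transcript, levels = names(tx)))
  z <- (as.numeric(obs) - 1e5 * p) / sqrt(1e5 * p * (1 - p))
  expect_gt(mean(abs(z) <= 3), 0.985)
  expect_lt(max(abs(z)), 4.5)
  expect_error(simulate_reads(substr(tx, 1, 50), expr, 10, cfg),
               "read_length")
})

test_that("paired mode emits proper mate pairs from one fragment", {
  cfg <- sim_config(n_genes = 10, gene_length_mean = 600,
                    gene_length_sd = 0, error_rate = 0, paired = TRUE,
                    seed = 8)
  gs <- simulate_gene_set(cfg)
  tx <- as.character(gs$seqs)
  expr <- setNames(rep(1, 10), names(tx))
  set.seed(2)
  rp <- simulate_reads(tx, expr, 500, cfg)
  expect_length(rp$reads, 500)
  expect_length(rp$reads2, 500)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x)))
  for (i in sample.int(500, 50)) {
    o <- rp$origin[i, ]
    t_ <- tx[[o$transcript]]
    r1 <- unname(rp$reads[[o$read_id]]); r2 <- unname(rp$reads2[[o$read_id]])
    # both mates match the transcript, on opposite strands
    m1 <- if (o$strand == "+") r1 else rc(r1)
    m2 <- if (o$strand == "+") rc(r2) else r2
    expect_true(grepl(m1, t_, fixed = TRUE))
    expect_true(grepl(m2, t_, fixed = TRUE))
  }
})

test_that("the experiment wrapper ties truth to reads and is reproducible", {
  sim <- clean_sim()
  cfg <- sim$cfg
  # origin sidecar sums equal library sizes exactly
  for (smp in names(sim$reads))
    for (r in seq_along(sim$reads[[smp]]))
      expect_equal(nrow(sim$reads[[smp]][[r]]$origin),
                   cfg$library_sizes[[smp]][r])
  # deleted homeologs produce zero reads
  del <- sim$deletions
  for (i in seq_len(nrow(del))) {
    tx_gone <- paste0(del$gene_id[i], "|", del$deleted_subgenome[i])
    for (r in seq_along(sim$reads$allo))
      expect_false(tx_gone %in% sim$reads$allo[[r]]$origin$transcript)
  }
  # same seed, same truth
  sim2 <- simulate_experiment(cfg)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$variants, sim2$variants)
  expect_identical(sim$reads$allo[[1]]$reads, sim2$reads$allo[[1]]$reads)
})

test_that("write_sim emits the expected plain-text artifacts", {
  cfg <- tiny_cfg()
  sim <- simulate_experiment(cfg)
  d <- tempfile("simout")
  write_sim(sim, d)
  expect_true(file.exists(file.path(d, "reference.fasta")))
  expect_true(file.exists(file.path(d, "p1_rep1.fastq")))
  expect_true(file.exists(file.path(d, "allo_rep1_1.fastq")))
  expect_true(file.exists(file.path(d, "allo_rep1_2.fastq")))
  expect_true(file.exists(file.path(d, "truth_variants.tsv")))
  expect_true(file.exists(file.path(d, "config.json")))
  fq <- Biostrings::readDNAStringSet(file.path(d, "p1_rep1.fastq"),
                                     format = "fastq")
  expect_length(fq, cfg$library_sizes$p1[1])
  unlink(d, recursive = TRUE)
})
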