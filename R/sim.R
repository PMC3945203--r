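#' Simulate a surrogate reference gene set
#'
#' Generates random intron-free transcript models laid out in order on
#' synthetic supercontigs with 0-based half-open coordinates. The
#' coordinates exist for the physical clustering analysis; all mapping is
#' done in transcript space.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A \code{gene_set}: list with \code{seqs} (a
#'   \code{DNAStringSet} named by gene id) and \code{coords} (data.frame
#'   with gene_id, supercontig, start, end, strand; 0-based half-open).
#' @export
simulate_gene_set <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "gene_set"))
  n <- cfg$n_genes
  len <- if (cfg$gene_length_sd == 0) rep(cfg$gene_length_mean, n)
         else round(rnorm(n, cfg$gene_length_mean, cfg$gene_length_sd))
  len <- pmax(as.integer(len), cfg$read_length)
  if (any(len <= 0)) stop("non-positive gene length")
  ids <- sprintf("g%05d", seq_len(n))
  seqs <- vapply(len, function(L)
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = ""), character(1))
  names(seqs) <- ids

  sc_idx <- ceiling(seq_len(n) / cfg$genes_per_supercontig)
  sc <- sprintf("sc%03d", sc_idx)
  start <- integer(n); end <- integer(n)
  gaps <- sample(200:2000, n, replace = TRUE)
  pos <- 0L
  for (i in seq_len(n)) {
    if (i > 1 && sc_idx[i] != sc_idx[i - 1]) pos <- 0L
    start[i] <- pos + gaps[i]
    end[i] <- start[i] + len[i]
    pos <- end[i]
  }
  coords <- data.frame(gene_id = ids, supercontig = sc, start = start,
                       end = end,
                       strand = sample(c("+", "-"), n, replace = TRUE),
                       stringsAsFactors = FALSE)
  structure(list(seqs = Biostrings::DNAStringSet(seqs), coords = coords),
            class = "gene_set")
}

# substitute alt bases at 0-based positions in a character-vector sequence
apply_subs <- function(seq_chars, pos0, alt) {
  if (length(pos0)) seq_chars[pos0 + 1L] <- alt
  seq_chars
}

#' Evolve parental and allopolyploid lineages from the reference
#'
#' Places substitutions i.i.d. per site on each branch of the strain
#' phylogeny: an ancestral branch shared by both parents and the
#' allopolyploid; pre-hybridization parent branches (inherited by the
#' matching allopolyploid subgenome); post-hybridization private tips for
#' each parent; and private allopolyploid subgenome branches. Sites are
#' kept bi-allelic: a site hit on one branch is excluded from the draws of
#' the others.
#'
#' @param gene_set a \code{\link{simulate_gene_set}} result.
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{genomes} (named list of \code{DNAStringSet}:
#'   parent1, parent2, allo_p1, allo_p2) and \code{variants} (data.frame
#'   gene_id, pos (0-based), ref, alt, lineage).
#' @export
evolve_lineages <- function(gene_set, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rates <- c(ancestral = cfg$divergence_ancestral,
             p1_branch = cfg$divergence_close,
             p2_branch = cfg$divergence_far,
             p1_private = cfg$post_hyb_subs_p1,
             p2_private = cfg$post_hyb_subs_p2,
             allo_p1_branch = cfg$post_hyb_subs_p1,
             allo_p2_branch = cfg$post_hyb_subs_p2)
  if (any(rates >= 1)) stop("substitution rates must be < 1")
  set.seed(stage_seed(cfg$seed, "lineages"))

  ref <- as_chr_seqs(gene_set$seqs)
  ids <- names(ref)
  carriers <- list(
    ancestral = c("parent1", "parent2", "allo_p1", "allo_p2"),
    p1_branch = c("parent1", "allo_p1"),
    p2_branch = c("parent2", "allo_p2"),
    p1_private = "parent1",
    p2_private = "parent2",
    allo_p1_branch = "allo_p1",
    allo_p2_branch = "allo_p2")
  genomes <- list(parent1 = character(0), parent2 = character(0),
                  allo_p1 = character(0), allo_p2 = character(0))
  var_list <- vector("list", length(ids))

  for (i in seq_along(ids)) {
    s <- strsplit(ref[[i]], "", fixed = TRUE)[[1]]
    L <- length(s)
    nmut <- rbinom(length(rates), L, rates)
    names(nmut) <- names(rates)
    tot <- sum(nmut)
    if (tot > L) stop("substitution rates too high for gene length")
    pos_all <- if (tot > 0) sample.int(L, tot) - 1L else integer(0)
    split_idx <- rep(names(rates), nmut)
    seqs_i <- list(parent1 = s, parent2 = s, allo_p1 = s, allo_p2 = s)
    if (tot > 0) {
      refb <- s[pos_all + 1L]
      alt_choice <- sample.int(3L, tot, replace = TRUE)
      alt <- vapply(seq_len(tot), function(j)
        setdiff(DNA_BASES, refb[j])[alt_choice[j]], character(1))
      for (br in names(rates)) {
        sel <- split_idx == br
        if (!any(sel)) next
        for (g in carriers[[br]])
          seqs_i[[g]] <- apply_subs(seqs_i[[g]], pos_all[sel], alt[sel])
      }
      var_list[[i]] <- data.frame(gene_id = ids[i], pos = pos_all,
                                  ref = refb, alt = alt,
                                  lineage = split_idx,
                                  stringsAsFactors = FALSE)
    }
    for (g in names(seqs_i))
      genomes[[g]][ids[i]] <- paste(seqs_i[[g]], collapse = "")
  }
  variants <- do.call(rbind, var_list[!vapply(var_list, is.null, logical(1))])
  if (is.null(variants))
    variants <- data.frame(gene_id = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           lineage = character(0), stringsAsFactors = FALSE)
  variants <- variants[order(variants$gene_id, variants$pos), ]
  rownames(variants) <- NULL
  list(genomes = lapply(genomes, Biostrings::DNAStringSet),
       variants = variants)
}

#' Apply clustered single-subgenome gene deletions
#'
#' For each cluster, a run of physically adjacent genes is removed from
#' exactly one allopolyploid subgenome, emulating large genomic deletions.
#' Clusters never overlap and alternate the deleted subgenome so library
#' totals stay balanced.
#'
#' @param genomes the \code{genomes} list from \code{\link{evolve_lineages}}.
#' @param gene_set the reference gene set (for supercontig adjacency).
#' @param cfg a \code{\link{sim_config}}.
#' @return list with updated \code{genomes} and \code{deletions}
#'   (data.frame gene_id, cluster, deleted_subgenome).
#' @export
apply_deletions <- function(genomes, gene_set, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  empty <- data.frame(gene_id = character(0), cluster = integer(0),
                      deleted_subgenome = character(0),
                      stringsAsFactors = FALSE)
  if (cfg$n_deletion_clusters == 0)
    return(list(genomes = genomes, deletions = empty))
  set.seed(stage_seed(cfg$seed, "deletions"))
  co <- gene_set$coords
  k <- cfg$deletion_cluster_size
  # candidate windows of k adjacent genes within one supercontig
  wins <- do.call(rbind, lapply(split(seq_len(nrow(co)), co$supercontig),
    function(idx) {
      idx <- idx[order(co$start[idx])]
      if (length(idx) < k) return(NULL)
      data.frame(first = idx[seq_len(length(idx) - k + 1)])
    }))
  if (is.null(wins) || nrow(wins) < cfg$n_deletion_clusters)
    stop("deletion clusters do not fit within the supercontigs")
  ord <- sample.int(nrow(wins))
  chosen <- integer(0); used <- character(0)
  for (w in ord) {
    genes_w <- co$gene_id[wins$first[w] + 0:(k - 1)]
    if (!any(genes_w %in% used)) {
      chosen <- c(chosen, w)
      used <- c(used, genes_w)
      if (length(chosen) == cfg$n_deletion_clusters) break
    }
  }
  if (length(chosen) < cfg$n_deletion_clusters)
    stop("could not place non-overlapping deletion clusters")
  del <- do.call(rbind, lapply(seq_along(chosen), function(j) {
    genes_w <- co$gene_id[wins$first[chosen[j]] + 0:(k - 1)]
    data.frame(gene_id = genes_w, cluster = j,
               deleted_subgenome = if (j %% 2 == 1) "P1" else "P2",
               stringsAsFactors = FALSE)
  }))
  for (sub in c("P1", "P2")) {
    slot <- if (sub == "P1") "allo_p1" else "allo_p2"
    gone <- del$gene_id[del$deleted_subgenome == sub]
    genomes[[slot]] <- genomes[[slot]][setdiff(names(genomes[[slot]]), gone)]
  }
  list(genomes = genomes, deletions = del)
}

#' Assign per-gene expression fates and ground-truth levels
#'
#' Samples an expression outcome category per gene from the configured
#' proportions and sets the true parental log2 ortholog ratio
#' \code{rho_p} (parent2 over parent1) and the true homeolog log2 ratio
#' \code{rho_h} accordingly: inheritance keeps \code{rho_h == rho_p}
#' (biased for a configurable fraction of genes, unbiased otherwise);
#' blending has a parental bias that is lost in the allopolyploid; bias is
#' the converse; reversal flips the sign. Base expression is log-normal.
#'
#' @param gene_set the reference gene set.
#' @param cfg a \code{\link{sim_config}}.
#' @return data.frame with gene_id, category, rho_p, rho_h, base_expr and
#'   the four true expression levels (parent1/parent2 orthologs,
#'   allopolyploid P1/P2 homeologs).
#' @export
assign_expression_fates <- function(gene_set, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$bias_log2_effect <= 0) stop("effect size must be > 0")
  set.seed(stage_seed(cfg$seed, "fates"))
  ids <- names(gene_set$seqs)
  n <- length(ids)
  cat_ <- sample(names(cfg$fate_proportions), n, replace = TRUE,
                 prob = cfg$fate_proportions)
  dir <- sample(c(-1, 1), n, replace = TRUE)
  eff <- cfg$bias_log2_effect
  rho_p <- numeric(n); rho_h <- numeric(n)
  inh <- cat_ == "inheritance"
  inh_biased <- inh & (runif(n) < cfg$inheritance_biased_frac)
  rho_p[inh_biased] <- dir[inh_biased] * eff
  rho_h[inh_biased] <- rho_p[inh_biased]
  bl <- cat_ == "blending"
  rho_p[bl] <- dir[bl] * eff
  bi <- cat_ == "bias"
  rho_h[bi] <- dir[bi] * eff
  rv <- cat_ == "reversal"
  rho_p[rv] <- dir[rv] * eff
  rho_h[rv] <- -rho_p[rv]
  base <- 2^rnorm(n, cfg$expr_log2_mean, cfg$expr_log2_sd)
  data.frame(gene_id = ids, category = cat_, rho_p = rho_p, rho_h = rho_h,
             base_expr = base,
             p1_expr = base * 2^(-rho_p / 2),
             p2_expr = base * 2^(rho_p / 2),
             allo_p1_expr = base * 2^(-rho_h / 2),
             allo_p2_expr = base * 2^(rho_h / 2),
             stringsAsFactors = FALSE)
}

# mutate reads in place with i.i.d. base errors
add_read_errors <- function(reads, error_rate) {
  if (error_rate == 0 || !length(reads)) return(reads)
  rl <- nchar(reads)
  nerr <- rbinom(length(reads), rl, error_rate)
  hit <- which(nerr > 0)
  for (i in hit) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    p <- sample.int(rl[i], nerr[i])
    ch[p] <- vapply(ch[p], function(b)
      sample(setdiff(DNA_BASES, b), 1), character(1))
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate sequencing reads from a transcript set
#'
#' Reads are drawn multinomially across transcripts proportionally to
#' expression times effective length, with uniform start positions, a
#' random strand, and i.i.d. base errors. In paired mode both mates come
#' from one fragment in standard forward/reverse orientation and the
#' origin table records the fragment once per mate.
#'
#' @param transcripts \code{DNAStringSet} or named character vector.
#' @param expr named expression weights (same names as transcripts;
#'   missing names get weight 0).
#' @param n_reads number of reads (fragments when \code{paired}).
#' @param cfg a \code{\link{sim_config}} (read length, error rate, paired,
#'   fragment model).
#' @param prefix read-name prefix.
#' @param paired override \code{cfg$paired}.
#' @return list with \code{reads} (named character), \code{reads2}
#'   (\code{NULL} unless paired) and \code{origin} (data.frame read_id,
#'   transcript, pos, strand, with truth of origin per fragment).
#' @export
simulate_reads <- function(transcripts, expr, n_reads, cfg, prefix = "r",
                           paired = cfg$paired) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_reads < 0) stop("library size must be >= 0")
  tx <- as_chr_seqs(transcripts)
  rl <- cfg$read_length
  if (length(tx) && min(nchar(tx)) < rl)
    stop("read_length exceeds the shortest transcript")
  w <- as.numeric(expr[names(tx)])
  w[is.na(w)] <- 0
  w <- w * (nchar(tx) - rl + 1)
  empty <- data.frame(read_id = character(0), transcript = character(0),
                      pos = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (n_reads == 0 || sum(w) == 0)
    return(list(reads = setNames(character(0), character(0)),
                reads2 = if (paired) setNames(character(0), character(0)),
                origin = empty))
  cnt <- as.integer(rmultinom(1, n_reads, w))
  tx_idx <- rep(seq_along(tx), cnt)
  tlen <- nchar(tx)[tx_idx]
  if (paired) {
    fl <- pmin(pmax(round(rnorm(length(tx_idx), cfg$fragment_length_mean,
                                cfg$fragment_length_sd)), rl), tlen)
    fstart <- floor(runif(length(tx_idx)) * (tlen - fl + 1))  # 0-based
    fwd <- runif(length(tx_idx)) < 0.5
    left <- substring(tx[tx_idx], fstart + 1, fstart + rl)
    right <- revcomp_chr(substring(tx[tx_idx], fstart + fl - rl + 1,
                                   fstart + fl))
    r1 <- ifelse(fwd, left, right)
    r2 <- ifelse(fwd, right, left)
    ids <- sprintf("%s_%07d", prefix, seq_along(tx_idx))
    names(r1) <- names(r2) <- ids
    r1 <- add_read_errors(r1, cfg$error_rate)
    r2 <- add_read_errors(r2, cfg$error_rate)
    origin <- data.frame(read_id = ids, transcript = names(tx)[tx_idx],
                         pos = as.integer(fstart),
                         strand = ifelse(fwd, "+", "-"),
                         stringsAsFactors = FALSE)
    list(reads = r1, reads2 = r2, origin = origin)
  } else {
    start <- floor(runif(length(tx_idx)) * (tlen - rl + 1))  # 0-based
    fwd <- runif(length(tx_idx)) < 0.5
    rd <- substring(tx[tx_idx], start + 1, start + rl)
    rd[!fwd] <- revcomp_chr(rd[!fwd])
    ids <- sprintf("%s_%07d", prefix, seq_along(tx_idx))
    names(rd) <- ids
    rd <- add_read_errors(rd, cfg$error_rate)
    origin <- data.frame(read_id = ids, transcript = names(tx)[tx_idx],
                         pos = as.integer(start),
                         strand = ifelse(fwd, "+", "-"),
                         stringsAsFactors = FALSE)
    list(reads = rd, reads2 = NULL, origin = origin)
  }
}

#' Simulate a complete allopolyploid expression experiment
#'
#' Runs the full generator: reference gene set, lineage evolution,
#' clustered deletions, expression fates, and sequencing reads for both
#' parents (single-end) and the allopolyploid (paired by default), with
#' ground truth for every stage. Deleted homeologs get zero expression and
#' therefore zero reads.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return An object of class \code{sim_experiment}: list with \code{cfg},
#'   \code{gene_set}, \code{genomes}, \code{variants}, \code{deletions},
#'   \code{truth} (per-gene expression/fate truth) and \code{reads}
#'   (per sample, a list of replicates from \code{\link{simulate_reads}}).
#'   Allopolyploid transcript names carry a \code{|P1} / \code{|P2}
#'   subgenome suffix.
#' @export
simulate_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gene_set <- simulate_gene_set(cfg)
  lin <- evolve_lineages(gene_set, cfg)
  dl <- apply_deletions(lin$genomes, gene_set, cfg)
  truth <- assign_expression_fates(gene_set, cfg)
  del_p1 <- truth$gene_id %in%
    dl$deletions$gene_id[dl$deletions$deleted_subgenome == "P1"]
  del_p2 <- truth$gene_id %in%
    dl$deletions$gene_id[dl$deletions$deleted_subgenome == "P2"]
  truth$allo_p1_expr[del_p1] <- 0
  truth$allo_p2_expr[del_p2] <- 0
  truth$deleted_subgenome <- ifelse(del_p1, "P1", ifelse(del_p2, "P2", ""))

  expr_vec <- function(col, ids) setNames(truth[[col]], truth$gene_id)[ids]
  allo_tx <- c(setNames(as_chr_seqs(dl$genomes$allo_p1),
                        paste0(names(dl$genomes$allo_p1), "|P1")),
               setNames(as_chr_seqs(dl$genomes$allo_p2),
                        paste0(names(dl$genomes$allo_p2), "|P2")))
  allo_expr <- c(setNames(truth$allo_p1_expr, paste0(truth$gene_id, "|P1")),
                 setNames(truth$allo_p2_expr, paste0(truth$gene_id, "|P2")))

  reads <- list(p1 = list(), p2 = list(), allo = list())
  for (smp in names(reads)) {
    sizes <- cfg$library_sizes[[smp]]
    for (r in seq_along(sizes)) {
      set.seed(stage_seed(cfg$seed, paste0("reads/", smp, "/", r)))
      reads[[smp]][[r]] <- switch(smp,
        p1 = simulate_reads(dl$genomes$parent1,
                            expr_vec("p1_expr", names(dl$genomes$parent1)),
                            sizes[r], cfg, prefix = paste0("p1_", r),
                            paired = FALSE),
        p2 = simulate_reads(dl$genomes$parent2,
                            expr_vec("p2_expr", names(dl$genomes$parent2)),
                            sizes[r], cfg, prefix = paste0("p2_", r),
                            paired = FALSE),
        allo = simulate_reads(allo_tx, allo_expr, sizes[r], cfg,
                              prefix = paste0("allo_", r),
                              paired = cfg$paired))
    }
  }
  structure(list(cfg = cfg, gene_set = gene_set, genomes = dl$genomes,
                 variants = lin$variants, deletions = dl$deletions,
                 truth = truth, reads = reads),
            class = "sim_experiment")
}

#' Write a simulated experiment to disk
#'
#' Emits FASTA references, FASTQ reads (Phred+33, constant quality derived
#' from the error rate), TSV truth tables (variants, expression, read
#' origins, deletions, gene coordinates) and a JSON echo of the
#' configuration.
#'
#' @param sim a \code{\link{simulate_experiment}} result.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  q <- if (sim$cfg$error_rate > 0)
    min(41L, as.integer(round(-10 * log10(sim$cfg$error_rate)))) else 41L
  qchar <- rawToChar(as.raw(33L + q))
  wfq <- function(rd, path) {
    x <- Biostrings::DNAStringSet(rd)
    qual <- Biostrings::BStringSet(strrep(qchar, Biostrings::width(x)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  }
  Biostrings::writeXStringSet(sim$gene_set$seqs,
                              file.path(dir, "reference.fasta"))
  for (g in names(sim$genomes))
    Biostrings::writeXStringSet(sim$genomes[[g]],
                                file.path(dir, paste0(g, ".fasta")))
  for (smp in names(sim$reads)) {
    for (r in seq_along(sim$reads[[smp]])) {
      rep_ <- sim$reads[[smp]][[r]]
      if (is.null(rep_$reads2)) {
        wfq(rep_$reads, file.path(dir, sprintf("%s_rep%d.fastq", smp, r)))
      } else {
        wfq(rep_$reads, file.path(dir, sprintf("%s_rep%d_1.fastq", smp, r)))
        wfq(rep_$reads2, file.path(dir, sprintf("%s_rep%d_2.fastq", smp, r)))
      }
      write.table(rep_$origin,
                  file.path(dir, sprintf("%s_rep%d_origin.tsv", smp, r)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write.table(sim$variants, file.path(dir, "truth_variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth, file.path(dir, "truth_expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$deletions, file.path(dir, "truth_deletions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$gene_set$coords, file.path(dir, "gene_coords.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_plain <- sim$cfg
  class(cfg_plain) <- NULL
  jsonlite::write_json(cfg_plain, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
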