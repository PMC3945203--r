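#' Build homeolog-specific reference gene sets from diagnostic SNPs
#'
#' Creates, for every gene of the surrogate reference, a P1-like and a
#' P2-like sequence by substituting diagnostic alleles: both sides receive
#' \code{ancestral} alleles; the P1 side additionally receives
#' \code{p1_shared} and \code{allo_p1} alleles and the P2 side
#' \code{p2_shared} and \code{allo_p2}. Parent-only (\code{p1_unique} /
#' \code{p2_unique}), unassigned allopolyploid-private and residual
#' variants are not applied. Positions where the two sides differ are the
#' discriminating positions.
#'
#' @param gene_set the surrogate reference gene set.
#' @param snp_table classified diagnostic SNP table.
#' @return An object of class \code{homeolog_ref}: list with
#'   \code{p1_like} / \code{p2_like} (named character), per-gene
#'   \code{discriminating} 0-based positions, and placeholders for
#'   informative intervals and culling (all genes initially retained).
#' @export
build_homeolog_references <- function(gene_set, snp_table) {
  ref <- as_chr_seqs(gene_set$seqs)
  ids <- names(ref)
  p1_cls <- c("ancestral", "p1_shared", "allo_p1")
  p2_cls <- c("ancestral", "p2_shared", "allo_p2")
  use <- snp_table[snp_table$class %in% union(p1_cls, p2_cls), ,
                   drop = FALSE]
  # one substitution per side per site (conflicts are pre-excluded by
  # classify_snps; guard anyway)
  dup_key <- paste(use$gene_id, use$pos)
  dup <- duplicated(dup_key) | duplicated(dup_key, fromLast = TRUE)
  if (any(dup)) {
    bad <- unique(dup_key[dup])
    keep <- !dup_key %in% bad
    message(sprintf("excluded %d site(s) with overlapping substitutions",
                    length(bad)))
    use <- use[keep, , drop = FALSE]
  }
  p1_like <- ref; p2_like <- ref
  discriminating <- setNames(vector("list", length(ids)), ids)
  for (g in unique(use$gene_id)) {
    v <- use[use$gene_id == g, , drop = FALSE]
    ch1 <- strsplit(ref[[g]], "", fixed = TRUE)[[1]]
    ch2 <- ch1
    s1 <- v$class %in% p1_cls
    s2 <- v$class %in% p2_cls
    ch1[v$pos[s1] + 1L] <- v$alt[s1]
    ch2[v$pos[s2] + 1L] <- v$alt[s2]
    p1_like[[g]] <- paste(ch1, collapse = "")
    p2_like[[g]] <- paste(ch2, collapse = "")
    discriminating[[g]] <- sort(v$pos[xor(s1, s2)])
  }
  for (g in ids)
    if (is.null(discriminating[[g]])) discriminating[[g]] <- integer(0)
  structure(list(p1_like = p1_like, p2_like = p2_like,
                 discriminating = discriminating,
                 informative = NULL, informative_length = NULL,
                 masked = FALSE,
                 retained = setNames(rep(TRUE, length(ids)), ids),
                 cull_reason = setNames(rep("ok", length(ids)), ids)),
            class = "homeolog_ref")
}

#' Informative intervals around discriminating positions
#'
#' A read can only be homeolog-assigned if it overlaps a discriminating
#' position, so the informative region of a gene is the union of windows
#' of one read length around each discriminating position:
#' \code{[p - (read_length - 1), p + read_length)}, clipped to the gene
#' and merged.
#'
#' @param positions 0-based discriminating positions.
#' @param read_length read length (>= 1).
#' @param gene_length gene length in bp.
#' @return list with \code{intervals} (data.frame \code{start},
#'   \code{end}, 0-based half-open) and \code{length} (total bp).
#' @export
informative_regions <- function(positions, read_length, gene_length) {
  stopifnot(read_length >= 1)
  if (!length(positions))
    return(list(intervals = data.frame(start = integer(0), end = integer(0)),
                length = 0L))
  ir <- IRanges::reduce(IRanges::IRanges(
    start = pmax(positions - (read_length - 1L), 0L) + 1L,
    end = pmin(positions + read_length, gene_length)))
  list(intervals = data.frame(start = IRanges::start(ir) - 1L,
                              end = IRanges::end(ir)),
       length = sum(IRanges::width(ir)))
}

#' Compute informative intervals for every gene of a homeolog reference
#'
#' @param homref a \code{\link{build_homeolog_references}} result.
#' @param read_length read length used for assignment.
#' @return the \code{homeolog_ref} with \code{informative} and
#'   \code{informative_length} filled in.
#' @export
add_informative_regions <- function(homref, read_length) {
  ids <- names(homref$p1_like)
  inf <- setNames(vector("list", length(ids)), ids)
  len <- setNames(integer(length(ids)), ids)
  for (g in ids) {
    r <- informative_regions(homref$discriminating[[g]], read_length,
                             nchar(homref$p1_like[[g]]))
    inf[[g]] <- r$intervals
    len[g] <- r$length
  }
  homref$informative <- inf
  homref$informative_length <- len
  homref$read_length <- as.integer(read_length)
  homref
}

#' Mask non-informative sequence in both homeolog references
#'
#' Positions outside the informative intervals are set to \code{N} in both
#' the P1-like and P2-like sequences, so reads there cannot be (mis)used
#' for homeolog assignment. The cumulative haploid informative length
#' \code{L} over retained genes is recorded (an input to
#' \code{\link{date_upper_bound}}).
#'
#' @param homref a reference with informative intervals
#'   (\code{\link{add_informative_regions}}).
#' @return the \code{homeolog_ref} with masked sequences and \code{L}.
#' @export
mask_noninformative <- function(homref) {
  if (is.null(homref$informative))
    stop("informative intervals not computed; call add_informative_regions()")
  homref$p1_unmasked <- homref$p1_like
  homref$p2_unmasked <- homref$p2_like
  for (g in names(homref$p1_like)) {
    iv <- homref$informative[[g]]
    L <- nchar(homref$p1_like[[g]])
    keep <- logical(L)
    if (nrow(iv))
      for (j in seq_len(nrow(iv)))
        keep[(iv$start[j] + 1L):iv$end[j]] <- TRUE
    if (all(keep)) next
    for (side in c("p1_like", "p2_like")) {
      ch <- strsplit(homref[[side]][[g]], "", fixed = TRUE)[[1]]
      ch[!keep] <- "N"
      homref[[side]][[g]] <- paste(ch, collapse = "")
    }
  }
  homref$masked <- TRUE
  homref$L <- sum(homref$informative_length[homref$retained])
  homref
}

#' Cull genes with insufficient parental coverage or informative length
#'
#' A gene is retained only when both parental transcriptomes supply at
#' least \code{min_parent_reads} reads and its informative region totals
#' at least \code{min_informative_len} bp (both thresholds inclusive).
#'
#' @param homref a \code{homeolog_ref} with informative lengths.
#' @param parent_counts matrix or data.frame with one row per gene
#'   (rownames = gene ids) and columns for the two parents.
#' @param min_parent_reads minimum reads per parent.
#' @param min_informative_len minimum informative length (bp).
#' @return the \code{homeolog_ref} with \code{retained},
#'   \code{cull_reason} and \code{L} updated.
#' @export
cull_genes <- function(homref, parent_counts, min_parent_reads = 5,
                       min_informative_len = 150) {
  ids <- names(homref$p1_like)
  cnt <- matrix(0, nrow = length(ids), ncol = 2,
                dimnames = list(ids, c("p1", "p2")))
  pc <- as.matrix(parent_counts)
  common <- intersect(rownames(pc), ids)
  cnt[common, ] <- pc[common, 1:2]
  low_expr <- cnt[, 1] < min_parent_reads | cnt[, 2] < min_parent_reads
  short_inf <- homref$informative_length[ids] < min_informative_len
  reason <- rep("ok", length(ids))
  reason[short_inf] <- "short-informative"
  reason[low_expr] <- "low-parent-expression"
  reason[low_expr & short_inf] <- "low-parent-expression;short-informative"
  homref$retained <- setNames(!low_expr & !short_inf, ids)
  homref$cull_reason <- setNames(reason, ids)
  homref$L <- sum(homref$informative_length[homref$retained])
  homref
}

#' @export
print.homeolog_ref <- function(x, ...) {
  cat("homeolog_ref:", length(x$p1_like), "genes;",
      sum(lengths(x$discriminating)), "discriminating positions;",
      if (x$masked) "masked;" else "unmasked;",
      sum(x$retained), "retained\n")
  if (!is.null(x$L)) cat("  cumulative informative length L =", x$L, "bp\n")
  invisible(x)
}

#' Write the homeolog references and their annotation
#'
#' Emits the two FASTA references (\code{_P1like} / \code{_P2like}), a TSV
#' of informative intervals (0-based half-open), and a TSV cull report.
#'
#' @param homref a \code{homeolog_ref}.
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, \code{dir}.
#' @export
write_homeolog_refs <- function(homref, dir, prefix = "homeolog") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(homref$p1_like),
                              file.path(dir, paste0(prefix, "_P1like.fasta")))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(homref$p2_like),
                              file.path(dir, paste0(prefix, "_P2like.fasta")))
  iv <- do.call(rbind, lapply(names(homref$informative), function(g) {
    d <- homref$informative[[g]]
    if (!nrow(d)) return(NULL)
    data.frame(gene_id = g, start = d$start, end = d$end,
               stringsAsFactors = FALSE)
  }))
  if (is.null(iv))
    iv <- data.frame(gene_id = character(0), start = integer(0),
                     end = integer(0))
  write.table(iv, file.path(dir, paste0(prefix, "_informative.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cull <- data.frame(gene_id = names(homref$retained),
                     retained = unname(homref$retained),
                     reason = unname(homref$cull_reason),
                     informative_length =
                       unname(homref$informative_length[names(homref$retained)]),
                     stringsAsFactors = FALSE)
  write.table(cull, file.path(dir, paste0(prefix, "_cull.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(L = homref$L, n_genes = length(homref$p1_like),
                            n_retained = sum(homref$retained)),
                       file.path(dir, paste0(prefix, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
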