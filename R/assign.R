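split_target <- function(x) {
  list(gene = sub("\\|P[12]$", "", x),
       side = ifelse(grepl("\\|P1$", x), "P1", "P2"))
}

#' Assign allopolyploid reads to homeologs at zero mismatches
#'
#' Maps reads (fragments when mates are given) against both masked
#' homeolog references. A fragment is counted for homeolog X of gene g iff
#' it aligns full length with zero mismatches to X's sequence of g and not
#' to the other homeolog reference anywhere. Equal zero-mismatch mapping
#' to both sides (or mates disagreeing on side or gene) is ambiguous;
#' reads that map to neither masked reference are ambiguous when they
#' align to an unmasked reference (they simply overlap no discriminating
#' site) and unassigned otherwise (e.g. a sequencing error under the
#' zero-mismatch rule).
#'
#' @param reads named character or \code{DNAStringSet}; first mates when
#'   paired.
#' @param homref a masked \code{homeolog_ref}.
#' @param reads2 second mates (or \code{NULL} for single-end).
#' @param k seed length for the zero-mismatch index.
#' @param detail also return the per-fragment assignment table.
#' @return list with \code{counts} (gene x c(allo_p1, allo_p2) matrix over
#'   all reference genes), \code{assigned} (per-side totals),
#'   \code{ambiguous}, \code{unassigned} and \code{n_fragments}; with
#'   \code{detail}, also \code{assignments} (data.frame fragment, status,
#'   gene, side).
#' @export
assign_reads <- function(reads, homref, reads2 = NULL, k = 21,
                         detail = FALSE) {
  if (!isTRUE(homref$masked)) stop("homeolog reference must be masked")
  ids <- names(homref$p1_like)
  masked <- c(setNames(homref$p1_like, paste0(ids, "|P1")),
              setNames(homref$p2_like, paste0(ids, "|P2")))
  idx <- build_index(masked, k = k)
  r1 <- as_chr_seqs(reads)
  paired <- !is.null(reads2)
  if (paired) {
    r2 <- as_chr_seqs(reads2)
    stopifnot(length(r1) == length(r2))
    frag_ids <- names(r1)
    all_reads <- c(setNames(r1, paste0(frag_ids, "/1")),
                   setNames(r2, paste0(frag_ids, "/2")))
  } else {
    frag_ids <- names(r1)
    all_reads <- r1
  }
  hits <- map_reads(all_reads, idx, max_mismatch = 0)

  counts <- matrix(0L, nrow = length(ids), ncol = 2,
                   dimnames = list(ids, c("allo_p1", "allo_p2")))
  n_frag <- length(frag_ids)
  if (!n_frag)
    return(list(counts = counts, assigned = c(allo_p1 = 0L, allo_p2 = 0L),
                ambiguous = 0L, unassigned = 0L, n_fragments = 0L,
                assignments = if (detail)
                  data.frame(fragment = character(0), status = character(0),
                             gene = character(0), side = character(0),
                             stringsAsFactors = FALSE)))

  frag_of <- function(q) if (paired) sub("/[12]$", "", q) else q
  if (nrow(hits)) {
    keyu <- paste(hits$query, hits$target)
    hu <- hits[!duplicated(keyu), , drop = FALSE]
    ts <- split_target(hu$target)
    hu$frag <- frag_of(hu$query)
    # per fragment: distinct (gene, side) pairs seen across mates
    keyf <- paste(hu$frag, hu$target)
    hf <- hu[!duplicated(keyf), , drop = FALSE]
    tf <- split_target(hf$target)
    ff <- factor(hf$frag, levels = unique(hf$frag))
    n_p1 <- tabulate(ff[tf$side == "P1"], nbins = nlevels(ff))
    n_p2 <- tabulate(ff[tf$side == "P2"], nbins = nlevels(ff))
    lev <- levels(ff)
    gene_for <- rep(NA_character_, nlevels(ff))
    one_side <- (n_p1 == 1 & n_p2 == 0) | (n_p2 == 1 & n_p1 == 0)
    sel <- one_side[as.integer(ff)]
    gene_for[as.integer(ff)[sel]] <- tf$gene[sel]
    side_for <- ifelse(n_p1 == 1 & n_p2 == 0, "allo_p1",
                       ifelse(n_p2 == 1 & n_p1 == 0, "allo_p2", NA))
    assigned_mask <- !is.na(side_for)
    add <- table(factor(gene_for[assigned_mask], levels = ids),
                 factor(side_for[assigned_mask],
                        levels = c("allo_p1", "allo_p2")))
    counts <- counts + unclass(add)
    ambiguous_frags <- lev[!assigned_mask]
    hit_frags <- lev
  } else {
    ambiguous_frags <- character(0)
    hit_frags <- character(0)
  }
  nohit_frags <- setdiff(frag_ids, hit_frags)
  # fragments with no masked hit: informative-region miss vs mismatch
  unassigned <- 0L
  if (length(nohit_frags)) {
    unmasked <- c(setNames(homref$p1_unmasked, paste0(ids, "|P1")),
                  setNames(homref$p2_unmasked, paste0(ids, "|P2")))
    idx_u <- build_index(unmasked, k = k)
    sel_reads <- if (paired)
      c(setNames(r1[nohit_frags], paste0(nohit_frags, "/1")),
        setNames(r2[nohit_frags], paste0(nohit_frags, "/2")))
    else r1[nohit_frags]
    hits_u <- map_reads(sel_reads, idx_u, max_mismatch = 0)
    exact_frags <- unique(frag_of(hits_u$query))
    ambiguous_frags <- c(ambiguous_frags, exact_frags)
    unassigned <- length(nohit_frags) - length(exact_frags)
    unassigned_frags <- setdiff(nohit_frags, exact_frags)
  } else unassigned_frags <- character(0)
  out <- list(counts = counts,
              assigned = c(allo_p1 = sum(counts[, 1]),
                           allo_p2 = sum(counts[, 2])),
              ambiguous = length(ambiguous_frags),
              unassigned = unassigned,
              n_fragments = n_frag)
  if (detail) {
    asg_df <- if (exists("lev") && any(assigned_mask))
      data.frame(fragment = lev[assigned_mask], status = "assigned",
                 gene = gene_for[assigned_mask],
                 side = side_for[assigned_mask], stringsAsFactors = FALSE)
    else data.frame(fragment = character(0), status = character(0),
                    gene = character(0), side = character(0),
                    stringsAsFactors = FALSE)
    amb_df <- data.frame(fragment = ambiguous_frags,
                         status = rep("ambiguous", length(ambiguous_frags)),
                         gene = rep(NA_character_, length(ambiguous_frags)),
                         side = rep(NA_character_, length(ambiguous_frags)),
                         stringsAsFactors = FALSE)
    una_df <- data.frame(fragment = unassigned_frags,
                         status = rep("unassigned", length(unassigned_frags)),
                         gene = rep(NA_character_, length(unassigned_frags)),
                         side = rep(NA_character_, length(unassigned_frags)),
                         stringsAsFactors = FALSE)
    out$assignments <- rbind(asg_df, amb_df, una_df)
  }
  out
}

#' Count parental reads on the parent's own masked homeolog reference
#'
#' Applies the same zero-mismatch, full-length rule used for allopolyploid
#' assignment to a parent's reads against its own homeolog-like masked
#' reference, so that parental ortholog counts share the per-gene
#' informative footprint with the homeolog counts. Reads matching more
#' than one gene are discarded.
#'
#' @param reads named character or \code{DNAStringSet}.
#' @param homref a masked \code{homeolog_ref}.
#' @param parent \code{"p1"} or \code{"p2"}: which side's reference to use.
#' @param k seed length.
#' @return list with \code{counts} (named integer over genes) and
#'   \code{total} assigned reads.
#' @export
count_parent_reads <- function(reads, homref, parent = c("p1", "p2"),
                               k = 21) {
  parent <- match.arg(parent)
  if (!isTRUE(homref$masked)) stop("homeolog reference must be masked")
  seqs <- if (parent == "p1") homref$p1_like else homref$p2_like
  idx <- build_index(seqs, k = k)
  hits <- map_reads(as_chr_seqs(reads), idx, max_mismatch = 0)
  ids <- names(seqs)
  cnt <- setNames(integer(length(ids)), ids)
  if (nrow(hits)) {
    keyu <- paste(hits$query, hits$target)
    hu <- hits[!duplicated(keyu), , drop = FALSE]
    ngenes <- table(hu$query)
    keep <- hu$query %in% names(ngenes)[ngenes == 1]
    t_ <- table(factor(hu$target[keep], levels = ids))
    cnt <- cnt + as.integer(t_)
    names(cnt) <- ids
  }
  list(counts = cnt, total = sum(cnt))
}
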