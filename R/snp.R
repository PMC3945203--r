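#' Per-gene, per-position base counts from alignments
#'
#' Accumulates A/C/G/T counts at every covered position of each target
#' gene from ungapped alignments. Reverse-strand alignments contribute the
#' reverse complement of the read.
#'
#' @param hits alignment data.frame (\code{query}, \code{target},
#'   \code{pos}, \code{strand}) from \code{\link{map_reads}} or
#'   \code{\link{read_sam}}.
#' @param reads named character vector or \code{DNAStringSet} of read
#'   sequences (original orientation), or \code{NULL} if \code{hits}
#'   carries a \code{seq} column.
#' @param targets reference gene set sequences (\code{DNAStringSet} or
#'   named character) defining target names and lengths.
#' @return named list (one element per target) of 4 x length integer
#'   matrices with rows A, C, G, T. Positions with no coverage have zero
#'   columns sums.
#' @export
pileup <- function(hits, reads, targets) {
  tg <- as_chr_seqs(targets)
  tl <- nchar(tg)
  tidx <- match(hits$target, names(tg))
  if (anyNA(tidx)) stop("alignments reference unknown genes")
  seqs <- if (!is.null(reads)) as_chr_seqs(reads)[hits$query] else hits$seq
  if (anyNA(seqs)) stop("read sequences missing for some alignments")
  mats <- .cpp_pileup(unname(seqs), tidx, hits$pos,
                      as.integer(hits$strand == "+"), unname(tl))
  names(mats) <- names(tg)
  mats
}

# choose, per read, the best alignment(s); drop reads whose best mismatch
# count is achieved in more than one gene (paralog guard); keep one row
# (leftmost best) per retained read
filter_unique_gene_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  o <- order(hits$query, hits$mismatches, hits$target, hits$pos)
  h <- hits[o, ]
  best <- !duplicated(h$query)
  best_mm <- setNames(h$mismatches[best], h$query[best])
  is_best <- h$mismatches == best_mm[h$query]
  hb <- h[is_best, ]
  ntarg <- tapply(hb$target, hb$query, function(x) length(unique(x)))
  keep_q <- names(ntarg)[ntarg == 1]
  hb <- hb[hb$query %in% keep_q, ]
  hb <- hb[!duplicated(hb$query), ]  # leftmost best within the gene
  rownames(hb) <- NULL
  hb
}

# shared site-calling core over a pileup list
call_sites <- function(pu, reference, decide) {
  ref <- as_chr_seqs(reference)
  out <- vector("list", length(pu))
  for (i in seq_along(pu)) {
    g <- names(pu)[i]
    m <- pu[[i]]
    cov <- colSums(m)
    covered <- which(cov > 0)
    if (!length(covered)) next
    refb <- strsplit(ref[[g]], "", fixed = TRUE)[[1]]
    rows <- match(refb[covered], DNA_BASES)
    mc <- m[, covered, drop = FALSE]
    ref_count <- mc[cbind(rows, seq_along(covered))]
    alt_m <- mc
    alt_m[cbind(rows, seq_along(covered))] <- -1L  # exclude ref base
    top1 <- apply(alt_m, 2, max)
    top_base <- DNA_BASES[apply(alt_m, 2, which.max)]
    # tie between two non-reference bases at the top -> no call
    tie <- apply(alt_m, 2, function(x) sum(x == max(x)) > 1) & top1 > 0
    keep <- decide(cov[covered], top1) & !tie
    if (!any(keep)) next
    out[[i]] <- data.frame(gene_id = g, pos = covered[keep] - 1L,
                           ref = refb[covered[keep]],
                           alt = top_base[keep],
                           ref_count = as.integer(ref_count[keep]),
                           alt_count = as.integer(top1[keep]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(gene_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      ref_count = integer(0), alt_count = integer(0),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Call variants from a haploid parental sample
#'
#' A site is called alternate when coverage reaches \code{min_cov} and the
#' best non-reference base accounts for at least \code{min_alt_frac} of
#' the coverage (tolerating sequencing error in an otherwise homozygous
#' sample). At most one alternate allele per site; a tie between two
#' non-reference bases yields no call.
#'
#' @param pu pileup list from \code{\link{pileup}}.
#' @param reference the surrogate reference gene set.
#' @param min_cov minimum coverage.
#' @param min_alt_frac minimum alternate fraction.
#' @return data.frame gene_id, pos (0-based), ref, alt, ref_count,
#'   alt_count.
#' @export
call_parent_variants <- function(pu, reference, min_cov = 5,
                                 min_alt_frac = 0.9) {
  call_sites(pu, reference, function(cov, alt)
    cov >= min_cov & alt / cov >= min_alt_frac)
}

#' Call variants from the allopolyploid (mixed) sample
#'
#' Heterozygous-like sites are retained: a site may carry a reference-like
#' allele from one homeolog and an alternate from the other, and homeolog
#' expression bias can push allele fractions far from one half, so the
#' fraction threshold is deliberately low.
#'
#' @param pu pileup list from \code{\link{pileup}}.
#' @param reference the surrogate reference gene set.
#' @param min_alt_reads minimum reads carrying the alternate.
#' @param min_alt_frac minimum alternate fraction of coverage.
#' @return data.frame as \code{\link{call_parent_variants}}.
#' @export
call_allo_variants <- function(pu, reference, min_alt_reads = 3,
                               min_alt_frac = 0.2) {
  call_sites(pu, reference, function(cov, alt)
    alt >= min_alt_reads & alt / cov >= min_alt_frac)
}

DIAG_CLASSES <- c("ancestral", "p1_unique", "p2_unique", "p1_shared",
                  "p2_shared", "allo_p1", "allo_p2", "allo_unclassified",
                  "residual")

#' Classify variants into diagnostic ancestry classes
#'
#' Partitions variants keyed by (gene, position, alternate allele) by
#' their presence across the two parents and the allopolyploid:
#' \code{ancestral} (all three), \code{p1_unique}/\code{p2_unique} (one
#' parent only), \code{p1_shared}/\code{p2_shared} (one parent plus the
#' allopolyploid), \code{allo_unclassified} (allopolyploid only, pending
#' linkage assignment), and a \code{residual} bin for variants seen in
#' both parents but not detected in the allopolyploid (excluded from
#' reference construction, since substitution requires detectability in
#' the allopolyploid). Sites with conflicting alternate alleles across
#' samples are flagged multi-allelic and excluded.
#'
#' @param var_p1,var_p2,var_allo variant tables from the calling
#'   functions.
#' @return data.frame gene_id, pos, ref, alt, class, with attribute
#'   \code{multiallelic} counting excluded sites.
#' @export
classify_snps <- function(var_p1, var_p2, var_allo) {
  key_site <- function(v) paste(v$gene_id, v$pos, sep = ":")
  key_var <- function(v) paste(v$gene_id, v$pos, v$alt, sep = ":")
  all_sites <- rbind(var_p1[c("gene_id", "pos", "ref", "alt")],
                     var_p2[c("gene_id", "pos", "ref", "alt")],
                     var_allo[c("gene_id", "pos", "ref", "alt")])
  if (!nrow(all_sites)) {
    out <- data.frame(gene_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      class = character(0), stringsAsFactors = FALSE)
    attr(out, "multiallelic") <- 0L
    return(out)
  }
  nalt <- tapply(all_sites$alt, key_site(all_sites),
                 function(x) length(unique(x)))
  multi <- names(nalt)[nalt > 1]
  uni <- all_sites[!key_site(all_sites) %in% multi, ]
  uni <- uni[!duplicated(key_var(uni)), ]
  k <- key_var(uni)
  in_p1 <- k %in% key_var(var_p1)
  in_p2 <- k %in% key_var(var_p2)
  in_al <- k %in% key_var(var_allo)
  cls <- rep(NA_character_, nrow(uni))
  cls[in_p1 & in_p2 & in_al] <- "ancestral"
  cls[in_p1 & !in_p2 & !in_al] <- "p1_unique"
  cls[!in_p1 & in_p2 & !in_al] <- "p2_unique"
  cls[in_p1 & !in_p2 & in_al] <- "p1_shared"
  cls[!in_p1 & in_p2 & in_al] <- "p2_shared"
  cls[!in_p1 & !in_p2 & in_al] <- "allo_unclassified"
  cls[in_p1 & in_p2 & !in_al] <- "residual"
  out <- uni
  out$class <- cls
  out <- out[order(out$gene_id, out$pos), ]
  rownames(out) <- NULL
  if (length(multi))
    message(sprintf("excluded %d multi-allelic site(s)", length(multi)))
  attr(out, "multiallelic") <- length(multi)
  out
}

#' Assign allopolyploid-private SNPs to a subgenome by linkage
#'
#' New (allopolyploid-only) variants are assigned to the P1- or P2-derived
#' homeolog when reads carrying the new allele are linked, on the same
#' read or mate pair, to known parental diagnostic alleles. A read voting
#' for subgenome P1 carries the alternate allele at covered
#' \code{p1_shared} sites and the reference allele at covered
#' \code{p2_shared} sites (and conversely). Mates named with \code{/1}
#' and \code{/2} suffixes are one linkage unit.
#'
#' @param hits_allo allopolyploid discovery alignments (after
#'   per-read unique-gene filtering).
#' @param reads_allo named read sequences for those alignments (mates may
#'   share one name).
#' @param snp_table classified table from \code{\link{classify_snps}}.
#' @param read_length read length (defines coverage windows).
#' @param min_links minimum linking fragments.
#' @param max_conflict_frac maximum tolerated fraction of linking
#'   fragments voting for the other subgenome.
#' @return the table with qualifying \code{allo_unclassified} rows
#'   reclassified to \code{allo_p1} / \code{allo_p2}.
#' @export
assign_allo_unique_by_ld <- function(hits_allo, reads_allo, snp_table,
                                     read_length = NULL, min_links = 3,
                                     max_conflict_frac = 0.05) {
  unc <- snp_table[snp_table$class == "allo_unclassified", , drop = FALSE]
  diag <- snp_table[snp_table$class %in% c("p1_shared", "p2_shared"), ,
                    drop = FALSE]
  if (!nrow(unc) || !nrow(diag) || !nrow(hits_allo)) return(snp_table)
  rd <- as_chr_seqs(reads_allo)

  genes <- intersect(unique(unc$gene_id), unique(hits_allo$target))
  assign_cls <- character(0)
  assign_key <- character(0)
  for (g in genes) {
    h <- hits_allo[hits_allo$target == g, , drop = FALSE]
    if (!nrow(h)) next
    dg <- diag[diag$gene_id == g, , drop = FALSE]
    ug <- unc[unc$gene_id == g, , drop = FALSE]
    if (!nrow(dg)) next
    seqs <- rd[h$query]
    rl <- nchar(seqs)
    hit_ir <- IRanges::IRanges(start = h$pos + 1L, width = rl)

    site_base <- function(sites) {
      ov <- IRanges::findOverlaps(
        IRanges::IRanges(start = sites$pos + 1L, width = 1L), hit_ir)
      i_site <- S4Vectors::queryHits(ov)
      i_hit <- S4Vectors::subjectHits(ov)
      b <- .cpp_base_at(unname(seqs[i_hit]), h$pos[i_hit],
                        as.integer(h$strand[i_hit] == "+"),
                        sites$pos[i_site])
      data.frame(site = i_site, hit = i_hit, base = b,
                 stringsAsFactors = FALSE)
    }
    # per-fragment subgenome vote from diagnostic sites
    dv <- site_base(dg)
    if (!nrow(dv)) next
    vote <- ifelse(dv$base == dg$alt[dv$site],
                   ifelse(dg$class[dv$site] == "p1_shared", "P1", "P2"),
                   ifelse(dv$base == dg$ref[dv$site],
                          ifelse(dg$class[dv$site] == "p1_shared",
                                 "P2", "P1"),
                          NA_character_))
    frag <- sub("/[12]$", "", h$query[dv$hit])
    tally <- table(frag[!is.na(vote)], vote[!is.na(vote)])
    p1v <- if ("P1" %in% colnames(tally)) tally[, "P1"] else
      setNames(rep(0, nrow(tally)), rownames(tally))
    p2v <- if ("P2" %in% colnames(tally)) tally[, "P2"] else
      setNames(rep(0, nrow(tally)), rownames(tally))
    frag_vote <- ifelse(p1v > 0 & p2v == 0, "P1",
                        ifelse(p2v > 0 & p1v == 0, "P2", "conflict"))
    names(frag_vote) <- rownames(tally)

    uv <- site_base(ug)
    uv <- uv[uv$base == ug$alt[uv$site], , drop = FALSE]
    if (!nrow(uv)) next
    for (s in unique(uv$site)) {
      frags <- unique(sub("/[12]$", "", h$query[uv$hit[uv$site == s]]))
      votes <- frag_vote[intersect(frags, names(frag_vote))]
      if (length(votes) < min_links) next
      fr_p1 <- mean(votes == "P1")
      fr_p2 <- mean(votes == "P2")
      cls <- if (fr_p1 >= 1 - max_conflict_frac) "allo_p1"
             else if (fr_p2 >= 1 - max_conflict_frac) "allo_p2"
             else NA_character_
      if (!is.na(cls)) {
        assign_key <- c(assign_key, paste(g, ug$pos[s], ug$alt[s], sep = ":"))
        assign_cls <- c(assign_cls, cls)
      }
    }
  }
  if (length(assign_key)) {
    k <- paste(snp_table$gene_id, snp_table$pos, snp_table$alt, sep = ":")
    idx <- match(assign_key, k)
    snp_table$class[idx] <- assign_cls
  }
  snp_table
}

#' Diagnostic class counts
#'
#' Tallies the classified SNP table per diagnostic class, reporting the
#' allopolyploid-private total (\code{allo_unique}) as the sum of its
#' three subclasses.
#'
#' @param snp_table classified table.
#' @return named integer vector over the diagnostic classes plus
#'   \code{allo_unique}.
#' @export
class_counts <- function(snp_table) {
  n <- setNames(integer(length(DIAG_CLASSES)), DIAG_CLASSES)
  t_ <- table(snp_table$class)
  n[names(t_)] <- as.integer(t_)
  c(n, allo_unique = sum(n[c("allo_p1", "allo_p2", "allo_unclassified")]))
}

#' SNP bookkeeping percentages
#'
#' From diagnostic class counts, computes the share of allopolyploid SNPs
#' already present in a parent, and the share of new
#' (allopolyploid-private) SNPs that linkage could assign to a subgenome.
#'
#' @param counts named counts as returned by \code{\link{class_counts}}
#'   (or a compatible named vector).
#' @param allo_total optional total number of SNPs detected in the
#'   allopolyploid sample; defaults to the sum of classes detected in the
#'   allopolyploid.
#' @return list with \code{allo_total}, \code{allo_unique},
#'   \code{ld_assigned}, \code{shared_pct}, \code{ld_assigned_pct}.
#' @export
snp_share_stats <- function(counts, allo_total = NULL) {
  allo_unique <- if ("allo_unique" %in% names(counts))
    unname(counts[["allo_unique"]])
  else sum(counts[c("allo_p1", "allo_p2", "allo_unclassified")])
  if (is.null(allo_total))
    allo_total <- unname(sum(counts[c("ancestral", "p1_shared",
                                      "p2_shared")]) + allo_unique)
  ld_assigned <- unname(sum(counts[c("allo_p1", "allo_p2")]))
  list(allo_total = allo_total, allo_unique = allo_unique,
       ld_assigned = ld_assigned,
       shared_pct = 100 * (allo_total - allo_unique) / allo_total,
       ld_assigned_pct = 100 * ld_assigned / allo_unique)
}

#' Per-marker ancestry verdict from diagnostic sites
#'
#' For markers (for example organellar loci) with known parental alleles
#' at diagnostic positions, tallies which parental allele each
#' allopolyploid read carries and issues a verdict: \code{sole-P1} /
#' \code{sole-P2} when every informative read at every site carries one
#' parent's allele (with at least \code{min_reads} informative reads in
#' total), \code{mixed} when both parents' alleles are seen, and
#' \code{insufficient} otherwise.
#'
#' @param hits_allo alignments of allopolyploid reads to the marker
#'   sequences.
#' @param reads_allo named read sequences.
#' @param marker_sites data.frame marker, gene_id (alignment target), pos
#'   (0-based), p1_allele, p2_allele.
#' @param min_reads minimum informative reads per marker.
#' @return data.frame marker, n_p1, n_p2, n_other, verdict.
#' @export
marker_ancestry <- function(hits_allo, reads_allo, marker_sites,
                            min_reads = 5) {
  rd <- as_chr_seqs(reads_allo)
  out <- lapply(split(marker_sites, marker_sites$marker), function(ms) {
    n_p1 <- 0L; n_p2 <- 0L; n_other <- 0L
    site_p1_seen <- logical(nrow(ms)); site_p2_seen <- logical(nrow(ms))
    for (j in seq_len(nrow(ms))) {
      h <- hits_allo[hits_allo$target == ms$gene_id[j], , drop = FALSE]
      if (!nrow(h)) next
      seqs <- rd[h$query]
      cover <- h$pos <= ms$pos[j] & ms$pos[j] < h$pos + nchar(seqs)
      if (!any(cover)) next
      b <- .cpp_base_at(unname(seqs[cover]), h$pos[cover],
                        as.integer(h$strand[cover] == "+"),
                        rep(ms$pos[j], sum(cover)))
      n_p1 <- n_p1 + sum(b == ms$p1_allele[j])
      n_p2 <- n_p2 + sum(b == ms$p2_allele[j])
      n_other <- n_other + sum(b != ms$p1_allele[j] & b != ms$p2_allele[j])
      site_p1_seen[j] <- any(b == ms$p1_allele[j])
      site_p2_seen[j] <- any(b == ms$p2_allele[j])
    }
    verdict <- if (n_p1 + n_p2 < min_reads) "insufficient"
      else if (n_p1 > 0 && n_p2 == 0) "sole-P1"
      else if (n_p2 > 0 && n_p1 == 0) "sole-P2"
      else "mixed"
    data.frame(marker = ms$marker[1], n_p1 = n_p1, n_p2 = n_p2,
               n_other = n_other, verdict = verdict,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write the diagnostic SNP table as a VCF subset
#'
#' Emits a minimal VCF v4.2: CHROM is the gene id, POS is 1-based, and the
#' diagnostic class is carried in \code{INFO/CLASS}. Per-sample allele
#' depths are written when count columns are present.
#'
#' @param snp_table classified table.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_snp_vcf <- function(snp_table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=homeofate-", packageVersion("homeofate")),
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Diagnostic ancestry class\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snp_table))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tCLASS=%s",
                       snp_table$gene_id, snp_table$pos + 1L,
                       snp_table$ref, snp_table$alt, snp_table$class), con)
  invisible(path)
}

#' Read a diagnostic SNP VCF written by \code{\link{write_snp_vcf}}
#'
#' @param path VCF file.
#' @return data.frame gene_id, pos (0-based), ref, alt, class.
#' @export
read_snp_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(gene_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      class = character(0), stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(gene_id = f[, 1], pos = as.integer(f[, 2]) - 1L,
             ref = f[, 4], alt = f[, 5],
             class = sub("^.*CLASS=([^;]+).*$", "\\1", f[, 8]),
             stringsAsFactors = FALSE)
}
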