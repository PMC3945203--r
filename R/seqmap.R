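#' Build a k-mer index over target sequences
#'
#' Indexes every k-mer occurrence in every target for seed lookup by the
#' ungapped mapper. k-mers containing non-ACGT characters (for example the
#' \code{N} bases of a masked homeolog reference) are not indexed and never
#' match.
#'
#' @param targets \code{DNAStringSet} or named character vector.
#' @param k seed length (8 to 31). The mapper partitions a read into
#'   \code{floor(read_length / k)} non-overlapping seeds; enumeration of
#'   hits is complete whenever that number exceeds the mismatch bound
#'   (pigeonhole).
#' @return An object of class \code{kmer_index}.
#' @export
build_index <- function(targets, k = 21) {
  seqs <- as_chr_seqs(targets)
  if (!length(seqs)) stop("targets must be nonempty")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("targets must be named")
  if (k < 8) stop("k must be >= 8")
  if (k > min(nchar(seqs))) stop("k exceeds the shortest target")
  ptr <- .cpp_build_index(seqs, as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), target_names = names(seqs),
                 target_lengths = setNames(nchar(seqs), names(seqs))),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  info <- .cpp_index_info(x$ptr)
  cat("kmer_index: k =", x$k, "|", info$n_targets, "targets |",
      format(info$n_kmers, big.mark = ","), "distinct k-mers\n")
  invisible(x)
}

#' Map reads with a mismatch bound (ungapped, both strands)
#'
#' Returns every full-length ungapped alignment of each read (or its
#' reverse complement) with at most \code{max_mismatch} mismatches, found
#' by exact k-mer seeding. Any alignment admitting at least one exact seed
#' is reported; when \code{floor(read_length / k) > max_mismatch} this
#' enumeration is complete. \code{N} positions never match, so masked
#' reference sequence is unmappable.
#'
#' @param reads \code{DNAStringSet} or character vector (named or not).
#' @param index a \code{\link{build_index}} result.
#' @param max_mismatch maximum mismatches per alignment.
#' @return data.frame with columns \code{query} (read name or index),
#'   \code{target}, \code{pos} (0-based start on target), \code{strand}
#'   (\code{"+"}/\code{"-"}) and \code{mismatches}, sorted for
#'   reproducibility.
#' @export
map_reads <- function(reads, index, max_mismatch = 0) {
  stopifnot(inherits(index, "kmer_index"))
  rd <- as_chr_seqs(reads)
  if (!length(rd))
    return(data.frame(query = character(0), target = character(0),
                      pos = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  hits <- .cpp_map_reads(unname(rd), index$ptr, as.integer(max_mismatch))
  qn <- if (!is.null(names(rd))) names(rd)[hits$query]
        else as.character(hits$query)
  out <- data.frame(query = qn, target = index$target_names[hits$target],
                    pos = hits$pos,
                    strand = ifelse(hits$strand == 1, "+", "-"),
                    mismatches = hits$mismatches, stringsAsFactors = FALSE)
  out <- out[order(hits$query, out$target, out$pos, out$strand), ]
  rownames(out) <- NULL
  out
}

# Exhaustive all-offsets, all-strands scan. Test oracle only; shares no
# code path with the seeded mapper.
map_reads_bruteforce <- function(reads, targets, max_mismatch = 0) {
  rd <- as_chr_seqs(reads)
  tg <- as_chr_seqs(targets)
  hits <- .cpp_map_bruteforce(unname(rd), unname(tg),
                              as.integer(max_mismatch))
  qn <- if (!is.null(names(rd))) names(rd)[hits$query]
        else as.character(hits$query)
  out <- data.frame(query = qn, target = names(tg)[hits$target],
                    pos = hits$pos,
                    strand = ifelse(hits$strand == 1, "+", "-"),
                    mismatches = hits$mismatches, stringsAsFactors = FALSE)
  out <- out[order(hits$query, out$target, out$pos, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Write alignments as a SAM subset
#'
#' Emits a minimal SAM v1 file: \code{@SQ} header lines, the strand bit of
#' FLAG, full-length match CIGARs and the \code{NM} tag. Reverse-strand
#' records store the reverse-complemented read, per SAM convention.
#'
#' @param hits alignment data.frame from \code{\link{map_reads}}.
#' @param reads the reads that were mapped (named character or
#'   \code{DNAStringSet}); names must match \code{hits$query}.
#' @param target_lengths named integer vector of target lengths.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
write_sam <- function(hits, reads, target_lengths, path) {
  rd <- as_chr_seqs(reads)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(target_lengths),
                     as.integer(target_lengths)), con)
  if (nrow(hits)) {
    seqs <- rd[hits$query]
    rev <- hits$strand == "-"
    seqs[rev] <- revcomp_chr(seqs[rev])
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       hits$query, ifelse(rev, 16L, 0L), hits$target,
                       hits$pos + 1L, nchar(seqs), seqs, hits$mismatches),
               con)
  }
  invisible(path)
}

#' Read a SAM subset into an alignment table
#'
#' Parses mapped records of a SAM file into the internal alignment format
#' (0-based positions). Records whose CIGAR contains anything other than a
#' single full-length match (insertions, deletions, clips) are skipped
#' with a warning, since the pipeline's alignment model is ungapped.
#'
#' @param path SAM file.
#' @return data.frame with \code{query}, \code{target}, \code{pos}
#'   (0-based), \code{strand}, \code{mismatches} (NM tag, \code{NA} if
#'   absent) and \code{seq} (read bases in original read orientation);
#'   attribute \code{skipped} counts skipped gapped records.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  skipped <- 0L
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) stop("malformed SAM record: ", ln)
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) != 0L) next  # unmapped
    if (!grepl("^[0-9]+M$", f[6])) {
      skipped <- skipped + 1L
      next
    }
    nm <- NA_integer_
    tags <- f[-(1:11)]
    nm_tag <- tags[startsWith(tags, "NM:i:")]
    if (length(nm_tag)) nm <- as.integer(sub("NM:i:", "", nm_tag[1]))
    rev <- bitwAnd(flag, 16L) != 0L
    seq_ <- f[10]
    if (rev && seq_ != "*") seq_ <- revcomp_chr(seq_)
    out[[length(out) + 1L]] <- data.frame(
      query = f[1], target = f[3], pos = as.integer(f[4]) - 1L,
      strand = if (rev) "-" else "+", mismatches = nm, seq = seq_,
      stringsAsFactors = FALSE)
  }
  if (skipped > 0)
    warning(sprintf("skipped %d gapped SAM record(s) (ungapped model)",
                    skipped))
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(query = character(0), target = character(0),
                         pos = integer(0), strand = character(0),
                         mismatches = integer(0), seq = character(0),
                         stringsAsFactors = FALSE)
  attr(res, "skipped") <- skipped
  res
}
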