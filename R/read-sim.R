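#' Load an experiment directory written by \code{\link{write_sim}}
#'
#' Reconstructs the input object for \code{\link{analyze_experiment}} from
#' plain-text artifacts: the surrogate reference FASTA, the gene
#' coordinate table, the configuration echo and the FASTQ read files
#' (mates paired by the \code{_1}/\code{_2} file suffix). Ground-truth
#' tables are loaded when present (simulated data) and skipped otherwise,
#' so the same layout serves real inputs.
#'
#' @param dir directory produced by \code{\link{write_sim}} (or laid out
#'   the same way).
#' @return a \code{sim_experiment}-shaped list usable by
#'   \code{\link{analyze_experiment}}.
#' @export
read_experiment <- function(dir) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) stop("missing input: ", p)
    p
  }
  cfg_raw <- jsonlite::read_json(need("config.json"), simplifyVector = TRUE)
  cfg_raw$library_sizes <- as.list(cfg_raw$library_sizes)
  cfg_raw$fate_proportions <- unlist(cfg_raw$fate_proportions)
  cfg <- do.call(sim_config, cfg_raw[intersect(names(cfg_raw),
                                               names(formals(sim_config)))])
  seqs <- Biostrings::readDNAStringSet(need("reference.fasta"))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  coords <- read.delim(need("gene_coords.tsv"), stringsAsFactors = FALSE)
  gene_set <- structure(list(seqs = seqs, coords = coords),
                        class = "gene_set")

  read_fq <- function(path) {
    x <- Biostrings::readDNAStringSet(path, format = "fastq")
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    out
  }
  reads <- list()
  for (smp in c("p1", "p2", "allo")) {
    reads[[smp]] <- list()
    r <- 1L
    repeat {
      single <- file.path(dir, sprintf("%s_rep%d.fastq", smp, r))
      mate1 <- file.path(dir, sprintf("%s_rep%d_1.fastq", smp, r))
      if (file.exists(single)) {
        rep_ <- list(reads = read_fq(single), reads2 = NULL)
      } else if (file.exists(mate1)) {
        rep_ <- list(reads = read_fq(mate1),
                     reads2 = read_fq(file.path(
                       dir, sprintf("%s_rep%d_2.fastq", smp, r))))
      } else break
      ofile <- file.path(dir, sprintf("%s_rep%d_origin.tsv", smp, r))
      if (file.exists(ofile))
        rep_$origin <- read.delim(ofile, stringsAsFactors = FALSE)
      reads[[smp]][[r]] <- rep_
      r <- r + 1L
    }
    if (!length(reads[[smp]]))
      stop("missing input: no FASTQ files for sample '", smp, "' in ", dir)
  }
  opt <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read.delim(p, stringsAsFactors = FALSE) else NULL
  }
  structure(list(cfg = cfg, gene_set = gene_set, genomes = NULL,
                 variants = opt("truth_variants.tsv"),
                 deletions = opt("truth_deletions.tsv"),
                 truth = opt("truth_expression.tsv"),
                 reads = reads),
            class = "sim_experiment")
}
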