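DNA_BASES <- c("A", "C", "G", "T")

# Deterministic child seed for a pipeline stage: the master seed combined
# with a hash of the stage name, kept below 2^31 so it is a valid R seed.
# Stages are therefore reproducible in isolation from the master seed.
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 * 7919 + h) %% 2147480009)
}

with_stage_seed <- function(seed, stage, expr) {
  set.seed(stage_seed(seed, stage))
  force(expr)
}

# Reverse complement for plain character vectors.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

as_chr_seqs <- function(x) {
  if (is(x, "DNAStringSet")) {
    out <- as.character(x)
    names(out) <- names(x)
    out
  } else if (is.character(x)) x
  else stop("sequences must be a DNAStringSet or named character vector")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_prob <- function(x, name, allow_one = FALSE) {
  hi_ok <- if (allow_one) x <= 1 else x < 1
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || !hi_ok)
    stop(sprintf("'%s' must be a rate in [0, 1%s", name,
                 if (allow_one) "]" else ")"))
  invisible(x)
}
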