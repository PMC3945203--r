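make_var <- function(gene_id = character(0), pos = integer(0),
                     ref = character(0), alt = character(0)) {
  data.frame(gene_id = gene_id, pos = pos, ref = ref, alt = alt,
             ref_count = rep(10L, length(pos)),
             alt_count = rep(10L, length(pos)), stringsAsFactors = FALSE)
}

test_that("pileup counts bases per covered position (interval oracle)", {
  set.seed(51)
  tgt <- c(g1 = random_dna(300), g2 = random_dna(250))
  empty <- pileup(data.frame(query = character(0), target = character(0),
                             pos = integer(0), strand = character(0)),
                  character(0), tgt)
  expect_true(all(vapply(empty, sum, numeric(1)) == 0))

  reads <- c(a = substr(tgt[["g1"]], 21, 80),
             b = substr(tgt[["g1"]], 51, 110),
             c = as.character(Biostrings::reverseComplement(
               Biostrings::DNAString(substr(tgt[["g2"]], 101, 160)))))
  hits <- data.frame(query = c("a", "b", "c"), target = c("g1", "g1", "g2"),
                     pos = c(20L, 50L, 100L), strand = c("+", "+", "-"),
                     stringsAsFactors = FALSE)
  pu <- pileup(hits, reads, tgt)
  # coverage equals brute-force interval overlap count
  for (g in names(tgt)) {
    cov_oracle <- integer(nchar(tgt[[g]]))
    for (i in which(hits$target == g)) {
      rng <- (hits$pos[i] + 1):(hits$pos[i] + 60)
      cov_oracle[rng] <- cov_oracle[rng] + 1L
    }
    expect_equal(unname(colSums(pu[[g]])), cov_oracle)
  }
  # error-free reads pile their own bases
  base_at_25 <- substr(tgt[["g1"]], 25, 25)
  expect_equal(unname(pu$g1[base_at_25, 25]), 1)
  expect_error(pileup(data.frame(query = "a", target = "g1", pos = 290L,
                                 strand = "+"), reads, tgt), "bounds")
})

test_that("parent variant calling applies coverage, fraction and tie rules", {
  ref <- c(g1 = "ACGTACGTAC")
  mk <- function(counts) {
    m <- matrix(0L, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (b in names(counts)) m[b, 3] <- counts[[b]]
    list(g1 = m)
  }
  # coverage 4 (below 5): no call even at 100% alt
  expect_equal(nrow(call_parent_variants(mk(c(T = 4)), ref)), 0)
  # 10 reads all alt: called (ref at pos 2 (0-based) is G)
  v <- call_parent_variants(mk(c(T = 10)), ref)
  expect_equal(v$pos, 2L)
  expect_equal(v$ref, "G")
  expect_equal(v$alt, "T")
  # 5/5 split between two alternates: tie, no call
  expect_equal(nrow(call_parent_variants(mk(c(T = 5, A = 5)), ref)), 0)
  # 9 alt / 1 ref = 90% alt: called at the inclusive boundary
  expect_equal(nrow(call_parent_variants(mk(c(T = 9, G = 1)), ref)), 1)
  expect_equal(nrow(call_parent_variants(mk(c(T = 8, G = 2)), ref)), 0)
})

test_that("allopolyploid calling keeps heterozygous-like sites", {
  ref <- c(g1 = "ACGTACGTAC")
  mk <- function(nalt, nref) {
    m <- matrix(0L, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
    m["T", 3] <- nalt; m["G", 3] <- nref
    list(g1 = m)
  }
  expect_equal(nrow(call_allo_variants(mk(2, 98), ref)), 0)   # < 3 reads
  expect_equal(nrow(call_allo_variants(mk(30, 70), ref)), 1)  # het-like
  expect_equal(nrow(call_allo_variants(mk(3, 97), ref)), 0)   # < 20%
  expect_equal(nrow(call_allo_variants(mk(3, 9), ref)), 1)
})

test_that("diagnostic classification partitions variants by sharing", {
  empty <- classify_snps(make_var(), make_var(), make_var())
  expect_equal(nrow(empty), 0)

  p1 <- make_var(c("g1", "g1", "g2", "g3", "g5"), c(10L, 20L, 5L, 7L, 1L),
                 c("A", "C", "G", "T", "A"), c("G", "T", "A", "C", "T"))
  p2 <- make_var(c("g1", "g2", "g2", "g3", "g6"), c(10L, 5L, 30L, 7L, 2L),
                 c("A", "G", "C", "T", "C"), c("G", "A", "G", "C", "A"))
  al <- make_var(c("g1", "g1", "g2", "g4"), c(10L, 20L, 30L, 3L),
                 c("A", "C", "C", "G"), c("G", "T", "G", "C"))
  cls <- classify_snps(p1, p2, al)
  get <- function(g, p) cls$class[cls$gene_id == g & cls$pos == p]
  expect_equal(get("g1", 10), "ancestral")      # in all three
  expect_equal(get("g1", 20), "p1_shared")      # p1 + allo
  expect_equal(get("g2", 5), "residual")        # both parents, not allo
  expect_equal(get("g2", 30), "p2_shared")      # p2 + allo
  expect_equal(get("g3", 7), "residual")
  expect_equal(get("g4", 3), "allo_unclassified")
  expect_equal(get("g5", 1), "p1_unique")
  expect_equal(get("g6", 2), "p2_unique")
  # partition: every variant exactly one class
  expect_false(any(is.na(cls$class)))
  expect_equal(sum(class_counts(cls)[homeofate:::DIAG_CLASSES]), nrow(cls))

  # symmetry: swapping parents swaps the class labels
  swapped <- classify_snps(p2, p1, al)
  swap_map <- c(ancestral = "ancestral", p1_unique = "p2_unique",
                p2_unique = "p1_unique", p1_shared = "p2_shared",
                p2_shared = "p1_shared", residual = "residual",
                allo_unclassified = "allo_unclassified")
  key <- function(x) paste(x$gene_id, x$pos, x$alt)
  expect_setequal(key(cls), key(swapped))
  m <- match(key(cls), key(swapped))
  expect_equal(unname(swap_map[cls$class]), swapped$class[m])

  # conflicting alternates at one site are excluded as multi-allelic
  al2 <- make_var("g2", 5L, "G", "T")  # p1/p2 say alt A, allo says T
  cls2 <- classify_snps(p1, p2, al2)
  expect_equal(attr(cls2, "multiallelic"), 1L)
  expect_false(any(cls2$gene_id == "g2" & cls2$pos == 5))
})

test_that("linkage assigns allopolyploid-private SNPs to a subgenome", {
  set.seed(61)
  refseq <- random_dna(200)
  # diagnostic p1_shared site at 50 (alt G), p2_shared at 120 (alt T),
  # unclassified new allele at 70 (alt A)
  base_at <- function(s, p) substr(s, p + 1, p + 1)
  other <- function(b, want) setdiff(c("A", "C", "G", "T"), b)[1]
  d1_alt <- other(base_at(refseq, 50)); u_alt <- other(base_at(refseq, 70))
  d2_alt <- other(base_at(refseq, 120))
  snp <- data.frame(
    gene_id = "g1", pos = c(50L, 120L, 70L),
    ref = c(base_at(refseq, 50), base_at(refseq, 120), base_at(refseq, 70)),
    alt = c(d1_alt, d2_alt, u_alt),
    class = c("p1_shared", "p2_shared", "allo_unclassified"),
    stringsAsFactors = FALSE)
  # subgenome P1 haplotype: alt at 50, alt at 70, ref at 120
  hap1 <- mutate_at(mutate_at(refseq, 50, d1_alt), 70, u_alt)
  reads <- setNames(vapply(1:5, function(i)
    substr(hap1, 21, 120), character(1)), paste0("r", 1:5))
  hits <- data.frame(query = names(reads), target = "g1", pos = 20L,
                     strand = "+", mismatches = 0L, stringsAsFactors = FALSE)
  out <- assign_allo_unique_by_ld(hits, reads, snp, min_links = 3)
  expect_equal(out$class[out$pos == 70], "allo_p1")
  # below min_links: stays unclassified
  out2 <- assign_allo_unique_by_ld(hits[1:2, ], reads[1:2], snp,
                                   min_links = 3)
  expect_equal(out2$class[out2$pos == 70], "allo_unclassified")
  # conflicting votes beyond tolerance: stays unclassified
  hap2 <- mutate_at(mutate_at(refseq, 120, d2_alt), 70, u_alt)
  reads_mix <- c(reads[1:3],
                 setNames(vapply(4:6, function(i) substr(hap2, 21, 120),
                                 character(1)), paste0("r", 4:6)))
  hits_mix <- data.frame(query = names(reads_mix), target = "g1", pos = 20L,
                         strand = "+", mismatches = 0L,
                         stringsAsFactors = FALSE)
  out3 <- assign_allo_unique_by_ld(hits_mix, reads_mix, snp, min_links = 3)
  expect_equal(out3$class[out3$pos == 70], "allo_unclassified")
})

test_that("linkage recovers simulated subgenome ancestry at zero error", {
  sim <- clean_sim()
  res <- clean_res()
  snps <- res$snps
  truth <- sim$variants
  tkey <- paste(truth$gene_id, truth$pos, truth$alt)
  skey <- paste(snps$gene_id, snps$pos, snps$alt)
  m <- match(skey, tkey)
  lin <- truth$lineage[m]
  assigned <- snps$class %in% c("allo_p1", "allo_p2")
  # no misassignment at zero error: every linkage-assigned variant sits on
  # the assigned subgenome's lineage (its allo branch, or the shared
  # parental branch when the variant escaped detection in that parent)
  expect_true(all(lin[assigned & snps$class == "allo_p1"] %in%
                    c("allo_p1_branch", "p1_branch")))
  expect_true(all(lin[assigned & snps$class == "allo_p2"] %in%
                    c("allo_p2_branch", "p2_branch")))
  # allo-branch variants near a diagnostic site on an expressed homeolog
  # are mostly assigned
  allo_branch <- which(!is.na(lin) & lin %in% c("allo_p1_branch",
                                                "allo_p2_branch"))
  near <- vapply(allo_branch, function(i) {
    dg <- snps[snps$gene_id == snps$gene_id[i] &
               snps$class %in% c("p1_shared", "p2_shared"), ]
    any(abs(dg$pos - snps$pos[i]) < sim$cfg$read_length)
  }, logical(1))
  cand <- allo_branch[near]
  if (length(cand) >= 5)
    expect_gte(mean(snps$class[cand] %in% c("allo_p1", "allo_p2")), 0.9)
})

test_that("class counts and share stats do the bookkeeping arithmetic", {
  expect_equal(sum(class_counts(make_var())[homeofate:::DIAG_CLASSES]), 0)
  toy <- data.frame(gene_id = "g", pos = 1:6, ref = "A", alt = "C",
                    class = c("ancestral", "p1_shared", "p2_shared",
                              "allo_p1", "allo_p2", "allo_unclassified"),
                    stringsAsFactors = FALSE)
  cc <- class_counts(toy)
  expect_equal(unname(cc["allo_unique"]), 3)
  expect_equal(unname(cc["allo_p1"] + cc["allo_p2"] + cc["allo_unclassified"]),
               unname(cc["allo_unique"]))
  st <- snp_share_stats(cc)
  expect_equal(st$allo_total, 6)
  expect_equal(st$shared_pct, 100 * 3 / 6)
  expect_equal(st$ld_assigned_pct, 100 * 2 / 3)
})

test_that("marker ancestry verdicts follow the read tallies", {
  set.seed(71)
  mito <- c(mt = random_dna(300))
  sites <- data.frame(marker = "mt_marker", gene_id = "mt",
                      pos = c(50L, 150L, 250L),
                      p1_allele = c("A", "C", "G"),
                      p2_allele = c("T", "G", "A"), stringsAsFactors = FALSE)
  mk_reads <- function(n, allele_col) {
    out <- list()
    for (i in seq_len(n)) {
      p <- sites$pos[(i %% 3) + 1]
      s <- substr(mito[["mt"]], p - 19, p + 20)
      s <- mutate_at(s, 20, sites[[allele_col]][(i %% 3) + 1])
      out[[i]] <- s
    }
    setNames(unlist(out), sprintf("m%02d", seq_len(n)))
  }
  p1_reads <- mk_reads(9, "p1_allele")
  hits <- function(rd, p0) data.frame(query = names(rd), target = "mt",
                                      pos = p0, strand = "+",
                                      stringsAsFactors = FALSE)
  starts <- vapply(seq_len(9), function(i) sites$pos[(i %% 3) + 1] - 20L,
                   integer(1))
  v1 <- marker_ancestry(hits(p1_reads, starts), p1_reads, sites)
  expect_equal(v1$verdict, "sole-P1")
  # 50/50 split: mixed
  p2_reads <- mk_reads(9, "p2_allele")
  names(p2_reads) <- sprintf("n%02d", 1:9)
  both <- c(p1_reads, p2_reads)
  v2 <- marker_ancestry(hits(both, c(starts, starts)), both, sites)
  expect_equal(v2$verdict, "mixed")
  # 3 reads only: insufficient
  v3 <- marker_ancestry(hits(p1_reads[1:3], starts[1:3]), p1_reads[1:3],
                        sites, min_reads = 5)
  expect_equal(v3$verdict, "insufficient")
})

test_that("diagnostic SNP VCF round-trips", {
  toy <- data.frame(gene_id = c("g1", "g2"), pos = c(0L, 41L),
                    ref = c("A", "G"), alt = c("C", "T"),
                    class = c("ancestral", "p2_shared"),
                    stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".vcf")
  write_snp_vcf(toy, f)
  back <- read_snp_vcf(f)
  expect_equal(back, toy)
  # POS is 1-based in the file
  expect_match(readLines(f)[5], "^g1\t1\t")
})
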