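---
title: "Resolving homeolog expression in an allopolyploid: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving homeolog expression in an allopolyploid: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homeofate)
```

## The problem

An allopolyploid carries two divergent parental genomes in one nucleus.
After hybridization, each gene exists as two homeologs — the copy derived
from each parent — and the central question is what happens to their
expression: does each homeolog keep its parent's expression level
(*parental expression inheritance*), does a parental difference disappear
(*homeolog expression blending*), does a new difference arise
(*homeolog expression bias*), or does the direction of a parental
difference flip (*homeolog expression reversal*)? A related,
total-expression question is *expression-level dominance*: for genes
differentially expressed between the parents, does the combined homeolog
expression resemble one parent rather than their average?

Answering these questions from bulk RNA-seq requires assigning each
allopolyploid read to its homeolog of origin, which is hard when no close
reference genome exists for either parent. `homeofate` implements a
surrogate-reference strategy: reads from the two parents and the
allopolyploid are mapped at low stringency to an annotated gene set from
a related reference strain, SNPs against that reference are classified
by which samples carry them, and two homeolog-specific reference gene
sets are reconstructed by substituting the appropriate alleles. The
allopolyploid reads are then re-mapped to both references at zero
mismatches; a read counts for a homeolog only when it matches that
homeolog's sequence perfectly and the other one nowhere.

## Diagnostic SNP classes

With three samples (parent 1, parent 2, allopolyploid) mapped to the
surrogate reference, each bi-allelic variant is classified by presence:

| class            | present in              | interpretation                          |
|------------------|-------------------------|------------------------------------------|
| `ancestral`      | both parents + allo     | predates the parental split              |
| `p1_shared`      | parent 1 + allo         | parent-1 branch before hybridization     |
| `p2_shared`      | parent 2 + allo         | parent-2 branch before hybridization     |
| `p1_unique`      | parent 1 only           | parent-1 tip after hybridization         |
| `p2_unique`      | parent 2 only           | parent-2 tip after hybridization         |
| `allo_*`         | allo only               | arose in the allopolyploid               |
| `residual`       | both parents, not allo  | detection shortfall in the allopolyploid |

Allopolyploid-private variants start `allo_unclassified` and are assigned
to a subgenome by linkage: reads (or mate pairs) carrying the new allele
vote through the parental diagnostic alleles they also cover. At least
`min_links = 3` voting fragments and near-unanimity
(`max_conflict_frac = 0.05`) are required. Sites with conflicting
alternate alleles across samples are excluded — the diagnostic framework
is bi-allelic.

The P1-like reference receives `ancestral + p1_shared + allo_p1` alleles,
the P2-like reference `ancestral + p2_shared + allo_p2`. Parent-only and
unassigned alleles are deliberately not applied: a substitution that the
allopolyploid data cannot confirm would contaminate the zero-mismatch
assignment target.

## Informative regions, masking and culling

A read can only be homeolog-assigned if it overlaps a position where the
two references differ. The *informative region* of a gene is therefore
the union of windows `[p - (read_length - 1), p + read_length)` around
its discriminating positions, merged and clipped; everything outside is
masked to `N` in both references, which makes it unmappable under the
zero-mismatch rule. Parental ortholog counts are produced by the same
zero-mismatch rule against each parent's own masked reference, so all
four measurements per gene share one effective target footprint and
length biases cancel in the ratios.

Genes are culled when either parent contributes fewer than 5 reads or
the informative region is shorter than 150 bp (both thresholds
inclusive, the literal reading of "fewer than" and "less than"). The
150 bp rule is applied to the union length of the informative intervals,
not the longest single interval. Culled genes are excluded from all
expression statistics but remain *transparent* for physical clustering:
having no expression information, they cannot interrupt a run of extreme
genes.

## Statistics

Counts are normalized to reads per million (RPM) of their library's
assigned total; for the allopolyploid, the reads assigned to the P1-like and
P2-like references are treated as two libraries with their own totals. Fold differences are oriented P2-side over P1-side. Differential
expression combines an exact test with a biological criterion: a
two-sided Fisher exact test on the 2x2 table of gene count versus library
remainder (replicates summed before testing; per-replicate counts are
retained in the outputs), Storey q-values for multiple testing
(pi0 estimated on the lambda grid 0, 0.05, ..., 0.95 with a cubic
smoother evaluated at 0.95 and clipped to (0, 1]; a conservative pi0 = 1
is used below 20 tests, where the smoother is unstable), and a 2-fold
threshold: a gene is DE only when `q < 0.05` *and* the fold magnitude is
at least 2. The Fisher p-value is computed as a vectorized
hypergeometric tail sum (all outcomes no more probable than the observed
table); `stats::fisher.test` is used as an independent oracle in the
test suite rather than as the implementation, purely for speed across
thousands of genes.

The two DE directions (parents; homeologs) define nine categories that
collapse into the four outcomes. Expression-level dominance is assessed
for parent-DE genes by comparing combined homeolog expression (summed
counts over both sides, normalized by the summed totals — not halved for
ploidy) against each parent with the same fold-plus-q rule:
indistinguishable from the high parent but different from the low parent
is `dominant_high`, the converse `dominant_low`, everything else
`intermediate`. "Resembles" is thus operationalized as
statistically-indistinguishable-plus-below-2-fold rather than
nearest-in-log-space, which makes the binning consistent with every
other decision in the pipeline. For dominant genes, the non-dominant
parent's homeolog is tested against its own ortholog to decide whether
the dominance is driven by a change in the non-dominant homeolog.

Extreme differential expression (EDE) requires at least 5 allopolyploid
reads and either expression from only one homeolog (`one_sided`) or an
RPM ratio of 50-fold or more (`fold50`). Gene-loss candidates are genes
with zero reads from one or both homeologs, with no minimum-read filter:
any single-silent pattern is a candidate. EDE genes are clustered along
supercontigs as maximal runs of two or more adjacent flagged genes
(culled genes transparent).

## Dating

Substitutions private to a parental tip accumulated only after the
allopolyploid lineage split from that parent, so the SNP count `S` on the
shortest parental branch, the surveyed sequence length `L` (the
cumulative masked informative length) and a mutation rate `mu` give an
upper bound `T = S / (L * mu)` on the hybridization time, reported
rounded to the nearest 100,000 years. No lower bound is available from
these data. The branch is selected automatically as
`min(p1_unique, p2_unique)`.

## The synthetic-data generator

The generator emulates the study conditions end to end, with full ground
truth. Its phylogeny has seven branches: an ancestral branch shared by
all samples (default 0.002 substitutions/site), pre-hybridization parent
branches at strongly asymmetric divergence (0.004 close, 0.04 far —
mirroring the order-of-magnitude SNP asymmetry between a parent closely
related to the reference strain and one approaching 8% divergence
when the ancestral share is included), and post-hybridization branches at
5e-4 applied independently to each parent's private tip and to the
corresponding allopolyploid subgenome (equal elapsed time on both sides
of the split). Sites are kept bi-allelic by excluding already-mutated
positions from later draws. Substitutions only: the diagnostic framework
and the zero-mismatch rule are SNP-based, so indels are out of scope;
whole-gene deletions are modelled separately as non-overlapping clusters
of adjacent genes removed from exactly one subgenome (default: three
clusters of three genes, alternating sides).

Expression fates are drawn per gene from configurable proportions,
defaulting to the four-outcome proportions of the study system this
package models (0.561, 0.251, 0.156, 0.032). Within inheritance, 25% of
genes carry a parental bias; this value is chosen so that roughly
two-thirds of genes end up not differentially expressed between
homeologs, matching the study's global picture. The effect size for
"biased" is 2 in log2 units (4-fold); base expression is log-normal
(log2 mean 5, sd 1.5). Reads are drawn multinomially over transcripts
proportionally to expression times effective length, with uniform
positions, random strand, i.i.d. base errors (default 0.001), and — for
the allopolyploid — proper mate pairs from fragments of 300 +- 30 bp
(an insert model the generator needs but that has no single canonical
value; these are typical short-insert values).

What the generator does *not* emulate: GC and positional bias,
quality-score error profiles, splice isoforms, partial deletions and
other structural variation, and library-preparation artifacts. Passing
recovery tests on these simulations therefore demonstrates the
correctness of the pipeline's logic under its own assumptions, not
robustness to every artifact of real libraries.

## Mapping

The built-in mapper is deliberately minimal: ungapped, full-length,
mismatch-bounded alignment seeded by exact k-mers. A read is partitioned
into `floor(read_length / k)` non-overlapping seeds; by pigeonhole, any
alignment with fewer mismatches than seeds retains at least one exact
seed, so enumeration is complete whenever
`floor(read_length / k) > max_mismatch`. Discovery mapping uses k = 9
and a mismatch bound of `ceiling(0.10 * read_length)`, tolerating ~8%
parent-reference divergence plus sequencing error; there is no canonical
setting for this "low stringency" phase, so it is exposed as a tunable. Zero-mismatch assignment uses k = 21. Reads whose best
mismatch count is achieved in more than one gene are discarded during
discovery to avoid paralog-inflated SNPs. Externally produced ungapped
alignments can be imported from a SAM subset; gapped records are skipped
with a warning.

## Numerical and design choices

* **Variant calling.** Parents are haploid: a site is called with
  coverage >= 5 and alternate fraction >= 0.9 (tolerating sequencing
  error). The allopolyploid mixes two homeologs whose expression ratio
  can be far from 1:1, so its calling uses an absolute floor of 3
  alternate reads and a low fraction threshold. The pipeline default for
  that fraction is 0.1: at the design effect size of 4-fold bias the
  minority homeolog contributes ~1/5 of a gene's reads, and a threshold
  at exactly 0.2 drops about half of the divergent parent's diagnostic
  SNPs in biased genes, which in turn corrupts the minority-side
  reference and the parental ortholog counts measured against it. Half
  the minority share (0.1) keeps those SNPs while staying well above the
  error floor (0.001 per base). `call_allo_variants()` itself defaults
  to the more conservative 0.2 for standalone use.
* **Ambiguous versus unassigned.** A fragment mapping nowhere on the
  masked references is re-checked against the unmasked references: a
  perfect match there means the fragment simply overlaps no
  discriminating site (ambiguous); no match anywhere means a sequencing
  error under the zero-mismatch rule (unassigned).
* **Zero-count folds.** One-sided zero RPMs give an infinite,
  flagged fold (DE when significant); double zeros are flagged undefined
  rather than pseudocounted. A pseudocount of 0.5 is used only in
  exported log-ratio tables for heat-map-style inspection.
* **Reversal and independence.** Inheritance of biased expression
  implies fully independent regulation of the two copies since the
  parents speciated; bias implies partial independence; blending implies
  none. Genes unbiased in both generations can be excluded from the
  denominator, counted as independent or counted as non-independent —
  all three treatments are reported. Reversal genes fit none of the
  three interpretations cleanly and are excluded and reported
  separately.
* **Determinism.** One master seed; each stage derives a child seed from
  a hash of its name, so stages are reproducible in isolation and a
  fixed seed yields byte-identical outputs.

## Problem sizes

The test suite exercises the full chain on simulations of 12-300 genes
with libraries of 4,000-300,000 reads; the acceptance script uses 1,000
genes with two replicates of 100,000 parental reads and 250,000
allopolyploid fragments. These sizes give every retained gene on the
order of a few hundred reads per homeolog — deep enough that the
4-fold simulated effects are comfortably beyond the 2-fold decision
boundary — while keeping a complete run in minutes on one CPU. At these
depths the recovered outcome proportions track the simulated truth to
within about two percentage points; residual misclassification is
concentrated in genes at the low tail of the expression distribution,
where the parental DE test loses power.

## Known limitations

* The mapper is ungapped; real data with indel-rich divergence need an
  external gapped mapper and the SAM import path, and indel-proximal
  SNPs will still be unusable for assignment.
* Reference reconstruction depends on variant detectability in all three
  samples; genes expressed in the allopolyploid but nearly silent in a
  parent are culled rather than rescued.
* Fisher's exact test on pooled replicates ignores biological
  overdispersion; a negative-binomial treatment is out of scope.
* The dating bound inherits the mutation-rate assumption wholesale and
  propagates no uncertainty.

## A worked miniature

```{r mini, eval = FALSE}
cfg <- sim_config(n_genes = 60, gene_length_mean = 600,
                  library_sizes = list(p1 = 2e4, p2 = 2e4, allo = 4e4),
                  n_deletion_clusters = 1, deletion_cluster_size = 2,
                  genes_per_supercontig = 20, seed = 7)
sim <- simulate_experiment(cfg)
res <- analyze_experiment(sim)
res$proportions          # recovered outcome proportions
res$loss$total           # gene-loss candidates
res$clusters$clusters    # physically clustered extreme genes
res$dating$T_report      # dated upper bound (years)
```
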