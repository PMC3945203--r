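NINE_TABLE <- data.frame(
  nine_category = 1:9,
  parent_state = c("P2_higher", "P1_higher", "equal",
                   "P2_higher", "P1_higher",
                   "equal", "equal",
                   "P2_higher", "P1_higher"),
  allo_state = c("P2_higher", "P1_higher", "equal",
                 "equal", "equal",
                 "P2_higher", "P1_higher",
                 "P1_higher", "P2_higher"),
  outcome = c("inheritance", "inheritance", "inheritance",
              "blending", "blending",
              "bias", "bias",
              "reversal", "reversal"),
  stringsAsFactors = FALSE)

#' Nine-category expression fate from parent and allopolyploid DE states
#'
#' Each gene's pair of DE directions (between the parental orthologs and
#' between the allopolyploid homeologs, each one of P2-higher, P1-higher
#' or equal) maps bijectively to one of nine categories, grouped into four
#' outcomes: inheritance (same state in both generations), blending (a
#' parental bias lost in the allopolyploid), bias (a new bias in the
#' allopolyploid) and reversal (the bias flips side).
#'
#' @param parent_state,allo_state character vectors of DE directions.
#' @return data.frame with \code{nine_category} (1-9) and \code{outcome}.
#' @export
classify_nine <- function(parent_state, allo_state) {
  stopifnot(length(parent_state) == length(allo_state))
  key <- paste(parent_state, allo_state)
  tab_key <- paste(NINE_TABLE$parent_state, NINE_TABLE$allo_state)
  idx <- match(key, tab_key)
  if (anyNA(idx)) stop("states must be P2_higher, P1_higher or equal")
  data.frame(nine_category = NINE_TABLE$nine_category[idx],
             outcome = NINE_TABLE$outcome[idx], stringsAsFactors = FALSE)
}

#' Classify expression fates for retained genes
#'
#' @param records \code{\link{expression_records}} table.
#' @param retained optional character vector of retained gene ids (all
#'   genes by default).
#' @return data.frame gene_id, parent_state, allo_state, nine_category,
#'   outcome.
#' @export
classify_fates <- function(records, retained = NULL) {
  if (!is.null(retained))
    records <- records[records$gene_id %in% retained, , drop = FALSE]
  nine <- classify_nine(records$parent_state, records$allo_state)
  data.frame(gene_id = records$gene_id,
             parent_state = records$parent_state,
             allo_state = records$allo_state,
             nine_category = nine$nine_category,
             outcome = nine$outcome,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proportions of the four expression outcomes
#'
#' @param fates \code{\link{classify_fates}} table.
#' @return named numeric vector (inheritance, blending, bias, reversal)
#'   summing to 1.
#' @export
outcome_proportions <- function(fates) {
  lv <- c("inheritance", "blending", "bias", "reversal")
  t_ <- table(factor(fates$outcome, levels = lv))
  setNames(as.numeric(t_) / sum(t_), lv)
}

#' Expression-level dominance and its driving homeolog
#'
#' For genes differentially expressed between the parents, compares the
#' combined homeolog expression in the allopolyploid to each parent with
#' the same fold-plus-significance rule used throughout:
#' indistinguishable from the highly expressed parent but different from
#' the lowly expressed one is dominant-high, the converse dominant-low,
#' anything else intermediate. For dominant genes, the non-dominant
#' parent's homeolog is tested against its own parental ortholog; a
#' change there marks the dominance as driven by the non-dominant
#' homeolog.
#'
#' @param records \code{\link{expression_records}} table (replicate-summed
#'   RPMs and parent DE calls).
#' @param parent_counts,parent_totals,allo_counts,allo_totals count
#'   matrices and library totals as in \code{\link{expression_records}}.
#' @param fold_thresh,q_thresh DE thresholds.
#' @return data.frame gene_id, high_parent, dominance (dominant_high /
#'   dominant_low / intermediate / not_applicable), driver
#'   (non_dominant_changed / non_dominant_unchanged / not_applicable).
#' @export
dominance_classify <- function(records, parent_counts, parent_totals,
                               allo_counts, allo_totals, fold_thresh = 2,
                               q_thresh = 0.05) {
  ids <- records$gene_id
  stopifnot(identical(ids, rownames(parent_counts)),
            identical(ids, rownames(allo_counts)))
  out <- data.frame(gene_id = ids, high_parent = NA_character_,
                    dominance = "not_applicable",
                    driver = "not_applicable", stringsAsFactors = FALSE)
  pd <- which(records$parent_de)
  if (!length(pd)) return(out)
  combined <- allo_counts[, 1] + allo_counts[, 2]
  total_combined <- sum(allo_totals)
  comb_rpm <- rpm_normalize(combined, total_combined)
  test_vs <- function(parent_col, genes) {
    p <- fisher_de(combined[genes], parent_counts[genes, parent_col],
                   total_combined, parent_totals[parent_col])
    q <- qvalues(p)$q
    rpm_par <- rpm_normalize(parent_counts[genes, parent_col],
                             parent_totals[parent_col])
    f <- fold_difference(comb_rpm[genes], rpm_par)
    call_de(f$fold, f$fold_mag, q, fold_thresh, q_thresh)$de
  }
  diff_p1 <- test_vs(1, pd)
  diff_p2 <- test_vs(2, pd)
  high_is_p2 <- records$parent_state[pd] == "P2_higher"
  diff_high <- ifelse(high_is_p2, diff_p2, diff_p1)
  diff_low <- ifelse(high_is_p2, diff_p1, diff_p2)
  dom <- ifelse(!diff_high & diff_low, "dominant_high",
                ifelse(diff_high & !diff_low, "dominant_low",
                       "intermediate"))
  out$high_parent[pd] <- ifelse(high_is_p2, "P2", "P1")
  out$dominance[pd] <- dom

  is_dom <- pd[dom != "intermediate"]
  if (length(is_dom)) {
    # non-dominant parent side: the one whose level the allopolyploid does
    # not match
    hp2 <- records$parent_state[is_dom] == "P2_higher"
    d_high <- out$dominance[is_dom] == "dominant_high"
    nd_is_p2 <- ifelse(d_high, !hp2, hp2)
    nd_col <- ifelse(nd_is_p2, 2L, 1L)
    p <- fisher_de(allo_counts[cbind(is_dom, nd_col)],
                   parent_counts[cbind(is_dom, nd_col)],
                   allo_totals[nd_col], parent_totals[nd_col])
    q <- qvalues(p)$q
    rpm_h <- rpm_normalize(allo_counts[cbind(is_dom, nd_col)],
                           allo_totals[nd_col])
    rpm_o <- rpm_normalize(parent_counts[cbind(is_dom, nd_col)],
                           parent_totals[nd_col])
    f <- fold_difference(rpm_o, rpm_h)
    changed <- call_de(f$fold, f$fold_mag, q, fold_thresh, q_thresh)$de
    out$driver[is_dom] <- ifelse(changed, "non_dominant_changed",
                                 "non_dominant_unchanged")
  }
  out
}

#' Flag extreme differentially expressed (EDE) genes
#'
#' Among genes with at least \code{min_reads} allopolyploid reads in
#' total, flags genes with expression from only one homeolog
#' (\code{one_sided}) or with an RPM ratio magnitude of
#' \code{fold_thresh} or more (\code{fold50}).
#'
#' @param allo_counts gene x 2 homeolog count matrix.
#' @param allo_totals per-side library totals (for the RPM ratio).
#' @param min_reads minimum total reads for eligibility.
#' @param fold_thresh extreme fold threshold (default 50).
#' @return character vector (named by gene) in \code{none}, \code{fold50},
#'   \code{one_sided}.
#' @export
find_ede <- function(allo_counts, allo_totals, min_reads = 5,
                     fold_thresh = 50) {
  tot <- allo_counts[, 1] + allo_counts[, 2]
  rpm1 <- rpm_normalize(allo_counts[, 1], allo_totals[1])
  rpm2 <- rpm_normalize(allo_counts[, 2], allo_totals[2])
  f <- fold_difference(rpm1, rpm2)
  flag <- rep("none", nrow(allo_counts))
  elig <- tot >= min_reads
  flag[elig & f$flag == "one_sided"] <- "one_sided"
  flag[elig & f$flag == "none" & f$fold_mag >= fold_thresh] <- "fold50"
  setNames(flag, rownames(allo_counts))
}

#' Gene-loss candidates from homeolog counts
#'
#' Genes with no reads from one or both homeologs (no minimum-read filter:
#' any single-sided expression pattern is a candidate). The flag names the
#' silent side.
#'
#' @param allo_counts gene x 2 homeolog count matrix over retained genes.
#' @return list with \code{flag} (named character: none / both_silent /
#'   P1_only / P2_only), per-category totals, \code{total} candidates and
#'   \code{detection_rate_pct} (share of genes with at least one read).
#' @export
loss_candidates <- function(allo_counts) {
  c1 <- allo_counts[, 1]; c2 <- allo_counts[, 2]
  flag <- rep("none", nrow(allo_counts))
  flag[c1 == 0 & c2 == 0] <- "both_silent"
  flag[c1 == 0 & c2 > 0] <- "P1_only"   # P1 homeolog silent
  flag[c1 > 0 & c2 == 0] <- "P2_only"   # P2 homeolog silent
  n <- c(both_silent = sum(flag == "both_silent"),
         P1_only = sum(flag == "P1_only"),
         P2_only = sum(flag == "P2_only"))
  list(flag = setNames(flag, rownames(allo_counts)),
       n_both_silent = unname(n["both_silent"]),
       n_p1_only = unname(n["P1_only"]),
       n_p2_only = unname(n["P2_only"]),
       total = sum(n),
       detection_rate_pct = 100 * mean(c1 + c2 > 0))
}

#' Physical clusters of EDE genes
#'
#' Orders genes along each supercontig and reports maximal runs of two or
#' more adjacent EDE genes. Genes culled from the analysis carry no
#' expression information and are transparent: they do not break a run.
#'
#' @param coords gene coordinate table (gene_id, supercontig, start).
#' @param ede_flag named flag vector from \code{\link{find_ede}} over
#'   analyzed (retained) genes.
#' @param retained character vector of retained gene ids.
#' @return list with \code{clusters} (data.frame supercontig, cluster,
#'   gene_id), \code{n_clustered}, \code{n_ede} and
#'   \code{clustered_fraction_pct}.
#' @export
cluster_ede <- function(coords, ede_flag, retained = names(ede_flag)) {
  is_ede <- names(ede_flag)[ede_flag != "none"]
  res <- list()
  cl <- 0L
  for (sc in unique(coords$supercontig)) {
    g <- coords[coords$supercontig == sc, , drop = FALSE]
    g <- g[order(g$start), , drop = FALSE]
    g <- g[g$gene_id %in% retained, , drop = FALSE]  # culled transparent
    if (!nrow(g)) next
    run <- rle(g$gene_id %in% is_ede)
    ends <- cumsum(run$lengths)
    starts <- ends - run$lengths + 1L
    for (j in which(run$values & run$lengths >= 2)) {
      cl <- cl + 1L
      res[[cl]] <- data.frame(supercontig = sc, cluster = cl,
                              gene_id = g$gene_id[starts[j]:ends[j]],
                              stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(res)) do.call(rbind, res)
    else data.frame(supercontig = character(0), cluster = integer(0),
                    gene_id = character(0), stringsAsFactors = FALSE)
  n_ede <- length(is_ede)
  list(clusters = clusters, n_clustered = nrow(clusters), n_ede = n_ede,
       clustered_fraction_pct =
         if (n_ede > 0) 100 * nrow(clusters) / n_ede else NA_real_)
}

#' Log2 expression-ratio table for heat-map-style inspection
#'
#' Exports, per gene, the four log2 ratios used to visualize extreme
#' expression patterns: between the two homeologs, between the two
#' parental orthologs, and between each homeolog and its own ortholog. A
#' pseudocount (default 0.5 reads) keeps zero counts finite; it is used
#' only here, never in the DE statistics.
#'
#' @param parent_counts,parent_totals,allo_counts,allo_totals count
#'   matrices and library totals as in \code{\link{expression_records}}.
#' @param pseudocount reads added to every count before normalization.
#' @return data.frame gene_id, allo_log2 (P2-like over P1-like homeolog),
#'   parent_log2 (P2 over P1 ortholog), p1_copy_log2 and p2_copy_log2
#'   (homeolog over own ortholog).
#' @export
log_ratio_table <- function(parent_counts, parent_totals, allo_counts,
                            allo_totals, pseudocount = 0.5) {
  stopifnot(identical(rownames(parent_counts), rownames(allo_counts)))
  rpm <- function(cnt, tot) (cnt + pseudocount) * 1e6 / tot
  p1 <- rpm(parent_counts[, 1], parent_totals[1])
  p2 <- rpm(parent_counts[, 2], parent_totals[2])
  a1 <- rpm(allo_counts[, 1], allo_totals[1])
  a2 <- rpm(allo_counts[, 2], allo_totals[2])
  data.frame(gene_id = rownames(parent_counts),
             allo_log2 = log2(a2 / a1),
             parent_log2 = log2(p2 / p1),
             p1_copy_log2 = log2(a1 / p1),
             p2_copy_log2 = log2(a2 / p2),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proportions of genes with independent, partially independent and
#' non-independent regulation
#'
#' Inheritance of biased expression indicates fully independent
#' regulation of the two copies since the parents speciated; homeolog
#' expression bias indicates partial independence; blending indicates no
#' independence. Genes unbiased in both generations are handled per
#' \code{treatment}: excluded from the denominator, counted as
#' independent, or counted as non-independent. Reversal genes are excluded
#' and reported separately.
#'
#' @param x a \code{\link{classify_fates}} table, or a named numeric
#'   vector with elements \code{biased_inheritance}, \code{bias},
#'   \code{blending}, \code{unbiased} (and optionally \code{reversal}).
#' @param treatment how to treat genes unbiased in both generations.
#' @return list with \code{full}, \code{partial}, \code{none} proportions
#'   and \code{n_reversal_excluded}.
#' @export
independence_proportions <- function(x,
    treatment = c("exclude_unbiased", "unbiased_as_independent",
                  "unbiased_as_nonindependent")) {
  treatment <- match.arg(treatment)
  if (is.numeric(x)) {
    biased_inh <- x[["biased_inheritance"]]
    bias <- x[["bias"]]
    blending <- x[["blending"]]
    unbiased <- x[["unbiased"]]
    n_rev <- if ("reversal" %in% names(x)) x[["reversal"]] else 0
  } else {
    biased_inh <- sum(x$outcome == "inheritance" & x$parent_state != "equal")
    unbiased <- sum(x$outcome == "inheritance" & x$parent_state == "equal")
    bias <- sum(x$outcome == "bias")
    blending <- sum(x$outcome == "blending")
    n_rev <- sum(x$outcome == "reversal")
  }
  full <- biased_inh; partial <- bias; none <- blending
  if (treatment == "unbiased_as_independent") full <- full + unbiased
  if (treatment == "unbiased_as_nonindependent") none <- none + unbiased
  denom <- full + partial + none
  list(full = full / denom, partial = partial / denom, none = none / denom,
       n_reversal_excluded = n_rev, treatment = treatment)
}
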