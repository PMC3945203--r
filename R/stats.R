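#' Reads-per-million normalization
#'
#' @param count read count(s).
#' @param library_total total assigned reads of the library.
#' @return \code{count * 1e6 / library_total}.
#' @export
rpm_normalize <- function(count, library_total) {
  if (any(library_total <= 0)) stop("library total must be > 0")
  count * 1e6 / library_total
}

#' Fold difference between two normalized expression values
#'
#' Fixed orientation: the P2-side value is the numerator. A zero
#' denominator with positive numerator (or the converse) gives an
#' infinite, one-sided fold; two zeros are undefined and flagged rather
#' than pseudocounted. The symmetric magnitude \code{max(f, 1/f)} is
#' provided for thresholding.
#'
#' @param rpm_p1 P1-side value (denominator).
#' @param rpm_p2 P2-side value (numerator).
#' @return data.frame with \code{fold}, \code{fold_mag} and \code{flag}
#'   (\code{"none"}, \code{"one_sided"}, \code{"undefined"}).
#' @export
fold_difference <- function(rpm_p1, rpm_p2) {
  stopifnot(all(rpm_p1 >= 0), all(rpm_p2 >= 0))
  fold <- rpm_p2 / rpm_p1
  both_zero <- rpm_p1 == 0 & rpm_p2 == 0
  one_sided <- xor(rpm_p1 == 0, rpm_p2 == 0)
  fold[both_zero] <- NaN
  mag <- pmax(fold, 1 / fold)
  mag[both_zero] <- NA_real_
  data.frame(fold = fold, fold_mag = mag,
             flag = ifelse(both_zero, "undefined",
                           ifelse(one_sided, "one_sided", "none")),
             stringsAsFactors = FALSE)
}

#' Two-sided Fisher exact test for count differences between libraries
#'
#' Tests, per gene, the 2x2 table \code{[[count_a, total_a - count_a],
#' [count_b, total_b - count_b]]} by summing all hypergeometric outcome
#' probabilities not exceeding that of the observed table (two-sided
#' exact p). Vectorized over genes; replicates should be summed before
#' testing.
#'
#' @param count_a,count_b per-gene counts in the two libraries.
#' @param total_a,total_b library totals.
#' @return numeric vector of two-sided p-values.
#' @export
fisher_de <- function(count_a, count_b, total_a, total_b) {
  if (any(c(count_a, count_b, total_a, total_b) < 0))
    stop("negative counts")
  n <- max(length(count_a), length(count_b))
  count_a <- rep_len(count_a, n); count_b <- rep_len(count_b, n)
  total_a <- rep_len(total_a, n); total_b <- rep_len(total_b, n)
  if (any(count_a > total_a | count_b > total_b))
    stop("totals must be >= counts")
  vapply(seq_len(n), function(i) {
    k <- count_a[i] + count_b[i]
    lo <- max(0, k - total_b[i])
    hi <- min(k, total_a[i])
    x <- lo:hi
    d <- dhyper(x, total_a[i], total_b[i], k)
    d_obs <- dhyper(count_a[i], total_a[i], total_b[i], k)
    min(1, sum(d[d <= d_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on the lambda grid 0, 0.05, ...,
#' 0.95 with a cubic smoother evaluated at the last grid point, clipped to
#' (0, 1], then computes step-up q-values
#' \code{q_i = pi0 * min_{p_(j) >= p_(i)} m p_(j) / j}. With fewer than 20
#' p-values the pi0 estimate is unstable and falls back to the
#' conservative 1.
#'
#' @param p vector of p-values in [0, 1].
#' @param lambda tuning grid for pi0 estimation.
#' @return list with \code{q} (same order as \code{p}) and \code{pi0}.
#' @export
qvalues <- function(p, lambda = seq(0, 0.95, by = 0.05)) {
  if (!length(p)) stop("empty p-value list")
  if (any(p < 0 | p > 1 | is.na(p))) stop("p-values must be in [0, 1]")
  m <- length(p)
  if (m < 20) {
    pi0 <- 1
  } else {
    pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- try(smooth.spline(lambda, pi0_l, df = 3), silent = TRUE)
    pi0 <- if (inherits(fit, "try-error")) min(1, pi0_l[length(pi0_l)])
           else predict(fit, x = max(lambda))$y
    pi0 <- min(1, max(pi0, 1e-8))
  }
  ord <- order(p)
  q_ord <- pi0 * m * p[ord] / seq_len(m)
  q_ord <- rev(cummin(rev(pmin(q_ord, 1))))
  q <- numeric(m)
  q[ord] <- q_ord
  list(q = q, pi0 = pi0)
}

#' Differential expression call
#'
#' Differential expression requires both statistical significance
#' (q below \code{q_thresh}) and the biological criterion of a
#' \code{fold_thresh}-or-greater difference. One-sided infinite folds are
#' DE when significant; undefined folds (both values zero) never are.
#'
#' @param fold,fold_mag signed fold (P2 over P1) and symmetric magnitude
#'   from \code{\link{fold_difference}}.
#' @param q q-values.
#' @param fold_thresh fold-change threshold (default 2).
#' @param q_thresh significance threshold (default 0.05).
#' @return data.frame with \code{de} (logical) and \code{state}
#'   (\code{"P2_higher"}, \code{"P1_higher"}, \code{"equal"}).
#' @export
call_de <- function(fold, fold_mag, q, fold_thresh = 2, q_thresh = 0.05) {
  de <- !is.na(fold_mag) & fold_mag >= fold_thresh & q < q_thresh
  state <- rep("equal", length(de))
  state[de & fold > 1] <- "P2_higher"
  state[de & fold < 1] <- "P1_higher"
  data.frame(de = de, state = state, stringsAsFactors = FALSE)
}

#' Per-gene expression records for parents and allopolyploid homeologs
#'
#' Builds the full expression table: RPM per source, the parental and
#' homeolog folds (P2 side over P1 side), Fisher exact p-values, Storey
#' q-values and DE states for both comparisons. Counts must already be
#' summed over replicates.
#'
#' @param parent_counts gene x 2 matrix (p1, p2 ortholog counts; rownames
#'   = gene ids).
#' @param parent_totals length-2 totals for the parent libraries.
#' @param allo_counts gene x 2 matrix (allo_p1, allo_p2 homeolog counts).
#' @param allo_totals length-2 totals of reads assigned to the P1-like and
#'   P2-like references.
#' @param fold_thresh,q_thresh DE thresholds.
#' @return data.frame, one row per gene.
#' @export
expression_records <- function(parent_counts, parent_totals, allo_counts,
                               allo_totals, fold_thresh = 2,
                               q_thresh = 0.05) {
  ids <- rownames(parent_counts)
  stopifnot(identical(ids, rownames(allo_counts)))
  p1_rpm <- rpm_normalize(parent_counts[, 1], parent_totals[1])
  p2_rpm <- rpm_normalize(parent_counts[, 2], parent_totals[2])
  a1_rpm <- rpm_normalize(allo_counts[, 1], allo_totals[1])
  a2_rpm <- rpm_normalize(allo_counts[, 2], allo_totals[2])
  fp <- fold_difference(p1_rpm, p2_rpm)
  fh <- fold_difference(a1_rpm, a2_rpm)
  pp <- fisher_de(parent_counts[, 1], parent_counts[, 2],
                  parent_totals[1], parent_totals[2])
  ph <- fisher_de(allo_counts[, 1], allo_counts[, 2],
                  allo_totals[1], allo_totals[2])
  qp <- qvalues(pp)$q
  qh <- qvalues(ph)$q
  dp <- call_de(fp$fold, fp$fold_mag, qp, fold_thresh, q_thresh)
  dh <- call_de(fh$fold, fh$fold_mag, qh, fold_thresh, q_thresh)
  data.frame(gene_id = ids,
             p1_rpm = p1_rpm, p2_rpm = p2_rpm,
             allo_p1_rpm = a1_rpm, allo_p2_rpm = a2_rpm,
             parent_fold = fp$fold, parent_fold_mag = fp$fold_mag,
             parent_flag = fp$flag,
             allo_fold = fh$fold, allo_fold_mag = fh$fold_mag,
             allo_flag = fh$flag,
             parent_p = pp, parent_q = qp,
             allo_p = ph, allo_q = qh,
             parent_de = dp$de, parent_state = dp$state,
             allo_de = dh$de, allo_state = dh$state,
             row.names = NULL, stringsAsFactors = FALSE)
}
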