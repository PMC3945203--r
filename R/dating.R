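#' Upper bound on the allopolyploidization time
#'
#' The number of SNPs on the shortest parental branch accumulated since
#' the allopolyploid lineage split from that parent, divided by the
#' mutation rate times the surveyed sequence length, bounds the
#' hybridization time from above: \code{T = S / (L * mu)}. Only an upper
#' bound is available; the data place no lower bound on the event.
#'
#' @param S SNP count on the shortest parental branch.
#' @param L cumulative haploid informative sequence length (bp) of the
#'   masked homeolog references.
#' @param mu mutation rate per site per year.
#' @return list with \code{S}, \code{L}, \code{mu}, \code{T_years},
#'   \code{T_report} (rounded to the nearest 100,000 years) and
#'   \code{bound = "upper"}.
#' @export
date_upper_bound <- function(S, L, mu) {
  if (S < 0) stop("S must be >= 0")
  if (L <= 0) stop("L must be > 0")
  if (mu <= 0) stop("mu must be > 0")
  T_years <- S / (L * mu)
  list(S = S, L = L, mu = mu, T_years = T_years,
       T_report = round(T_years / 1e5) * 1e5, bound = "upper")
}

#' Shortest-parental-branch SNP count
#'
#' Selects the smaller of the two parent-unique SNP counts from a
#' diagnostic class-count vector, the branch whose private substitutions
#' bound the hybridization time.
#'
#' @param counts named counts from \code{\link{class_counts}}.
#' @return integer count.
#' @export
shortest_branch_snps <- function(counts) {
  min(counts[["p1_unique"]], counts[["p2_unique"]])
}
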