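# Empirical conditional and conjunction false discovery rates.
#
# The estimator is the Andreassen-style ratio of empirical dominance
# counts on the bivariate p-value distribution:
#
#   cFDR_i = min(1, p1_i * #{j : p2_j <= p2_i} /
#                     #{j : p1_j <= p1_i and p2_j <= p2_i})
#
# Counts are inclusive (<=) and include the index SNP, so the denominator
# is always >= 1. The fast path is an O(N log N) sweep with a Fenwick
# (binary indexed) tree over compressed principal-p ranks; the O(N^2)
# brute-force oracle lives in the test suite.

# All three empirical counts for every point: c1 = #{p1_j <= p1_i},
# c2 = #{p2_j <= p2_i}, c12 = #{p1_j <= p1_i & p2_j <= p2_i}.
dominance_counts <- function(p1, p2) {
  n <- length(p1)
  c1 <- rank(p1, ties.method = "max")
  c2 <- rank(p2, ties.method = "max")
  key <- match(p1, sort(unique(p1)))   # dense rank of p1
  K <- max(key)
  tree <- integer(K)
  c12 <- integer(n)
  o <- order(p2)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && p2[o[j + 1L]] == p2[o[i]]) j <- j + 1L
    for (t in i:j) {                      # insert the tied-p2 group
      k <- key[o[t]]
      while (k <= K) {
        tree[k] <- tree[k] + 1L
        k <- k + bitwAnd(k, -k)
      }
    }
    for (t in i:j) {                      # then query its members
      k <- key[o[t]]
      s <- 0L
      while (k > 0L) {
        s <- s + tree[k]
        k <- k - bitwAnd(k, -k)
      }
      c12[o[t]] <- s
    }
    i <- j + 1L
  }
  list(c1 = as.integer(c1), c2 = as.integer(c2), c12 = c12)
}

#' Conditional FDR of a principal trait given a conditional trait
#'
#' @param p_principal Nominal p-values of the principal trait.
#' @param p_conditional Matching p-values of the conditional trait.
#' @return Per-SNP cFDR values, capped at 1. A single SNP returns its own
#'   principal p-value; empty input is an error.
#' @export
cfdr_values <- function(p_principal, p_conditional) {
  n <- length(p_principal)
  if (n == 0L) stop("empty input: cFDR undefined")
  stopifnot(length(p_conditional) == n,
            all(p_principal > 0 & p_principal <= 1),
            all(p_conditional > 0 & p_conditional <= 1))
  if (n == 1L) return(p_principal)
  cnt <- dominance_counts(p_principal, p_conditional)
  pmin(1, p_principal * cnt$c2 / cnt$c12)
}

#' Conjunction conditional FDR
#'
#' The probability that a SNP is wrongly declared associated with both
#' traits: the maximum of the two directional cFDRs, computed on the same
#' SNP set.
#'
#' @param cfdr_1g2 cFDR of trait 1 given trait 2.
#' @param cfdr_2g1 cFDR of trait 2 given trait 1.
#' @return Per-SNP ccFDR.
#' @export
ccfdr_values <- function(cfdr_1g2, cfdr_2g1) {
  if (length(cfdr_1g2) != length(cfdr_2g1)) {
    stop("directional cFDRs computed on mismatched SNP sets")
  }
  pmax(cfdr_1g2, cfdr_2g1)
}

#' Data-driven cFDR significance cutoff
#'
#' The cutoff is the maximum cFDR among SNPs whose principal-trait
#' p-value is genome-wide significant (p < `gw_alpha`); SNPs with cFDR
#' below the cutoff are declared significant.
#'
#' @param cfdr Per-SNP cFDR values.
#' @param p_principal Matching principal-trait p-values.
#' @param gw_alpha Genome-wide significance level (default 5e-8).
#' @return The cutoff (a single number).
#' @export
cfdr_threshold <- function(cfdr, p_principal, gw_alpha = 5e-8) {
  qual <- p_principal < gw_alpha
  if (!any(qual)) {
    stop("no SNP reaches p < ", gw_alpha, " in the principal trait; ",
         "the data-driven cutoff is undefined - supply a manual cutoff")
  }
  max(cfdr[qual])
}

#' Full conditional-FDR table for a harmonized pair
#'
#' Computes both directional cFDRs, the conjunction ccFDR, the
#' data-driven cutoffs and significance flags in one pass. The ccFDR
#' cutoff defaults to the maximum of the two directional cutoffs.
#'
#' @param pair A (typically LD-pruned) `harmonized_pair`.
#' @param gw_alpha Genome-wide significance level for the cutoffs.
#' @param ccfdr_cutoff Optional override for the conjunction cutoff.
#' @return A `cfdr_table` data.frame (snp_id, chrom, pos, p1, p2,
#'   cfdr_1g2, cfdr_2g1, ccfdr, sig_1g2, sig_2g1, sig_cc) with the
#'   cutoffs in attribute `cutoffs`.
#' @export
cfdr_table <- function(pair, gw_alpha = 5e-8, ccfdr_cutoff = NULL) {
  if (nrow(pair) == 0L) stop("empty input: cFDR undefined")
  cf12 <- cfdr_values(pair$p1, pair$p2)
  cf21 <- cfdr_values(pair$p2, pair$p1)
  cc <- ccfdr_values(cf12, cf21)
  cut12 <- tryCatch(cfdr_threshold(cf12, pair$p1, gw_alpha),
                    error = function(e) NA_real_)
  cut21 <- tryCatch(cfdr_threshold(cf21, pair$p2, gw_alpha),
                    error = function(e) NA_real_)
  cutcc <- ccfdr_cutoff %||%
    (if (all(is.na(c(cut12, cut21)))) NA_real_ else max(cut12, cut21, na.rm = TRUE))
  out <- data.frame(
    snp_id = pair$snp_id, chrom = pair$chrom, pos = pair$pos,
    p1 = pair$p1, p2 = pair$p2,
    cfdr_1g2 = cf12, cfdr_2g1 = cf21, ccfdr = cc,
    sig_1g2 = !is.na(cut12) & cf12 < cut12,
    sig_2g1 = !is.na(cut21) & cf21 < cut21,
    sig_cc = !is.na(cutcc) & cc < cutcc,
    stringsAsFactors = FALSE
  )
  attr(out, "cutoffs") <- list(cfdr_1g2 = cut12, cfdr_2g1 = cut21,
                               ccfdr = cutcc, gw_alpha = gw_alpha)
  class(out) <- c("cfdr_table", "data.frame")
  out
}
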