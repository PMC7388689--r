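# Pleiotropic-enrichment diagnostics: stratified QQ curves, fold
# enrichment, and conjunction Manhattan plot data.

#' Stratified QQ curves
#'
#' For each conditional-trait p-value cutoff t, the SNP subset with
#' p_conditional <= t yields the curve of empirical CDF position against
#' -log10 principal p, sorted ascending in the principal p-value. Leftward
#' deflection of stricter strata from the t = 1 baseline indicates
#' pleiotropic enrichment.
#'
#' @param pair A `harmonized_pair`.
#' @param principal 1 or 2: which trait is principal.
#' @param cutoffs Conditional p-value cutoffs (1 is the all-SNP baseline).
#' @return data.frame with columns `cutoff`, `q` (empirical CDF position)
#'   and `neglog10_p`; empty strata are skipped with a warning.
#' @export
stratified_qq <- function(pair, principal = 1,
                          cutoffs = c(1, 0.1, 0.01, 0.001, 0.0001)) {
  pp <- if (principal == 1) pair$p1 else pair$p2
  pc <- if (principal == 1) pair$p2 else pair$p1
  out <- lapply(cutoffs, function(t) {
    sel <- pc <= t
    k <- sum(sel)
    if (k == 0L) {
      warning("empty stratum at conditional cutoff ", t, " skipped",
              call. = FALSE)
      return(NULL)
    }
    p_sorted <- sort(pp[sel])
    data.frame(cutoff = t, q = seq_len(k) / k,
               neglog10_p = -log10(p_sorted))
  })
  do.call(rbind, out)
}

#' Fold-enrichment curves
#'
#' enrichment(t, x) compares the proportion of the conditional stratum
#' (p_conditional <= t) reaching principal p <= 10^-x with the same
#' proportion among all SNPs; the t = 1 baseline is identically 1. Grid
#' points with a zero denominator are omitted.
#'
#' @inheritParams stratified_qq
#' @param x_grid Grid of -log10 principal p values.
#' @return data.frame with columns `cutoff`, `x` and `enrichment`.
#' @export
fold_enrichment <- function(pair, principal = 1,
                            cutoffs = c(1, 0.1, 0.01, 0.001, 0.0001),
                            x_grid = seq(0, 8, by = 0.25)) {
  pp <- if (principal == 1) pair$p1 else pair$p2
  pc <- if (principal == 1) pair$p2 else pair$p1
  n <- length(pp)
  out <- lapply(cutoffs, function(t) {
    sel <- pc <= t
    k <- sum(sel)
    if (k == 0L) return(NULL)
    rows <- lapply(x_grid, function(x) {
      thr <- 10^(-x)
      num_all <- sum(pp <= thr)
      if (num_all == 0L) return(NULL)
      data.frame(cutoff = t, x = x,
                 enrichment = (sum(pp[sel] <= thr) / k) / (num_all / n))
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

#' Conjunction Manhattan plot data
#'
#' Transforms a cFDR table into plot-ready coordinates: -log10 ccFDR
#' against cumulative genomic position (per-chromosome offsets), with the
#' significance line at -log10 of the ccFDR cutoff.
#'
#' @param t A `cfdr_table`.
#' @return data.frame (snp_id, chrom, pos, x, neglog10_ccfdr, sig_cc) with
#'   attributes `threshold_line` (-log10 cutoff) and `chrom_centres` for
#'   axis labelling.
#' @export
conjunction_manhattan_data <- function(t) {
  chroms <- unique(t$chrom[order(suppressWarnings(as.numeric(t$chrom)),
                                 t$chrom)])
  offset <- 0
  offsets <- stats::setNames(numeric(length(chroms)), chroms)
  for (ch in chroms) {
    offsets[ch] <- offset
    offset <- offset + max(t$pos[t$chrom == ch]) + 1
  }
  out <- data.frame(
    snp_id = t$snp_id, chrom = t$chrom, pos = t$pos,
    x = t$pos + offsets[t$chrom],
    neglog10_ccfdr = -log10(t$ccfdr),
    sig_cc = t$sig_cc,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$x), , drop = FALSE]
  rownames(out) <- NULL
  cutoffs <- attr(t, "cutoffs")
  attr(out, "threshold_line") <-
    if (!is.null(cutoffs) && !is.na(cutoffs$ccfdr)) -log10(cutoffs$ccfdr)
    else NA_real_
  centres <- vapply(chroms, function(ch) {
    mean(range(out$x[out$chrom == ch]))
  }, 0)
  attr(out, "chrom_centres") <- stats::setNames(centres, chroms)
  out
}
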