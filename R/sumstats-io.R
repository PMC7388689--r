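# Reading, validating and harmonizing GWAS summary-statistics tables.
#
# A summary-statistics table is a plain data.frame (class "summary_stats")
# with one row per SNP and the columns snp_id, chrom, pos, a1 (effect
# allele), a2 (other allele), beta, se, pvalue, n, freq.

SUMSTATS_COLS <- c("snp_id", "chrom", "pos", "a1", "a2",
                   "beta", "se", "pvalue", "n", "freq")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Validate a summary-statistics table
#'
#' Checks the per-SNP invariants (se > 0, p in (0, 1], finite beta/se,
#' unique SNP ids, a1 != a2, freq in (0, 1)) and drops violating rows with
#' a warning. P-values of exactly zero are clamped to the smallest positive
#' normalized double rather than dropped, so extreme GWAS hits survive.
#'
#' @param x data.frame with the ten standard columns.
#' @return A validated `summary_stats` data.frame.
#' @export
as_sumstats <- function(x) {
  missing <- setdiff(SUMSTATS_COLS, names(x))
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  }
  x <- as.data.frame(x)[SUMSTATS_COLS]
  x$snp_id <- as.character(x$snp_id)
  x$chrom <- as.character(x$chrom)
  x$a1 <- toupper(as.character(x$a1))
  x$a2 <- toupper(as.character(x$a2))
  for (col in c("pos", "beta", "se", "pvalue", "n", "freq")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }

  zero_p <- !is.na(x$pvalue) & x$pvalue == 0
  if (any(zero_p)) {
    x$pvalue[zero_p] <- .Machine$double.xmin
    warning(sum(zero_p), " p-value(s) of exactly 0 clamped to ",
            format(.Machine$double.xmin), call. = FALSE)
  }

  ok <- !is.na(x$snp_id) & !is.na(x$pos) &
    is.finite(x$beta) & is.finite(x$se) & x$se > 0 &
    is.finite(x$pvalue) & x$pvalue > 0 & x$pvalue <= 1 &
    is.finite(x$n) & x$n > 0 &
    is.finite(x$freq) & x$freq > 0 & x$freq < 1 &
    x$a1 != x$a2 & !duplicated(x$snp_id)
  ok[is.na(ok)] <- FALSE
  if (any(!ok)) {
    warning(sum(!ok), " row(s) violating summary-statistics invariants dropped",
            call. = FALSE)
    x <- x[ok, , drop = FALSE]
  }
  rownames(x) <- NULL
  class(x) <- c("summary_stats", "data.frame")
  x
}

#' Read a GWAS summary-statistics TSV
#'
#' @param path Path to a tab-separated file with a header line.
#' @param column_map Named character vector mapping the standard names
#'   (`snp_id`, `chrom`, `pos`, `a1`, `a2`, `beta`, `se`, `pvalue`, `n`,
#'   `freq`) to the column names used in the file. Standard names absent
#'   from the map are looked up verbatim.
#' @return A validated `summary_stats` data.frame (invalid rows dropped
#'   with a warning; a missing mandatory column is an error).
#' @export
read_sumstats <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  for (std in SUMSTATS_COLS) {
    src <- if (!is.null(column_map) && std %in% names(column_map)) {
      column_map[[std]]
    } else std
    if (!src %in% names(raw)) {
      stop("mandatory column '", std, "' (file column '", src,
           "') not found in ", path)
    }
    raw[[std]] <- raw[[src]]
  }
  as_sumstats(raw)
}

#' Write a tabular result to TSV
#'
#' Plain tab-separated output with a header; round-trips through
#' [read_sumstats()] / `read.table()`.
#'
#' @param t Nonempty data.frame.
#' @param path Output path.
#' @export
write_table <- function(t, path) {
  if (is.null(t) || nrow(t) == 0L) stop("refusing to write an empty table")
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize two summary-statistics tables
#'
#' Inner join on SNP id, with trait-2 alleles aligned to trait 1. If the
#' trait-2 alleles are swapped relative to trait 1 (directly or on the
#' complementary strand), beta2 is negated and freq2 reflected; strand
#' flips with matching orientation are accepted as-is. Palindromic (A/T,
#' C/G) SNPs, whose orientation is unresolvable from alleles alone, are
#' removed. Irreconcilable allele pairs are dropped and counted.
#'
#' @param s1,s2 Validated `summary_stats` tables.
#' @return A `harmonized_pair` data.frame with columns snp_id, chrom, pos,
#'   a1, a2, beta1/se1/p1/n1/freq1, beta2/se2/p2/n2/freq2, maf (minor-allele
#'   frequency from trait-1 freq) and a logical `flipped` audit column.
#'   Attribute `audit` holds the palindromic / flipped / mismatch counts.
#' @export
harmonize <- function(s1, s2) {
  s1 <- as_sumstats(s1)
  s2 <- as_sumstats(s2)

  pal1 <- is_palindromic(s1$a1, s1$a2)
  pal2 <- is_palindromic(s2$a1, s2$a2)
  n_pal <- length(unique(c(s1$snp_id[pal1], s2$snp_id[pal2])))
  s1 <- s1[!pal1, , drop = FALSE]
  s2 <- s2[!pal2, , drop = FALSE]

  idx2 <- match(s1$snp_id, s2$snp_id)
  keep <- !is.na(idx2)
  s1 <- s1[keep, , drop = FALSE]
  s2 <- s2[idx2[keep], , drop = FALSE]

  c1 <- unname(COMPLEMENT[s2$a1])
  c2 <- unname(COMPLEMENT[s2$a2])
  same    <- s2$a1 == s1$a1 & s2$a2 == s1$a2
  swapped <- s2$a1 == s1$a2 & s2$a2 == s1$a1
  strand_same    <- !same & !swapped & c1 == s1$a1 & c2 == s1$a2
  strand_swapped <- !same & !swapped & c1 == s1$a2 & c2 == s1$a1
  flip <- swapped | strand_swapped
  ok <- same | swapped | strand_same | strand_swapped
  n_mismatch <- sum(!ok)

  s1 <- s1[ok, , drop = FALSE]
  s2 <- s2[ok, , drop = FALSE]
  flip <- flip[ok]
  beta2 <- ifelse(flip, -s2$beta, s2$beta)
  freq2 <- ifelse(flip, 1 - s2$freq, s2$freq)

  out <- data.frame(
    snp_id = s1$snp_id, chrom = s1$chrom, pos = s1$pos,
    a1 = s1$a1, a2 = s1$a2,
    beta1 = s1$beta, se1 = s1$se, p1 = s1$pvalue, n1 = s1$n, freq1 = s1$freq,
    beta2 = beta2, se2 = s2$se, p2 = s2$pvalue, n2 = s2$n, freq2 = freq2,
    maf = pmin(s1$freq, 1 - s1$freq),
    flipped = flip,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- list(n_palindromic = n_pal,
                             n_flipped = sum(flip),
                             n_mismatch = n_mismatch)
  class(out) <- c("harmonized_pair", "data.frame")
  out
}

# Split a harmonized pair back into its two single-trait tables (used by
# idempotence checks and by stages that want per-trait input again).
#' @rdname harmonize
#' @param pair A `harmonized_pair`.
#' @export
pair_to_sumstats <- function(pair) {
  s1 <- data.frame(snp_id = pair$snp_id, chrom = pair$chrom, pos = pair$pos,
                   a1 = pair$a1, a2 = pair$a2, beta = pair$beta1,
                   se = pair$se1, pvalue = pair$p1, n = pair$n1,
                   freq = pair$freq1, stringsAsFactors = FALSE)
  s2 <- s1
  s2$beta <- pair$beta2
  s2$se <- pair$se2
  s2$pvalue <- pair$p2
  s2$n <- pair$n2
  s2$freq <- pair$freq2
  list(trait1 = as_sumstats(s1), trait2 = as_sumstats(s2))
}
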