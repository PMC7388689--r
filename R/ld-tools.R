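# Reference-panel LD: pairwise r^2, windowed pruning, LD scores, and
# genome block partitions.

#' Pairwise squared correlation between two panel SNPs
#'
#' Squared Pearson correlation of the dosage (here haplotype allele)
#' vectors. A monomorphic SNP has undefined correlation and is reported
#' as 0 with a warning.
#'
#' @param panel A `genotype_panel`.
#' @param i,j SNP column indices.
#' @return r^2 in \[0, 1\].
#' @export
r2 <- function(panel, i, j) {
  m <- ncol(panel$haplotypes)
  if (i < 1 || i > m || j < 1 || j > m) stop("SNP index out of range")
  x <- panel$haplotypes[, i]
  y <- panel$haplotypes[, j]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("monomorphic SNP; r^2 reported as 0", call. = FALSE)
    return(0)
  }
  stats::cor(x, y)^2
}

# Greedy windowed pruning of a set of SNP indices (rows of `meta`, which
# carries chrom, pos, maf and the matching panel column). Mirrors the
# PLINK indep-pairwise scan: windows of `window` SNPs advanced by `step`,
# the lower-MAF member of each r^2 > r2_max pair removed, repeated to a
# fixed point. Ties on MAF remove the later SNP in position order.
prune_core <- function(meta, panel, window, step, r2_max) {
  keep <- rep(TRUE, nrow(meta))
  for (ch in unique(meta$chrom)) {
    rows <- which(meta$chrom == ch)
    rows <- rows[order(meta$pos[rows])]
    repeat {
      active <- rows[keep[rows]]
      n <- length(active)
      if (n < 2L) break
      changed <- FALSE
      starts <- unique(c(seq(1L, max(1L, n - 1L), by = step)))
      for (s in starts) {
        e <- min(s + window - 1L, n)
        if (e <= s) next
        win <- active[s:e]
        win <- win[keep[win]]
        if (length(win) < 2L) next
        R2 <- suppressWarnings(stats::cor(panel$haplotypes[, meta$col[win],
                                                           drop = FALSE]))^2
        R2[!is.finite(R2)] <- 0
        for (a in seq_len(length(win) - 1L)) {
          if (!keep[win[a]]) next
          for (b in (a + 1L):length(win)) {
            if (!keep[win[b]]) next
            if (R2[a, b] > r2_max) {
              drop <- if (meta$maf[win[a]] < meta$maf[win[b]]) win[a]
                      else if (meta$maf[win[b]] < meta$maf[win[a]]) win[b]
                      else win[b]  # MAF tie: later in position order
              keep[drop] <- FALSE
              changed <- TRUE
              if (drop == win[a]) break
            }
          }
        }
      }
      if (!changed) break
    }
  }
  keep
}

#' LD-prune a harmonized SNP table against a reference panel
#'
#' Within each sliding window of `window` SNPs (advanced by `step`), every
#' remaining pair with r^2 > `r2_max` loses its lower-MAF member; the scan
#' repeats until no within-window pair exceeds the threshold. Defaults are
#' the PLINK 1.9 indep-pairwise defaults (50, 5, 0.2). SNPs absent from
#' the panel pass through untouched with a warning.
#'
#' @param pair A `harmonized_pair` (sorted by chromosome and position).
#' @param panel A `genotype_panel` covering the SNPs.
#' @param window Window size in SNPs.
#' @param step Window shift in SNPs.
#' @param r2_max Pruning threshold on r^2.
#' @return The pruned `harmonized_pair`; attribute `pruned_out` lists the
#'   removed SNP ids.
#' @export
ld_prune <- function(pair, panel, window = 50, step = 5, r2_max = 0.2) {
  if (nrow(pair) == 0L) return(pair)
  col <- match(pair$snp_id, panel$snps$id)
  uncovered <- is.na(col)
  if (any(uncovered)) {
    warning(sum(uncovered), " SNP(s) not covered by the panel pass through",
            call. = FALSE)
  }
  meta <- data.frame(chrom = pair$chrom, pos = pair$pos,
                     maf = panel$snps$maf[col], col = col,
                     stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(pair))
  idx <- which(!uncovered)
  if (length(idx) >= 2L) {
    keep[idx] <- prune_core(meta[idx, , drop = FALSE], panel,
                            window, step, r2_max)
  }
  out <- pair[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- attr(pair, "audit")
  attr(out, "pruned_out") <- pair$snp_id[!keep]
  class(out) <- class(pair)
  out
}

#' Per-SNP LD scores from a reference panel
#'
#' The LD score of SNP j is the sum of adjusted squared correlations
#' r^2_adj = r^2 - (1 - r^2) / (n - 2) with every panel SNP within
#' `window_bp` on the same chromosome, including itself. The adjustment
#' removes the finite-panel upward bias of r^2 so independent SNPs
#' contribute zero on average.
#'
#' @param panel A `genotype_panel` sorted by position within chromosome.
#' @param window_bp Window half-width in base pairs.
#' @return data.frame with columns `id` and `ell`.
#' @export
ld_scores <- function(panel, window_bp = 1e6) {
  n <- nrow(panel$haplotypes)
  if (n < 3L) stop("need at least 3 haplotypes for adjusted r^2")
  s <- panel$snps
  m <- nrow(s)
  X <- scale(panel$haplotypes)
  X[!is.finite(X)] <- 0
  ell <- numeric(m)
  for (ch in unique(s$chrom)) {
    rows <- which(s$chrom == ch)
    pos <- s$pos[rows]
    chunk <- 512L
    for (a in seq(1L, length(rows), by = chunk)) {
      b <- min(a + chunk - 1L, length(rows))
      lo <- findInterval(pos[a] - window_bp - 0.5, pos) + 1L
      hi <- findInterval(pos[b] + window_bp, pos)
      Rm <- crossprod(X[, rows[a:b], drop = FALSE],
                      X[, rows[lo:hi], drop = FALSE]) / (n - 1)
      R2 <- Rm^2
      R2adj <- R2 - (1 - R2) / (n - 2)
      # mask pairs outside the bp window
      pj <- pos[a:b]
      pk <- pos[lo:hi]
      mask <- abs(outer(pj, pk, "-")) <= window_bp
      ell[rows[a:b]] <- rowSums(R2adj * mask)
    }
  }
  data.frame(id = s$id, ell = ell, stringsAsFactors = FALSE)
}

#' Validate a genome block partition
#'
#' @param blocks data.frame with `chrom`, `start`, `end`; 1-based half-open
#'   intervals, sorted and disjoint within chromosome.
#' @return The validated `block_partition`.
#' @export
validate_blocks <- function(blocks) {
  stopifnot(all(c("chrom", "start", "end") %in% names(blocks)),
            all(blocks$end > blocks$start))
  for (d in split(blocks, blocks$chrom)) {
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L && any(d$start[-1] < d$end[-nrow(d)])) {
      stop("block intervals overlap within a chromosome")
    }
  }
  blocks <- blocks[order(blocks$chrom, blocks$start), , drop = FALSE]
  rownames(blocks) <- NULL
  class(blocks) <- c("block_partition", "data.frame")
  blocks
}

#' Assign harmonized SNPs to partition blocks
#'
#' A SNP at position p belongs to the block with start <= p < end on its
#' chromosome; SNPs falling outside every interval get NA with a warning.
#'
#' @param pair A `harmonized_pair` (or any frame with chrom and pos).
#' @param blocks A `block_partition`.
#' @return Integer vector of row indices into `blocks` (NA if unassigned).
#' @export
assign_blocks <- function(pair, blocks) {
  blocks <- validate_blocks(blocks)
  out <- rep(NA_integer_, nrow(pair))
  for (ch in unique(pair$chrom)) {
    rows <- which(pair$chrom == ch)
    b <- which(blocks$chrom == ch)
    if (length(b) == 0L) next
    k <- findInterval(pair$pos[rows], blocks$start[b])
    hit <- k >= 1L & pair$pos[rows] < blocks$end[b][pmax(k, 1L)]
    out[rows[hit]] <- b[k[hit]]
  }
  if (anyNA(out)) {
    warning(sum(is.na(out)), " SNP(s) fall outside the block partition",
            call. = FALSE)
  }
  out
}

#' Read / write a block partition as 3-column BED
#'
#' BED uses 0-based half-open intervals; on read they are converted to the
#' internal 1-based half-open convention (start + 1, end + 1) and the
#' conversion is noted.
#'
#' @param path BED file path.
#' @return A `block_partition`.
#' @export
read_blocks_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(bed)[1:3] <- c("chrom", "start", "end")
  bed$chrom <- sub("^chr", "", as.character(bed$chrom))
  message("BED 0-based starts converted to 1-based half-open intervals")
  validate_blocks(data.frame(chrom = bed$chrom, start = bed$start + 1,
                             end = bed$end + 1, stringsAsFactors = FALSE))
}

#' @rdname read_blocks_bed
#' @param blocks A `block_partition`.
#' @export
write_blocks_bed <- function(blocks, path) {
  blocks <- validate_blocks(blocks)
  utils::write.table(
    data.frame(chrom = blocks$chrom, start = blocks$start - 1,
               end = blocks$end - 1),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a genotype panel as a minimal phased VCF
#'
#' Haplotypes are paired into diploid samples with phased GT fields
#' (an odd trailing haplotype is dropped with a warning).
#'
#' @param panel A `genotype_panel`.
#' @param path Output path (plain-text `.vcf`).
#' @export
write_panel_vcf <- function(panel, path) {
  hap <- panel$haplotypes
  n_hap <- nrow(hap)
  if (n_hap %% 2L == 1L) {
    warning("odd haplotype dropped when pairing into diploid samples",
            call. = FALSE)
    hap <- hap[-n_hap, , drop = FALSE]
  }
  n_ind <- nrow(hap) / 2L
  s <- panel$snps
  gt <- matrix("", n_ind, ncol(hap))
  odd <- seq(1L, nrow(hap), by = 2L)
  gt[] <- paste0(hap[odd, , drop = FALSE], "|", hap[odd + 1L, , drop = FALSE])
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=pleiopipe_synthetic_panel",
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele Frequency">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("SAMPLE%04d", seq_len(n_ind))), collapse = "\t")
  )
  info <- sprintf("AF=%.17g", s$maf)  # population ALT frequency, full precision
  body <- paste(s$chrom, s$pos, s$id, s$a2, s$a1, ".", "PASS", info, "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a reference panel from VCF
#'
#' Loads GT fields (phased or unphased) via vcfR and splits diploid
#' genotypes into haplotypes. ALT is taken as the effect allele; MAF is
#' read from the INFO AF field when present (folded), falling back to
#' the folded empirical ALT frequency.
#'
#' @param path VCF path (.vcf or .vcf.gz).
#' @return A `genotype_panel`.
#' @export
read_panel_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- gsub("[|/]", "", gt)
  a1 <- as.integer(substr(alleles, 1, 1))
  a2 <- as.integer(substr(alleles, 2, 2))
  m <- nrow(gt)
  n_ind <- ncol(gt)
  hap <- matrix(0L, 2L * n_ind, m)
  hap[seq(1L, 2L * n_ind, by = 2L), ] <- t(matrix(a1, m, n_ind))
  hap[seq(2L, 2L * n_ind, by = 2L), ] <- t(matrix(a2, m, n_ind))
  freq <- colMeans(hap)
  af <- suppressWarnings(as.numeric(vcfR::extract.info(v, element = "AF")))
  if (length(af) == m && all(is.finite(af))) freq <- af
  snps <- data.frame(
    id = fix[, "ID"], chrom = as.character(fix[, "CHROM"]),
    pos = as.numeric(fix[, "POS"]),
    a1 = fix[, "ALT"], a2 = fix[, "REF"],
    maf = pmin(freq, 1 - freq),
    stringsAsFactors = FALSE
  )
  rownames(snps) <- NULL
  structure(list(snps = snps, haplotypes = hap), class = "genotype_panel")
}
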