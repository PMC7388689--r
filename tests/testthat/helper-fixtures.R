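# Shared fixture builders: tiny in-code tables and panels.

# minimal well-formed summary-statistics data.frame
toy_sumstats <- function(n = 5, seed = 1) {
  set.seed(seed)
  data.frame(
    snp_id = paste0("rs", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 1000,
    a1 = rep(c("A", "C", "G", "T"), length.out = n),
    a2 = rep(c("G", "T", "A", "C"), length.out = n),
    beta = rnorm(n, 0, 0.05),
    se = runif(n, 0.01, 0.05),
    pvalue = runif(n),
    n = 10000,
    freq = runif(n, 0.1, 0.9),
    stringsAsFactors = FALSE
  )
}

# genotype panel built directly from a haplotype matrix
panel_from_haps <- function(hap, chrom = "1", pos = NULL, ids = NULL,
                            maf = NULL) {
  m <- ncol(hap)
  freq <- colMeans(hap)
  structure(list(
    snps = data.frame(
      id = ids %||% paste0("rs", seq_len(m)),
      chrom = rep(chrom, length.out = m),
      pos = pos %||% (seq_len(m) * 1000),
      a1 = rep("A", m), a2 = rep("G", m),
      maf = maf %||% pmin(freq, 1 - freq),
      block = 1L,
      stringsAsFactors = FALSE
    ),
    haplotypes = hap
  ), class = "genotype_panel")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# O(N^2) brute-force dominance-count cFDR oracle
cfdr_oracle <- function(p1, p2) {
  n <- length(p1)
  out <- numeric(n)
  for (i in seq_len(n)) {
    c2 <- sum(p2 <= p2[i])
    c12 <- sum(p1 <= p1[i] & p2 <= p2[i])
    out[i] <- min(1, p1[i] * c2 / c12)
  }
  out
}

# brute-force double-loop regional Bayes factors on the natural scale
rbf_oracle <- function(abf1, abf2) {
  k <- length(abf1)
  rbf4 <- 0
  if (k >= 2) {
    for (i in seq_len(k)) {
      for (j in seq_len(k)) {
        if (i != j) rbf4 <- rbf4 + abf1[i] * abf2[j]
      }
    }
    rbf4 <- rbf4 / (k * (k - 1))
  } else {
    rbf4 <- NA_real_
  }
  c(mean(abf1), mean(abf2), mean(abf1 * abf2), rbf4)
}

# harmonized_pair straight from two aligned p-value vectors
pair_from_p <- function(p1, p2, chrom = "1", pos = NULL) {
  n <- length(p1)
  out <- data.frame(
    snp_id = paste0("rs", seq_len(n)), chrom = rep(chrom, length.out = n),
    pos = pos %||% (seq_len(n) * 1000),
    a1 = "A", a2 = "G",
    beta1 = stats::qnorm(p1 / 2, lower.tail = FALSE) * 0.01, se1 = 0.01,
    p1 = p1, n1 = 1e4, freq1 = 0.3,
    beta2 = stats::qnorm(p2 / 2, lower.tail = FALSE) * 0.01, se2 = 0.01,
    p2 = p2, n2 = 1e4, freq2 = 0.3,
    maf = 0.3, flipped = FALSE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized_pair", "data.frame")
  out
}
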