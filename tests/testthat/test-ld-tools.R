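test_that("pairwise r2 matches hand correlations and handles edge cases", {
  hap <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1), c(0, 0, 1, 1), c(0, 0, 0, 0))
  panel <- panel_from_haps(hap)
  expect_equal(r2(panel, 1, 1), 1.0)
  expect_equal(r2(panel, 1, 3), 1.0)   # duplicated column
  expect_equal(r2(panel, 1, 2), 0.0)   # hand-computed orthogonal vectors
  expect_warning(expect_equal(r2(panel, 1, 4), 0), "monomorphic")
  expect_error(r2(panel, 1, 9), "out of range")
})

test_that("pruning removes the lower-MAF member of a violating pair", {
  set.seed(21)
  x <- rbinom(200, 1, 0.3)
  hap <- cbind(x, ifelse(runif(200) < 0.95, x, 1 - x))  # r2 >> 0.2
  panel <- panel_from_haps(hap, maf = c(0.3, 0.2))
  pair <- pair_from_p(c(0.5, 0.5), c(0.5, 0.5))
  pruned <- ld_prune(pair, panel)
  expect_equal(pruned$snp_id, "rs1")  # MAF 0.2 member removed
  expect_equal(attr(pruned, "pruned_out"), "rs2")
})

test_that("pruning is the identity when no pair exceeds the threshold", {
  cfg <- sim_config(m_snps = 100, n_panel = 400, rho_ld = 0, seed = 22)
  panel <- simulate_panel(cfg)
  truth <- simulate_effects(cfg, panel)
  ss <- simulate_sumstats(truth, panel, cfg)
  pair <- harmonize(ss$trait1, ss$trait2)
  pruned <- ld_prune(pair, panel, r2_max = 1)
  expect_equal(pruned$snp_id, pair$snp_id)  # r2_max = 1 removes nothing
})

test_that("after pruning no retained within-window pair exceeds r2_max", {
  cfg <- sim_config(m_snps = 200, n_panel = 200, rho_ld = 0.9,
                    block_sizes = 200, n_chrom = 1, seed = 23)
  panel <- simulate_panel(cfg)
  truth <- simulate_effects(cfg, panel)
  ss <- simulate_sumstats(truth, panel, cfg)
  pair <- harmonize(ss$trait1, ss$trait2)
  pruned <- ld_prune(pair, panel, window = 50, step = 5, r2_max = 0.2)
  expect_lt(nrow(pruned), nrow(pair))

  cols <- match(pruned$snp_id, panel$snps$id)
  n_kept <- length(cols)
  for (s in seq(1, max(1, n_kept - 1), by = 5)) {
    win <- cols[s:min(s + 49, n_kept)]
    R2 <- suppressWarnings(cor(panel$haplotypes[, win]))^2
    diag(R2) <- 0
    expect_lte(max(R2), 0.2)
  }

  # fixed point: re-pruning changes nothing
  again <- ld_prune(pruned, panel, window = 50, step = 5, r2_max = 0.2)
  expect_equal(again$snp_id, pruned$snp_id)
})

test_that("SNPs missing from the panel pass through with a warning", {
  set.seed(24)
  hap <- matrix(rbinom(400, 1, 0.4), 100, 4)
  panel <- panel_from_haps(hap)
  pair <- pair_from_p(runif(6), runif(6))  # rs5, rs6 uncovered
  expect_warning(pruned <- ld_prune(pair, panel), "not covered")
  expect_true(all(c("rs5", "rs6") %in% pruned$snp_id))
})

test_that("LD scores: independent SNPs give ell near 1, triplicates near 3", {
  cfg <- sim_config(m_snps = 300, n_panel = 1000, rho_ld = 0, seed = 25)
  panel <- simulate_panel(cfg)
  ell <- ld_scores(panel)
  expect_equal(mean(ell$ell), 1, tolerance = 0.1)

  set.seed(26)
  x <- rbinom(500, 1, 0.3)
  y <- rbinom(500, 1, 0.4)
  panel3 <- panel_from_haps(cbind(x, x, x, y), pos = c(1e3, 2e3, 3e3, 5e6))
  ell3 <- ld_scores(panel3)
  expect_equal(ell3$ell[1:3], rep(3, 3), tolerance = 1e-8)
  expect_equal(ell3$ell[4], 1, tolerance = 1e-8)  # outside the bp window

  # the diagonal term alone gives exactly 1 in the perfect-LD construction
  expect_true(all(ell3$ell >= 1 - 1e-8))
  expect_error(ld_scores(panel_from_haps(matrix(c(0, 1), 2, 1))), "haplotypes")
})

test_that("block assignment respects half-open interval boundaries", {
  blocks <- validate_blocks(data.frame(chrom = "1", start = c(1, 100),
                                       end = c(100, 200)))
  pair <- pair_from_p(rep(0.5, 4), rep(0.5, 4), pos = c(1, 99, 100, 150))
  idx <- assign_blocks(pair, blocks)
  expect_equal(idx, c(1L, 1L, 2L, 2L))  # pos = end goes to the next block

  # total on covered SNPs, NA + warning outside
  pair2 <- pair_from_p(rep(0.5, 2), rep(0.5, 2), pos = c(50, 250))
  expect_warning(idx2 <- assign_blocks(pair2, blocks), "outside")
  expect_equal(idx2, c(1L, NA))
})

test_that("BED round trip converts between 0-based and 1-based half-open", {
  blocks <- validate_blocks(data.frame(chrom = c("1", "1", "2"),
                                       start = c(1, 501, 1),
                                       end = c(501, 1001, 301)))
  path <- withr::local_tempfile(fileext = ".bed")
  write_blocks_bed(blocks, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2[1], 0)  # 0-based start on disk
  expect_message(back <- read_blocks_bed(path), "1-based")
  expect_equal(back$start, blocks$start)
  expect_equal(back$end, blocks$end)
})

test_that("overlapping block partitions are rejected", {
  expect_error(validate_blocks(data.frame(chrom = "1", start = c(1, 50),
                                          end = c(100, 150))), "overlap")
  expect_error(validate_blocks(data.frame(chrom = "1", start = 10, end = 10)))
})
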