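test_that("config validation enforces the simplex and bounds", {
  expect_error(sim_config(pi0 = 0.5, pi1 = 0.5, pi2 = 0.1, pi3 = 0),
               "sum to 1")
  expect_error(sim_config(rho_ld = 1))
  expect_silent(sim_config(m_snps = 100))
})

test_that("panel generation is seed-deterministic with block-structured LD", {
  cfg <- sim_config(m_snps = 500, n_panel = 200, rho_ld = 0.8,
                    block_sizes = 50, n_chrom = 2, seed = 11)
  p1 <- simulate_panel(cfg)
  p2 <- simulate_panel(cfg)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$snps, p2$snps)

  # adjacent within-block r^2 well above cross-block r^2
  same_block <- with(p1$snps, block[-1] == block[-length(block)])
  adj_r2 <- vapply(which(same_block), function(j) r2(p1, j, j + 1), 0)
  cross <- replicate(200, {
    b <- sample(unique(p1$snps$block), 2)
    i <- sample(which(p1$snps$block == b[1]), 1)
    j <- sample(which(p1$snps$block == b[2]), 1)
    r2(p1, i, j)
  })
  expect_gt(mean(adj_r2), 10 * mean(cross))

  # positions nondecreasing within chromosome, maf in (0, 0.5]
  for (ch in unique(p1$snps$chrom)) {
    expect_true(!is.unsorted(p1$snps$pos[p1$snps$chrom == ch]))
  }
  emp <- pmin(colMeans(p1$haplotypes), 1 - colMeans(p1$haplotypes))
  expect_true(all(emp > 0))
})

test_that("rho_ld = 0 gives near-independent adjacent SNPs", {
  cfg <- sim_config(m_snps = 400, n_panel = 200, rho_ld = 0,
                    block_sizes = 50, seed = 3)
  reps <- lapply(1:10, function(k) {
    cfgk <- cfg; cfgk$seed <- 100 + k
    p <- simulate_panel(cfgk)
    same_block <- with(p$snps, block[-1] == block[-length(block)])
    mean(vapply(which(same_block), function(j) r2(p, j, j + 1), 0))
  })
  # E[r^2] under independence is about 1/(n_panel - 1)
  expect_equal(mean(unlist(reps)), 1 / 199, tolerance = 0.3)
})

test_that("effect mixture hits its proportions, heritability and rg", {
  cfg <- sim_config(m_snps = 10000, n_panel = 100, pi0 = 0.5, pi1 = 0.15,
                    pi2 = 0.2, pi3 = 0.15, rg_shared = 1, h2_1 = 0.3,
                    h2_2 = 0.4, seed = 5)
  panel <- simulate_panel(cfg)
  truth <- simulate_effects(cfg, panel)
  prop <- as.numeric(table(factor(truth$snps$component, 0:3))) / cfg$m_snps
  expect_equal(prop, cfg$pi, tolerance = 3 * sqrt(0.25 / cfg$m_snps) / min(cfg$pi))

  w <- 2 * panel$snps$maf * (1 - panel$snps$maf)
  expect_equal(sum(w * truth$snps$beta1^2), 0.3, tolerance = 1e-10)
  expect_equal(sum(w * truth$snps$beta2^2), 0.4, tolerance = 1e-10)

  shared <- truth$snps$component == 3
  expect_gt(cor(truth$snps$beta1[shared], truth$snps$beta2[shared]), 0.99)

  # null SNPs have exactly zero effects
  expect_true(all(truth$snps$beta1[truth$snps$component %in% c(0, 2)] == 0))
  expect_true(all(truth$snps$beta2[truth$snps$component %in% c(0, 1)] == 0))
})

test_that("pure-null config labels every region model 0 with zero betas", {
  cfg <- sim_config(m_snps = 300, n_panel = 100, pi0 = 1, pi1 = 0, pi2 = 0,
                    pi3 = 0, h2_1 = 0, h2_2 = 0, seed = 6)
  panel <- simulate_panel(cfg)
  truth <- simulate_effects(cfg, panel)
  expect_true(all(truth$snps$beta1 == 0))
  expect_true(all(truth$regions$model == 0))
})

test_that("region labels follow the five-hypothesis rule", {
  cfg <- sim_config(m_snps = 5000, n_panel = 100, pi0 = 0.7, pi1 = 0.1,
                    pi2 = 0.1, pi3 = 0.1, seed = 7)
  panel <- simulate_panel(cfg)
  truth <- simulate_effects(cfg, panel)
  comp_by_block <- split(truth$snps$component, panel$snps$block)
  for (b in names(comp_by_block)) {
    cc <- comp_by_block[[b]]
    expected <- if (any(cc == 3)) 3
      else if (any(cc == 1) && any(cc == 2)) 4
      else if (any(cc == 1)) 1
      else if (any(cc == 2)) 2
      else 0
    expect_equal(truth$regions$model[truth$regions$block == as.integer(b)],
                 expected)
  }
})

test_that("null summary statistics have mean chi-square near 1", {
  cfg <- sim_config(m_snps = 20000, n_panel = 200, pi0 = 1, pi1 = 0,
                    pi2 = 0, pi3 = 0, h2_1 = 0, h2_2 = 0, seed = 8)
  panel <- simulate_panel(cfg)
  truth <- simulate_effects(cfg, panel)
  ss <- simulate_sumstats(truth, panel, cfg)
  z <- ss$trait1$beta / ss$trait1$se
  expect_gt(mean(z^2), 0.95)
  expect_lt(mean(z^2), 1.05)
  expect_silent(validate_blocks(panel_blocks(panel)))
})

test_that("polygenic mean chi-square matches the LD score expectation", {
  cfg <- sim_config(m_snps = 10000, n_panel = 200, n1 = 20000, pi0 = 0,
                    pi1 = 1, pi2 = 0, pi3 = 0, h2_1 = 0.5, h2_2 = 0, seed = 9)
  panel <- simulate_panel(cfg)
  ell <- ld_scores(panel)
  chi2 <- vapply(1:5, function(k) {
    cfgk <- cfg; cfgk$seed <- cfg$seed + 1000 * k
    truth <- simulate_effects(cfgk, panel)
    ss <- simulate_sumstats(truth, panel, cfgk)
    mean((ss$trait1$beta / ss$trait1$se)^2)
  }, 0)
  expected <- 1 + cfg$n1 * cfg$h2_1 * mean(ell$ell) / cfg$m_snps
  expect_equal(mean(chi2), expected, tolerance = 0.05)
})

test_that("summary statistics are deterministic and pass validation", {
  cfg <- sim_config(m_snps = 500, n_panel = 100, seed = 10)
  panel <- simulate_panel(cfg)
  truth <- simulate_effects(cfg, panel)
  a <- simulate_sumstats(truth, panel, cfg)
  b <- simulate_sumstats(truth, panel, cfg)
  expect_identical(a$trait1$pvalue, b$trait1$pvalue)
  expect_identical(a$trait2$beta, b$trait2$beta)
  expect_s3_class(as_sumstats(a$trait1), "summary_stats")
  expect_equal(nrow(as_sumstats(a$trait2)), cfg$m_snps)

  o1 <- simulate_outcome_sumstats(truth, cfg, panel)
  o2 <- simulate_outcome_sumstats(truth, cfg, panel)
  expect_identical(o1$beta, o2$beta)
})

test_that("the QUS-to-eBMD equation matches its printed coefficients", {
  expect_equal(ebmd_from_qus(3.687 / 0.002592 / 2, 3.687 / 0.002592 / 2), 0)
  expect_equal(ebmd_from_qus(750, 1250), 0.002592 * 2000 - 3.687)
  delta <- 37
  expect_equal(ebmd_from_qus(750 + delta, 1250) - ebmd_from_qus(750, 1250),
               0.002592 * delta)
})

test_that("panel VCF writing round-trips through vcfR", {
  cfg <- sim_config(m_snps = 60, n_panel = 40, n_chrom = 2, seed = 12)
  panel <- simulate_panel(cfg)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_panel_vcf(panel, path)
  back <- read_panel_vcf(path)
  expect_identical(back$snps$id, panel$snps$id)
  expect_identical(back$snps$pos, as.numeric(panel$snps$pos))
  expect_identical(unname(back$haplotypes), unname(panel$haplotypes))
  expect_identical(back$snps$a1, panel$snps$a1)
})
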