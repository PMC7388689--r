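test_that("Wakefield ABF matches its closed form", {
  # z = 0, V = 0.01, W = 0.1: the exponential term vanishes
  expect_equal(wakefield_abf(0, 0.1, abf_config(W = 0.1)),
               log(sqrt(0.01 / 0.11)))
  # W -> 0 recovers the null prior limit ABF = 1
  expect_equal(wakefield_abf(0.03, 0.1, abf_config(W = 1e-12)), 0,
               tolerance = 1e-10)
  # z = 2, V = W: sqrt(0.5) e^1
  expect_equal(wakefield_abf(0.2, 0.1, abf_config(W = 0.01)),
               log(sqrt(0.5) * exp(1)))
  # averaging over W on the log scale
  w3 <- abf_config()
  single <- vapply(w3$W, function(W) wakefield_abf(0.2, 0.1, abf_config(W)), 0)
  expect_equal(wakefield_abf(0.2, 0.1, w3),
               log(mean(exp(single))))
  expect_error(wakefield_abf(Inf, 0.1), "non-finite")
  expect_error(wakefield_abf(0.1, 0), "non-finite|nonpositive")
})

test_that("log-scale ABF arithmetic survives |z| = 50 without overflow", {
  labf <- wakefield_abf(50 * 0.01, 0.01)
  expect_true(is.finite(labf))
  rbf <- regional_bfs(c(labf, 0), c(labf, 0))
  expect_true(all(is.finite(rbf)))
})

test_that("regional BFs reproduce the hand-worked two-SNP region", {
  labf1 <- log(c(10, 1))
  labf2 <- log(c(8, 1))
  lrbf <- regional_bfs(labf1, labf2)
  expect_equal(exp(lrbf), c(5.5, 4.5, 40.5, 9), tolerance = 1e-12)

  pp <- region_posteriors(lrbf, rep(0.2, 5))
  expect_equal(unname(pp[4]), 40.5 / (1 + 5.5 + 4.5 + 40.5 + 9),
               tolerance = 1e-12)
  expect_equal(unname(pp[4]), 0.6694, tolerance = 1e-4)
  expect_equal(sum(pp), 1)
})

test_that("uninformative and degenerate regions behave as required", {
  # all ABFs = 1 -> every RBF = 1
  expect_equal(exp(regional_bfs(rep(0, 4), rep(0, 4))), rep(1, 4))
  # flat priors + unit RBFs -> uniform posteriors
  expect_equal(unname(region_posteriors(rep(0, 4), rep(0.2, 5))),
               rep(0.2, 5))
  # single-SNP region: model 4 impossible
  expect_equal(regional_bfs(log(5), log(2))[4], -Inf)
  expect_error(regional_bfs(numeric(0), numeric(0)), "empty")
  # permutation invariance
  set.seed(51)
  a <- rnorm(20); b <- rnorm(20); perm <- sample(20)
  expect_equal(regional_bfs(a, b), regional_bfs(a[perm], b[perm]))
})

test_that("vectorized regional BFs equal the brute-force double loop", {
  set.seed(52)
  for (rep in 1:100) {
    k <- sample(2:30, 1)
    labf1 <- rnorm(k, 0, 3)
    labf2 <- rnorm(k, 0, 3)
    got <- exp(regional_bfs(labf1, labf2))
    want <- rbf_oracle(exp(labf1), exp(labf2))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("EM priors: null data pushes mass to model 0, EM matches optim", {
  # strongly null regions: all RBFs tiny
  lrbf_null <- matrix(log(1e-6), 50, 4)
  pri <- estimate_priors(lrbf_null)
  expect_gt(pri[1], 0.95)
  # the Dirichlet floor keeps other components just off zero
  expect_true(all(pri[-1] > 0))

  # penalized log-likelihood never decreases along the EM trace
  set.seed(53)
  lrbf <- matrix(rnorm(200, 0, 2), 50, 4)
  pri2 <- estimate_priors(lrbf)
  trace <- attr(pri2, "loglik_trace")
  expect_true(all(diff(trace) >= -1e-9))
  expect_equal(sum(pri2), 1)

  # two-region toy: EM agrees with direct numerical maximization of the
  # same penalized objective (softmax-parametrized optim)
  lrbf_toy <- rbind(log(c(30, 0.1, 0.2, 0.1)), log(c(0.1, 8, 0.1, 0.2)))
  em <- suppressWarnings(estimate_priors(lrbf_toy))
  obj <- function(theta) {
    lpi <- c(0, theta) - pleiopipe:::logsumexp(c(0, theta))
    lw <- sweep(cbind(0, lrbf_toy), 2, lpi, `+`)
    -(sum(apply(lw, 1, pleiopipe:::logsumexp)) + 0.1 * sum(lpi))
  }
  opt <- optim(rep(0, 4), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  pi_opt <- exp(c(0, opt$par) - pleiopipe:::logsumexp(c(0, opt$par)))
  expect_equal(unname(em), unname(pi_opt), tolerance = 0.005,
               ignore_attr = TRUE)
})

test_that("top SNP selection follows the model-specific weights", {
  ids <- c("s1", "s2")
  labf1 <- log(c(10, 1)); labf2 <- log(c(8, 1))
  # model 3 weights prop. to ABF1*ABF2 = (80, 1)
  ts <- top_snp(labf1, labf2, 3, ids)
  expect_equal(ts$snp, "s1")
  expect_equal(ts$posterior, 80 / 81, tolerance = 1e-12)
  # single-SNP region: posterior 1
  ts1 <- top_snp(log(4), log(2), 1, "only")
  expect_equal(ts1$snp, "only")
  expect_equal(ts1$posterior, 1)
  # model 4 reports one top SNP per trait
  ts4 <- top_snp(labf1, labf2, 4, ids)
  expect_equal(unname(ts4$snp), c("s1", "s1"))
  # model 0 has no causal SNP
  expect_true(is.na(top_snp(labf1, labf2, 0, ids)$snp))
  # input order does not change the selected id
  ts_perm <- top_snp(rev(labf1), rev(labf2), 3, rev(ids))
  expect_equal(ts_perm$snp, ts$snp)
})

test_that("region classification applies a strict posterior cutoff", {
  res <- data.frame(region = c("a", "b", "c"),
                    PP0 = c(0.02, 0.05, 0.1), PP1 = c(0.01, 0.05, 0.9),
                    PP2 = c(0.01, 0, 0), PP3 = c(0.95, 0.9, 0),
                    PP4 = c(0.01, 0, 0))
  cls <- classify_regions(res, 0.9)
  expect_equal(cls$model3, "a")            # 0.95 > 0.9
  # 0.9 exactly fails the strict rule, for PP3 (b) and PP1 (c) alike
  expect_equal(cls$unclassified, c("b", "c"))
  expect_equal(cls$model1, character(0))
})

test_that("simulated single-model regions are recovered by posterior", {
  sim <- simulate_coloc_regions(400, snps_per_region = 20,
                                model_props = c(0.2, 0.2, 0.2, 0.2, 0.2),
                                z_causal = 7, seed = 54)
  res <- coloc_regions(sim$data)
  truth <- sim$truth$model[match(res$region, sim$truth$region)]
  acc <- mean(res$best_model == truth)
  expect_gt(acc, 0.7)
  # posteriors always normalized
  expect_true(all(abs(rowSums(res[, paste0("PP", 0:4)]) - 1) < 1e-9))
})
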