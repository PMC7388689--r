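# Synthetic GWAS data with known pleiotropy structure.
#
# The generator emulates the ingredients the pipeline consumes: a
# reference haplotype panel with block-diagonal LD (latent-Gaussian AR(1)
# thresholded to alleles), paired summary statistics from a four-component
# mixture (null / trait-1-only / trait-2-only / shared), and an outcome
# trait causally downstream of trait 1 for Mendelian-randomization tests.

#' Simulation configuration
#'
#' @param m_snps Number of SNPs.
#' @param n1,n2 GWAS sample sizes for traits 1 and 2. Defaults mirror a
#'   modest DXA femoral-neck BMD meta-analysis and a biobank-scale heel
#'   ultrasound eBMD study.
#' @param n_outcome Outcome (fracture-like) GWAS sample size.
#' @param n_panel Number of reference haplotypes.
#' @param block_sizes SNPs per LD block (recycled across the genome).
#' @param rho_ld Within-block adjacent-SNP latent correlation in \[0, 1);
#'   a vector is recycled across blocks, giving the heterogeneous
#'   block-to-block LD a real genome shows (and LD score regression
#'   needs: with identical LD everywhere the regressor is uninformative).
#' @param pi0,pi1,pi2,pi3 Mixture proportions: null, trait-1-only,
#'   trait-2-only, shared. Must sum to 1.
#' @param h2_1,h2_2 Target SNP heritabilities in \[0, 1).
#' @param rg_shared Effect-size correlation for shared-component SNPs.
#' @param gamma_causal Causal effect of trait 1 (exposure) on the outcome.
#'   The default is negative: higher bone density lowers fracture risk.
#' @param pleiotropy_sd SD of direct (non-mediated) outcome effects added
#'   to every causal SNP; 0 gives a clean instrumental-variable setting.
#' @param n_chrom Number of chromosomes the blocks are spread over.
#' @param seed Integer seed; every generator is reproducible from
#'   (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(m_snps = 10000, n1 = 32965, n2 = 426824,
                       n_outcome = 264973, n_panel = 400,
                       block_sizes = 50, rho_ld = c(0.35, 0.65, 0.9),
                       pi0 = 0.90, pi1 = 0.03, pi2 = 0.05, pi3 = 0.02,
                       h2_1 = 0.25, h2_2 = 0.30, rg_shared = 0.64,
                       gamma_causal = -0.4, pleiotropy_sd = 0,
                       n_chrom = 22, seed = 42) {
  cfg <- list(m_snps = m_snps, n1 = n1, n2 = n2, n_outcome = n_outcome,
              n_panel = n_panel, block_sizes = block_sizes, rho_ld = rho_ld,
              pi = c(pi0, pi1, pi2, pi3), h2_1 = h2_1, h2_2 = h2_2,
              rg_shared = rg_shared, gamma_causal = gamma_causal,
              pleiotropy_sd = pleiotropy_sd, n_chrom = n_chrom, seed = seed)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$m_snps >= 1, cfg$n_panel >= 4, all(cfg$block_sizes >= 1),
            all(cfg$rho_ld >= 0), all(cfg$rho_ld < 1),
            all(cfg$pi >= 0), cfg$h2_1 >= 0, cfg$h2_1 < 1,
            cfg$h2_2 >= 0, cfg$h2_2 < 1,
            abs(cfg$rg_shared) <= 1, cfg$n1 > 1, cfg$n2 > 1)
  if (abs(sum(cfg$pi) - 1) > 1e-12) {
    stop("mixture proportions pi0..pi3 must sum to 1")
  }
  invisible(cfg)
}

# Non-palindromic, non-identical allele pairs (effect, other).
ALLELE_PAIRS <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                      c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))

#' Simulate a block-LD reference haplotype panel
#'
#' Haplotypes arise from a latent AR(1) Gaussian within each LD block
#' (correlation `rho_ld` between adjacent SNPs, zero across blocks),
#' thresholded so each SNP's effect-allele frequency is its MAF, drawn
#' Uniform(0.05, 0.5). Monomorphic columns (possible by chance at low MAF)
#' are repaired by flipping a single haplotype so every SNP is polymorphic.
#'
#' @param cfg A [sim_config()].
#' @return A `genotype_panel`: list with `snps` (id, chrom, pos, a1, a2,
#'   maf, block) and `haplotypes` (n_panel x m_snps 0/1 matrix).
#' @export
simulate_panel <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    m <- cfg$m_snps
    sizes <- rep(cfg$block_sizes, length.out = ceiling(m / min(cfg$block_sizes)) * 2)
    sizes <- sizes[cumsum(sizes) - sizes < m]
    sizes[length(sizes)] <- m - sum(sizes[-length(sizes)])
    n_blocks <- length(sizes)
    block <- rep(seq_len(n_blocks), times = sizes)

    n_chrom <- min(cfg$n_chrom, n_blocks)
    chrom_of_block <- sort(rep_len(seq_len(n_chrom), n_blocks))
    chrom <- chrom_of_block[block]

    # positions: 2-10 kb spacing, restarting per chromosome
    gaps <- sample(2000:10000, m, replace = TRUE)
    pos <- stats::ave(gaps, chrom, FUN = cumsum)

    maf <- stats::runif(m, 0.05, 0.5)
    ap <- ALLELE_PAIRS[sample.int(nrow(ALLELE_PAIRS), m, replace = TRUE), ,
                       drop = FALSE]

    rho_block <- rep(cfg$rho_ld, length.out = n_blocks)
    n_hap <- cfg$n_panel
    lat <- matrix(0, n_hap, m)
    innov <- matrix(stats::rnorm(n_hap * m), n_hap, m)
    for (j in seq_len(m)) {
      rho <- rho_block[block[j]]
      if (j > 1L && block[j] == block[j - 1L]) {
        lat[, j] <- rho * lat[, j - 1L] + sqrt(1 - rho^2) * innov[, j]
      } else {
        lat[, j] <- innov[, j]
      }
    }
    hap <- matrix(0L, n_hap, m)
    thr <- stats::qnorm(1 - maf)
    for (j in seq_len(m)) hap[, j] <- as.integer(lat[, j] > thr[j])

    mono <- which(colSums(hap) %in% c(0L, n_hap))
    for (j in mono) hap[sample.int(n_hap, 1L), j] <- 1L - hap[1L, j]

    # population LD per block, from a large draw of the same latent
    # process: the haplotype panel above is then a finite reference
    # sample from this population, as in a real analysis
    n_pop <- 4000L
    Rpop <- lapply(split(seq_len(m), block), function(idx) {
      kk <- length(idx)
      rho <- rho_block[block[idx[1]]]
      latp <- matrix(stats::rnorm(n_pop * kk), n_pop, kk)
      if (kk > 1L) {
        for (jj in 2:kk) {
          latp[, jj] <- rho * latp[, jj - 1L] + sqrt(1 - rho^2) * latp[, jj]
        }
      }
      hp <- matrix(0L, n_pop, kk)
      for (jj in seq_len(kk)) hp[, jj] <- as.integer(latp[, jj] > thr[idx[jj]])
      R <- suppressWarnings(stats::cor(hp))
      R[!is.finite(R)] <- 0
      diag(R) <- 1
      R
    })

    snps <- data.frame(
      id = sprintf("rs%07d", seq_len(m)),
      chrom = as.character(chrom), pos = pos,
      a1 = ap[, 1], a2 = ap[, 2], maf = maf, block = block,
      stringsAsFactors = FALSE
    )
    structure(list(snps = snps, haplotypes = hap, Rpop = Rpop),
              class = "genotype_panel")
  })
}

# population (or, failing that, panel-estimated) LD of a block's columns
pop_block_cor <- function(panel, idx) {
  b <- panel$snps$block[idx[1]]
  if (!is.null(panel$Rpop) && !is.null(panel$Rpop[[as.character(b)]])) {
    return(panel$Rpop[[as.character(b)]])
  }
  if (!is.null(panel$Rpop) && b <= length(panel$Rpop)) {
    return(panel$Rpop[[b]])
  }
  block_cor(panel, idx)
}

#' Block partition implied by a simulated panel
#'
#' Converts the generator's LD blocks into a genome partition of 1-based
#' half-open intervals \[start, end), with boundaries at midpoints between
#' adjacent blocks' flanking SNPs.
#'
#' @param panel A `genotype_panel` with a `block` column.
#' @return A `block_partition` data.frame (chrom, start, end).
#' @export
panel_blocks <- function(panel) {
  s <- panel$snps
  out <- do.call(rbind, lapply(split(s, s$chrom), function(d) {
    b <- split(d$pos, d$block)
    first <- vapply(b, min, 0)
    last <- vapply(b, max, 0)
    o <- order(first)
    first <- first[o]; last <- last[o]
    nb <- length(first)
    start <- c(1, floor((last[-nb] + first[-1]) / 2) + 1)
    end <- c(start[-1], last[nb] + 1)
    data.frame(chrom = d$chrom[1], start = start, end = end,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  validate_blocks(out)
}

#' Simulate true and LD-smeared marginal effect sizes
#'
#' Each SNP is assigned a mixture component (0 null, 1 trait-1-only,
#' 2 trait-2-only, 3 shared) with probabilities `pi0..pi3`. Causal effects
#' are zero-mean Gaussian, rescaled so the realized
#' sum of 2 maf (1 - maf) beta^2 equals the target heritability exactly;
#' shared-component pairs are bivariate with correlation `rg_shared`.
#' Marginal (LD-smeared) effects R beta, with R the panel's within-block
#' haplotype correlation, are stored alongside so downstream generators
#' (including the outcome trait) smear consistently. Region labels follow
#' the five colocalization hypotheses: shared SNP present -> model 3;
#' else both trait-specific kinds present -> model 4; else 1 / 2 / 0.
#'
#' @param cfg A [sim_config()].
#' @param panel The matching `genotype_panel`.
#' @return A `truth_table`: list with `snps` (component, beta1, beta2,
#'   beta1_marg, beta2_marg per SNP) and `regions` (block, model).
#' @export
simulate_effects <- function(cfg, panel) {
  validate_sim_config(cfg)
  m <- cfg$m_snps
  stopifnot(nrow(panel$snps) == m)
  with_seed(cfg$seed + 1L, {
    comp <- sample.int(4L, m, replace = TRUE, prob = cfg$pi) - 1L
    beta1 <- numeric(m)
    beta2 <- numeric(m)
    c1 <- comp == 1L
    c2 <- comp == 2L
    c3 <- comp == 3L
    beta1[c1] <- stats::rnorm(sum(c1))
    beta2[c2] <- stats::rnorm(sum(c2))
    if (any(c3)) {
      z1 <- stats::rnorm(sum(c3))
      z2 <- cfg$rg_shared * z1 +
        sqrt(1 - cfg$rg_shared^2) * stats::rnorm(sum(c3))
      beta1[c3] <- z1
      beta2[c3] <- z2
    }
    w <- 2 * panel$snps$maf * (1 - panel$snps$maf)
    scale_to_h2 <- function(beta, h2) {
      v <- sum(w * beta^2)
      if (v == 0) {
        if (h2 > 0) warning("no causal SNPs drawn; effects left at 0",
                            call. = FALSE)
        return(beta)
      }
      if (h2 == 0) {
        warning("target heritability 0 with nonzero causal proportions; ",
                "effects scaled to 0", call. = FALSE)
        return(beta * 0)
      }
      beta * sqrt(h2 / v)
    }
    beta1 <- scale_to_h2(beta1, cfg$h2_1)
    beta2 <- scale_to_h2(beta2, cfg$h2_2)

    # LD smear on the standardized-genotype scale (as in a real GWAS:
    # E[z_j] = sqrt(n) sum_k r_jk beta_std_k), then back to allelic units
    blocks <- panel$snps$block
    sw <- sqrt(w)
    beta1_marg <- numeric(m)
    beta2_marg <- numeric(m)
    for (idx in split(seq_len(m), blocks)) {
      R <- pop_block_cor(panel, idx)
      beta1_marg[idx] <- as.numeric(R %*% (beta1[idx] * sw[idx])) / sw[idx]
      beta2_marg[idx] <- as.numeric(R %*% (beta2[idx] * sw[idx])) / sw[idx]
    }

    region_model <- vapply(split(comp, blocks), function(cc) {
      if (any(cc == 3L)) return(3L)
      has1 <- any(cc == 1L)
      has2 <- any(cc == 2L)
      if (has1 && has2) 4L else if (has1) 1L else if (has2) 2L else 0L
    }, integer(1))
    regions <- data.frame(block = as.integer(names(region_model)),
                          model = unname(region_model))
    regions <- regions[order(regions$block), , drop = FALSE]
    rownames(regions) <- NULL

    snps <- data.frame(id = panel$snps$id, component = comp,
                       beta1 = beta1, beta2 = beta2,
                       beta1_marg = beta1_marg, beta2_marg = beta2_marg,
                       stringsAsFactors = FALSE)
    structure(list(snps = snps, regions = regions), class = "truth_table")
  })
}

# correlation matrix of a set of panel columns (with tiny ridge so the
# Cholesky used for correlated noise always exists)
block_cor <- function(panel, idx) {
  X <- panel$haplotypes[, idx, drop = FALSE]
  R <- suppressWarnings(stats::cor(X))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R
}

#' Simulate paired GWAS summary statistics
#'
#' Per-SNP estimates are the LD-smeared marginal effects plus correlated
#' estimation noise: within each block the noise z-scores have the panel's
#' LD correlation, as in a real GWAS of unrelated samples. Standard errors
#' follow the quantitative-trait approximation
#' se = 1 / sqrt(2 n maf (1 - maf)); p-values are two-sided normal.
#'
#' @param truth A `truth_table` from [simulate_effects()].
#' @param panel The matching `genotype_panel`.
#' @param cfg The [sim_config()].
#' @return List of two validated `summary_stats` tables (`trait1`, `trait2`).
#' @export
simulate_sumstats <- function(truth, panel, cfg) {
  stopifnot(nrow(truth$snps) == nrow(panel$snps))
  with_seed(cfg$seed + 2L, {
    list(
      trait1 = sumstats_from_marginals(truth$snps$beta1_marg, panel, cfg$n1),
      trait2 = sumstats_from_marginals(truth$snps$beta2_marg, panel, cfg$n2)
    )
  })
}

# shared machinery: marginal effects + block-correlated noise -> table
sumstats_from_marginals <- function(beta_marg, panel, n) {
  s <- panel$snps
  m <- nrow(s)
  se <- 1 / sqrt(2 * n * s$maf * (1 - s$maf))
  noise <- numeric(m)
  for (idx in split(seq_len(m), s$block)) {
    R <- pop_block_cor(panel, idx)
    L <- chol(R + diag(1e-8, length(idx)))
    noise[idx] <- as.numeric(crossprod(L, stats::rnorm(length(idx))))
  }
  beta_hat <- beta_marg + noise * se
  z <- beta_hat / se
  p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  as_sumstats(data.frame(
    snp_id = s$id, chrom = s$chrom, pos = s$pos, a1 = s$a1, a2 = s$a2,
    beta = beta_hat, se = se, pvalue = p, n = n, freq = s$maf,
    stringsAsFactors = FALSE
  ))
}

#' Simulate outcome-trait summary statistics for MR testing
#'
#' The outcome's true per-SNP effects are `gamma_causal` times trait 1's
#' true effects, plus optional direct-pleiotropy noise; marginal effects
#' inherit the LD smear stored in the truth table, and estimation noise is
#' added as in [simulate_sumstats()].
#'
#' @inheritParams simulate_sumstats
#' @return A validated `summary_stats` table for the outcome.
#' @export
simulate_outcome_sumstats <- function(truth, cfg, panel) {
  with_seed(cfg$seed + 3L, {
    beta_marg <- cfg$gamma_causal * truth$snps$beta1_marg
    if (cfg$pleiotropy_sd > 0) {
      causal <- truth$snps$component != 0L
      direct <- numeric(nrow(truth$snps))
      direct[causal] <- stats::rnorm(sum(causal), 0, cfg$pleiotropy_sd)
      beta_marg <- beta_marg + direct
    }
    sumstats_from_marginals(beta_marg, panel, cfg$n_outcome)
  })
}

#' Simulate per-region summary data for colocalization calibration
#'
#' Independent-SNP regions drawn from the five regional hypotheses
#' (0 no signal, 1 trait-1-only, 2 trait-2-only, 3 one shared causal SNP,
#' 4 two distinct causal SNPs). Causal SNPs receive z-scores with
#' magnitude |N(z_causal, 1)| and random sign, so the median causal |z|
#' is about `z_causal`; all other z-scores are standard normal.
#'
#' @param n_regions Number of regions.
#' @param snps_per_region SNPs per region.
#' @param model_props Length-5 probabilities of models 0-4.
#' @param z_causal Centre of the causal |z| distribution.
#' @param se Common standard error used to turn z-scores into (beta, se).
#' @param seed Integer seed.
#' @return List with `data` (region, snp, beta1, se1, beta2, se2) and
#'   `truth` (region, model).
#' @export
simulate_coloc_regions <- function(n_regions, snps_per_region = 50,
                                   model_props = c(0.70, 0.10, 0.10, 0.08, 0.02),
                                   z_causal = 6, se = 0.02, seed = 1) {
  stopifnot(length(model_props) == 5, abs(sum(model_props) - 1) < 1e-9,
            snps_per_region >= 2)
  with_seed(seed, {
    k <- snps_per_region
    model <- sample.int(5L, n_regions, replace = TRUE, prob = model_props) - 1L
    draw_causal_z <- function(n) {
      abs(stats::rnorm(n, z_causal, 1)) * sample(c(-1, 1), n, replace = TRUE)
    }
    rows <- vector("list", n_regions)
    for (r in seq_len(n_regions)) {
      z1 <- stats::rnorm(k)
      z2 <- stats::rnorm(k)
      mm <- model[r]
      if (mm == 1L) {
        z1[1L] <- z1[1L] + draw_causal_z(1L)
      } else if (mm == 2L) {
        z2[1L] <- z2[1L] + draw_causal_z(1L)
      } else if (mm == 3L) {
        z1[1L] <- z1[1L] + draw_causal_z(1L)
        z2[1L] <- z2[1L] + draw_causal_z(1L)
      } else if (mm == 4L) {
        z1[1L] <- z1[1L] + draw_causal_z(1L)
        z2[2L] <- z2[2L] + draw_causal_z(1L)
      }
      perm <- sample.int(k)  # causal position not always first
      rows[[r]] <- data.frame(region = r, snp = sprintf("r%d_s%d", r, seq_len(k)),
                              beta1 = (z1 * se)[perm], se1 = se,
                              beta2 = (z2 * se)[perm], se2 = se,
                              stringsAsFactors = FALSE)
    }
    list(data = do.call(rbind, rows),
         truth = data.frame(region = seq_len(n_regions), model = model))
  })
}

#' Heel-ultrasound estimated BMD from QUS parameters
#'
#' Estimated calcaneal bone mineral density as the published linear
#' combination of broadband ultrasound attenuation (BUA, dB/MHz) and speed
#' of sound (SOS, m/s): 0.002592 x (BUA + SOS) - 3.687, in g/cm^2.
#'
#' @param bua Broadband ultrasound attenuation.
#' @param sos Speed of sound.
#' @return Estimated BMD.
#' @export
ebmd_from_qus <- function(bua, sos) {
  stopifnot(is.finite(bua), is.finite(sos))
  0.002592 * (bua + sos) - 3.687
}
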