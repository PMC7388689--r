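# Unstratified LD score regression: SNP heritability per trait and
# cross-trait genetic covariance / correlation, with block-jackknife
# standard errors.

# contiguous jackknife block id for each of n SNPs
jk_blocks <- function(n, n_blocks) {
  as.integer(cut(seq_len(n), breaks = n_blocks, labels = FALSE))
}

wls_slope <- function(y, x, w) {
  fit <- stats::lm.wfit(cbind(1, x), y, w)
  stats::setNames(fit$coefficients, c("intercept", "slope"))
}

#' SNP heritability by LD score regression
#'
#' Regresses per-SNP chi-square statistics on LD scores under
#' E\[chi2_j\] = 1 + N h2 ell_j / M + (intercept - 1), with the standard
#' two-step weighting: a provisional 1/max(ell, 1) fit supplies h2 for
#' heteroskedasticity weights 1 / (max(ell, 1) (1 + N h2 ell / M)^2),
#' then the weighted fit is final. h2 = slope M / N. Standard errors come
#' from a delete-one block jackknife over contiguous SNP blocks.
#'
#' @param z Per-SNP z-scores (beta / se), LD-score-matched order.
#' @param ell Matching LD scores.
#' @param N Sample size (scalar or per-SNP; the mean is used).
#' @param M Number of SNPs the heritability refers to (default
#'   `length(z)`).
#' @param weighted Use LDSC weights (`FALSE` gives an ordinary
#'   least-squares fit, exact on toy inputs).
#' @param jackknife Compute block-jackknife SEs; requires at least
#'   `n_blocks` SNPs.
#' @param n_blocks Number of jackknife blocks.
#' @param chisq_max SNPs with chi2 above this cap are excluded (outlier
#'   control); set `Inf` to disable.
#' @return An `ldsc_fit` list: h2, h2_se, intercept, intercept_se, slope,
#'   M, N, n_snps_used.
#' @export
fit_h2 <- function(z, ell, N, M = length(z), weighted = TRUE,
                   jackknife = TRUE, n_blocks = 200, chisq_max = 80) {
  stopifnot(length(z) == length(ell))
  chi2 <- z^2
  keep <- is.finite(chi2) & is.finite(ell) & chi2 <= chisq_max
  if (sum(!keep) > 0L) {
    message(sum(!keep), " SNP(s) removed by the chi-square cap / finiteness filter")
  }
  chi2 <- chi2[keep]
  ell_k <- ell[keep]
  n_snp <- length(chi2)
  if (jackknife && n_snp < max(n_blocks, 200L)) {
    stop("need at least ", max(n_blocks, 200L),
         " SNPs for the block jackknife; set jackknife = FALSE for toy fits")
  }
  Nbar <- mean(N)

  fit_once <- function(idx) {
    y <- chi2[idx]
    x <- ell_k[idx]
    if (weighted) {
      w0 <- 1 / pmax(x, 1)
      h2_0 <- max(0, wls_slope(y, x, w0)[["slope"]] * M / Nbar)
      w <- 1 / (pmax(x, 1) * (1 + Nbar * h2_0 * x / M)^2)
    } else {
      w <- rep(1, length(y))
    }
    wls_slope(y, x, w)
  }

  co <- fit_once(seq_len(n_snp))
  h2 <- co[["slope"]] * M / Nbar
  h2_se <- NA_real_
  int_se <- NA_real_
  if (jackknife) {
    blk <- jk_blocks(n_snp, n_blocks)
    jk <- vapply(seq_len(n_blocks), function(b) {
      cb <- fit_once(which(blk != b))
      c(cb[["slope"]] * M / Nbar, cb[["intercept"]])
    }, numeric(2))
    h2_se <- sqrt((n_blocks - 1) / n_blocks *
                    sum((jk[1, ] - mean(jk[1, ]))^2))
    int_se <- sqrt((n_blocks - 1) / n_blocks *
                     sum((jk[2, ] - mean(jk[2, ]))^2))
  }
  if (h2 < -1e-8 || h2 > 1) {
    warning("h2 estimate ", signif(h2, 3), " outside [0, 1]", call. = FALSE)
  }
  structure(list(h2 = h2, h2_se = h2_se, intercept = co[["intercept"]],
                 intercept_se = int_se, slope = co[["slope"]],
                 M = M, N = Nbar, n_snps_used = n_snp),
            class = "ldsc_fit")
}

#' Cross-trait genetic correlation by LD score regression
#'
#' Regresses z1 z2 products on LD scores under
#' E\[z1 z2\] = sqrt(N1 N2) rho_g ell / M + cross-intercept (the
#' intercept absorbs sample overlap and is estimated, not fixed).
#' rho_g = slope M / sqrt(N1 N2) and r_g = rho_g / sqrt(h2_1 h2_2), with
#' the per-trait heritabilities fit by [fit_h2()] on the same SNPs. The
#' jackknife re-estimates all three regressions per deleted block, so the
#' r_g standard error propagates heritability uncertainty.
#'
#' @param pair A `harmonized_pair` with matching rows to `ell`.
#' @param ell Per-SNP LD scores.
#' @param M Number of SNPs (default `nrow(pair)`).
#' @param n_blocks Jackknife blocks.
#' @param chisq_max Outlier cap applied to both traits' chi2.
#' @param jackknife Compute the block jackknife SE.
#' @return An `ldsc_rg` list: rg, rg_se, p, rho_g, cross_intercept,
#'   h2_1, h2_2 (full `ldsc_fit`s), n_snps_used.
#' @export
fit_rg <- function(pair, ell, M = nrow(pair), n_blocks = 200,
                   chisq_max = 80, jackknife = TRUE) {
  stopifnot(nrow(pair) == length(ell))
  z1 <- pair$beta1 / pair$se1
  z2 <- pair$beta2 / pair$se2
  keep <- is.finite(z1) & is.finite(z2) & is.finite(ell) &
    z1^2 <= chisq_max & z2^2 <= chisq_max
  z1 <- z1[keep]; z2 <- z2[keep]; ell_k <- ell[keep]
  n_snp <- length(z1)
  if (jackknife && n_snp < max(n_blocks, 200L)) {
    stop("need at least ", max(n_blocks, 200L), " SNPs for the jackknife")
  }
  N1 <- mean(pair$n1[keep])
  N2 <- mean(pair$n2[keep])

  slopes_once <- function(idx) {
    # per-trait h2 slopes (two-step weights) and the cross slope with
    # symmetric weights, all on the same SNP subset
    h2_slope <- function(chi2, N) {
      w0 <- 1 / pmax(ell_k[idx], 1)
      h2_0 <- max(0, wls_slope(chi2[idx], ell_k[idx], w0)[["slope"]] * M / N)
      w <- 1 / (pmax(ell_k[idx], 1) * (1 + N * h2_0 * ell_k[idx] / M)^2)
      wls_slope(chi2[idx], ell_k[idx], w)[["slope"]] * M / N
    }
    h1 <- h2_slope(z1^2, N1)
    h2 <- h2_slope(z2^2, N2)
    w0 <- 1 / pmax(ell_k[idx], 1)
    rho_0 <- wls_slope((z1 * z2)[idx], ell_k[idx], w0)[["slope"]] *
      M / sqrt(N1 * N2)
    w <- 1 / (pmax(ell_k[idx], 1) *
                ((1 + N1 * max(0, h1) * ell_k[idx] / M) *
                   (1 + N2 * max(0, h2) * ell_k[idx] / M) +
                   (sqrt(N1 * N2) * rho_0 * ell_k[idx] / M)^2))
    cf <- wls_slope((z1 * z2)[idx], ell_k[idx], w)
    rho_g <- cf[["slope"]] * M / sqrt(N1 * N2)
    c(h1 = h1, h2 = h2, rho_g = rho_g, xint = cf[["intercept"]])
  }

  est <- slopes_once(seq_len(n_snp))
  if (est[["h1"]] <= 0 || est[["h2"]] <= 0) {
    stop("nonpositive heritability estimate; genetic correlation undefined")
  }
  rg <- est[["rho_g"]] / sqrt(est[["h1"]] * est[["h2"]])
  rg_se <- NA_real_
  p <- NA_real_
  if (jackknife) {
    blk <- jk_blocks(n_snp, n_blocks)
    jk <- vapply(seq_len(n_blocks), function(b) {
      e <- slopes_once(which(blk != b))
      e[["rho_g"]] / sqrt(max(e[["h1"]], 1e-12) * max(e[["h2"]], 1e-12))
    }, 0)
    rg_se <- sqrt((n_blocks - 1) / n_blocks * sum((jk - mean(jk))^2))
    p <- 2 * stats::pnorm(-abs(rg / rg_se))
  }
  h2_1 <- fit_h2(z1, ell_k, N1, M = M, jackknife = jackknife,
                 n_blocks = n_blocks, chisq_max = Inf)
  h2_2 <- fit_h2(z2, ell_k, N2, M = M, jackknife = jackknife,
                 n_blocks = n_blocks, chisq_max = Inf)
  structure(list(rg = rg, rg_se = rg_se, p = p, rho_g = est[["rho_g"]],
                 cross_intercept = est[["xint"]],
                 h2_1 = h2_1, h2_2 = h2_2, n_snps_used = n_snp),
            class = "ldsc_rg")
}
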