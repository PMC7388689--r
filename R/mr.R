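# Two-sample summary-data Mendelian randomization: instrument selection,
# inverse-variance-weighted estimate, and Egger sensitivity analysis.

#' Select genetic instruments for an exposure
#'
#' Genome-wide-significant exposure SNPs (p < `alpha`), LD-pruned against
#' the reference panel with the same windowed algorithm (and defaults) as
#' the data-preparation stage.
#'
#' @param exposure A `summary_stats` table for the exposure trait.
#' @param panel A `genotype_panel`.
#' @param alpha Instrument p-value threshold.
#' @param window,step,r2_max Pruning parameters (see [ld_prune()]).
#' @return Character vector of instrument SNP ids.
#' @export
select_instruments <- function(exposure, panel, alpha = 5e-8,
                               window = 50, step = 5, r2_max = 0.2) {
  exposure <- as_sumstats(exposure)
  sig <- exposure[exposure$pvalue < alpha, , drop = FALSE]
  if (nrow(sig) == 0L) {
    stop("no exposure SNP reaches p < ", alpha, "; zero instruments")
  }
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  col <- match(sig$snp_id, panel$snps$id)
  keep <- rep(TRUE, nrow(sig))
  covered <- which(!is.na(col))
  if (length(covered) >= 2L) {
    meta <- data.frame(chrom = sig$chrom[covered], pos = sig$pos[covered],
                       maf = panel$snps$maf[col[covered]],
                       col = col[covered], stringsAsFactors = FALSE)
    keep[covered] <- prune_core(meta, panel, window, step, r2_max)
  }
  sig$snp_id[keep]
}

#' Inverse-variance-weighted MR estimate
#'
#' Pools per-instrument Wald ratios with weights betaX^2 / seY^2:
#' estimate = sum(bX bY / seY^2) / sum(bX^2 / seY^2),
#' se = sqrt(1 / sum(bX^2 / seY^2)) (fixed effect). When Cochran's
#' Q / (n - 1) exceeds 1 the se is inflated by sqrt(Q / (n - 1))
#' (multiplicative random effects). With one instrument this reduces to
#' the Wald ratio bY / bX.
#'
#' @param bx,sx Instrument effect estimates and SEs on the exposure.
#' @param by,sy Matching estimates and SEs on the outcome.
#' @return An `mr_result` list: estimate, se, p, n_instruments, method,
#'   Q, and the per-instrument Wald ratios.
#' @export
mr_ivw <- function(bx, sx, by, sy) {
  n <- length(bx)
  stopifnot(n >= 1, length(by) == n, length(sy) == n, all(sy > 0))
  if (all(bx == 0)) stop("all exposure effects are zero; IVW undefined")
  w <- bx^2 / sy^2
  # n = 1 reduces exactly (not just to rounding) to the Wald ratio
  est <- if (n == 1L) by / bx else sum(bx * by / sy^2) / sum(w)
  se <- sqrt(1 / sum(w))
  Q <- sum((by - est * bx)^2 / sy^2)
  if (n > 1 && Q / (n - 1) > 1) se <- se * sqrt(Q / (n - 1))
  structure(list(estimate = est, se = se,
                 p = 2 * stats::pnorm(-abs(est / se)),
                 n_instruments = n, method = "IVW", Q = Q,
                 wald_ratios = by / bx),
            class = "mr_result")
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free
#' intercept (weights 1 / seY^2). The slope estimates the causal effect;
#' a nonzero intercept indicates directional pleiotropy. Standard errors
#' use the multiplicative random-effects convention (residual scale
#' bounded below by 1).
#'
#' @inheritParams mr_ivw
#' @return An `mr_result` list: estimate, se, p, intercept, intercept_se,
#'   intercept_p, n_instruments, method.
#' @export
mr_egger <- function(bx, sx, by, sy) {
  n <- length(bx)
  if (n < 3L) stop("MR-Egger needs at least 3 instruments")
  stopifnot(length(by) == n, length(sy) == n, all(sy > 0))
  fit <- stats::lm(by ~ bx, weights = 1 / sy^2)
  sm <- summary(fit)
  scale <- min(1, sm$sigma)
  co <- sm$coefficients
  slope <- co["bx", "Estimate"]
  slope_se <- co["bx", "Std. Error"] / scale
  int <- co["(Intercept)", "Estimate"]
  int_se <- co["(Intercept)", "Std. Error"] / scale
  structure(list(estimate = slope, se = slope_se,
                 p = 2 * stats::pt(-abs(slope / slope_se), df = n - 2),
                 intercept = int, intercept_se = int_se,
                 intercept_p = 2 * stats::pt(-abs(int / int_se), df = n - 2),
                 n_instruments = n, method = "Egger"),
            class = "mr_result")
}

#' Two-sample MR of an exposure on an outcome
#'
#' Harmonizes exposure and outcome tables, selects instruments
#' (genome-wide significant + LD-pruned), and reports IVW with Egger
#' sensitivity when at least three instruments survive. The exposure
#' GWAS here is continuous BMD-like; whether a binary outcome arrives on
#' the log-odds scale is up to the caller's input files.
#'
#' @param exposure,outcome `summary_stats` tables.
#' @param panel A `genotype_panel` for pruning.
#' @param alpha Instrument p-value threshold.
#' @param window,step,r2_max Pruning parameters.
#' @return List with `ivw`, `egger` (NULL below 3 instruments), and the
#'   per-instrument table `instruments`.
#' @export
mr_analysis <- function(exposure, outcome, panel, alpha = 5e-8,
                        window = 50, step = 5, r2_max = 0.2) {
  inst_ids <- select_instruments(exposure, panel, alpha, window, step, r2_max)
  h <- harmonize(exposure, outcome)
  h <- h[h$snp_id %in% inst_ids, , drop = FALSE]
  if (nrow(h) == 0L) stop("no instrument survives harmonization")
  ivw <- mr_ivw(h$beta1, h$se1, h$beta2, h$se2)
  egger <- if (nrow(h) >= 3L) mr_egger(h$beta1, h$se1, h$beta2, h$se2) else NULL
  instruments <- data.frame(snp_id = h$snp_id, chrom = h$chrom, pos = h$pos,
                            beta_exposure = h$beta1, se_exposure = h$se1,
                            beta_outcome = h$beta2, se_outcome = h$se2,
                            wald_ratio = h$beta2 / h$beta1,
                            stringsAsFactors = FALSE)
  list(ivw = ivw, egger = egger, instruments = instruments)
}
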