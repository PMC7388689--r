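# End-to-end orchestration: harmonize -> prune -> cFDR/ccFDR ->
# enrichment -> colocalization -> LDSC -> MR, from one config, with a
# run manifest capturing every parameter and per-stage count.

#' Pipeline configuration
#'
#' Either demo mode (`sim` set: everything is generated from a
#' [sim_config()]) or real-data mode (paths to two summary-statistics
#' TSVs, a panel VCF and a block BED).
#'
#' @param out_dir Output directory (created if needed).
#' @param sim A [sim_config()] for demo mode, or NULL.
#' @param sumstats1,sumstats2,panel_vcf,blocks_bed Real-data input paths
#'   (ignored in demo mode).
#' @param outcome Optional outcome-trait TSV for the MR stage.
#' @param window,step,r2_max Pruning parameters.
#' @param gw_alpha Genome-wide significance level.
#' @param qq_cutoffs Conditional p-value strata.
#' @param W ABF prior variances.
#' @param pp_cutoff Posterior cutoff for region classification.
#' @param mr_alpha Instrument p-value threshold.
#' @param coloc_pruned Run colocalization on the pruned set instead of
#'   the full harmonized set (default FALSE: the regional model wants
#'   dense signal).
#' @param figures Also render figures (PDF).
#' @param seed Seed for demo mode.
#' @return A `pipeline_config` list (validated).
#' @export
pipeline_config <- function(out_dir, sim = NULL,
                            sumstats1 = NULL, sumstats2 = NULL,
                            panel_vcf = NULL, blocks_bed = NULL,
                            outcome = NULL,
                            window = 50, step = 5, r2_max = 0.2,
                            gw_alpha = 5e-8,
                            qq_cutoffs = c(1, 0.1, 0.01, 0.001, 0.0001),
                            W = c(0.01, 0.1, 0.5), pp_cutoff = 0.9,
                            mr_alpha = 5e-8, coloc_pruned = FALSE,
                            figures = FALSE, seed = 42) {
  cfg <- list(out_dir = out_dir, sim = sim, sumstats1 = sumstats1,
              sumstats2 = sumstats2, panel_vcf = panel_vcf,
              blocks_bed = blocks_bed, outcome = outcome,
              window = window, step = step, r2_max = r2_max,
              gw_alpha = gw_alpha, qq_cutoffs = qq_cutoffs, W = W,
              pp_cutoff = pp_cutoff, mr_alpha = mr_alpha,
              coloc_pruned = coloc_pruned, figures = figures, seed = seed)
  if (is.null(sim)) {
    paths <- c(sumstats1, sumstats2, panel_vcf, blocks_bed)
    if (length(paths) < 4L) {
      stop("real-data mode needs sumstats1, sumstats2, panel_vcf and blocks_bed")
    }
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L) {
      stop("input path(s) not found: ", paste(missing, collapse = ", "))
    }
  } else {
    validate_sim_config(sim)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full cross-trait pleiotropy pipeline
#'
#' Executes every stage, writes each stage's TSV into `out_dir`, and
#' finishes with `manifest.json` capturing parameters, seed, per-stage
#' row counts, computed thresholds and headline estimates. All stages are
#' deterministic given the config, so repeated demo runs are
#' byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = cfg[setdiff(names(cfg), "sim")],
                   seed = if (!is.null(cfg$sim)) cfg$sim$seed else NA,
                   mode = if (is.null(cfg$sim)) "real" else "demo")
  out <- function(f) file.path(cfg$out_dir, f)

  if (!is.null(cfg$sim)) {
    run_stage("simulate", {
      panel <- simulate_panel(cfg$sim)
      truth <- simulate_effects(cfg$sim, panel)
      ss <- simulate_sumstats(truth, panel, cfg$sim)
      s1 <- ss$trait1
      s2 <- ss$trait2
      s_out <- simulate_outcome_sumstats(truth, cfg$sim, panel)
      blocks <- panel_blocks(panel)
      write_table(s1, out("sumstats_trait1.tsv"))
      write_table(s2, out("sumstats_trait2.tsv"))
      write_table(s_out, out("sumstats_outcome.tsv"))
      write_table(truth$snps, out("truth_snps.tsv"))
      write_table(truth$regions, out("truth_regions.tsv"))
      write_panel_vcf(panel, out("panel.vcf"))
      write_blocks_bed(blocks, out("blocks.bed"))
      manifest$simulation <- cfg$sim[setdiff(names(cfg$sim), "")]
    })
  } else {
    run_stage("load", {
      s1 <- read_sumstats(cfg$sumstats1)
      s2 <- read_sumstats(cfg$sumstats2)
      panel <- read_panel_vcf(cfg$panel_vcf)
      blocks <- read_blocks_bed(cfg$blocks_bed)
      s_out <- if (!is.null(cfg$outcome)) read_sumstats(cfg$outcome) else NULL
    })
  }
  manifest$counts <- list(snps_trait1 = nrow(s1), snps_trait2 = nrow(s2))

  pair <- run_stage("harmonize", {
    p <- harmonize(s1, s2)
    write_table(p, out("harmonized.tsv"))
    manifest$counts$snps_harmonized <- nrow(p)
    manifest$harmonize_audit <- attr(p, "audit")
    p
  })

  pruned <- run_stage("prune", {
    pr <- ld_prune(pair, panel, cfg$window, cfg$step, cfg$r2_max)
    write_table(pr, out("pruned.tsv"))
    writeLines(pr$snp_id, out("prune.in"))
    manifest$counts$snps_pruned <- nrow(pr)
    pr
  })

  cf <- run_stage("cfdr", {
    tab <- cfdr_table(pruned, gw_alpha = cfg$gw_alpha)
    write_table(tab, out("cfdr.tsv"))
    cuts <- attr(tab, "cutoffs")
    manifest$thresholds <- cuts
    manifest$counts$sig_trait1_given_trait2 <- sum(tab$sig_1g2)
    manifest$counts$sig_trait2_given_trait1 <- sum(tab$sig_2g1)
    manifest$counts$sig_conjunction <- sum(tab$sig_cc)
    tab
  })

  run_stage("enrichment", {
    qq <- rbind(cbind(principal = 1,
                      stratified_qq(pruned, 1, cfg$qq_cutoffs)),
                cbind(principal = 2,
                      stratified_qq(pruned, 2, cfg$qq_cutoffs)))
    write_table(qq, out("stratified_qq.tsv"))
    fe <- rbind(cbind(principal = 1,
                      fold_enrichment(pruned, 1, cfg$qq_cutoffs)),
                cbind(principal = 2,
                      fold_enrichment(pruned, 2, cfg$qq_cutoffs)))
    write_table(fe, out("fold_enrichment.tsv"))
  })

  run_stage("coloc", {
    coloc_in <- if (cfg$coloc_pruned) pruned else pair
    rd <- pair_to_regions(coloc_in, blocks)
    res <- coloc_regions(rd, abf_config(cfg$W))
    write_table(res, out("coloc_regions.tsv"))
    cls <- classify_regions(res, cfg$pp_cutoff)
    manifest$coloc <- list(
      priors = as.numeric(attr(res, "priors")),
      pp_cutoff = cfg$pp_cutoff,
      regions_total = nrow(res),
      regions_per_model = vapply(cls[paste0("model", 0:4)], length, 0L),
      regions_unclassified = length(cls$unclassified))
  })

  run_stage("ldsc", {
    ell <- ld_scores(panel)
    write_table(ell, out("ld_scores.tsv"))
    ell_m <- ell$ell[match(pair$snp_id, ell$id)]
    ok <- !is.na(ell_m)
    h1 <- fit_h2(pair$beta1[ok] / pair$se1[ok], ell_m[ok], mean(pair$n1))
    h2 <- fit_h2(pair$beta2[ok] / pair$se2[ok], ell_m[ok], mean(pair$n2))
    rg <- fit_rg(pair[ok, , drop = FALSE], ell_m[ok])
    manifest$ldsc <- list(
      h2_trait1 = h1$h2, h2_trait1_se = h1$h2_se,
      h2_trait2 = h2$h2, h2_trait2_se = h2$h2_se,
      rg = rg$rg, rg_se = rg$rg_se, rg_p = rg$p,
      cross_intercept = rg$cross_intercept)
  })

  if (!is.null(s_out)) {
    run_stage("mr", {
      mr <- mr_analysis(s1, s_out, panel, alpha = cfg$mr_alpha,
                        window = cfg$window, step = cfg$step,
                        r2_max = cfg$r2_max)
      write_table(mr$instruments, out("mr_instruments.tsv"))
      manifest$mr <- list(
        ivw_estimate = mr$ivw$estimate, ivw_se = mr$ivw$se,
        ivw_p = mr$ivw$p, n_instruments = mr$ivw$n_instruments,
        egger_estimate = if (!is.null(mr$egger)) mr$egger$estimate else NA,
        egger_intercept = if (!is.null(mr$egger)) mr$egger$intercept else NA,
        egger_intercept_p = if (!is.null(mr$egger)) mr$egger$intercept_p else NA)
    })
  }

  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       force = TRUE)
  if (isTRUE(cfg$figures)) make_figures(cfg$out_dir)
  invisible(manifest)
}

#' Render pipeline figures from stage outputs
#'
#' Stratified QQ panels, fold-enrichment curves, and the conjunction
#' Manhattan plot with its significance line, rendered from the stage
#' TSVs in `out_dir` (a missing stage skips its figure with a warning).
#'
#' @param out_dir A directory produced by [run_pipeline()].
#' @param format Graphics format understood by [ggplot2::ggsave()]
#'   (default "pdf", which needs no raster device).
#' @return Paths of the figures written, invisibly.
#' @export
make_figures <- function(out_dir, format = "pdf") {
  written <- character(0)
  fig <- function(name) file.path(out_dir, paste0(name, ".", format))
  stage <- function(name) {
    p <- file.path(out_dir, name)
    if (!file.exists(p)) {
      warning("stage output ", name, " missing; figure skipped", call. = FALSE)
      return(NULL)
    }
    utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }

  qq <- stage("stratified_qq.tsv")
  if (!is.null(qq)) {
    g <- ggplot2::ggplot(qq, ggplot2::aes(x = -log10(q),
                                          y = neglog10_p,
                                          colour = factor(cutoff))) +
      ggplot2::geom_line() +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::facet_wrap(~principal, labeller = ggplot2::label_both) +
      ggplot2::labs(x = expression(-log[10] ~ "empirical quantile"),
                    y = expression(-log[10] ~ "nominal p"),
                    colour = "conditional p <") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(fig("stratified_qq"), g, width = 9, height = 4.5)
    written <- c(written, fig("stratified_qq"))
  }

  fe <- stage("fold_enrichment.tsv")
  if (!is.null(fe)) {
    g <- ggplot2::ggplot(fe, ggplot2::aes(x = x, y = enrichment,
                                          colour = factor(cutoff))) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~principal, labeller = ggplot2::label_both) +
      ggplot2::labs(x = expression(-log[10] ~ "nominal p"),
                    y = "fold enrichment", colour = "conditional p <") +
      ggplot2::theme_minimal()
    ggplot2::ggsave(fig("fold_enrichment"), g, width = 9, height = 4.5)
    written <- c(written, fig("fold_enrichment"))
  }

  cf <- stage("cfdr.tsv")
  if (!is.null(cf)) {
    class(cf) <- c("cfdr_table", "data.frame")
    manifest_path <- file.path(out_dir, "manifest.json")
    if (file.exists(manifest_path)) {
      mf <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
      attr(cf, "cutoffs") <- as.list(mf$thresholds)
    }
    md <- conjunction_manhattan_data(cf)
    g <- ggplot2::ggplot(md, ggplot2::aes(x = x,
                                          y = neglog10_ccfdr,
                                          colour = chrom)) +
      ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
      ggplot2::labs(x = "genomic position", y = expression(-log[10] ~ "ccFDR")) +
      ggplot2::theme_minimal()
    thr <- attr(md, "threshold_line")
    if (is.finite(thr)) {
      g <- g + ggplot2::geom_hline(yintercept = thr, colour = "red")
    }
    ggplot2::ggsave(fig("conjunction_manhattan"), g, width = 9, height = 4)
    written <- c(written, fig("conjunction_manhattan"))
  }
  invisible(written)
}
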