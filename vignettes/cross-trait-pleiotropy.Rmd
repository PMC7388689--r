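---
title: "Methods: cross-trait pleiotropy from GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-trait pleiotropy from GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pleiopipe analyses two traits' GWAS summary statistics jointly to find
shared genetic architecture. The motivating setting is bone densitometry:
a small DXA-based femoral-neck BMD meta-analysis alongside a biobank-scale
heel-ultrasound estimated BMD (eBMD) study, with a fracture GWAS as the
downstream outcome. Nothing in the code is specific to bone traits; any
pair of summary-statistics tables with effect sizes, standard errors,
p-values, sample sizes and allele frequencies will do.

This vignette documents the models, the estimators, the tunable
parameters, and the synthetic-data generator the test suite relies on —
including what that generator deliberately does *not* emulate.

## Harmonization and LD pruning

Two tables are inner-joined on SNP id. Trait-2 alleles are aligned to
trait 1: a swapped pair (directly or on the complementary strand) negates
`beta2` and reflects `freq2`; palindromic A/T and C/G SNPs are removed
outright because strand orientation cannot be resolved from alleles alone
(frequency-based resolution is possible but fragile at intermediate MAF;
removal is the conservative standard). Irreconcilable allele pairs are
dropped and counted. P-values of exactly zero are clamped to the smallest
positive normalized double rather than dropped, so the strongest hits
survive with a finite rank.

Pruning mirrors the PLINK `--indep-pairwise` scan with its defaults
(window 50 SNPs, step 5, r² threshold 0.2): within each window every
remaining pair with r² > 0.2 loses its lower-MAF member, windows advance
by 5 SNPs, and the scan repeats to a fixed point. Ties on MAF remove the
later SNP in position order — the reference implementations are silent
and determinism matters more than the particular choice. r² is the
squared Pearson correlation of reference-panel dosages.

## Conditional and conjunction FDR

For SNP *i* with principal p-value $p_{1i}$ and conditional p-value
$p_{2i}$, the empirical conditional FDR is the dominance-count ratio

$$\widehat{\mathrm{cFDR}}_i = \min\!\left(1,\;
  p_{1i}\,\frac{\#\{j: p_{2j} \le p_{2i}\}}
               {\#\{j: p_{1j} \le p_{1i},\, p_{2j} \le p_{2i}\}}\right),$$

with inclusive counts that contain SNP *i* itself (the denominator is
never 0). Both conditioning directions are computed; the conjunction
ccFDR is their maximum. No kernel smoothing is applied: the raw empirical
estimator is exactly testable against an $O(N^2)$ counting oracle, which
the test suite does, and the fast path (a Fenwick-tree sweep over
compressed ranks, $O(N\log N)$) must agree bit-for-bit.

Significance cutoffs are data-driven: the cutoff is the *maximum* cFDR
among SNPs that are genome-wide significant ($p < 5\times10^{-8}$) in
the principal trait, so the conditional analysis is anchored to the
conventional threshold. The conjunction cutoff defaults to the larger of
the two directional cutoffs (an explicit override is available; applying
one direction's cutoff is equally defensible and the choice is exposed
rather than hidden).

Enrichment diagnostics are the standard conditional QQ and
fold-enrichment constructions, stratifying the principal trait's
p-values by conditional-trait cutoffs $p < 1, 0.1, 0.01, 0.001, 0.0001$.
The $t = 1$ stratum is the baseline and its fold enrichment is
identically 1.

## Five-hypothesis regional colocalization

Per SNP and trait, the Wakefield approximate Bayes factor under a
$N(0, W)$ effect prior is

$$\mathrm{ABF} = \sqrt{1 - r}\;\exp(r z^2 / 2), \qquad
  r = \frac{W}{V + W},$$

with $V$ the squared standard error and $z$ the association z-score,
averaged over $W \in \{0.01, 0.1, 0.5\}$ on the log scale. These are the
documented defaults of the pairwise-GWAS colocalization literature for
continuous traits; they are exposed in `abf_config()`.

Regions (by default: a supplied genome partition of non-overlapping
blocks; the field-standard partition has 1,703 of them) are scored under
five models — 0: no association; 1/2: one causal SNP for one trait;
3: one SNP causal for both; 4: two distinct causal SNPs. With per-SNP
ABFs $a_{1i}, a_{2i}$ in a $k$-SNP region, the regional Bayes factors
average over equally likely causal placements:

$$\mathrm{RBF}_1 = \tfrac1k \sum_i a_{1i}, \quad
  \mathrm{RBF}_3 = \tfrac1k \sum_i a_{1i} a_{2i}, \quad
  \mathrm{RBF}_4 = \frac{\sum_{i \ne j} a_{1i} a_{2j}}{k(k-1)}.$$

All arithmetic stays on the log scale. RBF₄ is computed by a
leave-one-out log-sum-exp rather than as
$\log(\Sigma_1 \Sigma_2 - \Sigma_{12})$: when one SNP dominates both
traits the subtraction cancels catastrophically, while the
leave-one-out form is exact for any $|z|$ the pipeline will ever see.

Genome-wide model priors are estimated by EM over regions, maximizing
$\sum_r \log(\pi_0 + \sum_m \pi_m \mathrm{RBF}_{rm})$ on the 5-simplex
with symmetric Dirichlet(1.1) smoothing so no component collapses to the
boundary (convergence: log-likelihood gain below 1e-8, cap 1,000
iterations). Single-SNP regions are reported but excluded from prior
estimation, since model 4 is undefined for them. Posteriors follow as
$\mathrm{PP}_m \propto \pi_m \mathrm{RBF}_m$ with $\mathrm{RBF}_0 = 1$,
and a region is *classified* as model $m$ when $\mathrm{PP}_m$ strictly
exceeds 0.9 — a cutoff whose empirical FDR for the model-3 list stays
below 0.1 in the calibration simulation that both the test suite and
`scripts/acceptance.R` run. The putative causal SNP of a region is the
argmax of the within-region posterior under the best-supported model
(weights $a_{1i}$, $a_{2i}$, or $a_{1i}a_{2i}$ for models 1/2/3; model 4
reports one top SNP per trait), ties broken by position order.

Colocalization runs on the *unpruned* harmonized SNPs by default: the
regional model integrates over dense local signal, and pruning can
remove the causal variant itself (a flag restores the pruned set).
Sample overlap between the two GWAS is not corrected for; with shared
subjects the effect-estimate errors correlate and PP₃ can be inflated —
callers with overlapping cohorts should treat model-3 calls accordingly.

## LD score regression

LD scores are $\ell_j = \sum_k \tilde r^2_{jk}$ over panel SNPs within
1 Mb (including $j$ itself), with the finite-panel bias correction
$\tilde r^2 = r^2 - (1 - r^2)/(n - 2)$, so independent SNPs contribute
zero on average. Heritability comes from the weighted regression of
$\chi^2_j$ on $\ell_j$ under
$E[\chi^2_j] = 1 + N h^2 \ell_j / M + (\text{intercept} - 1)$: a
provisional $1/\max(\ell,1)$ fit supplies $h^2$ for heteroskedasticity
weights, then the weighted fit is final; $h^2 = \text{slope}\cdot M/N$.
SNPs with $\chi^2 > 80$ are excluded (standard outlier control,
configurable). Cross-trait genetic covariance regresses $z_1 z_2$ on
$\ell$ with a free cross-intercept that absorbs sample overlap;
$r_g = \rho_g / \sqrt{h^2_1 h^2_2}$. Standard errors are delete-one
block jackknives over 200 contiguous SNP blocks, re-estimating all three
regressions per deleted block so the $r_g$ SE propagates heritability
uncertainty. Only the unstratified estimator is implemented; partitioned
(annotation-stratified) regression needs external annotation resources
and is deliberately out of scope.

## Two-sample Mendelian randomization

Instruments are genome-wide-significant exposure SNPs, LD-pruned with
the same windowed algorithm and defaults as data preparation. The
primary estimator is fixed-effect IVW,
$\hat\gamma = \sum_j \beta_{Xj}\beta_{Yj}/s_{Yj}^2 \big/ \sum_j
\beta_{Xj}^2/s_{Yj}^2$, with multiplicative random-effects SE inflation
when Cochran's $Q/(n-1) > 1$; a single instrument reduces exactly to the
Wald ratio. MR-Egger (weighted regression with free intercept) is the
pleiotropy sensitivity analysis. This MR protocol is a reconstruction of
standard practice, not a reproduction of any specific published
pipeline, and the output does not presume a scale for a binary outcome —
log-odds inputs yield log-odds causal effects.

At moderate instrument strength the significance filter induces
winner's curse: selected $|\hat\beta_X|$ are overestimated and the IVW
estimate attenuates toward zero. The demo run in the README shows this
(−0.30 recovered for a simulated −0.4 at NCP ≈ 14 instruments); the
recovery tests use strong instruments where the bias is negligible,
which is also the regime real MR practice aims for.

## The synthetic-data generator

Every downstream stage is tested against data with known truth, from
`sim_config()`:

* **Panel.** Haplotypes from a latent Gaussian AR(1) per LD block,
  thresholded so each SNP's effect-allele frequency is its MAF
  (Uniform(0.05, 0.5)). `rho_ld` may be a vector recycled over blocks —
  the default (0.35, 0.65, 0.9) makes true LD scores vary across the
  genome, which LD score regression *requires*: with identical LD in
  every block the regressor is nearly constant and reference-panel noise
  attenuates the slope. Each block also carries a population LD matrix
  estimated from a large (4,000-haplotype) transient draw of the same
  latent process; the stored panel is then a finite reference *sample*
  from that population, exactly the role a reference panel plays in a
  real analysis. Monomorphic columns (possible by chance at low MAF) are
  repaired by flipping a single haplotype.
* **Effects.** Each SNP draws a mixture component — null, trait-1-only,
  trait-2-only, shared — with probabilities `pi0..pi3`. Causal effects
  are Gaussian, rescaled so the realized $\sum 2f(1-f)\beta^2$ equals the
  target heritability exactly; shared pairs are bivariate with
  correlation `rg_shared` (default 0.64, a published cross-trait genetic
  correlation for the two BMD measures). Marginal effects are LD-smeared
  on the standardized-genotype scale,
  $E[z_j] = \sqrt{n} \sum_k r_{jk} \beta^{(\mathrm{std})}_k$, then
  converted back to allelic units — the GWAS-correct expectation.
  Smearing allelic effects directly would couple MAF into both the
  response and the regressor of LD score regression and bias $h^2$
  upward by tens of percent.
* **Summary statistics.** $\hat\beta_j = \beta^{(\mathrm{marg})}_j +
  \varepsilon_j s_j$ with $s_j = 1/\sqrt{2 n f_j (1-f_j)}$ (the
  quantitative-trait approximation; no liability-scale modelling) and
  noise correlated within blocks according to the population LD, as for
  a GWAS of unrelated samples. The outcome trait's true effects are
  `gamma_causal` times trait 1's (default −0.4: higher bone density,
  fewer fractures), plus optional direct-pleiotropy noise, smeared with
  the same matrices so Wald ratios are unbiased for `gamma_causal`.
* **Region truth.** A block is labelled model 3 if it contains a shared
  SNP, model 4 if it contains both trait-specific kinds, else 1/2/0.
  Note that a polygenic block with several causal SNPs genuinely
  violates the one-causal-SNP assumption of the regional model; in such
  blocks a model-4 call against a model-3 label is the model being
  honest, not a bug, and the calibration simulation therefore uses
  single-causal regions (`simulate_coloc_regions()`).

What the generator does **not** emulate: genotyping/imputation error,
population stratification and relatedness (the LDSC intercept is
therefore ≈ 1 by construction), MAF-dependent architecture, real
1000-Genomes LD, case-control liability scales, and consortium scale
(~10⁷ SNPs). Passing tests show the estimators are correct under the
stated model, not that any particular real dataset will reproduce any
particular number.

## Problem sizes and numerical choices

The test suite and acceptance script run at desk scale, chosen once:
calibration and model-recovery simulations use 2,000 and 4×500 regions
of 50 SNPs; LDSC recovery uses m = 20,000 SNPs, n = 50,000, a
500-haplotype panel and 20 effect/noise replicates over a fixed panel;
the null-control and power checks use m = 4,000 with 50 and 20
replicates; the deterministic demo uses m = 1,500. Sample sizes in demo
configurations are scaled with the genome so per-SNP non-centrality is
realistic — compressing a genome to thousands of SNPs while keeping
consortium sample sizes pushes per-SNP χ² past the outlier cap and
degrades every regression-based estimate, which is a property of the
compression, not of the estimators.

Other numerical decisions: all Bayes-factor work on the log scale
(finite through $|z| \ge 50$); cFDR counts are inclusive and include the
index SNP (off-by-one changes results, so this is fixed and tested);
EM convergence at 1e-8 log-likelihood gain with a Dirichlet(1.1) floor;
pruning ties broken by position; `PP > 0.9` strictly; jackknife blocks
contiguous in SNP order. Every generator call is reproducible from
(config, seed), and the seeded demo pipeline is byte-identical across
runs — the run manifest records every parameter, threshold and count
needed to re-create the outputs.
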