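---
title: "Dissecting the heritability of a sex-limited ordinal trait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the heritability of a sex-limited ordinal trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ordherit` implements a complete variance-component workflow for a
male-limited ordinal trait scored in a small number of categories — the
motivating case is a four-level pattern-baldness score — together with a
seeded cohort simulator that generates data with exactly the statistical
structure the analysis assumes. This vignette explains the models, the
estimators, the simulator, and the numerical and design choices, so that a
reader can judge what a passing test suite does and does not establish.

## The liability-threshold view of an ordinal score

The ordinal score $Y_o \in \{1,\dots,k\}$ with category frequencies
$\pi_j$ is treated as a thresholded version of a latent standard-normal
liability: thresholds $t_j = \Phi^{-1}(\pi_1 + \dots + \pi_j)$ cut the
liability axis into the observed categories. Writing $z_j = \phi(t_j)$ for
the normal density at threshold $j$ and
$V(Y_o) = \sum_j \pi_j w_j^2 - (\sum_j \pi_j w_j)^2$ for the variance of
the scored categories (scores $w_j = 1,\dots,k$), a heritability estimated
on the observed score scale converts to the liability scale by the factor

$$ h_l^2 = h_{o}^2 \; \frac{V(Y_o)}{(\sum_j z_j)^2}. $$

For four categories at frequencies $(0.32, 0.23, 0.27, 0.18)$ this factor
is about 1.18 (`liability_factor()`); `to_liability()` applies it without
clipping, flagging transformed values above 1 rather than hiding them,
because such values are themselves diagnostic of upward bias in the input.

The factor is derived from a first-order (linear) approximation of the
score as a function of liability. It is exact in the limit of small
heritability and mildly optimistic at large $h^2$; we use it only to
transform point estimates, never standard errors.

## Variance components by AI-REML

All heritability estimation goes through one engine, `reml_fit()`, which
maximizes the restricted likelihood of
$y \sim N(X\beta,\; \sum_c \sigma^2_c A_c + \sigma^2_e I)$
for an arbitrary list of relationship matrices $A_c$:

* the first accepted update is an EM-REML step (slow but monotone and
  sign-preserving), after which average-information (AI) updates are used;
* a proposal that lowers the restricted likelihood is step-halved, and if
  halving fails the iteration falls back to EM;
* convergence requires $|\Delta \log L| < 10^{-6}$ and
  $\max_c |\Delta\sigma^2_c| / V_p < 10^{-8}$, with a cap of 100
  iterations; a non-converged fit is returned flagged, not raised;
* the sampling covariance of $\hat\sigma^2$ is the inverse AI matrix at
  convergence, and proportion-scale quantities (`h2_from_fit()`) carry
  delta-method standard errors derived from it;
* `constrain = TRUE` floors components at $10^{-6} V_p$; the
  MAF/LD-stratified fit defaults to unconstrained estimation so component
  estimates may be negative — a genuine feature of the analysis it
  mirrors, where a rare-variant component below zero keeps the total
  unbiased.

The test suite verifies the engine against direct maximization of the
same restricted likelihood (grid search plus Nelder-Mead) on fixtures
small enough for brute force, to $10^{-3}$, and against grouped-jackknife
standard errors on sib-pair designs.

Model variants are thin wrappers: a pedigree fit uses
`pedigree_grm()` (first-degree pairs set to 0.5, everything else 0); the
close/distant-relative partition `big_k_small_k_fit()` fits the full GRM
together with `threshold_bigk()` (off-diagonals below 0.05 zeroed, the
diagonal and entries at the cutoff retained); `ldms_fit()` builds one GRM
per MAF-bin-by-LD-quartile component. The big K matrix keeps its
self-relatedness diagonal unchanged — the component then models variance
present in everyone but co-inherited only by close relatives.

## MAF/LD stratification and the enrichment test

`assign_ldms_bins()` places each SNP into one of three MAF bins
(half-open intervals with right edges $10^{-3}$, $0.01$, $0.5$; a MAF of
exactly 0.01 falls in the middle bin) and one of four genome-wide LD-score
quartiles. Quartiles are rank-based with ties broken by input order, so
the partition is always balanced to within one SNP. LD scores
(`ld_scores()`) sum squared Pearson correlations over a 20 Mb window
centred on each SNP, including the SNP itself, so $\ell_i \ge 1$. The raw
squared correlation is used by default, matching the printed definition of
the score; the small-sample-adjusted estimator is available via
`adjusted = TRUE` for sensitivity analyses.

Given per-component estimates $h^2_c$ and SNP counts $M_c$, the
fold-enrichment of a component set $C$ is
$h^2_C M / (M_C h^2)$, and the test statistic divides the per-SNP
difference

$$ d = \frac{h^2_C}{M_C} - \frac{h^2 - h^2_C}{M - M_C} $$

by its delta-method standard error from the joint sampling covariance of
the component estimates ($a_i = 1/M_C + 1/(M - M_C)$ for $i \in C$, else
$-1/(M-M_C)$), against a two-sided standard normal. The covariance route
is the natural reading of an SE "estimated using the covariance matrix" of
the component estimates; with a diagonal covariance it reduces to the
independent-SE case.

## Association, conditional-joint selection, and variance explained

`mlm_assoc()` performs per-SNP generalized least squares with the
variance structure fixed at the null fit (`fit_null_mlm()`, a constrained
single-GRM REML on LD-pruned model SNPs):
$\hat\beta = x'Py / x'Px$, $\mathrm{se} = (x'Px)^{-1/2}$. We deliberately
do not leave out the tested SNP's chromosome from the model GRM; the
resulting proximal contamination slightly deflates test statistics at
causal SNPs but keeps the implementation simple and the null calibration
exact, which the tests verify. Male X genotypes are tested on the
hemizygous $\{0,2\}$ coding, so `per_allele_effect_x()` halves reported
X effects.

`cojo_select()` rebuilds joint least-squares systems from marginal
summary statistics plus reference-panel LD: $X'y_j$ is recovered as
$b_j S_{jj}$ with $S_{jj}$ the centred sum of squares of the reference
dosages, $y'y$ from the per-SNP implied residual variance (median across
SNPs), and cross-products farther apart than 10 Mb (or across
chromosomes) are set to zero. Forward selection seeds with the smallest
marginal p-value; each step computes conditional statistics of all
remaining SNPs given the selected set (Schur complement, so the cost is
one small solve per step), adds the best SNP if its conditional p-value
passes the threshold and its LD $r^2$ with every selected SNP is below
0.9, refits, and drops any SNP whose joint p-value has risen above the
threshold. When the reference panel is the GWAS sample itself this
reproduces individual-level stepwise regression exactly — the test suite
checks the selected set and joint effects against an explicit
individual-level oracle to $10^{-6}$.

The secondary pruning step (`joint_regression_prune()`) is backward
elimination on the joint model at the genome-wide threshold; the
criterion behind the analysis it mirrors is not fully specified, and this
is our reading of "selective multiple regression": every reported SNP
must survive jointly. A singular joint system drops the higher-index
member of the offending dependency first.

`variance_explained_by_set()` builds a GRM from the selected SNPs only
(autosomal columns standardized by $2p(1-p)$, hemizygous X columns by
their empirical population SD) and reports the single-component REML
proportion.

## LD score regression

`ldsc_h2()` regresses $\chi^2_j$ on $\ell_j$ with a free intercept;
$\hat h^2 = \text{slope} \cdot M / \bar N$. Weights are $1/\ell_j$
(over-counting correction) times the squared reciprocal of the expected
$\chi^2$ from a first-pass unweighted fit (heteroskedasticity
correction). Uncertainty comes from a leave-one-block-out jackknife over
contiguous, equal-count SNP blocks (default 200). `ldsc_rg()` regresses
$z_{1j} z_{2j}$ on $\ell_j$ after allele harmonization, estimates the
genetic covariance from the slope, and normalizes by the two
heritabilities computed with the same weights — this makes the
self-correlation exactly 1 — with the standard error and p-value from a
block jackknife of the correlation itself. The intercepts are always
free; traits whose observed-scale $h^2$ falls below 0.05 trigger a
warning rather than an error, matching a reporting filter rather than a
validity condition.

## Fertility and the selection gradient

`fertility_regression()` regresses offspring count on the age-adjusted
phenotype after excluding counts above 20, and reports the Pearson
correlation with a Fisher-z interval. `selection_gradient()` converts the
slope analytically: children per phenotype SD = slope × SD, and the
gradient divides by mean offspring count, i.e. the regression of
*relative* fitness on the standardized phenotype. The analytic route is
identical to refitting relative fitness by linearity, which a test
verifies via the invariance of the gradient under rescaling of counts.

## The cohort simulator

`simulate_cohort()` generates, from one root seed (with per-stage
sub-streams so any stage can be regenerated in isolation):

* **Genotypes.** Haplotypes follow first-order copying: the allele at a
  SNP is copied from the adjacent SNP with probability `ld_decay`,
  otherwise redrawn at its own frequency. Copying chains are broken at
  random block boundaries (`block_break_prob`, default 0.05 per adjacent
  pair) and at chromosome ends; the blocks give the LD scores a genuine
  spread, which the MAF/LD stratification needs to be meaningful.
  Autosomes carry diploid dosages; the male X carries one haplotype
  stored as $\{0,2\}$. SNPs are laid out 2000 per chromosome at 50 kb
  spacing, so the 20 Mb LD window spans about 400 SNPs.
* **Pedigree.** Brother and father-son pairs are created by gene
  dropping (`gamete_drop()`): per-site Mendelian sampling from parental
  dosages for autosomes, and a son's X drawn from his mother only, so
  father-son X sharing is structurally zero. Phase is not tracked, so
  transmitted haplotypes are unlinked across heterozygous sites; this
  leaves expected relatedness (0.5 for first-degree autosomal pairs)
  untouched but shrinks the variance of realized relatedness relative to
  real genomes.
* **Architecture.** Genetic variance is apportioned over
  MAF-bin-by-LD-quartile components in the proportions `bin_enrichment`.
  The default places everything in the common-MAF bin with quartile
  shares proportional to (0.35, 0.34, 0.19, 0.13) — the printed shares
  sum to 1.01 from rounding, so they are normalized. Defaults
  `h2_auto = 0.36`, `h2_x = 0.03` follow the three-GRM partition the
  package mirrors; `h2_fam = 0.21` adds variance shared (correlation
  0.5) within first-degree pairs but untagged by the simulated SNPs,
  which is what the big K component estimates.
* **Ordinal phenotype.** Liability is thresholded at the quantiles of
  the category frequencies. Age shifts the liability by
  `age_slope / sum(z_j)` per year, so the ordinal regression of score on
  age has slope approximately `age_slope` (default 0.02/year over ages
  40-73); this is a documented approximation — age acts on liability,
  not additively on the rounded score.
* **Repeat measurement.** The second measurement re-thresholds a noisy
  copy of the latent scale. The noise SD is expressed in latent-SD
  units; `repeat_sd_for_target()` solves the bivariate-normal ordinal
  correlation (by numerical integration and root finding) for the SD
  that yields a target repeatability, 0.88 by default. The environmental
  mechanism behind repeatability (permanent vs transient environment) is
  deliberately not modelled — a single error SD is exposed.
* **Fertility.** Offspring counts are Poisson with identity-link mean
  `fertility_mean + fertility_slope × liability`, clipped at zero and
  truncated at 20 (matching the analysis' exclusion rule). The default
  slope is calibrated so the regression of children on the ordinal score
  is −0.030; the calibration uses the analytic covariance between
  liability and score, $\mathrm{cov}(L, S) = \sum_j z_j$.

### What the simulator does and does not emulate

The generator reproduces the *statistical* structure the estimators
assume: a normal liability, independent per-SNP effects within
components, Mendelian inheritance, hemizygous X dosage. It does not
emulate realistic demography or recombination maps, imputation
uncertainty, pseudo-autosomal regions, assortative mating, shared
environment beyond the family variance component, or genotyping error.
Passing recovery tests therefore demonstrate that the estimators are
correct under their own model — not that the model is adequate for any
particular real cohort.

### Desk-scale caveats

Two desk-scale phenomena are worth understanding because they are real
properties of the methods, not artifacts:

* With a few thousand SNPs in strong LD, the effective number of
  independent markers is small and GRM entries between unrelated
  individuals have noise SD well above the 0.05 relatedness cutoff, so
  thresholded "close-relative" matrices pick up noise pairs and
  unrelated-subset selection over-prunes. The analyses this package
  mirrors use about a million SNPs, pushing that noise SD to ~0.001. The
  recovery tests for the close/distant-relative partition therefore use
  independent sites, where 5000 SNPs put the noise floor safely below
  the cutoff.
* When genetic variance is enriched in low-LD regions, a *single*-GRM
  fit is misspecified and its estimate does not equal the simulated
  heritability — which is precisely the argument for the MAF/LD
  stratification. The stratified fit is correctly specified under the
  simulator and recovers the component shares; small transfers between
  adjacent LD quartiles remain at these sample sizes because
  neighbouring components' GRMs are highly correlated.

## Problem sizes used by the test suite

The simulation-based checks run at n = 2000 individuals with 5000
autosomal and 500 X SNPs (20 seeds, split between the flat-architecture
pedigree recovery and the enriched-architecture stratified recovery),
n = 3000 split in halves for the genetic-correlation recovery, 5000 null
SNPs for type-I calibration, and 4 × 10^5 simulated individuals for the
case-control ascertainment analysis. These sizes were chosen so the whole
suite exercises every estimator end-to-end in a few minutes on a laptop
while keeping Monte-Carlo error well inside the stated tolerances.

## Known limitations

* Standard errors are not transformed to the liability scale.
* The mixed-model scan offers no leave-one-chromosome-out mode and no
  non-infinitesimal test.
* The conditional-joint selection treats inter-window LD as exactly zero
  and reconstructs $y'y$ from a median across SNPs; with reference
  panels other than the GWAS sample itself the usual caveats about LD
  mismatch apply.
* Ordinal-to-liability conversion assumes the score is a monotone
  threshold function of a single normal liability; probit/ordinal-GLMM
  estimation of the liability model is out of scope.
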