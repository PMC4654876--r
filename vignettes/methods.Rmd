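---
title: "Models and methods in gpgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gpgwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`gpgwas` implements a complete analysis chain for quantitative traits
measured on livestock populations organized in paternal half-sib families:
SNP quality control, relationship matrices, REML variance components,
Bayesian whole-genome regression for association, and cross-validated
genomic prediction.  This vignette documents the models, the tunable
parameters, the numerical choices, and the limits of what the synthetic
data can demonstrate.

## The trait-adjustment mixed model and REML

Raw phenotypes are adjusted before genome-wide analysis with the animal
model

$$ y = Xb + Wc + u + e, \qquad
   c \sim N(0, I\sigma^2_{cg}),\;
   u \sim N(0, G\sigma^2_a),\;
   e \sim N(0, I\sigma^2_e), $$

where $X$ carries the categorical fixed effects breed type, gender and
production system (reference-level dummy coding, first level alphabetically
as reference) and the linear covariates age at slaughter, days from
slaughter to fat extraction and diet metabolic energy, with marbling score
added for muscle traits; $W$ maps animals to contemporary groups (feedlot
location x year); and $G$ is the VanRaden method-1 genomic relationship
matrix

$$ G = \frac{ZZ'}{\sum_j 2p_j(1-p_j)}, \qquad Z_{ij} = x_{ij} - 2p_j . $$

Allele frequencies are estimated from the analyzed sample, which makes the
rows of $G$ sum to zero exactly; because that also makes $G$ singular, a
ridge of $10^{-6}$ is added to the diagonal before any inversion.

`fit_reml()` maximizes the restricted likelihood by average information
(AI) updates with step-halving, falling back to an EM step whenever the AI
step leaves the parameter space or fails to improve the restricted
log-likelihood; variances are floored at $10^{-8}\,\mathrm{var}(y)$
(boundary projection).  Convergence is declared when the restricted
log-likelihood changes by less than $10^{-6}$ or the relative parameter
change falls below $10^{-8}$.  The standard error of $\hat h^2$ comes from
the delta method applied to the inverse AI matrix.  When the AI matrix is
numerically singular — e.g. with $G = I$, where $\sigma^2_a$ and
$\sigma^2_e$ are not separately identifiable — the fit warns and reports
the boundary solution.

Two conventions were genuinely open and are settable:

* **Heritability denominator.**  By default
  $h^2 = \sigma^2_a/(\sigma^2_a + \sigma^2_{cg} + \sigma^2_e)$, i.e. the
  contemporary-group variance counts as phenotypic variance;
  `h2_includes_cg = FALSE` excludes it.
* **Missing covariates.**  Animals with missing covariates are dropped
  with a warning rather than mean-imputed.

Adjusted phenotypes are $y^* = y - X\hat b - W\hat c$ with $\hat b$ the
GLS solutions and $\hat c$ the contemporary-group BLUPs; the additive
genetic and residual parts remain in $y^*$.  Note $\hat b$ is GLS, so
$y^*$ is centered only approximately (the GLS intercept differs from the
sample mean by a small amount).

## SNP quality control

Filters run in a fixed order — call rate (> 20% missing removed), minor
allele frequency (< 0.05 removed; exactly 0.05 kept), Hardy–Weinberg
equilibrium (one-degree-of-freedom chi-square goodness-of-fit p
$< 10^{-6}$ removed; monomorphic SNPs return p = 1), then correlation
pruning — and the QC report counts removals in that order.  The chi-square
test was chosen over the exact test because it is the routine choice for
50K-chip QC and has a closed form the tests can verify.

Correlation pruning scans left-to-right in map order within each
chromosome, dropping a SNP whose absolute Pearson dosage correlation with
any retained SNP in the preceding 50-SNP window reaches 0.95; ties are
broken by always keeping the earlier SNP in map order.  Whether such
pruning should be windowed or genome-wide is a judgment call; the windowed
greedy rule is $O(M \cdot w)$ and reflects that near-collinear pairs are
overwhelmingly local.

Sporadic missing genotypes (the use case is < 1% missingness surviving the
call-rate filter) are imputed by a Binomial$(2, \hat p_j)$ draw at the
SNP's observed allele frequency — frequency-preserving in expectation,
deterministic under the seed, and never touching observed cells.  This is
an internal single-marker imputer, not a phasing-based one; it ignores LD
information entirely, which is acceptable at sporadic missingness levels
but would not be for low-density panel imputation.

## BayesC$\pi$ whole-genome regression

The association model for adjusted phenotypes is

$$ y^*_i = \mu + \sum_{j=1}^{M} x_{ij} a_j + e_i , $$

with the spike-and-slab mixture prior
$a_j \mid \pi, \sigma^2_a \sim (1-\pi)\,N(0, \sigma^2_a) + \pi\,\delta_0$,
scaled-inverse-chi-square priors on $\sigma^2_a$ (df $v_a = 4$) and
$\sigma^2_e$ (df $v_e = 10$), and a uniform prior on $\pi$.  The prior
scales are anchored to the REML fit:

$$ S^2_a = \frac{\hat\sigma^2_u\,(v_a - 2)}
                {v_a\,(1-\pi)\sum_j 2p_j(1-p_j)}, \qquad
   S^2_e = \frac{\hat\sigma^2_0\,(v_e - 2)}{v_e} . $$

Because $S^2_a$ references $\pi$ while $\pi$ is itself sampled, the scale
is frozen at the initialization value $\pi_0 = 0.9$; the alternative
(re-deriving the scale from the running $\pi$) makes the prior
data-dependent in a way the anchoring formula does not intend.

Each Gibbs sweep samples: the general mean from its normal full
conditional (flat prior; $\mu$ is sampled even though $y^*$ is
near-centered, matching the model as written); each SNP's inclusion
indicator from the marginal likelihood ratio of the current residuals
(computed in log space) followed, when included, by the effect from its
normal full conditional; $\sigma^2_a$ from a scaled inverse chi-square
with df $v_a + m$ ($m$ = number included); $\sigma^2_e$ with df
$v_e + n$; and $\pi \sim \mathrm{Beta}(M - m + 1,\, m + 1)$.  Residuals
$e = y^* - \mu - Xa$ are maintained incrementally, giving $O(nM)$ per
sweep; the sweep is implemented in C++ and uses R's RNG, so chains are
bit-reproducible given `chain_config(seed = )`.  SNPs are updated in
ascending map order each sweep (`randomize_order = TRUE` permutes the
order per sweep; posterior summaries agree within Monte-Carlo error).

Initialization: all $a_j = 0$, $\pi = 0.9$, $\sigma^2_a = S^2_a$,
$\sigma^2_e = \hat\sigma^2_0$, $\mu = \bar y^*$.  Production defaults are
a 45,000-iteration chain with 5,000 burn-in; the package's tests use
shorter chains (600–8,000 iterations) at correspondingly smaller problem
sizes.

The per-SNP summaries are the posterior inclusion probability (PPI, the
post-burn-in mean of the indicator) and the *unconditional* posterior mean
effect (zeros included), which is the allele-substitution-effect summary
used downstream.  Two oracle modes support verification: `pi_fixed = 0`
with `fix_variances = TRUE` reduces the model to Bayesian ridge
regression, whose posterior mean has the closed form
$(X'X + \lambda I)^{-1}X'y$; `pi_fixed = 1` forces the null model.

## Genome-wise significance by permutation

Following the shuffling approach to genome-wise error control, the
adjusted phenotypes are permuted against intact genotypes, the sampler is
rerun per permutation, and the largest PPI of each permutation is
recorded.  With `n_perm` permutations at level $\alpha$ the threshold is
the ascending order statistic of rank
$\lceil (1-\alpha)\,n_\mathrm{perm} \rceil$ — the 950th of 1,000 at
$\alpha = 0.05$ — selected by a stable ascending sort.  Each permutation
gets a seed derived deterministically from the master seed, so the whole
procedure is reproducible and individual permutations can be re-run in
isolation.

The percentage of additive genetic variance attributed to a significant
SNP is reported as $100 \cdot 2p(1-p)\,\hat a^2 / \hat\sigma^2_u$ with
$\hat a$ the unconditional posterior-mean effect and $\hat\sigma^2_u$ the
REML additive variance.  This expression assumes linkage equilibrium
between the SNP and the rest of the genome and is flagged as a
convention in the output; summed over SNPs in LD it double-counts.
Candidate features are joined from a user-supplied BED/GFF3 annotation
over a 1-Mb window centered on each significant SNP (BED's 0-based
half-open coordinates are converted to 1-based inclusive on import).

## Genomic prediction and cross-validation

`make_folds()` packs whole sire families into `k = 10` folds (greedy:
families of each breed, largest first, onto the currently smallest fold),
so no sire family spans two folds and every breed present in a validation
fold also appears in training.  Fold sizes stay within a few animals of
$n/k$ when family sizes are balanced.

`blup_predict()` solves $y^* = 1\mu + Za + e$ for the combined
training + validation set with validation records absent, by two
algebraically equivalent routes kept as mutual checks: the mixed-model
equations over all animals, and the kernel form
$\hat a_v = K_{vt}(K_{tt} + \lambda I)^{-1}(y^*_t - \hat\mu)$ with
$\lambda = \sigma^2_e/\sigma^2_a$.  In both routes the intercept is
absorbed by centering on the training mean, which is what makes the
equivalence exact (a jointly estimated GLS intercept would differ at the
fourth decimal and break the cross-check).  Variance components are
re-used from the full-data REML fit by default — re-estimating per
training fold is available via `refit_each_fold` but is not the default,
as the components are a property of the trait rather than the split.

Fold metrics are the validation correlation $r(\mathrm{EBV}, y^*)$, the
realized accuracy $r/\sqrt{\hat h^2}$ (with $\hat h^2$ from the full-data
REML fit), and the slope of the regression of $y^*$ on EBV (1 for
unbiased prediction).  Folds where the EBVs have zero variance — or with
$h^2 = 0$, where realized accuracy is undefined — are flagged `NA` and
excluded from the across-fold mean and its standard error
$\mathrm{sd}/\sqrt{k}$.

A structural consequence worth knowing: with a one-generation pedigree
recording sires only, strictly sire-disjoint validation folds have *zero*
pedigree relationship to their training sets, so PBLUP EBVs are
identically zero and every fold is flagged.  Real pedigrees escape this
through recorded dams, related sires or deeper ancestry; a pedigree-based
accuracy under this design therefore says more about pedigree
completeness than about the predictor.  The PBLUP machinery is exercised
instead on splits that leave half-sibs in training.

## The synthetic-data generator

`simulate_genotypes()` models each chromosome as consecutive LD blocks of
`ld_block_size` SNPs.  Per block a pool of `n_founder_haplotypes` (default
20) founder haplotypes is built in which each SNP carries exactly
$\mathrm{round}(K p)$ copies of the coded allele, assigned by a latent
ancestry ranking that is redrawn with probability `hap_switch_prob` per
SNP — so allele patterns persist locally and pairwise LD decays with map
distance, while founder frequencies are quantized to multiples of $1/K$.
Gametes copy one founder haplotype per block.  Each animal receives one
gamete drawn from its sire's two haplotypes (picked per block) and one
population gamete, producing paternal half-sib families with the expected
mean genomic relationship of 0.25; dams are unrecorded, matching a thin
one-generation pedigree.

Phenotypes are intercept + fixed effects + QTL breeding value +
contemporary-group effect + residual.  Categorical fixed-effect magnitudes
default to 0.25–1.0 phenotypic SD (large enough that adjustment matters,
small enough not to dominate); contemporary groups default to 8 levels
(2 locations x 4 years) assigned at random.  QTL effects are rescaled so
that the empirical variance of true breeding values equals `h2` exactly on
the scale where $\mathrm{var(TBV)} + \mathrm{var(cg)} +
\mathrm{var}(e) = 1$; the realized heritability recorded in the truth
object therefore excludes fixed-effect variance from its denominator,
consistent with heritability being defined after adjustment.  Large-effect
QTL are sized through $2p(1-p)a^2$ to carry their configured share of the
genetic variance, with the residual share spread over `n_poly_qtl`
normally distributed background effects.

What the generator does *not* emulate: realistic bovine LD maps and
recombination hotspots, selection and drift across generations,
genotyping batch effects, and multi-trait genetic correlations.  Passing
tests on this generator demonstrate correctness of the estimators under
the assumed variance structure — not calibration on real cattle data.

## Problem sizes and observed behaviour

The test-suite and the reproduction script run everything at desk scale on
one core: heritability recovery at $n = 1500$, $M = 2000$ over 10 seeds
(REML $\hat h^2$ averages within a few points of the simulated 0.5); QTL
localization at $n = 1000$, $M = 2000$ with one QTL carrying 25% of the
genetic variance over 5 seeds (the QTL's block reaches PPI ≈ 1 after QC
pruning); genome-wise type-I control from 100 pure-noise replicates x 50
permutations with 600-iteration chains (exceedance rate near the nominal
0.05); and 5-fold cross-validation at $n = 500$, $M = 600$ comparing
GBLUP with the Bayesian predictor under large-QTL and purely polygenic
architectures (the Bayesian method wins under a large QTL; the two agree
closely when polygenic).

One measured property deserves emphasis.  Under a *dense* causal
background (here 200 causal SNPs among 2,000) combined with strong
half-sib structure (50 sires for 1,000 animals), the genome-wide baseline
PPI of truly null SNPs settles around 0.05–0.07 rather than near zero:
the sampled $\pi$ equilibrates near 0.91, making inclusion cheap for all
SNPs, and null SNPs partially tag family membership, which correlates
with the polygenic breeding values retained in $y^*$.  With 500 sires, or
a 50-SNP background, the same median falls to 0.007–0.03.  PPIs should
therefore be read against the permutation threshold — which inherits the
same baseline under the null and calibrates the genome-wise error rate —
rather than against an absolute "small" value.

## Known limitations

* AI-REML forms dense $n \times n$ matrices; beyond $n \approx 10^4$ a
  sparse/low-rank implementation would be needed.
* The permutation procedure at production settings (1,000 permutations x
  45,000-iteration chains) is cluster-scale by construction; the `desk`
  preset (50–100 permutations, ≤ 5,000 iterations) is for method
  development, and its thresholds are noisier.
* The variance-explained convention ignores LD between significant SNPs.
* Sporadic imputation ignores haplotype information (see above).
* Single-trait only; no genetic-correlation or multi-tissue modelling.
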