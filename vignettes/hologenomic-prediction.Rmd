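---
title: "Hologenomic prediction with genomic, microbial and interaction kernels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hologenomic prediction with genomic, microbial and interaction kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hologen)
```

## The model

`hologen` predicts quantitative traits of animals from host genotypes,
gut microbiome composition, and their interplay. The phenotype of animal
$m$ is modelled as

$$
y = \mu + dl_i + cg_j + sex_k + pen_{l(j)} + a_m + o_m + ao_m + e,
$$

with fixed effects of dam line (2 levels), contemporary group and sex, a
random pen effect ($pen \sim N(0, I\sigma^2_{pen})$, pens nested in
contemporary group), and up to three kernel-structured random effects:

* $a \sim N(0, G\sigma^2_a)$ — additive genomic values, with $G$ the
  VanRaden (Method 1) genomic relationship matrix,
  $G = ZZ^\top / 2\sum_j p_j(1-p_j)$, $Z$ the dosage matrix centered by
  twice the allele frequency;
* $o \sim N(0, M\sigma^2_o)$ — microbial values, with $M = XX^\top/q$
  from the log-transformed, centered and scaled relative abundances of
  $q$ OTU (a pseudocount of 0.001 is added to all abundances before the
  log);
* $ao \sim N(0, (G \circ M)\sigma^2_{ao})$ — genome-by-microbiome
  interaction, with $G \circ M$ the Hadamard product, PSD by the Schur
  product theorem. The product is not rescaled: its variance parameter
  absorbs scale.

The nested model family M0 (baseline) … M4 (all three kernels) lets the
variance explained by each information source be compared.
Heritability $h^2$, microbiability $m^2$ and the interaction fraction
$i^2$ are the posterior fractions $\sigma^2_\bullet / (\sigma^2_a +
\sigma^2_o + \sigma^2_{ao} + \sigma^2_{pen} + \sigma^2_e)$, the pen and
residual variances included in the denominator.

## Fitting: Gibbs sampling in the kernel eigenbasis

Each kernel effect is reparameterized through the eigendecomposition of
its kernel restricted to the records with observed phenotypes:
$u = U\sqrt{\Lambda}\,\alpha$ with $\alpha \sim N(0, \sigma^2 I)$.
Because $U$ has orthonormal columns, the full conditional of $\alpha$ is
diagonal and one $n \times r$ matrix–vector product per kernel per
iteration suffices. Eigenvalues below $10^{-10}$ are truncated
(numerical PSD enforcement with negligible variance loss). Fixed effects
(flat prior) and pen effects are drawn as one joint Gaussian block —
their cross-correlation with single-sire pens would otherwise dominate
the autocorrelation time. When the total coefficient dimension is at
most 200 the sampler instead draws *all* effects as a single Gaussian
block per iteration (a two-block Gibbs with the variances): at that size
the cubic solve is cheap, mixing improves substantially, and with fixed
variance components each draw is exact. Point estimates of effects are
Rao–Blackwellized (averages of conditional means rather than draws).

Variance components have scaled-inverse-$\chi^2$ priors with 5 degrees
of freedom; scales are set so the prior modes split half the phenotypic
variance equally among the active random terms (kernels plus pen), the
residual receiving the other half. This is the convention of the
Bayesian kernel-regression software family this sampler follows; both
the degrees of freedom and the split are arguments of
`mcmc_settings()`.

Records with a missing (masked) trait value contribute nothing to the
likelihood; their predictions are the fixed part plus the kernel
projection $K_{\text{miss,obs}} K_{\text{obs}}^{+} \hat u_{\text{obs}}$
— the conditional mean of their effects given the sampled training
effects, identical to the joint masked-record prediction under this
model — plus the pen effect when the pen was observed in training and 0
otherwise (pens are train-set-specific in a single-sire-pen design).
Default chain settings are 120,000 iterations, 20,000 burn-in, thinning
5; cross-validation uses a reduced 12,000/2,000/5 profile whose
agreement we verify in the recovery tests. Effective sample sizes are
estimated from the autocorrelation time with Geyer's initial positive
sequence truncation.

## Preprocessing

Markers with call rate below 0.90 or minor allele frequency below 0.05
are removed (strictly below: boundary markers are kept, a literal
reading of "lower than"); remaining missing dosages are imputed to
twice the allele frequency, which leaves allele frequencies invariant
and is the GBLUP convention. OTU with a total raw count below 1,200 are
removed *before* rarefaction to 10,000 counts per sample; samples with
fewer reads than the rarefaction depth are dropped with a warning (the
alternative — keeping them unrarefied — would break the constant-depth
assumption of the downstream transforms).

Two centering conventions are implemented for the OTU matrix: the
default `mean-of-logs` (a true standardization; columns of $X$ sum to
zero and $\mathrm{tr}(M) = n-1$ under the $n-1$ divisor) and
`log-of-mean` (literal column-mean centering on the abundance scale).
Only the former yields the zero-mean columns the Gaussian-kernel
interpretation assumes, so it is the default; neither is asserted to be
the "original". The standard-deviation divisor ($n-1$ or $n$) is
likewise exposed.

## Feature preselection and cross-validation

The single-feature scan fits
$y = \mu + dl + cg + sex + pen + sire + \beta x + e$ by least squares
per feature and reports the Wald p-value for $\beta$. Pen is treated as
a fixed factor in the scan so the whole 40k-marker pass reduces to one
design-matrix projection reused across features (residualize once,
regress each residualized feature); this is algebraically identical to
per-feature full fits and at most mildly conservative. Markers and OTU
are Bonferroni-corrected separately ($p < \alpha/q$ within feature
type) because they enter separate kernels. Randomly reduced sets are
size-matched uniform samples.

Cross-validation groups animals by sire: sires are partitioned into four
equal folds, by a greedy agglomerative rule on a sire relatedness matrix
when one is supplied (each fold seeded with the most-related remaining
pair and grown by mean relatedness, so related sires never straddle
train and test) and at random otherwise. Anti-leakage conventions:
allele frequencies, OTU standardization statistics and the IR/RR
feature sets are recomputed from training animals only, inside every
fold; predictions are scored against raw phenotypes with Pearson
correlation and MSE, so M0 remains a meaningful baseline.

## Post-analysis

Predictive abilities pooled over trait, stage, model, complexity and
fold are analysed with
`r ~ T + S + M + C + F + S:M + S:C + M:C + T:S + T:M + T:C`
under sum-to-zero coding; type-III sums of squares are coding-dependent
and this coding is the convention of the tooling this analysis follows
(`car::Anova`). Least-squares means and pairwise contrasts come from
`emmeans`, Tukey-adjusted by default (`none` and `bonferroni` are
exposed; the adjustment choice is not dictated by the method itself).
Terms made inestimable by empty cells are flagged, never silently
dropped.

## The synthetic-data generator

The generator emulates a commercial swine design: paternal half-sib
families (default 28 sires × 20 progeny) in single-sire, single-sex
pens of 20 nested in 6 contemporary groups; biallelic markers with
allele frequencies drawn from [0.05, 0.5]; each progeny receives one
allele sampled from its sire's pair and one population allele, inducing
the half-sib genomic covariance of 0.25. Markers are simulated without
linkage: the kernels depend only on the relationship structure, which
half-sib sampling provides. Microbiomes are logistic-normal: a latent
log-abundance vector (baseline profile SD 1.5, a shared per-animal
factor carrying 30% of the latent variance, unit noise) is softmaxed
and sampled as multinomial counts at fixed depth; an optional host
covariate shifts the latent means linearly — the simplest mechanism
that makes genome and microbiome non-independent for stress tests.
Phenotypes are the exact sum of stored fixed, pen, genomic, microbial,
interaction and residual components; variance parameters are scaled by
$\mathrm{tr}(K)/n - \bar K$, the expected realized sample variance per
unit parameter, which reduces to the mean kernel diagonal for the
grand-mean-zero kernels $G$ and $M$ but is also correct for the
Hadamard kernel whose grand mean is not zero. All streams derive from
one root seed by named substreams (`genotypes`, `otu:<stage>`,
`phenotypes`), so each component is reproducible in isolation.

What the generator does *not* emulate: linkage disequilibrium,
multi-generation pedigrees, realistic taxonomy, sequencing error, or
the weight-stratified subsampling of 4–5 pigs per pen used when only
part of a pen is sequenced (the simulator generates microbiomes for all
animals; subsetting is left to the caller). Passing tests on these data
therefore demonstrate correctness of the machinery, not performance on
real microbiomes.

## Problem sizes, identifiability, and known limitations

The recovery experiments fit M4 on 560 animals (28 families), 5,000
markers and 500 OTU with the 12,000/2,000/5 chain profile (about half a
minute per fit on one core); the model-ordering experiments use 560
animals, 2,000 markers and 150 OTU. The OTU count in the ordering
experiment is chosen so the microbial signal is learnable at this
sample size: the accuracy of kernel regression on $q$ independent
features scales like $n\,m^2 / (n\,m^2 + q)$, and 1.7k OTU at $n = 560$
would leave any model contrast buried in shrinkage. The recovery
population uses two pens of 10 per sire: with a single pen per sire the
pen effect and the family-mean genomic effect would be exactly
confounded and the pen fraction meaningless.

A limitation that users of linkage-free half-sib simulations should
know: $G$ of such a population is close to $0.75\,I$ plus 0.25 times
family blocks, because realized-relationship deviations are
$O(1/\sqrt{\text{markers}})$. The within-family additive variance is
then nearly unidentifiable from the residual (and from the
diagonal-dominant Hadamard kernel), and the posterior mean of $h^2$ is
pulled toward the other fractions — on these data M4 typically returns
$\hat h^2 \approx 0.16$ for a planted 0.30 while $m^2$, pen and
residual fractions are recovered well. We verified this is the exact
posterior, not a sampler artifact: an independent random-walk
Metropolis on the marginal likelihood of the variance components
reproduces the Gibbs means, a linear mixed model with explicit sire and
pen terms recovers the realized family and pen variances of the same
data, and the sampler itself matches the closed-form mixed-model
solution to $10^{-3}$ when variances are fixed. The same geometry keeps
the null posterior mean of $i^2$ near 0.15: trading residual for
interaction variance along a nearly diagonal kernel costs little
likelihood, and the ridge volume (not the prior — halving the prior
degrees of freedom moves the means by under 0.03) dominates the
posterior mean. With real genotypes, linkage makes $G$ informative at
all levels and these fractions are far better identified; estimates of
$i^2$ from diagonal-dominant interaction kernels deserve caution
everywhere.

Numerical choices collected in one place: kernel symmetry enforced to
$10^{-10}$ and PSD to $-10^{-8}$; eigenvalues below $10^{-10}$
truncated; zero-variance OTU columns dropped and reported; collinear
scan features get `NA` p-values rather than silent zeros; empty
informative selections raise a typed condition that cross-validation
records as a not-estimable cell; the residual vector is recomputed every
2,000 sweeps to cap floating-point drift; all "lower than" thresholds
remove strictly-below values, keeping boundary cases.
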