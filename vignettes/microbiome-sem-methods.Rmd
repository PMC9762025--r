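---
title: "Methods: a recursive structural equation model for microbiome-mediated genetic effects on growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a recursive structural equation model for microbiome-mediated genetic effects on growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the model answers

When a gut microbe's abundance is associated with an animal's growth, the
association mixes two very different things: a causal effect of the microbe on
the host, and a shared host-genetic background that shapes both the microbiome
and growth. A multiple-trait mixed model captures the correlation but cannot
say which part is causal. microsem implements a three-trait *recursive*
structural equation model (SEM) that separates them, treating one OTU
(operational taxonomic unit) abundance at a time as a mediator between host
genetics and growth.

The three traits, in fixed order, are ADG_AL (average daily gain under ad
libitum feeding, g/day), ADG_R (average daily gain under restricted feeding —
a proxy for feed efficiency, since intake is fixed), and M (the OTU's
CSS-normalized abundance). Each animal records M and exactly one growth trait,
depending on the feeding regime it was assigned to at weaning; the other
growth trait is missing by design.

## Model

For $n$ animals, stacking the three trait vectors into $\mathbf y$:

$$
\mathbf y = (\boldsymbol\Lambda \otimes \mathbf I_n)\,\mathbf y
 + \mathbf X\mathbf b + \mathbf Z_l\,\mathbf l + \mathbf Z_c\,\mathbf c
 + \mathbf Z_u\,\mathbf u + \mathbf e,
\qquad
\boldsymbol\Lambda = \begin{pmatrix} 0 & 0 & \lambda_{AL}\\
0 & 0 & \lambda_{R}\\ 0 & 0 & 0\end{pmatrix},
$$

where $\lambda_{AL}$ and $\lambda_R$ are the structural coefficients — the
expected change in each growth trait (g/day) per one-unit increase in
CSS-normalized abundance, holding genetics and environment fixed. The
systematic effects $\mathbf b$ are the batch-farm combination (5 levels) and
the weaning-weight class (2 levels). Litter effects $\mathbf l$, cage effects
$\mathbf c$, genomic effects $\mathbf u$ and residuals $\mathbf e$ are
Gaussian with 3×3 covariance matrices $\mathbf L_0$, $\mathbf C_0$,
$\mathbf G_0$, $\mathbf R_0$; genomic effects are correlated across animals
through the genomic relationship matrix $\mathbf G$
($\mathbf u \sim N(\mathbf 0, \mathbf G_0 \otimes \mathbf G)$). $\mathbf R_0$
is *diagonal*, which is what makes the recursive structure identifiable: with
uncorrelated residuals, the only way the mediator can share non-genetic,
non-environmental signal with growth is through $\lambda$.

Because the structure is acyclic, $(\mathbf I - \boldsymbol\Lambda)$ is
unit-triangular, and solving for $\mathbf y$ gives an ordinary multiple-trait
animal model (the *reduced model*) whose covariance matrices are the starred
transforms

$$
\boldsymbol\Theta_0^{*} = (\mathbf I_3-\boldsymbol\Lambda)^{-1}\,
\boldsymbol\Theta_0\,(\mathbf I_3-\boldsymbol\Lambda)^{-\top},
\qquad \boldsymbol\Theta_0 \in \{\mathbf L_0, \mathbf C_0, \mathbf G_0, \mathbf R_0\}.
$$

Expanding the genetic block gives the quantities the package reports: the
total genetic variance of a growth trait $t$ splits exactly into a direct part
$\sigma^2_{u,t}$ and a microbiota-mediated part
$2\lambda_t\,\sigma_{u,t,M} + \lambda_t^2\,\sigma^2_{u,M}$; the total genetic
covariance of $t$ with M splits into $\sigma_{u,t,M}$ (direct) and
$\lambda_t\,\sigma^2_{u,M}$ (mediated); and the growth–growth covariance
carries the mediated term
$\lambda_{AL}\sigma_{u,M,R} + \lambda_R\sigma_{u,M,AL} +
\lambda_{AL}\lambda_R\sigma^2_{u,M}$. These identities hold per draw, exactly,
and the package asserts them (`reduced_model_check()`): the scalar expansions
and the matrix transform must agree to machine precision.

Heritabilities are reported in two flavours: *direct* uses the unstarred
components, $h^2_t = \sigma^2_{u,t} / (\sigma^2_{u,t} + \sigma^2_{l,t} +
\sigma^2_{c,t} + \sigma^2_{e,t})$, and *total* applies the starred transform
to every component first. The two differ whenever mediation is active; direct
heritability exceeds total heritability when the mediated genetic effect
opposes the direct one.

## Inference

The posterior is sampled by Gibbs (`fit_sem()`), with the compute-heavy
kernel in C++:

1. **Data augmentation.** The structurally missing growth trait of each
   animal is drawn from its residual conditional. This keeps every covariance
   full conditional balanced, and is valid exactly because $\mathbf R_0$ is
   diagonal.
2. **Location blocks.** For each growth trait, the fixed effects and the
   structural coefficient are drawn *jointly* from their multivariate-normal
   full conditional (the mediator enters as one more regressor column). They
   share the mean structure, so blocking them removes the dominant posterior
   correlation; with scalar $\lambda$ updates the effective sample size of
   $\lambda$ was roughly half of what the blocked update achieves. Litter and
   cage effects are drawn as independent 3×3 blocks; genomic effects are
   drawn in the eigenbasis of $\mathbf G$, where their full conditional
   factorizes into $n$ independent 3×3 Gaussians — one eigendecomposition per
   dataset, $O(n^2)$ per sweep.
3. **Covariance matrices.** $\mathbf L_0, \mathbf C_0, \mathbf G_0$ from
   inverse-Wishart full conditionals (the genomic one weighting cross-products
   by inverse eigenvalues), residual variances from scaled inverse
   chi-square.

Priors are proper and weakly informative: inverse-Wishart with 5 degrees of
freedom and scale `diag(0.5 × empirical trait variances)` for the three
random-effect matrices, scaled inverse chi-square (df 4, scale 0.5 × empirical
variance) per residual, flat priors for fixed effects and structural
coefficients. Posterior results for the variance components are therefore
prior-sensitive at $n \approx 400$ — a sensitivity worth reporting in any
application, not assuming away. The flat priors can be replaced by Gaussian
ones through `sem_chain_config(prior_var_b=, prior_var_lambda=)`; the test
suite uses that option for a Geweke-style joint-distribution check
(alternating parameter and data simulation must leave the prior invariant),
which validates every full conditional jointly and requires proper priors.

Chains are bit-reproducible given `seed`. The default configuration is a
desk-scale chain of 20,000 iterations (5,000 burn-in, thinning 10), sized so
that one OTU fits interactively; a production configuration of
1,000,000/300,000/100 is available through the same object. Significance
follows the 95% highest-posterior-density rule: a coefficient is declared
different from zero when its HPD interval (shortest window over the sorted
draws, ties broken to the lowest start) excludes zero. Relevance is a separate
magnitude call: |posterior mean / phenotypic SD| ≥ 0.2. The phenotypic SD used
for standardization defaults to the observed SD of the trait and can be
overridden, since a model-based SD is equally defensible and the two differ in
the second decimal.

## Preprocessing choices

- **OTU filtering** removes features detected in fewer than 5% of samples or
  contributing less than 0.01% of the grand count total. Both thresholds are
  *strict-less-than* removal rules, so values exactly at a threshold are
  retained, and the abundance share is computed against the grand total of
  all counts — the only unit-free reading.
- **CSS normalization** divides each sample's counts by the cumulative sum of
  its counts up to the median (quantile 0.5) of its positive counts, then
  rescales by the median scaling factor so values stay count-like. The
  adaptive quantile search of the original CSS method is deliberately not
  reproduced — the fixed 0.5 quantile makes the transform deterministic and
  auditable. Whether abundances should additionally be log2-transformed is
  genuinely open (published CSS units are sometimes logged, sometimes not);
  both are supported, the scale is recorded in the dataset metadata, and the
  default is untransformed.
- **ADG** is the within-animal OLS slope of weekly body weight on age, g/day.
- **SNP QC** applies, in order: individual call rate > 0.90, SNP call rate
  > 0.95, MAF > 0.05 (computed after individual removal, matching PLINK's
  sequential behaviour), autosomal SNPs with known positions only. The GRM is
  VanRaden method 1 with observed allele frequencies — the construction most
  likely behind any unstated "genomic relationship matrix" in this field —
  blended with 1% identity so the sampler's eigendecomposition is always
  positive definite; the blend weight is recorded in the output.

## The synthetic population

`simulate_population()` generates the study conditions end to end: ~400
animals in ~195 litters and ~189 cages across 5 batch-farm levels and two
weaning-weight classes, genotypes as binomial dosages with allele frequencies
Uniform(0.05, 0.5) feeding the same VanRaden GRM code used for real data,
random effects drawn from their Kronecker covariances, traits built in
generative order (M first, then each growth trait with its $\lambda$ times M),
a random 50/50 regime assignment, and structural masking of the unobserved
growth trait. Litters never contribute more than two animals to one cage,
matching the husbandry rule that prevents confounding of cage and maternal
effects. The default truth mirrors the study's scale: growth-trait phenotypic
SDs near 5–6 g/day, genetic correlation 0.59 between the growth traits,
mediator heritability ≈ 0.15, batch means spanning a few g/day.

Two deliberate simplifications:

- The generator emits abundances directly on the continuous CSS-like scale;
  it does not simulate sequencing counts, so count-level zero inflation and
  library-size noise are outside what passing tests demonstrate.
- The default truth sets the litter–M and cage–M covariances to zero. With at
  most two animals per litter and cage, those covariances are not separable
  from $\lambda$ — in replicate experiments a litter–M covariance of 0.05
  inflated the posterior mean of $\lambda$ by ≈ 0.1–0.2 at $n = 600$. This is
  a real limitation of the design, not of the sampler: an environmental
  factor that affects both the mediator and growth within cages is
  confounded with the causal path. The genetic covariances, which *are*
  identified through the relationship matrix, default to nonzero
  (corr 0.2 with M).

## Validation suite and problem sizes

The tests exercise, at sizes chosen to keep the full suite in minutes:
algebraic equivalence of the scalar decomposition and the matrix transform on
1,000 random PD matrices (≤ 1e−10); a degenerate-model check where all
random-effect covariances vanish and the posterior mean of $\lambda_R$ must
match the closed-form OLS coefficient within Monte-Carlo error (run with a
small covariance prior scale, so the fit actually operates in the degenerate
regime); null coverage of the $\lambda$ HPD over 200 replicates at $n = 300$
(chains of 2,500, observed ≈ 0.95–0.98); recovery of $\lambda_R = 1$ over 20
replicates at $n = 600$ (chains of 6,000); generator self-consistency — the
empirical phenotype covariance of 20,000 simulated unrelated animals must
match the starred totals within 2%; and the VanRaden large-SNP limit (mean
GRM diagonal 1.00 ± 0.05 from 5,000 HWE SNPs on 200 animals). The Geweke
check runs 4,000 successive-conditional cycles on a 30-animal model and
compares quartiles, not moments — inverse-Wishart moments barely exist at
these degrees of freedom.

## Numerical notes and edge cases

- `hpd_interval()` needs ≥ 20 draws; constant chains give zero-width
  intervals; `effective_sample_size()` uses Geyer's initial-positive-sequence
  truncation and reports a degenerate warning for constant chains.
- The sampler raises descriptive errors for non-PD full-conditional matrices
  (with the iteration number) and aborts when any variance crosses an
  overflow guard of 1e12, advising stronger priors.
- All-zero OTU tables, samples with zero CSS scaling factors, monomorphic
  SNP panels and all-missing SNPs are rejected with named diagnostics rather
  than propagating NaNs.
- Per-OTU study loops derive each OTU's chain seed deterministically from the
  base seed and the OTU id, so subsets and resumed runs reproduce the full
  run row for row.

## Known limitations

- One mediator at a time: interactions among OTUs, or joint mediation, are
  out of scope, as are non-recursive (feedback) structures and estimation of
  residual covariances — the latter is the identifiability price of the
  recursive model.
- No multiple-testing adjustment across OTUs: the per-OTU HPD rule is the
  decision criterion, by design.
- Litter/cage–mediator confounding, discussed above.
- Mixing on the structural coefficients is the slowest direction of the
  chain: desk-scale runs yield an effective sample size of a few tens to ~100
  per thousand saved draws at study size ($\lambda$ is entangled with the
  genetic covariances). Chain length, not problem size, is the lever; the
  production configuration yields effective sizes an order of magnitude
  larger. Posterior means of $\lambda$ also overshoot by roughly 10% at
  $n = 600$ when genetic covariances with the mediator are present, because
  those covariance components are themselves shrunk toward zero and the
  structural coefficient absorbs the remainder.
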