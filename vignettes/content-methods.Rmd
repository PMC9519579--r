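---
title: "Multi-context genetic prediction of expression: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-context genetic prediction of expression: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multi-context expression studies — multi-tissue bulk RNA-seq, or
cell-type-resolved single-cell panels — measure the same individuals
repeatedly. Expression of a gene in context $c$ for one individual is
modelled as

$$E_c = \mathbf{g}\boldsymbol\beta + \mathbf{g}\boldsymbol\gamma_c +
\varepsilon_c,$$

a context-shared cis-genetic component $\mathbf g\boldsymbol\beta$, a
context-specific component $\mathbf g\boldsymbol\gamma_c$, and noise
$\varepsilon_c$ that is *correlated across contexts within an individual*
(shared environment, library effects, cellular composition). Methods that
model each context separately ignore this correlation and conflate shared
with specific effects; joint penalized fits borrow strength but still return
a single mixed predictor per context. This package builds separate
predictors for the shared and specific components and recombines them, so
that downstream analyses (association testing, context fine-mapping) can
attribute signal to the right level.

## Decomposition

After residualizing on per-context covariates (`residualize()`) and
centering/scaling each gene-context vector to mean 0 and *population*
variance 1 (`center_scale()`; the $\tfrac1I\sum E^2 = 1$ convention keeps the
decomposition's variance bookkeeping exact), the observed value decomposes
into the individual's mean over their observed contexts and the deviation
from it:

$$E_{ic} = \underbrace{\bar E_{i\cdot}}_{\text{shared}} +
\underbrace{(E_{ic} - \bar E_{i\cdot})}_{\text{specific}}.$$

The two parts are orthogonal, reconstruct the input exactly at every
observed entry, and the specific parts of one individual sum to zero —
these identities are asserted to 1e-10 in the test suite. Averaging over
$k$ contexts shrinks the shared component's noise variance by roughly
$\sigma^2(1+\rho(k-1))/k$, so the decomposition converts intra-individual
noise correlation $\rho$ into cleaner specific components: as $\rho$ grows,
$(1-\rho)\sigma^2$ is all that remains in the deviations. Missing contexts
are handled by taking each individual's mean over observed contexts only
(unbiased under missingness that is unrelated to expression, and the only
choice that preserves the zero-sum identity). Individuals observed in a
single context carry a specific deviation of exactly zero; they still
contribute to the shared fit, which keeps its sample size maximal.

`decompose_expression()` optionally extracts an intermediate *group-shared*
level (e.g. a brain-tissue group): the individual's mean over the group's
observed contexts minus the overall shared value, with the specific
deviation then taken relative to shared + group. A group with fewer than
two contexts is collapsed, since its group component would be
indistinguishable from a specific one.

## Component predictors and the full model

Each component is regressed on cis genotype dosages with an elastic net
(`glmnet`, mixing parameter $\alpha = 0.5$, the convention of the TWAS
weight-training lineage; exposed as an argument). Honest out-of-fold
predictions come from one of two cross-validation modes:

* `cv = "nested"` — an outer 10-fold split yields predictions from models
  never trained on the predicted fold, with an inner 10-fold CV selecting
  the penalty inside each outer training split; a whole-data refit at the
  whole-data CV penalty gives export weights.
* `cv = "preval"` — `cv.glmnet(keep = TRUE)` prevalidation: the same
  per-fold honesty for the *predictions*, with the penalty selected once on
  the pooled CV curve. This is the default in the study drivers because it
  is an order of magnitude cheaper at simulation scale; the nested mode is
  available everywhere and used in the unit tests.

Genotypes are standardized internally during fitting; exported weights are
on the dosage scale. The per-context *full* model is an ordinary least
squares recombination of the two out-of-fold component predictions,

$$E_c = \alpha_c + \hat E^{\text{shared}} w^{\text{sh}}_c +
\hat E^{\text{specific}}_c w^{\text{sp}}_c + \varepsilon,$$

fit on out-of-fold predictions to prevent leakage. Because the specific
component is a *deviation*, its predictor can track the observed expression
with the wrong sign; the regression weight $w^{\text{sp}}_c$ re-signs and
re-scales it. Each context then exports a single combined weight vector
$w^{\text{sh}}_c\hat{\boldsymbol\beta} +
w^{\text{sp}}_c\hat{\boldsymbol\gamma}_c$.

Significance per model is a Gaussian profile-likelihood ratio test of the
observed component against its out-of-fold prediction,
$n\log(\mathrm{RSS}_0/\mathrm{RSS}_1)$ on 1 df (2 df for the full model,
dropping to 1 when a component predictor is constant), with the
intercept-only null. Model comparison uses the cross-validated adjusted
$R^2$, $1-(1-R^2)(n-1)/(n-p-1)$ with $R^2$ the squared correlation;
`select_best_model()` breaks exact ties toward the model with fewer
predictors, then lexicographically. Whether the full model's test should
use out-of-fold or refit predictions is genuinely open; out-of-fold keeps
the null calibration exact, so that is the choice here.

## Baselines

The *context-by-context* baseline fits the same elastic net independently
to each context's observed expression. The *joint group-LASSO* baseline
minimizes

$$\sum_c \frac{\mathrm{RSS}_c}{2 n_c} + \lambda \sum_m \lVert
B_{m\cdot}\rVert_2$$

so that a SNP's coefficients across contexts are jointly zero or active.
It is a reimplementation of the published objective of the joint
multi-tissue approach it stands in for, not a wrapper of that software; the
$1/(2n_c)$ weights balance unequal context sample sizes, and individuals
missing from a context simply drop out of that context's loss. The solver
is block coordinate descent over SNP rows (Rcpp): the per-row subproblem
with unequal curvatures $a_c$ has stationary point
$b_c = z_c/(a_c + \lambda/\lVert b\rVert)$, solved by safeguarded bisection;
convergence is declared when the largest coefficient change in a sweep
falls below 1e-6 (1e-4 inside CV folds), capped at 10^4 sweeps with the
best iterate returned and flagged otherwise. The penalty path is 15
log-spaced values from $\lambda_{\max}$ (the smallest penalty with an empty
model) down to $0.05\,\lambda_{\max}$, chosen by 5-fold CV with folds
assigned at the individual level so a person is held out of every context
at once. At $\lambda = 0$ the solver reproduces per-context OLS and with
one context it matches a plain LASSO — both are asserted against
independent solvers in the tests.

## Hierarchical FDR

Leaf p-values live on a gene → context → model tree: a context node
aggregates its models' p-values by Simes ($\min_k p_{(k)} K/k$, valid under
the positive dependence typical of tests sharing genotypes; Fisher's
product would not be), and a gene node aggregates its context nodes the
same way. Selection is Benjamini–Hochberg at level $q$ on gene p-values;
within selected genes, BH on context p-values at the multiplicatively
adjusted level $q R_1/G$; within selected gene-contexts, BH on leaf
p-values at that level further scaled by the gene's context selection
fraction. The output is tree-consistent by construction, and the gene-level
FDR is verified at $q = 0.05$ under a 500-gene global null in the tests.
Because the method/model sits at the leaf level, predictors from different
methods can be pooled into one tree (`pool_methods()`) and corrected
jointly rather than competing in separate analyses.

## The simulation framework

`sim_config()` encodes the generative model used throughout: independent
cis SNPs with dosage $\mathrm{Bin}(2, p_m)$, $p_m \sim
\mathrm{Unif}(0.05, 0.50)$ (no LD, no rare variants); shared effects
$\beta_m \sim N(0, h^2/(M\pi))$ on a Bernoulli($\pi$) causal mask; specific
effects $N(0, h_c^2/(\lambda M \pi))$ on the shared-causal SNPs, plus
Poisson($\lambda$) truly specific eQTLs per specific context placed on
SNPs with no shared effect (the same effect-size law — no separate scale is
stated for them); equicorrelated noise with per-context variance
$1-h^2-h_c^2$ and off-diagonals $\rho\sigma_{c_1}\sigma_{c_2}$. Defaults
follow the GTEx-like design: 20 contexts, 500 SNPs, $h^2=0.3$,
$h_c^2=0.1$, $\pi=0.05$, $\lambda=1$, per-context sample sizes drawn
uniformly from 75–410 out of a common pool of 410, individuals not
observed everywhere.

Choices the generative description leaves open, fixed once here:

* **Component scale.** The genetic components are built from
  *column-standardized* genotypes, so that $\mathrm{var}(G\beta) = h^2$
  holds and the noise variance $1 - h^2 - h_c^2$ completes a unit total
  variance. With raw dosages the realized heritability would shrink by
  $E[2p(1-p)] \approx 0.46$ and the stated noise variance would no longer
  be complementary. The dosage matrices handed to the models remain raw;
  standardization at fit time is a modeling choice, made inside the
  fitting functions.
* **Effect-size denominator.** $M\pi$ is the *expected* causal count; the
  realized count varies per gene, so realized heritability varies too.
  This is deliberate (it matches the printed law); no per-gene rescaling
  is applied.
* **Which SNPs carry specific effects.** All shared-causal SNPs do
  ("subsampled" with rate 1, consistent with the $\lambda M\pi$ variance
  denominator at $\lambda = 1$), plus the Poisson additions.
* **Which contexts carry specific effects.** A random subset of size
  `frac_contexts_specific * C` per gene (default: all); the truly specific
  additions go to the same subset. The specific variance share is
  subtracted from the noise variance only in those contexts, keeping every
  context's total variance at 1.
* **Per-context variance.** Contexts in a brain-like group additionally
  receive $N(0, h^2_{\dot b}/(\lambda M\pi))$ effects on shared-causal
  SNPs, with the group share likewise removed from their noise.

For phenotypes (`phenotype_config()`), causal gene-context pairs are drawn
from genes with a nonzero genetic component, their true genetic expression
is standardized in the external cohort, and effect sizes are
$\delta \sim N(0, \sigma^2_{ge}/n_{\text{pairs}})$. The noise variance
defaults to $1-\sigma^2_{ge}$ so the total phenotypic variance is 1 with
genetic share $\sigma^2_{ge}$; the literal $1-\sigma^2_{ge}/n_{\text{pairs}}$
parametrization (which leaves the total slightly above 1) is available via
`literal_noise = TRUE`. In the TWAS power study the per-gene shared
proportion of expression heritability is drawn from $\mathrm{Unif}(0,1)$
and the external cohort (default 10000 individuals) is simulated gene by
gene from the training MAFs, which keeps memory flat in the number of
genes.

## Numerical choices

* Elastic-net paths use 50 log-spaced penalties down to
  $0.05\,\lambda_{\max}$ by default; the shipped simulation studies use 30–35
  to keep a single-CPU run affordable. The penalty is still selected by CV
  over the full grid in either case.
* Fold assignments are drawn from a seed derived deterministically from the
  study seed and the gene/component label, so retraining is bit-identical.
* A component fit whose selected weights are all zero is a valid "null
  model": its prediction is the intercept, its CV $R^2$ is defined as 0 and
  its LRT p-value is 1.
* Zero-variance gene-contexts are excluded at `center_scale()` with a
  recorded reason; constant covariate columns are dropped before
  residualization, collinear ones with a warning.
* Association Z-scores are capped at |40|; gene scoring is rank-based
  (max-|Z| and Mann–Whitney AUC), so the cap never changes a result.

## Study sizes shipped with the package

The packaged acceptance study (`scripts/acceptance.R`) runs the
prediction-accuracy design at 16 genes per noise-correlation setting
($\rho \in \{0, 0.3, 0.6\}$, 20 contexts, 500 SNPs) and the TWAS power
design at 40 genes (20 causal × 3 contexts, $\sigma^2_{ge} = 0.2$, external
cohort 10000, two heritability settings × two replicates). These sizes are
the package's choice of a desk-scale study: means over gene-context pairs
are stable at a few hundred pairs per setting, and a full run completes on
one CPU in well under half an hour. The unit-test suite uses smaller
configurations still, chosen to exercise every code path rather than to
estimate effect sizes precisely.

## What the simulations do and do not show

The generator reproduces the sampling structure that motivates the method —
repeated measures with correlated noise, sparse shared-plus-deviation
genetic architecture, uneven per-context sample sizes — but not linkage
disequilibrium between cis SNPs, rare variants, trans effects, or
expression count noise; genotype effects are strictly additive and linear.
Passing the packaged studies therefore demonstrates correctness of the
estimators and orderings *under the assumed model*, not performance on any
particular real cohort. In real data the decomposition additionally
depends on covariate residualization quality, and the specific components
of lowly sampled contexts can be dominated by measurement noise.
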