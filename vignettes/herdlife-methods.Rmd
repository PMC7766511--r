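---
title: "Random regression genetic evaluation of cattle longevity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random regression genetic evaluation of cattle longevity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdlife)
```

## The problem

Longevity in beef cattle is usually measured as the time a cow stays in
the herd after her first calving. It is sex-limited, expressed late in
life, and shaped by culling decisions that mix genetically distinct
causes: death from old age, structural breakdown, disease, reproductive
failure, poor performance, or no recorded reason. `herdlife` treats
longevity as a longitudinal binary trait — one record per cow per year of
age from 2 to 15 (14 age classes) — and estimates how the genetic basis
of staying in the herd changes with age.

Three codings of the yearly records are supported. Traditional longevity
(TL) codes 1 while the cow is alive and 0 after culling, so it measures
survival regardless of productivity. Functional longevity requires a
calving: FLa codes 1 only for ages with an assigned calving and 0
otherwise, treating "alive but not calving" identically to "culled";
FLb distinguishes them, coding 0 only after culling and a missing value
for alive-without-calving ages. Missing FLb cells are excluded from the
likelihood entirely, which is equivalent to integrating them out under
the Gaussian working likelihood.

### Age conventions

The yearly slot of an event uses completed years: a cow culled at 5.6
years was alive at age 5, so TL is 1 through age 5 and 0 from age 6. A
calving at $m$ months is assigned to slot $\mathrm{clamp}(\lfloor m/12 +
0.5\rfloor, 2, 15)$. No standard defines how fractional ages map onto
the 14 yearly slots, so these conventions are declared here and applied
consistently by the trait builder, the quality control, and the
simulator. One consequence worth noting: a 30-month first calving (the
upper edge of the admissible window) rounds to the age-3 slot.

### Quality control

Edits are applied in a fixed order so the removal counts in the QC
report are reproducible: (1) records missing birth date, herd, culling
reason or culling date; (2) cows with more than one culling record; (3)
cows born before 1990; (4) first calving outside 19–30 months; (5)
culling age above 20 years. Cows culled above 15 years are reassigned to
the natural-death group (culling "due to age") before any group
counting; unknown-reason cows under 15 fall to miscellaneous.

## The model

For observation $y_{ij}$ of cow $i$ at age $j$ (a 0/1 code, analyzed with
a linear working likelihood):

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Hq} + \mathbf{Za} + \mathbf{Wp} + \mathbf{e}$$

Every effect is a regression on normalized Legendre polynomials
$\phi_n(x) = \sqrt{(2n+1)/2}\,P_n(x)$ of the standardized age
$x_j = -1 + 2(j-2)/13$. "Order $k$" means polynomial degree $k$, hence
$k+1$ coefficients per effect level; orders 2–4 are the ones evaluated
for longevity. The fixed part carries an embryo-transfer contrast and
one regression curve per year-season of birth (two six-month seasons;
the herd-year-season label is herd × birth year × season). The random
parts are coefficient vectors per herd-year-season level
($\mathbf{q} \sim N(0, R_q \otimes I)$), per animal
($\mathbf{a} \sim N(0, G_0 \otimes A)$, with $A$ the pedigree
relationship matrix) and per cow for the permanent environment
($\mathbf{p} \sim N(0, R_p \otimes I)$). The residual variance is either
a single class or one class per age (14 classes per trait).

Multiple-trait fits stack the per-trait covariate matrix
block-diagonally; a cow recorded for one trait only (the culling-reason
analyses) still carries coefficients for all trait blocks, coupled
through the multi-trait $G_0$. Between-trait residual covariances are
fixed at zero — traits are never co-recorded in the five-trait
culling-reason layout, and this keeps the residual conditionals
univariate.

### Priors

* Fixed effects: Gaussian with variance $10^{10}$ (vague).
* $R_q, G_0, R_p$: inverted Wishart IW($\nu$, $V\nu$) with $\nu = 3$.
  The scale $V$ is a "basis-scaled identity": $V = c\,I$ with $c$ chosen
  so the grid average of $t_j' V t_j$ equals a share of the phenotypic
  variance — shares 0.1 (herd-year-season), 0.3 (additive), 0.2
  (permanent environment). These weakly-informative scales keep the
  prior's age-variance profile on the phenotypic scale without
  dominating the data.
* Residual classes: scaled inverse chi-square with $\nu_e = 3$ and scale
  0.4 of the phenotypic variance.

### Gibbs sampler

Location effects are sampled block-by-block — all coefficients of one
level jointly — which mixes far better than scalar updates for
regression coefficients; the additive block's prior precision couples
animals through $G_0^{-1} \otimes A^{-1}$, visited animal-by-animal with
the sparse neighbor sums. Covariance matrices are drawn from their
inverted-Wishart full conditionals (the additive scale matrix uses
cross-products through $A^{-1}$), residual classes from scaled inverse
chi-square conditionals. The sampler is compiled (RcppArmadillo) with
its own seeded generator, so a chain configuration and seed reproduce
retained draws exactly. Default desk-scale chains are 20,000 cycles with
10,000 burn-in and thinning 10; production chains for national data
would be an order of magnitude longer (e.g. 500,000 / 250,000 / 10) and
are available through `chain_config()`. A failed Cholesky of a sampled
covariance stops the run with iteration diagnostics — there is no silent
positive-definiteness repair.

### Model comparison

The per-cycle conditional Gaussian deviance given all location effects
is recorded; DIC $= D(\bar\theta) + 2 p_D$ with $p_D = \bar D -
D(\bar\theta)$, the deviance at the posterior means of all parameters.
Because the deviance is conditional (the working-likelihood choice for
linear-on-binary models), DIC magnitudes are comparable between models
fitted to the same data but not to values computed under a marginal
likelihood. Posterior model probabilities use
$\mathrm{PMP}_s = \exp(-\Delta_s/2)/\sum_r \exp(-\Delta_r/2)$ with
$\Delta_s$ the DIC excess over the best model, computed after
subtracting the minimum so huge DIC gaps cannot overflow; the lowest-DIC
model always has the highest PMP. Negative $p_D$ is reported with a
flag, never clipped. Convergence is checked with the Geweke diagnostic
(first 10% vs last 50% of the chain, spectral-density-at-zero standard
errors estimated via an AIC-selected autoregression); the
Heidelberger–Welch procedure is not implemented — only Geweke is
provided natively.

## Genetic parameters

Age-wise covariance matrices come from the congruence transform
$\phi = T R_q T'$, $\Sigma = T G_0 T'$, $\theta = T R_p T'$ (with the
block-diagonal $T$ for multi-trait fits). Heritability at age $j$ is
$h^2_j = \sigma^2_{a_j}/(\sigma^2_{a_j} + \sigma^2_{q_j} +
\sigma^2_{p_j} + \sigma^2_{e_j})$. Posterior SEs of every derived
quantity come from applying the transform to each retained draw and
summarizing, not from a delta method. Genetic correlations use
$r_{jj'} = \sigma_{a_{jj'}}/\sqrt{\sigma^2_{a_j}\sigma^2_{a_{j'}}}$, the
same formula serving within-trait age pairs and between-trait blocks.
Windowed averages ("all ages" vs ages 3–12 inclusive) take the strict
upper triangle for square within-trait blocks (diagonal excluded) and
all entries for rectangular between-trait blocks; multi-block summaries
average per pair first, then grand-mean, which is the convention that
reproduces published table arithmetic.

## Selection metrics

EBVs over ages are $T\hat a_i$ at the posterior-mean coefficients.
Relative breeding values standardize the EBVs of a sire set at one age
to mean 100 and (sample) SD 5, the customary proof scale. Sires are
eligible for ranking if they have strictly more than 5 daughters with
records; the top fraction takes $\lceil f n \rceil$ ids ranked by EBV at
the selection age, ties broken by id for determinism. Expected daughter
longevity regresses an observed daughter metric (average culling age;
proportions alive at 6, 9, 12 years, all on completed years) on RBV by
OLS; prediction accuracy is the raw Pearson correlation between
predicted and observed values, with no adjustment for EBV reliability.
Top-vs-bottom comparisons report the percent difference with the top
mean in the denominator.

## The synthetic-data generator

The simulator produces exactly the structure the model assumes, which is
what makes parameter recovery a meaningful test:

* **Pedigree.** Founders of alternating sex; each generation mates every
  already-born female once to a service sire (a configurable share of
  available males, default 0.2 — bulls serve many cows) with a fixed
  number of offspring per mating. Only females receive life histories,
  since the trait is sex-limited.
* **True values.** Founder additive coefficient vectors are drawn from
  $N(0, G_0)$; descendants are the parent average plus a Mendelian
  deviation with covariance $(0.5 - 0.25(F_s + F_d))G_0$, so
  $\mathrm{Var}(\mathbf a) = G_0 \otimes A$ exactly. Permanent
  environment and herd-year-season vectors are iid from their
  covariances; year-season fixed curves and an embryo-transfer contrast
  complete the mean.
* **Responses.** In `gaussian` mode the continuous model response is
  emitted directly — this is the mode for exact recovery checks, because
  the fitted model matches the generator. In `binary` mode the latent
  response is thresholded: the cow is culled in the first year whose
  latent value falls below the threshold, the culling reason is drawn
  from a configurable distribution (defaults follow the mix reported for
  large North American Angus data: ~25% natural death, 4% structural, 1%
  disease, 26% fertility, 10% performance, 34% miscellaneous), the first
  calving age is uniform on 19–29 months (the 19–30 admissible window
  minus the month that would round past the age-2 slot and postdate an
  age-2 culling), and later calvings occur at alive ages with
  probability `plogis(1.5 + latent)`. The fitted model is still
  linear-on-binary, so binary-mode recovery is approximate by design;
  only gaussian mode is used for exact recovery tests. An optional
  coupling parameter lets culling reasons correlate with the additive
  level for multi-trait exercises; by default reasons are independent of
  the genetics, a deliberate simplification — nothing is claimed about
  the data-generating process of real culling.

What the simulator does **not** emulate: censoring (still-alive cows are
out of scope, as evaluations here keep only cows with culling
information), genomic marker data, non-Gaussian herd effects,
selection-driven missingness, or time trends in management. Passing
recovery tests therefore demonstrates correctness of the estimation
machinery under the model's own assumptions, not robustness to real-data
violations of them.

## Numerical choices and problem sizes

* Inbreeding is accounted for in $A^{-1}$ (Meuwissen–Luo recursion plus
  Henderson's rules); ignoring it biases variance components. Unknown
  parents are treated as unrelated founders, with no genetic groups.
* Pedigree pruning keeps ancestors up to 10 generations (shortest-path
  distance from a phenotyped descendant) and re-closes parenthood at the
  boundary.
* The test suite verifies the sampler against independent oracles: the
  dense tabular relationship matrix, a direct sparse mixed-model-equation
  solve at fixed variances, conjugate closed forms for the residual and
  inverse-Wishart updates, and gaussian-mode recovery of a constant
  heritability curve (scaled-identity coefficient covariances with
  residuals proportional to the squared basis row norms give an
  age-constant $h^2$, making the target unambiguous).
* Suite problem sizes are chosen for a single-CPU desk run: recovery uses
  ~150 cows / 300 pedigree animals with 4,000-cycle chains over 10
  replicates; model-structure selection uses ~120 cows with 3,000-cycle
  chains. The properties checked (credible-band coverage, DIC ordering)
  are scale-free, so these sizes trade only statistical sharpness, not
  validity.

## Known limitations

* The working likelihood is Gaussian on binary codes, as is standard for
  large-scale longevity RRM; threshold/probit versions and proportional
  hazards models are not implemented.
* DIC uses the conditional deviance; comparisons are within-data only.
* Prediction accuracies are raw Pearson correlations, not adjusted for
  EBV reliability.
* The multi-trait sampler fixes between-trait residual covariances at
  zero.
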