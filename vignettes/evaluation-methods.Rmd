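---
title: "Quantitative genetic evaluation with population structure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative genetic evaluation with population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qgtrial)
```

## The problem

Open-pollinated progeny trials are the workhorse of forest-tree breeding:
seed is collected from selected mother trees ("plus-trees"), offspring are
planted in randomized incomplete blocks with single-tree plots across a few
sites, and the resemblance among half-sibs identifies the additive genetic
variance. In many breeding bases — Norway spruce in southern Sweden being
the motivating case — the mothers descend from genetically differentiated
populations (marker-defined clusters such as CSE, RusBal, NPL, CEU, CSE-ALP
and ALP). Because each half-sib family belongs to exactly one population,
among-population mean differences masquerade as family resemblance: a model
that ignores the structure attributes that variation to the additive
genetic variance.

`qgtrial` fits the two standard alternatives side by side. **Model A**
omits any population term; **model B** adds a fixed population effect. The
package then quantifies what the choice does to heritability, genetic
correlations, population differentiation (Qst) and — via cross-validation —
to the accuracy of predicted breeding values.

## The model and its assumptions

The joint-site animal model is

$$y_{jklm} = \mu + P_l + S_j + B_{k(j)} + G_{m(l)} + SG_{jm(l)} + e_{jklm}$$

with fixed population $P_l$ (model B only), site $S_j$ and block-within-site
$B_{k(j)}$; random additive effects $G \sim N(0, \sigma^2_A A)$ over the
pedigree relationship matrix $A$; an optional site-by-additive interaction
$SG \sim N(0, \sigma^2_{SG} (I \otimes A))$; and residuals that are
homogeneous within a site and uncorrelated across sites (no tree grows at
two sites). A population-by-site fixed interaction is available behind a
flag but off by default; screening in trials of this design finds it
negligible for almost all traits.

Assumptions worth stating explicitly:

- **Strict half-sibs.** Open-pollinated progeny are treated as true
  half-sibs: fathers unknown, mutually unrelated, and unrelated to the
  mothers, so full-sib contamination or relatedness among pollen parents
  would inflate $\sigma^2_A$. No coefficient-of-relationship correction
  (such as dividing family covariance by 2.5) is applied; users can apply
  one by scaling the estimates if their material warrants it.
- **Founder mothers are unrelated and non-inbred.** No deeper pedigree is
  modelled. Inbreeding is nonetheless computed exactly (Meuwissen-Luo
  recursion) so arbitrary uploaded pedigrees are handled correctly.
- **Blocks are nested in sites** and stored as the pair (site, block).

For the *type-B* analysis the same trait at the two sites is treated as two
responses with a full 2x2 additive covariance (parameters
$\sigma^2_{a1}, \sigma_{a12}, \sigma^2_{a2}$) and site-specific residual
variances with zero cross-site residual covariance; for *bivariate*
trait-pair analyses the additive structure is the analogous 2x2 matrix over
traits and the residual is an unstructured 2x2 within tree, estimated on
jointly observed rows.

## REML machinery

Likelihood evaluations work on the sparse mixed-model equations
$C = W'R^{-1}W + \mathrm{blockdiag}(0, G^{-1})$ with $W = [X, Z]$. The
pedigree enters only through $A^{-1}$, assembled in one pass by Henderson's
rules with exact Mendelian-sampling variances; its log-determinant (needed
by the likelihood) is the sum of the log Mendelian-sampling variances. One
evaluation is one sparse Cholesky factorization, so fits with thousands of
equations take milliseconds per iteration.

Updates are Newton steps on the **average-information matrix**
$AI_{ij} = \frac{1}{2} (Q_i P y)' P (Q_j P y)$, where
$Q_i = \partial V / \partial \theta_i$ and $P$ is the REML projection —
every term is a handful of sparse solves. The score is obtained by central
finite differences of the exact restricted log-likelihood rather than from
trace terms: the traces require selected elements of $C^{-1}$, which cost
as much as a dense inverse without a Takahashi-style selected inversion,
whereas a likelihood evaluation is cheap; with steps of
$10^{-5} \max(|\theta_k|, 10^{-3}\,\mathrm{scale}_k)$ the score is accurate
to far below the convergence tolerance. Globalization is by monotone
step-halving: a proposed step is shortened until the log-likelihood does
not decrease, variances stay above their floor and every 2x2 covariance
block stays positive definite. The log-likelihood trace is therefore
non-decreasing by construction (and is stored on the fit for inspection).
This monotone-halving safeguard plays the role usually assigned to EM-REML
fallback iterations, with the same guarantee and less machinery.

Numerical choices:

- **Convergence**: relative log-likelihood change below `tol` (default
  `1e-8`) *and* relative parameter updates below `sqrt(tol)`; maximum 50
  iterations; a trust-region-style cap keeps any single step below half the
  parameter's magnitude or a fifth of its phenotypic scale.
- **Variance floor**: `1e-6` times the trait's phenotypic variance instead
  of allowing negative components; estimates ending on the floor are
  flagged `boundary` (Qst for weakly differentiated traits routinely pins
  $\sigma^2_G$ there). Covariances start at 0 so early steps do not commit
  to a correlation sign; boundary correlations of +-1 are approached from
  inside the cone rather than jumped onto.
- **Starting values**: half the phenotypic variance per variance component.
- **Fixed-effect coding**: treatment contrasts with the first level by
  lexical sort as reference; candidate columns are added in term order and
  dropped greedily when they do not increase rank, so aliased columns of
  *later* terms are dropped first, and a term losing all its columns (e.g.
  population perfectly confounded with site) is a named error.
- **Uncertainty**: the variance-component covariance is the inverse
  average-information matrix at the optimum; fixed effects get
  $(X'V^{-1}X)^{-1}$ from the same factorization. Derived parameters use
  the delta method with analytic gradients (checked against finite
  differences in the tests).
- **Wald tests** of fixed terms use denominator degrees of freedom
  $n - \mathrm{rank}(X)$. This residual approximation is anti-conservative
  when the tested term varies at the family level and families are few; it
  is adequate for the many-family designs this package targets, and no
  Kenward-Roger-style adjustment is attempted.
- **AIC** is $-2\ell_R + 2p_\theta$ with $p_\theta$ the number of variance
  parameters, for comparing covariance structures under a fixed mean model.

## Derived parameters

Per site, $h^2 = \hat\sigma^2_A / (\hat\sigma^2_A + \hat\sigma^2_e)$. The
site-by-additive interaction variance is *not* part of the denominator by
default: the per-site parametrization treats each site's phenotypic
variance as additive plus residual, which is the convention under which the
reference tables' printed components reproduce their printed
heritabilities; `include_interaction = TRUE` switches to the joint-site
convention.

$Q_{ST} = \hat\sigma^2_G / (\hat\sigma^2_G + 2\hat\sigma^2_A)$, computed
per site from a refit with population random and fixed effects reduced to
mean and block. The denominator uses twice the additive variance exactly as
written; classical half-sib Qst derivations sometimes account the
within-population variance differently, and we deliberately follow the
evaluation convention rather than re-deriving it.

Breeding values are $\widehat{EBV} = \hat\mu + \hat G (+ \hat P)$; the
population solution enters only under model B (reference population
contributes 0 by coding). Every pedigree member receives an EBV through
$A$, which is what lets cross-validation predict held-out trees from their
relatives. Per-population genetic correlations (when wanted) are obtained
by subsetting to one population and refitting, not by a grouped model.

## Cross-validation

`kfold_split()` assigns phenotyped trees to k random folds of near-equal
size (difference at most one), deterministically from a seed. The fold unit
is the individual tree by default: half-sib information then flows from
training relatives to test trees, which is precisely what gives pedigree
prediction its power (and what published analyses of this design report);
`by_family = TRUE` closes that channel for a stricter assessment. Per fold,
the model is refitted with the test trees' phenotypes withheld, EBVs are
predicted through the pedigree, and the Pearson correlation with the
withheld phenotypes is recorded. PA is the mean fold correlation with
standard error $\sigma/\sqrt{k}$; ACC divides PA by the *mean of the square
roots* of the per-fold heritabilities (not the square root of the mean).
The relative accuracy improvement is $100(ACC_B - ACC_A)/ACC_B$ — the
denominator is model B's accuracy, the convention under which the reference
study's printed improvement percentages are reproduced exactly from its
printed accuracies. ACC can exceed 1 in a replicate when a training fit
underestimates $h^2$; this is honest noise, not a bug. Cross-validation is
per site by default (reference reports are per trial); joint-site CV is
available by passing `site = NULL`.

## The synthetic-trial generator

`simulate_trial()` draws data from exactly the model family the estimators
assume, at a desk scale chosen to mirror a southern Swedish spruce progeny
trial while keeping a full pipeline run in seconds:
`spruce_preset()` uses 6 populations x 50 families x 10 offspring (3,000
trees) on 2 sites with 10 blocks each, and two traits:

- a growth-like trait (`DBH`): $\sigma^2_A = 300$, $\sigma^2_e = 600$
  (theoretical $h^2 = 0.33$), strong differentiation $Q_{ST} = 0.20$,
  cross-site additive correlation $r_B = 0.95$;
- a density-like trait (`DENS`): $\sigma^2_A = 1400$, $\sigma^2_e = 150$
  ($h^2 = 0.90$), weak differentiation $Q_{ST} = 0.04$, $r_B = 0.85$;
- additive correlation $r_a = -0.6$ between them (the growth/wood-quality
  trade-off), residual correlation $-0.2$; block variance about a tenth of
  the phenotypic variance; the second site shifted by about half a
  phenotypic SD.

The variance magnitudes and the $h^2$/Qst regimes are anchored to the
growth- and density-trait rows of the packaged reference tables; values the
reference material does not pin down (block variance, site shifts, the
exact $r_B$ and $r_a$ levels, 10 blocks per site) were chosen once as
field-realistic and are not tuned.

Population effects are drawn $N(0, \sigma^2_{pop})$ with
$\sigma^2_{pop} = 2\sigma^2_A Q/(1-Q)$, so the theoretical Qst is exact in
expectation; a fixed-means mode supports ordering tests. Every individual
carries one additive value per (trait, site) cell: founders from the factor
model $g_{t,j} = \mathrm{sd}_t(\sqrt{r_{B,t}} z_t + \sqrt{1-r_{B,t}}
w_{t,j})$ with $z$ and $w$ correlated $r_a$ across traits, offspring as
half mother plus a Mendelian deviation with 3/4 of the cell covariance.
Both the shared factor and the site deviations are inherited, so this is
distributionally identical to the classical additive-plus-interaction
(SG) formulation with $\sigma^2_{SG} = \sigma^2_A(1 - r_B)$; the package
therefore does not carry a second generator mode. One consequence of
differing per-trait $r_B$: the realized cross-trait correlation at one site
is $r_a(\sqrt{r_{B1} r_{B2}} + \sqrt{(1-r_{B1})(1-r_{B2})})$ — the
simulation truth reports this attenuated value and recovery is judged
against it. Blocks are filled by random assignment within site; true
alpha-design layouts are not generated.

What passing tests on these simulations does **not** show about real data:
the generator has no full-sib contamination, no pollen-parent relatedness,
no spatial autocorrelation within blocks, no selective mortality or
measurement instrument error, and its populations differ only in means
(not in within-population variances). Estimates on real trials inherit all
of those risks even when every synthetic check passes.

## Validation strategy and problem sizes

The test suite validates each stage against an independent route: the
relationship-matrix inverse against dense inversion (random pedigrees up to
500 individuals, inbreeding included), the animal-model likelihood against
the reparametrized family model on balanced half-sib data (the marginal
covariances coincide when $\sigma^2_f = \sigma^2_A/4$,
$\sigma^2_w = \sigma^2_e + 0.75\sigma^2_A$; agreement to $10^{-6}$, also
cross-checked against `lme4`), BLUEs/BLUPs against dense GLS formulas,
and the full pipeline by parameter recovery: 30 preset replicates for the
recovery means, 500 small replicates for the size of the population Wald
test, 3 replicates for the directional cross-validation contrast. Those
sizes keep the whole suite around ten minutes on one CPU while leaving the
Monte-Carlo error small enough for 3-SE assertions.

One row of the shipped reference table (Horeda, model B, TTangW) is
internally inconsistent as printed — its heritability cannot be obtained
from its variance components under any rounding of the inputs — and the
tests assert that this is the *only* row that fails the reproduction check
(see `?spruce_reference_estimates`).

## Known limitations

- No spatial (e.g. AR1xAR1) residual modelling, no dominance or epistatic
  relationship matrices, no genomic (marker-based) relationships, and no
  multivariate fits beyond two responses.
- The Wald denominator df approximation is liberal for few-family designs.
- Per-population correlation estimates come from subset refits, which
  discards cross-population information.
- The REML engine assumes every random structure is linear in its
  parameters (true for all models here); arbitrary user-defined covariance
  functions are out of scope.
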