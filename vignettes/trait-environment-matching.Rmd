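---
title: "Partitioning plastic, genetic and turnover contributions to trait-environment matching"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning plastic, genetic and turnover contributions to trait-environment matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitmatch)
```

## The scientific problem

Along an environmental gradient, community-average trait values usually
track the environment. Three processes can maintain that match: individual
plants adjusting their phenotype to where they grow (phenotypic
plasticity), heritable divergence among populations (genetic
differentiation, possibly amounting to local adaptation), and changes in
which species are present and abundant (species turnover). These operate on
very different timescales — within a growing season, over generations, and
over decades of community reassembly — so their relative sizes determine
how fast community traits can respond to environmental change.

`traitmatch` implements the three analysis layers needed to compare them in
one system:

1. a reciprocal-transplant variance partition separating plastic (E),
   genetic (G) and G×E contributions to intraspecific trait variation;
2. a decomposition of community-weighted-mean (CWM) trait turnover into
   species-turnover, intraspecific and covariation components;
3. within-site phenotypic selection estimates, used to test whether
   selection points toward the local CWM.

## The transplant partition model

The experimental template is two transects on a mountainside, each with
low, mid and high-elevation sites (nominally 715, 870 and 1,040 m a.s.l.).
Individuals from every site are planted back at all three elevations of
their own transect, randomized over four blocks per transplant site with
seven individuals per origin per block: 504 individuals in all.

Each trait, on its variance-stabilizing scale (square root for height, log
for leaf area and SLA), is modelled as

$$y = \mu + \alpha_{EL_O} + \beta_{EL_T} + (\alpha\beta)_{EL_O \times EL_T}
      + \tau_R + b_{R:EL_T:block} + \gamma\,\text{Init.biom} + \varepsilon$$

where $EL_O$ is the elevation of origin (genetic signal), $EL_T$ the
elevation of transplant (plastic signal), $R$ the transect, $b$ a block
effect nested in transect × transplant site, and Init.biom the
initial-biomass covariate that absorbs differences in starting size. With
sum-to-zero coding, a type III ANOVA gives each term's marginal sum of
squares — the increase in residual SS when that term alone is dropped — and
the plasticity share is

$$\%E = 100 \cdot \frac{SS_E}{SS_E + SS_G}.$$

The G×E interaction is the local-adaptation signal (home populations doing
better than foreign ones); it is reported in the table but excluded from
the ratio because it cannot be attributed to either source. The ratio is
undefined when both SS are zero and is then reported as `NA`, never coerced
to 0 or 100. It is invariant to rescaling the response, so the choice of
measurement units is immaterial.

### Design choices in the engine

**Fixed nested blocks.** The field-standard formulation treats block as a
random intercept with Satterthwaite degrees of freedom. This package
instead fits block as a *fixed* nested factor: the plasticity share only
needs the two marginal sums of squares for $EL_O$ and $EL_T$, which are
well defined in the fixed-effects fit, and the fixed-block F-ratios for the
remaining terms are then approximations rather than mixed-model tests.
REML/Satterthwaite machinery is deliberately out of scope. Because R's
formula-marginality rules assign the wrong degrees of freedom to a nested
fixed `R:EL_T:block` term, blocks are coded as an explicit within-cell
sum-to-zero contrast matrix (18 columns for 6 sites × 4 blocks), which is
orthogonal to every site-level term in balanced data and keeps all marginal
SS estimable in unbalanced data.

**Sum-to-zero contrasts everywhere.** Type III marginal tests are only
meaningful under this coding; the fitting function sets it internally so
the user cannot accidentally combine treatment coding with marginal SS.

**Type III = type I on balanced factorials.** This classical identity is
the correctness oracle used in the tests, with one caveat: it applies to
the purely factorial part of the model. A sampled continuous covariate is
never exactly orthogonal to the factors, so the oracle comparison is run on
fits without the covariate; `car::Anova(type = 3)` serves as an independent
cross-check on unbalanced fits including it.

**Survival.** Summer survival is analysed with a logit-link binomial GLM on
the same design; the type III analogue is the likelihood-ratio deviance
from dropping each term. Cells with all-identical outcomes are named in a
separation warning. A deviance-scale plasticity share can be computed from
this table and is documented as an analogue, not an ANOVA quantity.

**Post hoc comparisons** use estimated marginal means (`emmeans`): cell
predictions with the covariate at its grand mean, block contrasts at their
column means, other factors averaged with equal weights, and Tukey
adjustment of pairwise contrasts by default (configurable).

**Initial biomass** cannot be measured destructively before transplanting,
so it is predicted from morphology via bidirectional stepwise selection
starting at the intercept model. AIC is the default criterion; BIC is
available because AIC admits a spurious predictor with probability ≈ 0.16,
which matters when the candidate list is long.

**Exclusions.** Individuals dead over winter (transplant shock) are removed
before any analysis; summer deaths are excluded from trait and biomass
models but retained in the survival model. Deaths and missing traits make
the design unbalanced — precisely why the type III machinery is used.

## The CWM decomposition

For each site $j$, the specific CWM $\sum_i p_{ij} x_{ij}$ uses site-local
trait values (it carries ITV) and the fixed CWM $\sum_i p_{ij} \bar x_i$
uses gradient-wide species means (species turnover only). The
intraspecific series is their difference. Regressing each series on the
gradient and taking sums of squares yields the exact identity

$$SS_{specific} = SS_{fixed} + SS_{intra} + SS_{cov},$$

where the covariation term is defined as the remainder (twice the
cross-product of the fixed and intraspecific series against the gradient
model); it is negative when species turnover and intraspecific shifts
oppose each other. The ITV share $100 \cdot SS_{intra}/(SS_{intra} +
SS_{fixed})$ is computed on the gradient-*explained* components — the
"explanatory power" reading — with total-variance shares also reported.

Open choices, resolved as follows:

- **Species gradient-wide means** default to abundance-weighted means of
  the site-specific values (unweighted available), since a species' fixed
  trait should represent where it actually occurs.
- **Gradient model**: simple linear regression on the numeric gradient by
  default; a factor-coded one-way model is available for designs with few
  distinct gradient levels.
- **Missing site-specific values** where a species is present are a strict
  error by default; an opt-in policy substitutes the gradient-wide mean
  with a warning.
- **Two-site inputs** are accepted (the regression saturates, so explained
  equals total SS); shares are undefined and reported `NA` when the
  specific series has no variance.

## Selection analysis and the CWM-optimality check

Within each site, relative fitness is $w_i = W_i/\bar W$ with final dry
biomass among survivors as $W$; traits are standardized within site with
the sample (n−1) standard deviation. The selection differential is $S =
\mathrm{cov}(w, z)$ with significance from the Pearson correlation, and
gradients $\beta$ are the partial coefficients of the joint OLS fit of $w$
on all standardized traits. These satisfy $S = R\beta$ exactly, with $R$
the trait correlation matrix and $\beta$ the fitted coefficients — an
identity the tests assert at 1e-8 on every simulated replicate.

Standardization and relative fitness are computed *within* site because the
analysis is site-specific; a global option exists but is off by default.
Traits enter on the raw measured scale (standardization makes the scale
choice a convention; a transformed-scale switch exists). No multiplicity
adjustment is applied across the site × trait grid, matching the
per-cell reporting convention of selection tables.

The optimality check compares $\mathrm{sign}(S)$ with
$\mathrm{sign}(CWM - \text{population mean})$ per site × trait. Exact ties
are scored indeterminate and dropped from the consistency fraction. Both
inputs must be declared on the same trait scale; the function refuses
mismatched declarations rather than silently comparing incomparable
numbers.

## What the synthetic generator does and does not emulate

`simulate_transplant()` reproduces the statistical skeleton of the design:
the crossed origin × transplant grid within transects, blocks nested in
sites, additive plastic/genetic/G×E/transect/block effects on the
*transformed* trait scale (back-transformed for output, so the analysis
model is exactly additive and parameter recovery is well-posed), Bernoulli
survival on a logistic scale, and lognormal fitness whose true selection
gradients on within-site standardized traits are set by construction.
Optional switches add MCAR missing traits (mimicking plants with too few
leaves to sample) and a transplant-shock pre-filter.

Default magnitudes are the package's own choices, made once: residual SDs
of 1.0 (sqrt-mm height), 0.52 and 0.19 (log leaf area and SLA) are
realistic for a small understory herb and sized from the residual mean
squares typical of such experiments; the plastic low-to-high span is set
to one residual SD and the genetic span to 0.6 residual SD, so that the
expected plasticity share of a default study is ≈ 73% — plasticity
dominant but the genetic signal clearly detectable. Survival is highest at
mid-elevation (logit offsets −0.3/+0.5/−0.3 around an intercept of 1.4),
and fitness loads positively on height and leaf area and negatively on SLA.

What it does **not** emulate: spatial autocorrelation within blocks,
non-additive trait architecture, selection on unmeasured correlated
characters, demography beyond one season, and any dispersal or gene-flow
process. Passing tests therefore demonstrate that the *estimators* recover
known structure of this form — not that real data meet the model's
assumptions.

`simulate_community()` uses Gaussian niche responses for abundances and
linear intraspecific trends for site-specific traits; with zero slopes and
noise it collapses to a pure species-turnover community, the ground truth
for the zero-ITV tests.

## Numerical choices and degenerate inputs

- Marginal SS via QR refits on column-subsets of the model matrix; term
  df are rank differences, so aliased terms surface as 0-df rows flagged
  `NA` rather than fabricated tests.
- Abundance rows are renormalized to sum to 1; deviations beyond 1e-6 draw
  a warning, an all-zero row is an error.
- One transect (or no block replication) drops the corresponding term with
  a warning instead of failing; fewer than two elevation levels is an
  error.
- Zero-variance traits, all-equal survival outcomes, all-zero fitness and
  collinear gradient-model traits are rejected with the offending
  trait/cell/pair named.
- Simulations take one integer seed that fully determines the output;
  byte-identical reproduction is part of the test contract.

## Problem sizes used in the test suite

The suite favours many small, deterministic checks: the standard 504-record
design for model fits, 20-seed batches for the %E recovery medians
(pure-plastic ≥ 95%, pure-genetic ≤ 5%), 200 null simulations for the
type I error of the F test, 100 replicates of n = 300 for
selection-gradient recovery, and 500 replicates for p-value uniformity.
These sizes give stable pass/fail behaviour at conventional tolerances
while keeping the whole suite near ten seconds.

## Known limitations

- Fixed-block F-ratios approximate, and do not reproduce, mixed-model
  (REML + Satterthwaite) tests; only the SS ratio underlying %E is claimed
  to be robust to that modelling choice.
- The deviance-scale %E for survival is an analogue, not an ANOVA result.
- The optimality check is a sign test; it does not estimate the distance
  of the selective optimum from the CWM.
- Quadratic (stabilizing) selection gradients are out of scope; only
  directional gradients are fitted.
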