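---
title: "Methods: quantifying selective migration with polygenic scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying selective migration with polygenic scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migsel)
```

## The problem

When migration is selective with respect to genotype — when people carrying
higher values of some polygenic score (PGS) move preferentially towards
cities — the geographic distribution of that score changes within a single
generation. Grouping individuals by **county of birth** (POB) reflects the
older spatial arrangement; grouping the same individuals by **county of
residence** (POR) reflects the arrangement after contemporary migration.
`migsel` measures the difference between the two and asks whether it is
driven by direct genetic effects rather than environmental confounding.

## The variance-partition statistic

For a variable $y$ (an adjusted PGS or a principal component) and a county
grouping, the package computes

$$\mathrm{Var}_{county} \;=\; \frac{SSB}{SSB + SSW},$$

where $SSB = \sum_c n_c(\bar y_c - \bar y)^2$ and
$SSW = \sum_c \sum_i (y_{ci} - \bar y_c)^2$. This is the fraction of
inter-individual variance explained by county differences, identical to the
$R^2$ of the one-way dummy-coded linear model (a property the test suite
asserts to $10^{-12}$). Significance comes from the one-way ANOVA F test;
the family-wise error is controlled by a Bonferroni correction with a
*declared* test count (by convention 100 when scanning PCs, 169 when
scanning PGSs), which may exceed the number of p-values at hand.

Whether POB and POR *jointly* explain more variance than either alone is
tested with a Gaussian likelihood-ratio chi-square comparing the two-factor
linear model against each single-factor model, with degrees of freedom equal
to the number of estimable dummy columns added. We chose the likelihood-ratio
(chi-square) form rather than an F test because the comparison is naturally
cast as nested Gaussian models; for the sample sizes involved the two are
indistinguishable. For the direct claim "POR explains more than POB" no
classical test applies (the two statistics are computed on the same
individuals), so the package offers a paired nonparametric bootstrap over
individuals (`varCountyDiffBootstrap()`, default 1,000 resamples) and reports
it alongside the joint-model rule; neither is claimed to reproduce any
particular published p-value.

## Adjustment

Every score is residualized by OLS on an intercept, sex, age, sex×age and
age², optionally the top $k$ principal components (default $k = 100$, capped
at the number supplied — PC computation itself is out of scope, PCs are
inputs), and optionally a *driver* score to be regressed out; residuals are
then standardized. Missing data are handled complete-case per operation with
dropped counts reported. Standardization constants come from the analysis
subsample unless a reference subsample is supplied (useful when contrasts
should be expressed in whole-cohort standard deviations). Adjustment is
idempotent and order-invariant, and residuals are orthogonal to every fitted
column to $10^{-8}$ after scaling — all asserted in the test suite.

## The sibling design

Full sibships are built from pairwise kinship estimates: pairs inside the
open window $0.177 < \hat\phi < 0.354$ are kept and sibships are the
connected components of the retained pair graph (the sib relation is treated
as transitive; the kinship source defines pairs, not clusters). Sibships are
then **harmonized by birthplace**: each sibship is partitioned by POB,
subgroups of two or more become sibships, and singletons are dropped because
their deviation from a size-1 mean is identically zero.

Within each sibship the sibship mean (including the individual) is
subtracted. Deviations are free of everything shared by the family —
ancestry, rearing environment, parental effects — so a nonzero
$\mathrm{Var}_{county}$ of deviations grouped by POR indicates direct
genetic association with migration.

Two numerical conventions matter here:

* Grouping deviations by POB must give zero *exactly*: every group is a
  union of whole sibships whose deviation sums vanish by construction.
  `siblingVarCounty()` detects label-homogeneous sibships and applies the
  identity ($SSB = 0$) instead of leaving it to floating-point cancellation.
* All-zero deviations would give $0/0$; the statistic is defined as 0 and
  flagged degenerate.

Because centered deviations are not exchangeable in the way plain ANOVA
assumes, significance uses a **simulation null**: each of $n_{sims}$
(default 10,140) draws assigns one standard-normal value per individual and
pushes it through the identical centering and grouping. The empirical
p-value is $(r+1)/(n_{sims}+1)$ with $r$ the number of null statistics
*strictly greater* than the observed one (ties are not exceedances; whether
to count them is genuinely ambiguous, and the strict rule is the
conservative-in-$r$ choice, documented here). The null depends only on the
sibship/label structure, so it is computed once and reused across all
scores. The test suite checks the rate of $p \le 0.05$ over 200 replicate
null datasets against its binomial tolerance.

## Migration taxonomy and contrasts

The country is divided into three areas: the two city areas and ORE ("other
regions"). At the *county* level a city area is its whole county; at the
*city* level only the city proper counts and city-county residents outside
it are excluded. Birth and residence areas combine into nine migration
groups, with moves inside one area collapsed to the stayer label. Group and
county means are reported with normal-theory 95% CIs and Z tests against
zero (sensible because the values are adjusted and standardized, so zero is
the cohort average), with Benjamini–Hochberg FDR within each family of
tests. Two-sample comparisons (destination contrasts by origin, birth-cohort
trends) use the unequal-variance (Welch-style) normal approximation — the
simplest defensible reading of a generic "Z-test" at these group sizes.
Birth-year bins are half-open $[lo, hi)$ with configurable edges; edge bins
may be wider so the oldest and youngest cohorts stay populated.

## Migration regression

The migration phenotype is defined only for the ORE-born: controls still
reside in ORE, cases reside in a city proper. Logistic models are fit at
three levels:

* population: $\mathrm{logit}\,P(Y_i = 1) = \alpha_0 + \beta\,PGS_i +
  d_i^T\zeta$, with sex and age as covariates (deliberately *not* the
  richer covariate set used for score adjustment — the two sets are
  configurable independently);
* within/between: the score enters as the within-sibship deviation and the
  sibship mean, $\beta_W (PGS_{ij} - \overline{PGS}_j) + \beta_B
  \overline{PGS}_j$, separating direct effects from family-level
  confounding;
* each in fixed- and mixed-effects variants, the latter adding a sibship
  random intercept.

Mixed models are fit by adaptive Gauss–Hermite quadrature with 10 nodes
(`lme4::glmer`), falling back to the Laplace approximation when quadrature
fails; with a single scalar random effect this is accurate and cheap.
Inference is Wald (estimate, SE, OR with 95% CI). Educational attainment can
be added as years (linear) or as categories (dummies, lowest category as
reference; categories with no cases or no controls are flagged and kept with
a warning). Degenerate designs error out explicitly: constant phenotype,
complete separation, no phenotype-discordant sibships (within effect
unidentifiable), all sibship means equal (between term collinear).

For comparability analyses a fixed-effects population model can be refit on
one seeded-random member per sibship (`pickOnePerSibship()`), or on an
unrelated subsample built by greedily removing the individual with the most
remaining relationships at kinship $\ge 0.088$ (ties broken by a seeded
draw) — the construction that retains close to the maximal sample.

## Liability transformation

Heritabilities of binary traits estimated on the observed scale are rescaled
by the Robertson multiplier $K(1-K)/z^2$, where $K$ is prevalence and $z$
the standard-normal density at the threshold $t = \Phi^{-1}(1-K)$. At
$K = 0.5$ the multiplier is exactly $\pi/2$. The transformation is linear,
so a supplied SE is propagated by the same multiplier; no ascertainment
correction is applied because the intended inputs come from
population-sampled (not case-ascertained) estimation samples. REML/GREML
estimation itself is out of scope — the observed-scale estimates are inputs.

## The synthetic cohort

Real biobank data of this kind are access-restricted, so the package ships a
generator whose defaults *are* the assumed study conditions:

* 15 counties, two of them containing the cities (default weights 0.30 and
  0.12, the remainder spread unevenly over ORE);
* sibships with size distribution (0.45, 0.40, 0.11, 0.04) over sizes 1–4
  (size-1 "sibships" are unrelated singletons), all members sharing POB;
* a latent genetic value $g = g_{fam} + g_{dev}$ with
  $\mathrm{Var}(g_{fam}) = \mathrm{Var}(g_{dev}) = 0.5$, giving sib–sib
  correlation 0.5;
* every score loading on the single shared component (EA score loading
  0.95; others 0.7 … −0.25) plus idiosyncratic noise for unit variance,
  with small sex/age effects so the adjustment stage has work to do;
* migration to either city with log-odds
  $\alpha_{dest} + \beta_g g + \lambda g_{fam} + u_j$, the family
  environment $u_j$ shared by sibs. Because both city destinations share
  one genetic term, the case/control log-odds of reaching *either* city is
  exactly linear in $g$, so logistic fits on the ORE-born recover the
  generator coefficient without collapsing-categories bias. The family
  loading $\lambda$ makes the between-family effect exceed the within-family
  one, as observed in real cohorts; an alternative generator mode
  (`migWithinBetween`) specifies $\beta_W$ and $\beta_B$ directly and gives
  an exact truth for recovery tests;
* years of education driven by a second genetic value correlated 0.8 with
  $g$, plus family and individual noise, and a degree indicator at 16
  years;
* a kinship list with every within-sibship pair near 0.25 (truncated into
  the open sibling window) plus decoy pairs outside it; PCs as
  county-of-birth mean shifts plus noise; a low rate (0.05) of within-ORE
  moves so the "moves within an area are ignored" rule is exercised.

The effect sizes $\beta_g = 0.23$ and $\lambda = 0.12$ (with EA-score
loading 0.95) were set once, analytically, so that the *implied* marginal
associations land at a population OR near 1.3 and a within-sibship OR near
1.2 per score SD — the order of magnitude such cohorts report. The
derivation: the population slope on the score is
$\ell(\beta_g + \lambda\,\mathrm{Var}(g_{fam}))\approx 0.95(0.23 + 0.06)
\approx 0.27$; the within-sibship slope is attenuated by the reliability of
the score deviation as a proxy for the genetic deviation,
$\beta_g\,\ell\,\mathrm{Var}(g_{dev}^{(pair)}) /
(\ell^2 \mathrm{Var}(g_{dev}^{(pair)}) + \sigma^2_{idio}/2) \approx 0.20$.
No generator parameter was revisited afterwards.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: linkage disequilibrium and genotype-level
structure (scores are drawn, not computed from variants), multi-generation
dynamics, assortative mating, participation bias beyond a simple age/sex
effect, real geography or county-level environments, half-sibs and twins,
and any environmentally induced county differences in scores. Tests
demonstrate that the statistics do what they claim under the generative
model, not that the model is true of any country.

## Problem sizes and determinism

Defaults were chosen so a full run is interactive: the default cohort is
~21,000 individuals (12,000 families), the sibling null uses 10,140 draws,
the bootstrap 1,000 resamples. The validation suite uses 5,000-sibship
cohorts for parameter recovery (20 replicates), 200 replicate datasets with
500-draw nulls for type-I error, and 50 replicates for the directionality
property. Every random step — generator, null, bootstrap, tie-breaks,
member picks — flows from an explicit integer seed, and identical seeds
reproduce outputs byte-for-byte.

## Known limitations

Group contrasts use normal approximations, adequate for the group sizes the
taxonomy produces but not for very sparse origin–destination cells (such
cells are flagged, not tested). The empirical-null p-value is bounded below
by $1/(n_{sims}+1)$. The greedy unrelated filter is near-optimal, not
provably maximal. The joint EA models condition on a phenotype that is
itself heritable, so their coefficients answer an attenuation question, not
a causal-mediation one.
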