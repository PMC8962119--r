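---
title: "Genetic testing without a progeny trial: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic testing without a progeny trial: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Progeny trials — designed plantings of known families — are the classical
instrument for estimating the genetic worth of selected parents in tree
breeding, but they take a rotation or more to deliver. When an existing
plantation was raised from seed-orchard crops, the same two ingredients can
be recovered in place: *who the mothers are* (from codominant markers) and
*how much of the growth variation is genetic* (from a mixed model that
separates genetic from environmental structure). `orchardgt` implements
that workflow: microsatellite diversity statistics, likelihood-based
maternity assignment with simulated confidence, pedigree relationship
matrices, REML animal models with spatially structured residuals, AICc
model comparison, heritability, and BLUP breeding values for forward
(offspring) or backward (mother) selection.

## Diversity and marker informativeness

For each locus with allele frequencies $p_i$ estimated by counting (two
observations per non-missing call; missing calls are dropped locus by
locus), the package reports

* $N_A$, the allele count, and $N_E = 1/\sum_i p_i^2$, the effective
  number of alleles;
* $H_O$, the fraction of typed individuals carrying two different alleles,
  and $H_E = 1 - \sum_i p_i^2$ (gene diversity). The uncorrected form is
  the default because it satisfies the identity $H_E = 1 - 1/N_E$ used as
  an internal invariant; Nei's $2N/(2N-1)$ correction is available behind
  a flag and breaks that identity by design;
* $F = 1 - H_O/H_E$, negative under heterozygote excess, reported as
  missing (never 0/0) at monomorphic loci;
* across-locus means with standard errors $\mathrm{sd}/\sqrt{L}$, the
  parenthetical-SE convention of per-population diversity tables.

Marker informativeness uses the polymorphic information content
$\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$ and two
non-exclusion probabilities under Hardy–Weinberg equilibrium with
$a_k = \sum_i p_i^k$:

* first parent: $\mathrm{NE}_{1P} = 1 - E_1$ with
  $E_1 = 1 - 4a_2 + 2a_2^2 + 4a_3 - 3a_4$ (the Jamieson–Taylor one-parent
  exclusion polynomial). This is exactly the probability that a random
  non-mother carries at least one transmissible allele of a random
  offspring; the test-suite verifies it against exhaustive enumeration
  over genotype pairs.
* identity: $\mathrm{NE}_I = 2a_2^2 - a_4$, the probability that two
  random individuals share a genotype.

Multi-locus values are products over loci (independence). Different
programs print slightly different exclusion variants; the polynomial above
is the documented contract of this package, and published single-study
values are not used as oracles.

## Maternity assignment

The likelihood machinery follows the standard maximum-likelihood parentage
approach for codominant markers with a genotyping-error model. With error
rate $e$ (default 0.01), an observed genotype is the true one with
probability $1-e$ and a random HWE genotype with probability $e$ — a
per-genotype replacement model, the simplest one consistent with a single
"error rate" number. Marginalizing the per-locus likelihood over true
genotypes gives the closed form

$$P(\text{obs offspring} \mid \text{obs dam}) =
  (1-e)^2\,T(o\mid m) + e(2-e)\,H(o),$$

where $T(o\mid m)$ is the Mendelian transmission probability with the
paternal allele drawn from population frequencies, and $H(o)$ the HWE
frequency of the observed offspring genotype. The per-locus LOD is
$\ln$ of that over $H(o)$; the total LOD sums over shared typed loci. The
closed form is verified against an exhaustive sum over true-genotype pairs
in the tests.

The $\Delta$ statistic is the best-minus-second-best LOD when at least two
candidates have positive LOD, the best LOD itself when it is the only
positive one, and 0 when no candidate has positive LOD (the convention of
the dominant parentage software; the branches are documented here because
source descriptions are typically silent). Confidence tiers come from
Monte-Carlo calibration: `simulate_critical_delta()` generates offspring
from random HWE mothers (default 10,000), injects errors and locus
masking, offers the same number of candidates (true mother present with
probability `prop_candidates_sampled`, default 1 for a closed, fully
genotyped orchard), and returns for each confidence level $c$ (strict
0.95, relaxed 0.80) the smallest $\Delta^*$ such that assignments with
$\Delta \ge \Delta^*$ are correct at rate $\ge c$. Ties on LOD break to
the lexicographically first candidate id and are flagged.

Offspring without confident assignments stay in the phenotypic analysis
with unknown dam (founder treatment in the relationship matrix), and
offspring with no typed loci are listed as unassigned with a reason.

## The spatial animal model

The genetic-testing core fits, by REML,

$$y = Xb + Zu + \xi + \eta,$$

with $u \sim N(0, \sigma^2_A A)$ the additive genetic effects ($A$ from
the maternal pedigree by the tabular method; unknown sires are distinct
unrelated founders, so maternal half-sibs have expected relationship
0.25), $\xi \sim N(0, \sigma^2_\xi R)$ a spatially structured residual,
and $\eta \sim N(0, \sigma^2_\eta I)$ the nugget. $X$ is intercept-only by
default. Seven candidate structures for $R$ are supported: exponential
$e^{-d/r}$, Gaussian $e^{-(d/r)^2}$, spherical, linear, rational
quadratic $1-(d/r)^2/(1+(d/r)^2)$ (the `corRatio` convention — the family
name alone does not pin down a formula), all on raw coordinate distances;
and AR1 and AR1$\otimes$AR1 on a rasterized grid. For
AR1$\otimes$AR1 the entry for trees in cells $(r_1,c_1), (r_2,c_2)$ is
$\rho_{row}^{|r_1-r_2|}\rho_{col}^{|c_1-c_2|}$ — the observed-cell
submatrix of the full Kronecker product, never materialized (a 450 × 450
grid would make the full matrix 202,500-square). The 1-D AR1 is defined
on the row-major cell index of the grid, a documented choice: sources
that list "AR1" among candidate structures rarely say what the lag runs
over, and any 1-D ordering is defensible only as a baseline (it ranks
poorly whenever the field is genuinely two-dimensional).

Rasterization maps the coordinate bounding box affinely onto the grid
with truncation; collisions move the later tree (id order) to the nearest
free cell by Chebyshev distance with a deterministic row-major ring scan,
guaranteeing an injective assignment. The default 450 × 450 grid follows
the scale used for a ~1.3 ha stand at metre-level GPS resolution; tests
use small grids.

Numerical choices: the restricted likelihood is evaluated dense (the
target problems have a few hundred trees) in the Patterson–Thompson form
including the $\ln|X'X|$ constant, so it matches the orthonormal
error-contrast definition exactly (the test-suite checks this to 1e-8 at
$n \le 12$). Optimization runs over log variances and scaled-logit
correlations in $(-0.999, 0.999)$ (ranges on log scale) with Nelder–Mead
from three seeded starts (equal, genetic-heavy, and spatial-heavy
variance splits), convergence tolerance 1e-10 on the log-likelihood, and
the best optimum kept — same data and seeds give bit-identical fits.
Near-singular covariance matrices get jitter escalation
(1e-10 → 1e-6 of the mean diagonal) before failing. Standard
errors come from the observed information (central-difference Hessian on
the natural scale); at boundary estimates (a variance near 0) the
corresponding SE is reported as `NA` rather than a fabricated number.

Model comparison uses
$\mathrm{AICc} = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$ counting the
fixed effect plus every estimated variance/correlation parameter
(animal-only 3; distance structures and AR1 5; AR1$\otimes$AR1 6).
Published df columns in comparable tables cannot be reconciled with their
AICc arithmetic, so this rule is the package's documented convention.

Heritability is $h^2 = \sigma^2_A/(\sigma^2_A+\sigma^2_\xi+\sigma^2_\eta)$
— the spatially structured variance stays in the denominator. This is
forced by arithmetic on the reference variance decomposition
(9.086/26.449 = 0.344; excluding the spatial term would give 0.650) and
is the conservative choice: micro-site variation a tree experiences is
part of its phenotypic variance.

Breeding values are BLUPs
$\hat u = \hat\sigma^2_A A Z' \hat V^{-1}(y - X\hat b)$ for every pedigree
member; non-phenotyped mothers get predictions through $A$ (their row of
$Z$ is zero). The test-suite checks equivalence with Henderson's
mixed-model equations. A family model (i.i.d. dam effects instead of the
individual animal effect) is available via `model_spec(genetic =
"family")` for the backward-selection variant; note its variance
component is a family variance (a quarter of the additive variance under
half-sib theory), so its `h2` slot is not a narrow-sense heritability.

## Moran's I

Spatial autocorrelation of the phenotype is tested before modelling.
Weights are row-standardized inverse Euclidean distances by default (a
k-nearest-neighbour scheme is the alternative); the weighting scheme is
an explicit package default, not an empirical fact inherited from any
particular study. The expectation is $-1/(n-1)$; the variance uses the
Cliff–Ord randomization formula, and a permutation p-value (seeded) is
available alongside the normal approximation. Coincident points make
inverse-distance weights undefined; the error message directs to jitter
or the knn scheme.

## The synthetic orchard generator

Because real datasets of this kind are typically not public, every stage
is validated against a generator with known truth:

* **Allele frequencies**: per locus, allele count uniform on 4–17 and
  symmetric Dirichlet(0.3) frequencies. The concentration was chosen once
  so that mean $H_E$ over 7 loci lands in 0.6–0.75, the level seen in
  conifer microsatellite panels; it is not tuned per test.
* **Genotypes**: mothers from HWE; each offspring gets a fair maternal
  pick plus a pollen allele from the same frequencies (closed orchard; a
  contamination fraction is a config option, default 0). Genotyping
  errors replace recorded genotypes at the configured rate.
* **Family sizes**: default truncated geometric on 1–6 with mode 1,
  matching the observed pattern that most reconstructed families are
  singletons; recovery experiments use balanced 60 dams × 5 offspring.
* **Phenotypes**: $u$ by Cholesky of $\sigma^2_A A$; $\xi$ on the full
  grid by the Kronecker-factored Cholesky $L_{row} Z L_{col}'$; $\eta$
  i.i.d.; $y = \mu + u + \xi + \eta$ with $\mu = 20$ cm DBH. Default
  truth takes the reference variance components (9.086, 12.478,
  4.885 cm²) with $\rho_{row} = \rho_{col} = 0.8$ — the autocorrelations
  are a deliberate choice strong enough to make spatial structure
  detectable, since no empirical estimate of them is available.
  Coordinates are cell centres jittered uniformly by ±0.3 cell widths —
  enough to exercise the rasterization collision logic while keeping the
  cell recoverable.
* **Placement**: trees occupy random distinct cells by default. A
  `"dispersed"` mode places each sib at the free cell farthest from its
  already-placed sibs (greedy max–min). This matters for one documented
  phenomenon, below.

What the generator does *not* emulate: selfing and inbreeding, linked
loci, mutation, null alleles, batch effects between mother and offspring
genotyping, anisotropy, and age structure. A green recovery test
establishes that the estimator recovers the generating model at the
stated design — not that any particular field dataset satisfies that
model.

## The direction of the unmodeled-spatial bias

A noteworthy empirical point, reproduced as a directional property in the
acceptance tests: what ignoring spatial structure does to
$\hat\sigma^2_A$ depends on where sibs stand relative to the field.

* Under **random placement**, sib pairs share the environmental field no
  more and no less than random pairs, and the unmodeled positive
  covariance among neighbours loads onto the only structured component
  available — the sib blocks of $A$ — so the animal-only fit *inflates*
  $\hat\sigma^2_A$.
* Under **dispersed placement** (families spread evenly through the
  stand, as reconstructed families in plantations tend to be), sibs share
  *less* of the field than random pairs; the apparent sib resemblance is
  depressed and the animal-only $\hat\sigma^2_A$ shrinks, frequently to
  the zero boundary, while the animal + AR1$\otimes$AR1 fit restores it.

The acceptance suite asserts the depression on dispersed simulations with
1–6 offspring per dam. It is a directional property of means over
replicates, not a numeric target.

## Pipeline and determinism

`run_pipeline()` chains screening (trees with DBH strictly above the
threshold, default 30 cm, are excluded — boundary values kept), diversity
tables, maternity assignment per cohort, Moran's I, rasterization, model
comparison, and breeding-value ranking, writing CSV/JSON artifacts.
Diversity is compared jointly across groups, but the spatial stages
(Moran's I through breeding values) run separately per offspring cohort:
distinct plantations have distinct environmental fields, and pooling them
would ask one AR1 ⊗ AR1 surface to describe two sites. With several
cohorts the spatial artifacts are suffixed by site. All
randomness derives from a single root seed split deterministically per
stage (`split_seed()`), so two runs with the same inputs and seed are
byte-identical. The configuration file is JSON (not YAML): the package
avoids dependencies outside the guaranteed environment, and `jsonlite` is
the only serialization dependency it needs.

## Known limitations

* Maternity only; no paternity or parent-pair analysis, and no sibship
  reconstruction.
* Dense linear algebra limits fits to a few thousand trees.
* The genotyping-error model is genotype-replacement, not allelic dropout
  or stutter; threshold calibration assumes candidates drawn from the
  same allele frequencies as the data.
* SEs from the observed information are asymptotic and unreliable at
  variance boundaries (reported as `NA` when the information matrix is
  not invertible).
* The family model's variance component is not rescaled to an additive
  variance; users comparing it with the animal model must multiply by 4
  themselves.
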