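---
title: "Vine copula models for virtual patient populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vine copula models for virtual patient populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Pharmacometric simulation needs *virtual populations*: tables of subject
covariates (age, body size, renal and hepatic markers, sex, race-ethnicity)
whose joint distribution is realistic. Realism has two parts — each
covariate's marginal distribution, and the dependence between covariates
(weight and fat mass are strongly related; creatinine differs by sex). A
multivariate normal couples the two and forces normal margins; resampling a
real dataset preserves both but requires sharing subject-level data.

`vinepop` separates them with a copula: each covariate is described by its
own kernel density estimate, the data are mapped through their fitted CDFs
to the uniform scale (probability integral transform, PIT), and the
dependence among the resulting *pseudo-observations* is modelled by a vine
copula — a factorization of the d-dimensional copula into d(d−1)/2
bivariate (conditional) copulas arranged in a sequence of trees. The fitted
model is a compact JSON document with no subject-level data in it, which
makes it shareable; simulating from it yields complete covariate tables of
any size.

## Model and estimation

**Marginals.** Continuous covariates get a Gaussian KDE with the Silverman
rule-of-thumb bandwidth, tabulated on a 512-point grid extending 4
bandwidths beyond the data range; the CDF is the normalized trapezoidal
integral of that table, and quantiles invert it by monotone interpolation
(round-trip accurate to about 1e-4 relative over the observed range).
Covariates flagged *log-scale* (the biochemical measurements and fat mass)
are modelled on the log scale, so back-transformed simulations are strictly
positive. Pseudo-observations are clamped to [1e-10, 1 − 1e-10]. Sampling
weights, when present, rescale each observation's contribution to the
density, the level frequencies and the likelihood; the bandwidth rule uses
weighted moments with the total weight in place of the sample size, so an
integer weight is exactly equivalent to duplicating a row.

**Categorical covariates.** A discrete variable has no unique PIT; copulas
over unordered categories are not identified. We use the standard
randomized PIT: a level occupying the probability interval (F(level−),
F(level)] is mapped to a uniform draw within that interval. The jitter seed
is part of the fit configuration and is recorded in the model, so fits are
reproducible. Because the result depends on how the levels are ordered,
`fit_vine_with_categorical()` fits one vine per level permutation (k!
candidates, capped at k ≤ 7) with a shared jitter realization, and keeps
the minimum-AIC model. For two-level covariates such as sex the ordering is
immaterial up to copula rotation, so the plain `fit_vine()` default
(sorted levels) suffices.

**Pair copulas.** Nine parametric families are implemented: independence,
gaussian, student_t, clayton, gumbel, frank, joe, bb1 (Clayton–Gumbel) and
bb8 (Joe–Frank). The Archimedean families are built from their generators;
densities and h-functions (conditional CDFs, the partial derivatives of the
copula CDF) are evaluated in log space so strong dependence does not
overflow. Families whose base orientation only expresses positive
dependence are offered with 90/180/270-degree rotations; which rotations
are tried follows the sign of the empirical Kendall tau. Parameters are
estimated by (weighted) maximum likelihood from a tau-inversion starting
point, and the family is selected by AIC, with the independence copula
always among the candidates. AIC ties break deterministically: fewer
parameters, then family name, then rotation.

**Structure selection.** Trees are chosen sequentially. Tree 1 is the
maximum spanning tree over the covariates with edge weight |Kendall tau| of
the pairwise-complete pseudo-observations; each selected edge gets its
AIC-best pair copula; conditional pseudo-observations are then propagated
through the fitted h-functions, and the next tree is selected the same way
among the edges allowed by the proximity condition (an edge of tree t+1 may
join only edges of tree t sharing a node). Kruskal's algorithm with a fixed
tie-break (weight descending, then lexicographic node names) makes the
structure deterministic. Kendall's tau was chosen as the edge weight
because it is invariant under the monotone PIT and has closed-form
relations to most family parameters; whether subsequent trees re-run the
spanning-tree search under proximity (as here) or inherit a fixed structure
is a genuinely open design point — we follow the standard sequential
selection.

**Missing data.** Estimation never imputes: each edge is fitted on the rows
complete for its conditioned pair and conditioning set, and missing inputs
propagate missing conditional pseudo-observations. Covariates with fewer
than 10 non-missing values are an error; edges with fewer than 20 complete
pairs fall back to the independence copula with a warning.

**Simulation.** `simulate_vine()` applies the inverse Rosenblatt transform:
independent uniforms are pushed through chains of inverse h-functions in an
order derived from the vine (the top tree's conditioned variables are
vine leaves and can be peeled off one at a time), then each uniform column
is mapped to the natural scale by the marginal quantile — exponentiated for
log-scale covariates, decoded through the cumulative level probabilities
for categorical ones. Simulated tables are complete by construction.
Subgroup populations come from rejection sampling against filters
(`simulate_subgroup()`), with geometrically growing batches (starting at
4n) and an attempt budget; an acceptance rate below 1e-4 at the budget is
reported as an infeasible filter set.

## Evaluation metrics

The evaluation simulates replicates of the observed table size and
compares, per replicate:

* **Marginal metrics** — relative error `RE = (M_sim − M_obs) / M_obs` of
  the mean, SD and 5th/50th/95th percentiles (linear interpolation between
  order statistics) of every continuous covariate, and category frequencies
  for categorical ones. Comparisons use the observed non-missing values and
  an equal number of simulated values, so values the model extrapolates
  into never-observed regions (fat mass at age ≥ 60 in the reference
  design) do not enter.
* **Correlation** — Pearson correlations per continuous pair, on the
  modelling (log) scale, with error |r_sim − r_obs|.
* **Contour overlap** — the dependence-shape metric: for each pair, both
  samples' densities are estimated by a binned 2D Gaussian KDE on one
  shared 256×256 grid padded by 3 bandwidths; the 95% highest-density
  region (HDR, "95% density contour") of each is the superlevel set of the
  density threshold enclosing 95% of the estimated mass; the overlap is the
  Jaccard index, 100·area(A∩B)/area(A∪B). Areas, intersections and unions
  are computed by counting grid cells — with both HDRs discretized on the
  same grid this equals polygon clipping up to grid resolution, is exactly
  symmetric, returns exactly 100 for identical samples and 0 for disjoint
  ones. Contour rings are still extracted (`density_contour()`) for
  plotting and reporting, with shoelace areas. Contours are computed on the
  modelling scale (log for biochemical covariates), matching how the
  dependence was estimated.

Summaries report the median over replicates and covariates/pairs, and the
coefficient of variation of each metric across replicates.
`compare_subgroup_strategies()` evaluates virtual subgroups obtained both
by filtering full-model simulations and by fitting a copula to the
subgroup data; `holdout_missing_validation()` masks a covariate inside
anchor bands, refits, and checks the simulated in-band distribution
against the held-out values.

## The synthetic data generator

No subject-level reference data ship with the package; `generate_fixture()`
creates NHANES-like adult tables so every stage is testable. Margins target
the published adult summary statistics: truncated normals matched by
moments for age (46.05 ± 17.21, range 18–79), weight (82.02 ± 22.17),
height (167.16 ± 10.09) and albumin (4.28 ± 0.35), moment-matched
lognormals for fat mass, creatinine, ALT, AST, ALP and bilirubin, 51.5%
female, and the five race-ethnicity frequencies (26.6/36.9/22.8/10.6/3.1%).
Dependence comes from a latent Gaussian copula with a fixed correlation
matrix chosen once to mirror the qualitative structure of the reference
analysis: a strong weight–fat block (ρ = 0.70) with moderate weight–height
(0.45), mild age effects on creatinine, ALP and albumin, a strong ALT–AST
pair (0.70), and sex shifts on height, creatinine, bilirubin, fat, albumin
and ALT (|ρ| = 0.2–0.5, signed so that women are shorter, with lower
creatinine and higher fat mass). Missingness emulates the reference
pattern: fat mass blanked for everyone aged ≥ 60 plus 45% at random below
60 (total ≈ 56%), and ~6.3% random missingness per laboratory covariate.

What the generator does *not* emulate: survey design effects, heaped or
censored laboratory values, outliers and measurement error, or any
dependence beyond a Gaussian copula (no tail asymmetry). Passing the
package's tests therefore demonstrates that estimation, simulation and the
metrics are internally correct and self-consistent on data of realistic
scale and shape — not that any particular fitted model describes a real
population.

## Numerical choices and problem sizes

* Pseudo-observation clamp 1e-10; log-density floor −700; parameter boxes
  per family sized so generators stay within double range at the clamp
  (e.g. clayton θ ≤ 20, gumbel θ ≤ 17, bb1 θ, δ ≤ 4), covering taus beyond
  0.9.
* h-function inverses: closed form for independence, gaussian, student_t
  and clayton; 60-step vectorized monotone bisection otherwise (round trip
  ≈ 1e-8, also the tolerance asserted in tests).
* Kendall tau by Knight's O(n log n) algorithm in compiled code
  (tau-b, tie-corrected); `stats::cor(method = "kendall")` is quadratic and
  too slow for the ~200 pair evaluations a 12-covariate structure search
  needs.
* Student-t degrees of freedom bounded to [2, 50]; frank |θ| ≤ 35 with the
  Debye-function tau.
* The test and acceptance workloads fit the full 12-covariate model on
  n = 10,000 synthetic subjects and evaluate with 10 simulation replicates —
  a deliberate scale-down of the reference analysis (27,008 subjects, 100
  replicates) that leaves the medians stable; parameter-recovery checks use
  n = 5,000 across 10 seeds.

## Known limitations

* Sequential (tree-by-tree) estimation is the standard heuristic, not joint
  maximum likelihood; no model averaging over structures.
* Non-parametric pair copulas are deliberately out of scope, so sharply
  non-elliptical shapes (e.g. heart-shaped weight–fat clouds) are captured
  only as well as the parametric families allow.
* The categorical ordering search is factorial in the number of levels and
  refuses k > 7; conditional simulation given fixed covariate values is not
  implemented (subgroups use rejection sampling).
* Weighted fits reweight the likelihood and the marginals; design-based
  variance estimation for survey data is out of scope.
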