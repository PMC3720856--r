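---
title: "Models and methods behind elevgrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind elevgrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(elevgrad)
```

This vignette is the package's own account of the statistical machinery:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
decisions taken where the design was genuinely open.

## The sampling design

The data model is a stationed nested-plot survey: elevational stations at
fixed vertical intervals (default seven stations, 1000–2200 m asl at
200 m steps), each with a small number of plots (default three), each
plot a set of nested circles — 1 m radius for ground cover, 5 m for
understorey stems (2 ≤ dbh < 10 cm), 10 m for subcanopy (10–30 cm) and
20 m for canopy trees (≥ 30 cm). Stratum membership uses half-open
intervals `[2, 10)`, `[10, 30)`, `[30, ∞)` so no stem is counted twice.
Ground cover is recorded on a seven-point ordinal scale (0 absent; 1
< 1%; 2 1–4%; 3 5–24%; 4 25–49%; 5 50–74%; 6 75–100%).

## Fisher's alpha and the additive partition

Plot diversity is Fisher's log-series alpha, the unique positive root of
`S = α·ln(1 + N/α)`. The left side is strictly increasing in α with
supremum `N`, so a root exists precisely when `S < N`; `S = N` (every
individual a different species) is reported as a degenerate case — an
error for a single query, a flagged `NA` row in table output so that tiny
plots cannot abort a pipeline run. The solver brackets on `[1e-6, 1e6]`
(expanding the upper bound where needed), applies Brent's method, and
polishes with Newton steps to a re-substitution residual below `1e-10`.

Beta-diversity is additive: the alpha of the station-pooled community
minus the arithmetic mean of its plot alphas. Because alpha is nonlinear
in `(S, N)`, beta can be negative — three identical plots pool to the same
`S` at triple the `N`, and alpha decreases in `N` at fixed `S`. This is a
documented property of the partition, not an error.

Ground-cover records enter diversity calculations through a
pseudo-abundance: the rounded midpoint of each cover class interval
(0, 1, 3, 15, 37, 62, 88). Field protocols for this scale do not fix a
conversion, so the midpoint convention is this package's explicit choice;
any monotone recoding would change alpha values but not their ordering.

## Biomass

Stem biomass uses the moist-forest allometry `AGB = 0.0509·ρ·dbh²·H`
(kg; dbh in cm, H in m, ρ in g cm⁻³) with heights from the simplified
allometry `H = c·dbh^(2/3)`. The coefficient `c` (m cm^(−2/3)) is
calibrated per station as the mean over plots of
`H_tallest / dbh_tallest^(2/3)`; the measured tallest-tree height is used
*only* for calibration — every stem's height, including the tallest
tree's, then comes from the fitted allometry. Wood density resolves by
species, then genus (first token of the binomial, split on space or
underscore), then a site default of 0.56 g cm⁻³, with provenance
reported. Subcanopy and canopy census areas differ, so plot biomass
density merges them per area:
`AGB/m² = ΣAGB_sub/(π·10²) + ΣAGB_can/(π·20²)`, algebraically identical
to extrapolating subcanopy totals by the 4× area ratio over the 20 m
plot (asserted to `1e-12` in the tests). Understorey stems are excluded
from biomass and filtered with a warning.

## Trend models and model averaging

Responses (plot alpha, station beta, biomass density) are modelled by
Gaussian OLS against elevation, slope and leaf area index. Predictors are
centred and scaled before any polynomial or interaction term is formed;
this keeps the design conditioned and matches the convention of reporting
standardized coefficients. The candidate set is every subset of the term
lattice closed under marginality (an interaction only with all its
lower-order terms): 19 models for three main effects with all
interactions. AIC uses the full Gaussian log-likelihood
`n·ln(2πRSS/n) + n + 2(k+1)` so values coincide with `stats::AIC` and are
comparable across software. Whether elevation enters linearly or
quadratically is decided once, by the AIC of the two maximal models, with
ties to the simpler linear form; when the quadratic form is selected, the
squared term travels with the linear term as one block and interactions
involve the linear term only (the lattice over
`{elevation, elevation², …}` with free quadratic interactions would not
be identifiable at n = 21).

Akaike weights are `exp(−Δᵢ/2)` normalized; models with weight at or
below 10% of the maximum are dropped, the rest renormalized, and a term's
importance is the summed weight of retained models containing it. Models
with more coefficients than observations support (relevant for
station-level beta, n = 7) are skipped and recorded, not fitted.

The Mitchell–Olds & Shaw extremum test fits `y ~ x + x²`, locates
`u = −b₁/(2b₂)`, and compares the quadratic against the two constrained
quadratics whose extremum is pinned at `min(x)` and `max(x)` — nested
2-parameter models `y = a + b₂(x² − 2θx)` — by F tests. A hump (U) is
declared only when both constrained models are rejected and the curvature
is negative (positive). The construction matches `vegan::MOStest`
(F statistics agree to four decimals on shared fixtures). Under a flat
null at n = 21 the measured size is about 0.03 at nominal 0.05; under a
strongly sloped monotone null the test inherits the known behaviour of
the published construction, namely that an interior extremum of the
*fitted quadratic* can be supported even when the generating trend is
linear — a caveat for users, stated here rather than patched away,
because the package reproduces the standard test.

## Model-based composition analysis

Sites × species count tables are modelled with one log-link GLM per
species. The family is negative binomial with per-species ML dispersion
(Newton updates on the size parameter θ interleaved with IRLS); when the
profile likelihood still increases at θ = 10⁶ — variance no larger than
the mean — the Poisson fit is kept and flagged. The fitter matches
`MASS::glm.nb` to four decimals on shared data. Ordinal ground-cover
classes (0–6) are modelled as counts under the same family; this is an
approximation, adequate for deviance partitioning, and is the one place
the package knowingly treats an ordinal variable as a count.

Inference is a sequential analysis of deviance: terms (or term *blocks* —
for ground cover the forest-structure variables basal area, canopy height
and LAI enter as a single grouped block, then slope, then elevation)
enter in a stated order, and the statistic for each step is the summed
per-species deviance reduction. Per species, θ is estimated once on the
full model and held fixed across the nested sequence, so the reductions
telescope exactly to the null-minus-full deviance — the additivity the
percent-deviance partition relies on. p-values come from a PIT residual
bootstrap: under the null fit of each comparison, probability-integral
residuals `u ~ U(F(y−1), F(y))` are drawn, site rows of the u-matrix are
resampled with replacement *jointly across species* (preserving the
cross-species dependence that makes naive per-species resampling
invalid), inverted through the null quantile function, and both models
refitted; the add-one Monte-Carlo convention `(1 + #{stat* ≥ stat})/(1+B)`
gives a valid finite-sample test. A joint row-permutation mode is
provided as a cross-check. Measured type-I error at n = 21, K = 10,
B = 199 sits at 0.02–0.04 over repeated 500-dataset experiments — the
test runs slightly conservative in small samples.

Species observed in fewer than `min_occurrence = 3` plots are excluded
from the pipeline's composition stage: with ~20 sites such species
contribute almost no information and destabilize dispersion estimates.

## Phylogenetic structure

Community relatedness uses cophenetic (path-length) distances on the
species-pool tree and the mean pairwise distance (MPD) over species
present, unweighted by abundance. The null model is the independent swap:
random 2×2 checkerboard flips that preserve every community's richness
and every species' occupancy exactly. The proposal (pick a random 2×2,
flip only if it is a checkerboard) is symmetric, so the chain's
stationary distribution is uniform over the fixed-margin matrices — the
tests verify this against exhaustive enumeration of a small state space,
with decorrelated sampling (autocorrelated thinning at short lags
inflates chi-square rejection and was deliberately avoided). Defaults are
30,000 burn-in attempts, 3,000 attempts between samples, 999 samples,
comfortable for matrices around 7 stations × 30–90 species; the pipeline
default scales these down (see problem sizes below).

The standardized effect size is `(MPD_obs − mean_null)/sd_null` with
moments over the null samples only; the net relatedness index is its
negation, so positive NRI = clustering. `p_low` is the one-tailed
add-one proportion of null MPDs at or below the observed value, small
when a community is more related than the null allows. Communities
containing the whole pool cannot move under a margin-preserving null and
are flagged degenerate (`sd_null = 0`); communities with fewer than two
species return `NA`. Station-level communities pool the three woody
strata (understorey + subcanopy + canopy) as presence; ground cover is
left out of the phylogenetic analysis because herbaceous species are not
on the woody species-pool tree.

## The synthetic-data generator

The generator exists so that every stage above can be exercised, and its
estimators validated, on data whose truth is known. It emulates:

- a regional pool with log-series abundance structure, implemented as the
  sequential urn scheme (new species with probability `α/(α+i−1)`), whose
  expected richness `α(ψ(α+N) − ψ(α))` matches the Fisher relation to
  well under the tolerances of the recovery tests and whose abundances
  sum exactly to the requested count;
- Gaussian occupancy curves along elevation,
  `p = p_max·exp(−(z−opt)²/2τ²)`, with species optima evolved by Brownian
  motion on a simulated pure-birth tree (rate = root-to-tip variance,
  tree rescaled to unit height) and clipped — not reflected — at the range
  ends, clipping bias being negligible at the default rates;
- abundance-given-presence by thinning a plot-level log-series draw, so
  realized communities keep a known link to the generating α;
- stratum-specific truncated-exponential dbh distributions, and
  tallest-tree calibration pairs built from the true height coefficient
  plus noise, making `c` recoverable;
- covariate trends: hump-shaped LAI (quadratic with a configurable peak),
  linearly declining canopy height, slope as pure noise, U-shaped canopy
  openness clipped to [0, 100];
- ground cover from independent (non-phylogenetic) Gaussian response
  curves, with a latent percentage binned through the ordinal scale —
  the latent-Beta model is an assumption, since no abundance distribution
  is implied by a cover scale.

Default parameter values are chosen once to resemble a realistic tropical
mountain survey: a 92-species woody pool and 67 ground-cover species,
regional `α = 20`, niche breadths lognormal around 250 m, pre-thinning
draw sizes (120/60/15 stems per plot by stratum) that yield on the order
of 900 realized stems over 21 plots and canopy densities near 60
trees/ha. The qualitative-recovery experiments use a deliberately strong
filtering scenario — root optimum 1000 m, Brownian rate 2.5×10⁵ m²,
niche breadth around 200 m — in which declining diversity and
high-elevation phylogenetic clustering are properties of the generating
process, not tuning targets.

What the generator does *not* emulate: spatial structure within plots,
temporal dynamics, fire or disturbance (a grassland summit station is
represented simply as a low-richness, low-biomass station), dispersal
limitation, species interactions, and observation error in dbh or cover
estimation. Passing tests therefore demonstrate correctness of the
estimators and calibration of the tests under the stated generative
model, not robustness to everything real surveys contain.

## Numerical choices and problem sizes

- Root finding: bracket expansion is geometric; Newton polish stops at
  residual `1e-10` or 200 iterations.
- IRLS: log link, working weights `μ/(1+μ/θ)`, deviance-change tolerance
  `1e-8`, 200 iterations, linear predictor clamped at ±30; rank-deficient
  designs are rejected with the collinear columns named.
- θ estimation: Newton on the profile score with a divergence shortcut
  (score still positive at the cap ⇒ Poisson); cap 10⁶.
- Ties: equal AICs select the linear elevation form; the weight-retention
  rule is strictly greater-than, so a model at exactly 10% of the maximum
  weight is dropped.
- Master seeds split deterministically per stage, so individual generator
  stages are reproducible in isolation; all compiled code draws through
  R's RNG, so `set.seed` governs everything.
- Default analysis sizes (`analysis_config`) — 199 bootstrap resamples,
  199 null matrices, 10,000 burn-in/500 thinning — keep a full 21-plot
  pipeline run around a minute on one core; the statistical defaults of
  the standalone functions (999 nulls, 30,000/3,000 chain schedule) are
  the publication-grade settings.

## Known limitations

- Beta-diversity models at station level rest on very few observations;
  most of the candidate set is not estimable there and the package says
  so rather than fitting silently.
- The NB-on-ordinal treatment of cover classes and the grouped
  structure-variable block are pragmatic conventions; both are flagged in
  the function documentation.
- The extremum test's behaviour under strong monotone trends (see above)
  is inherited from the published construction.
- The resampled multivariate test is slightly conservative at small n;
  p-values near the nominal level should be read accordingly.
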