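---
title: "Classifying areas by their migration trajectories: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying areas by their migration trajectories: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migtraj)
```

## The problem

Internal and international migration reshape the size and composition of
local populations over decades. Cross-sectional area classifications — the
workhorse of geodemographics — summarise who lives where at one census, but
cannot distinguish a ward whose in-migration has been rising steadily for
thirty years from one whose identical current level is the tail end of a
decline. `migtraj` implements the longitudinal alternative: a *group-based
multi-trajectory model* (GBMTM) that clusters areas by the joint shape of
several migration indicators across multiple censuses, together with the
indicator construction, boundary harmonisation, enumeration diagnostics,
cluster profiling and classification-comparison machinery that a complete
analysis needs.

## The model

Let $y_{ikt}$ be indicator $k \in 1..K$ of area $i$ at coded time
$t \in 0..T-1$ (decadal censuses coded $0,1,2,\dots$; equal spacing is the
simplest identifiable coding for decennial data). The model assumes $G$
latent groups. Conditional on membership in group $g$, every observed cell
is independent Gaussian around a polynomial mean:

$$y_{ikt} \mid g \;\sim\; N\!\big(\mu_{gk}(t),\, \sigma_k^2\big),
\qquad \mu_{gk}(t) = \sum_{j=0}^{o_{gk}} \beta_{gkj}\, t^j ,$$

and the marginal likelihood of an area mixes the group-conditional
likelihoods with proportions $\pi_g$:

$$\ell = \sum_i \log \sum_g \pi_g \prod_{(k,t)\,\mathrm{obs}}
  f\!\left(y_{ikt} \mid \mu_{gk}(t), \sigma_k\right).$$

Cells absent from the availability mask (for example, age and tenure
composition of in-movers is unavailable at the first census in the design
this package emulates) simply drop out of the product — a
missing-at-random treatment, which is the only defensible option when the
missingness is a property of the data collection, not of the areas.

Modelling choices worth making explicit:

* **Outcome family.** The default is a plain Gaussian on the percentage
  scale; indicators are not standardised before fitting, so trajectory
  coefficients read directly in percentage points. Percentages are bounded,
  and a censored-normal family (`family = "censored"`, bounds 0 and 100) is
  provided for panels with genuine boundary piles; it is not the default
  because for ward-level migration shares the mass at the bounds is
  negligible and the Gaussian EM has closed-form updates.
* **Variance structure.** One noise scale per indicator shared across
  groups (`variance = "shared"`) is the default, matching the common
  practice of trajectory software; `variance = "group"` frees it.
* **Mixing proportions** are parameterised directly on the simplex. No
  covariates predict membership — classification is the goal, not
  regression on group labels.

## Estimation

`gbmt()` maximises the likelihood by expectation-maximisation:

1. **E-step** — posterior memberships
   $p_{ig} \propto \pi_g \exp \ell_{ig}$, computed in log space with
   max-subtraction so that a single area cannot underflow all groups.
2. **M-step** — $\pi_g = \bar p_{\cdot g}$; each $\beta_{gk}$ by
   posterior-weighted least squares of $y$ on the time polynomial (the
   per-time sufficient statistics make this $O(NT)$ per group-indicator);
   $\sigma_k$ from posterior-weighted residuals. For the censored family
   the M-step maximises the expected complete-data log-likelihood
   numerically per indicator (BFGS over the stacked group coefficients and
   the scale), accepted only when it improves — a generalised EM that
   preserves monotonicity.

Convergence is declared when the relative log-likelihood change drops
below `tol` (default `1e-8`); the full trace is kept on the fitted object
and the test suite asserts it never decreases. Initialisation is k-means
on per-area, missing-aware time means of each indicator, with clusters
relabelled by descending size so that a per-group `orders` matrix keeps
addressing the same group across refits; later starts jitter the features.
The best of `n_starts` runs by log-likelihood is kept. A collapsed group
($\pi_g < 10^{-4}$) or a noise scale at its floor ($10^{-3}$ percentage
points, needed so that degenerate zero-noise panels terminate cleanly)
marks a run as degenerate; if all starts degenerate the fit is returned
with a warning rather than silently accepted. Groups are canonicalised by
descending $\pi$ and modal-assignment ties break to the lowest index, so
fits are reproducible and comparable across runs.

## Choosing the number of groups

`gbmt_enumerate()` fits a range of $G$ and tabulates, per candidate:

* **BIC** $= \ell - \tfrac{1}{2} p \ln n$ and **AIC** $= \ell - p$, on the
  trajectory-literature scale where larger (less negative) is better. Two
  sample-size conventions circulate for panel mixtures, so both are
  reported: `bic_obs` uses the count of non-missing cells, `bic_subjects`
  the number of areas. The parameter count is
  $p = (G-1) + \sum_{g,k}(o_{gk}+1) + \#\sigma$.
* **Normalised entropy** $1 + \sum_i \sum_g p_{ig} \ln p_{ig} / (N \ln G)$,
  1 for crisp assignment.
* **APPA** (average posterior probability of assignment) per group, its
  implied **OCC** (odds of correct classification,
  $\frac{\mathrm{APPA}/(1-\mathrm{APPA})}{\pi/(1-\pi)}$; an APPA of
  exactly 1 is reported as odds capped at $9.5\times10^7$ with a flag),
  and the **mismatch** between assigned share and $\hat\pi$.
* The smallest estimated group share.

An advisory *elbow* flags the $G$ beyond which the absolute BIC gain first
falls below a user fraction (default one half) of the preceding gain — the
"levelling out" of the criterion curve. It is deliberately advisory: class
enumeration in this literature combines fit indices with the substantive
question of whether an extra group shows unique characteristics, and the
final choice stays with the analyst.

Because published applications print APPA and OCC but often not the group
shares, `invert_occ()` solves the OCC definition for $\pi_j$ — a useful
internal-consistency check on any printed diagnostics table, and the one
worked example of this kind that can be recomputed exactly from published
numbers (the package's acceptance script does exactly that).

After settling on $G$, `adjust_orders()` prunes the polynomial orders
per (group, indicator): the highest-order coefficient whose Wald statistic
(coefficient over its posterior-weighted least-squares standard error — a
pseudo-class approximation; the full mixture information matrix is
deliberately out of scope) is not significant at `alpha` is dropped, the
model refit, and so on until every retained top-order term is significant.
Backward elimination at level `alpha` necessarily removes *more* terms as
`alpha` shrinks; the default 0.05 is the conventional choice.

## The six indicators

`build_panel()` turns census-style count tables into the six migration
indicators, all simple shares (`share_pct()`), per (area, year):

| indicator | numerator | denominator |
|---|---|---|
| `pct_internal` | internal in-movers | usual residents |
| `pct_international` | international in-movers | usual residents |
| `pct_age_18_24` | in-movers aged 18–24 | all in-movers |
| `pct_age_65plus` | in-movers aged 65+ | all in-movers |
| `pct_owner` | owner-occupying in-mover households | in-mover households |
| `pct_social` | socially renting in-mover households | in-mover households |

An *in-mover* is a person (or household head) whose enumerated address
differs from their address one year earlier. Two semantics decisions: a
zero denominator yields a *missing* share, not zero — unobserved and zero
are different facts, and the likelihood treats them differently; and
absent count columns propagate to missing indicator cells for the same
reason. An optional per-record `adjust_factor` pre-scales the internal
in-mover count (a hook for corrections for incompletely stated origin
addresses); no adjustment is the default because no general formula
exists — the factor is the user's statement.

## Boundary harmonisation

Counts are converted between boundary systems by `convert_counts()` using
areal weighting: target value $= \sum_s w_{s\to t} x_s$, with sources
lacking weights split equally across their targets. Counts are converted
*before* indicators are computed — areal weighting of ratios is not
mass-conserving — and converted counts stay fractional, since the shares
built from them are scale-free. A source mixing weighted and weight-free
rows is an error rather than a guess, because the two regimes are
alternatives with different provenance. `validate_conversion()` compares a
manual conversion against a reference on a relative-discrepancy scale; the
tolerance is a user parameter since no universal threshold for
"significantly different output" exists. For carrying a *categorical*
classification across geographies, `transfer_labels()` uses the
largest-weight (majority) rule with ties to the lowest label — a stated
assumption, since fractional label transfer has no canonical rule.

## Profiling and comparison

`cluster_profile()` implements classify-analyse: areas are hard-assigned
to their modal group, then profiled by per-cluster attribute means with a
one-way fixed-effects ANOVA per attribute (via `stats::lm`). Hard
assignment ignores posterior uncertainty — with the near-1 APPAs typical
of well-separated solutions this is harmless, and a posterior-weighted
variant is available for sensitivity. No multiple-testing correction is
applied by default (a Bonferroni option exists); profiling here is
descriptive, not confirmatory. `geography_summary()` adds per-cluster
regional and urban shares.

`classification_association()` compares two classifications by Pearson
chi-square (no continuity correction; empty rows/columns dropped with a
warning) and Cramér's V $=\sqrt{\chi^2 / (n(\min(r,c)-1))}$;
`correspondence_report()` flags strong (share > 0.5) and evenly split
(within ±0.1 of uniform) rows — advisory thresholds for reading the table.

## What the synthetic generator does and does not emulate

`sim_spec()` / `simulate_panel()` generate panels with known structure:
group labels drawn from $\pi$, polynomial means, additive Gaussian noise,
clipping to $[0,100]$ (counted and reported; inactive when means sit well
inside the bounds), and an availability mask. The defaults mirror the
study design the package targets — 9,976 areas, censuses 1981–2011, six
indicators with the four age/tenure indicators unavailable in 1981, six
groups with mixing proportions equal to the published cluster shares
(63.2, 21.3, 10.7, 2.4, 1.9, 0.5%) — with sketched trajectories for the
six named cluster types and noise scales (1.5, 0.8, 5, 3, 6, 5 percentage
points) chosen once as plausible ward-level within-cluster heterogeneity:
tighter for the two population shares, looser for the compositional
indicators whose denominators are small. Published sources do not report
within-group dispersion, so these are assumptions to vary in sensitivity
studies, not estimates.

Deliberately *not* emulated: spatial autocorrelation, realistic geography,
non-Gaussian heavy tails, and denominators-driven heteroscedasticity
across areas. Passing recovery tests therefore demonstrate that the
estimator is correct under its own assumptions, not that real census
panels satisfy them.

One generator subtlety governs how recovery results must be read: at
$N = 2000$ areas the label draw itself carries binomial noise of about
0.011 SE per group share, so the fitted $\hat\pi$ — which tracks the
*realised* shares to machine precision on well-separated panels — differs
from the design $\pi$ by sampling noise no estimator can remove. Recovery
is therefore judged on the replicate average against the design values and
per-replicate against the realised shares.

## Numerical choices, sizes, defaults

* EM tolerance `1e-8` (relative), `max_iter = 500`, `n_starts = 3`
  (tests and examples often use 1–2 starts: k-means initialisation on
  well-separated panels reaches the global basin directly).
* All randomness flows from one integer seed through a derived-seed
  stream, so every fit, simulation and pipeline run is reproducible.
* The test suite's recovery study uses 2,000-area, three-group panels
  with 5-SD group separation and the historical missingness pattern —
  10 replicates for estimation, 20 for enumeration over $G = 1..5$ —
  sizes chosen to make sampling error small relative to the bounds being
  asserted while keeping the whole suite quick on one core.
* Degenerate inputs: zero-noise panels converge with $\sigma$ pinned at
  the floor and a warning; overfitted $G$ may legitimately collapse a
  group or fail the tight tolerance — both are flagged, recorded in the
  enumeration table, and never silently discarded.

## Known limitations

The model inherits GBMTM's standard caveats: the groups are a convenient
discretisation of what may be continuous heterogeneity; enumeration
indices rarely speak with one voice and the final $G$ is a judgement; and
standard errors for trajectory coefficients are not provided (the Wald
tests inside `adjust_orders()` are a pseudo-class approximation used only
for pruning). The areal-weighting converter ignores the distance decay of
migration and uneven population distribution within source zones — the
known cost of areal weighting without ancillary data — and the package
does not compute overlap weights from polygon geometry; it consumes
pre-built lookup tables.
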