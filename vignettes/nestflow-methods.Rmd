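---
title: "Methods: models, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind `nestflow`, the
meaning and defaults of its parameters, what the built-in simulator
does and does not cover, and the numerical choices that shape the
results. The worked example lives in the README; here we explain *why*
the package computes what it computes.

## The data model

A **colony map** is one blind mapping of one polydomous colony at one
timepoint: nests and trees as nodes (with coordinates, population or
mound volume, canopy cover), and trails as edges (internest or
foraging, with length and a traffic sampling gap). Traffic is
converted to a rate:

- `ants_per_cm = 10 / sample_gap_cm` — the sampling protocol counts
  the gap between ten consecutive ants walking the trail, so a 10 cm
  gap means one ant per cm of trail.
- `total_ants = ants_per_cm * length_cm` — the standing count on the
  trail.
- The trail **weight** normalises that count by the population it
  could draw on: the mean of the two nest populations for an internest
  trail, the single nest population for a foraging trail. Weights are
  therefore comparable across colonies of very different size.

Populations can be measured directly or derived from mound volume via
a user-supplied calibration (`population_from_volume()`); the map
constructor validates every type invariant and names the offending
node or trail in its errors rather than coercing silently.

## Resource flow

The per-nest flow measure is **weighted betweenness**: trail weights
enter shortest-path computations as distances via their reciprocal
(`1 / weight`), so heavy trails are short. Trees and foraging trails
participate as sources/targets of paths but trees are terminal — a
tree has betweenness zero by construction since no path passes
*through* it. Endpoints of a path do not count toward their own
betweenness, and tied shortest paths split the count fractionally
(each of $k$ tied routes contributes $1/k$). Zero-weight trails are
excluded: a trail nobody walks carries no flow.

Raw betweenness is normalised by the colony's maximum nest value so
every map lands on $[0, 1]$, making the measure comparable across
colonies and timepoints. Two edge cases are handled explicitly:

- A map where every nest has betweenness zero (e.g. a star of
  foraging trails) normalises to all zeros and is flagged
  `degenerate` in `colony_metrics()`; there is no flow structure to
  rank.
- The categorical summary `categorize_flow()` maps normalised values
  to `zero` (= 0), `low` (0–0.25), `medium` (0.25–0.75, inclusive),
  `high` (0.75–1), and `one` (= 1).

Colony-level metrics are **foraging effort** (foraging traffic as a
share of total traffic) and the **worker-to-forager ratio**.

## Nest histories

Repeated mappings are blind: nest identity must be reconstructed.
`link_identities()` matches nests across consecutive maps by
proximity (greedy nearest-first within `max_link_distance`, default
2 m, each nest matched at most once), producing persistent tracks.
Each interval between consecutive maps then yields events: a track
present before but not after was **abandoned**; a nest with no
antecedent was **founded**. The bookkeeping identity

$$\text{nests}_{t+1} = \text{nests}_t + \text{founded} - \text{abandoned}$$

is asserted on every interval, and `net_nest_change()` applies the
same arithmetic to long-term count tables. Percentage changes are
reported to one decimal from the raw counts; note that published
count tables occasionally carry rounding inconsistencies (a 14-to-2
decline is −85.7 %, whatever a summary row may say), so the package
always recomputes from counts rather than trusting printed
percentages.

`classify_founders()` attributes each founded nest to a natal nest
when the attribution is unambiguous (a single established neighbour
within budding range); otherwise the candidate set is reported and
downstream analyses choose a policy (below).

## Survival analysis: extended Cox with a QAP null

Nest abandonment is modelled on **counting-process records**: one row
per nest per inter-mapping interval, `(start, stop]` in interval
units, `event = 1` if the nest was abandoned in that interval.
Covariates (normalised betweenness, size, canopy, tree distance,
worker-to-forager ratio) are taken at the start of each interval, so
the model is an extended (time-varying covariate) Cox proportional
hazards model. Delayed entry (nests founded mid-study) is handled
naturally by the counting-process form. Colony enters as a factor by
default (`colony = "factor"`), or as a stratum (`colony =
"stratum"`) when colony-specific baseline hazards are preferred; ties
use Efron's method.

Nests in a colony share a network: their covariates and fates are not
independent, so the asymptotic Wald/likelihood p-values of the Cox
fit are not trusted for inference. Instead, `qap_cox()` uses a
**quadratic assignment procedure**: the tested covariate is permuted
*within each colony-by-timepoint map* (all other columns, including
co-adjusted covariates, keep their observed structure), the model is
refit, and the observed z statistic is ranked against $B$ null
statistics with the add-one estimator

$$p = \frac{1 + \#\{|z_b| \ge |z_{obs}|\}}{B + 1},$$

which can never be smaller than $1/(B+1)$. Lower and upper tails are
available and reuse the same null draws. Permutation seeds are drawn
up front from the user seed, so results are exactly reproducible and
the null distribution is independent of the tail choice.

**Separation policy.** With few events, a covariate can perfectly
order events before non-events, making the partial likelihood
monotone and its coefficient meaningless. `fit_extended_cox()`
*warns* when any coefficient exceeds 15 in absolute value (the fit is
still returned, because an adjusted nuisance covariate may be
separable while the tested one is fine). `qap_cox()` *refuses* to run
when the tested covariate itself is separable — a permutation p-value
for an uninterpretable statistic would be misleading — and null
refits that go separable are dropped from the null (counted in
`n_failed`, with the effective `B_ok` reported). With fewer than
roughly 100 usable permutations the p-value resolution is coarse and
a warning says so.

## Budding analysis: binomial GLMM

For every interval in which at least one nest was founded, each
established nest is labelled `founder` or `nonfounder` (ambiguous
attributions become `possible_founder`). The model is a binomial GLMM
(`lme4::glmer`, bobyqa optimiser) with random intercepts for colony,
nest within colony, and season, and the fixed effect(s) of interest.
Inference is a **chi-squared analysis of deviance**: twice the
log-likelihood difference between the full model and the same model
without the fixed effects, on as many degrees of freedom as fixed
parameters dropped, with both models forced onto identical rows.

Two choices deserve emphasis:

- **Covariate timing.** The default `timing = "start"` reads
  covariates from the map at the *start* of the founding interval,
  and change covariates (`d_*`) over the *preceding* interval. The
  alternative `timing = "end"` (covariates from the map in which the
  bud first appears) is provided for comparability but is mechanically
  confounded for network measures: the new bud's trail itself raises
  its natal nest's betweenness, so end-timed betweenness "predicts"
  founding even when founding is random. Under the null the start
  timing is calibrated and the end timing is not; use `"end"` only
  with covariates the founding event cannot alter.
- **Possible-founder policy.** `exclude` (default) drops ambiguous
  nests; `as_founder` and `as_nonfounder` recode them.
  `policy_sensitivity()` runs all three and flags whether the
  conclusion at $\alpha = 0.05$ is stable across codings.

## The simulator

`simulate_colonies()` generates colonies with known ground truth for
calibration and power studies. Per colony: nest coordinates in a
square arena, internest trails as a random spanning tree plus extra
edges (probability `extra_edge_prob = 0.3` per candidate), trees
claimed by at most one nest each via foraging trails
(`forage_prob = 0.8`), lognormal nest populations
(`meanlog = 9.8`, `sdlog = 1.5`, i.e. median ≈ 18,000 workers —
realistic wood-ant scale). Each step, nests are abandoned and buds
founded by logistic models:

$$\operatorname{logit} P(\text{abandon}) =
  \operatorname{logit}(0.15) + \beta_{ab} \cdot \text{betweenness},
\qquad
\operatorname{logit} P(\text{bud}) =
  \operatorname{logit}(0.10) + \beta_{bud} \cdot \text{betweenness}$$

with all $\beta$ defaulting to 0 (the null). Buds are placed 3–8 m
from the natal nest, at least 2.5 m clear of other nests and recent
ghosts, and connected by a single trail to the natal nest, which
makes founder attribution unambiguous by construction. After
abandonment the network is reconnected if it fragments, at least one
nest always survives, populations drift lognormally
(`pop_drift_sd = 0.3`), and a fraction of trails turn over
(`trail_drop_prob = 0.08`). Every planted event is written to a truth
ledger with its per-nest probability and natal nest.

The default configuration — 13 colonies, 5 timepoints (summer 2012
through summer 2014, alternating seasons), 2–21 initial nests, 4–16
trees — is the package's chosen study scale: large enough that the
null-calibration and power checks in the test suite have meaningful
resolution, small enough to run on a laptop. These sizes are a design
choice of this package, not a property of any particular field
system.

**What the simulator does not cover.** Trails are straight lines with
independent traffic; there is no seasonality in behaviour beyond the
season label, no resource depletion at trees, no polygyny/queen
structure, no spatial correlation in abandonment beyond what the
network induces, and no measurement error in nest populations.
Calibration and power results transfer to field data only insofar as
these simplifications are benign; they validate the *machinery*, not
any biological claim.

## Validation strategy

The test suite validates against independent oracles, never against
the package's own output:

- Betweenness is compared with an exhaustive simple-path enumeration
  on every fixture map of ≤ 7 nodes, and on random maps; trees must
  come out exactly zero.
- The Cox partial likelihood is compared with a direct grid
  evaluation of the Breslow log partial likelihood on a toy data set
  (maximiser agreement to three decimals), and Kaplan–Meier values
  against hand-computed products.
- QAP and analysis-of-deviance p-values are checked for uniformity
  under the null (Kolmogorov–Smirnov over replicate simulations) and
  for power under planted effects (a log-hazard slope of −2 must be
  detected at $p \le 0.05$ in at least 80 % of replicates; a planted
  budding logit slope of 3 must be recovered within its confidence
  interval).
- Bookkeeping identities are asserted on every simulated interval,
  founder classification must recover 100 % of planted natal nests on
  unambiguous fixtures, and a fixed-seed pipeline rerun must be
  byte-identical.

`scripts/acceptance.R` re-runs this study against the installed
package and writes the computed quantities as JSON (see the README).

## Limitations

- The QAP null holds the network and all other covariates fixed and
  permutes only the tested covariate within maps; it tests *that
  covariate's* association, conditional on everything else, and does
  not address confounding by unmeasured network position.
- The Cox model treats intervals as the time axis; unequal calendar
  gaps between mappings are not rescaled. With seasonal mapping this
  is deliberate (the interval is the natural unit), but it is an
  assumption.
- GLMM random-effect variances are often estimated near zero at these
  sample sizes; the analysis of deviance is still valid but singular
  fits are tolerated rather than reported as errors.
- Identity linking is purely spatial; nests that move more than
  `max_link_distance` between mappings break their track and appear
  as an abandonment plus a founding.
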