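---
title: "Modelling patient-referral networks between health facilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling patient-referral networks between health facilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(referralnet)
```

## The problem

District health systems in many low- and middle-income countries are
organised as a tier hierarchy — dispensaries (primary care), health
centres (secondary) and hospitals (tertiary) — in which health centres are
meant to act as *gatekeepers*: dispensaries refer upward to health
centres, which filter cases onward to hospitals. Whether referrals
actually follow this route is an empirical question. `referralnet`
analyses it in two steps: descriptive network statistics that
operationalise gatekeeping, and exponential random graph models (ERGMs)
that estimate which facility and dyad characteristics drive tie
formation.

The unit of analysis is a **binary directed network** per district and
care domain (childcare vs non-communicable diseases). Referral ledgers
record events per condition category; data preparation collapses them so
that `y_ij = 1` whenever at least one referral from facility `i` to
facility `j` was recorded in any category during the observation window.
Weights are deliberately discarded: over a short window (three months in
the reference design), multiplicities are too noisy to model, while the
existence of a channel is comparatively reliable. Facilities that
received referrals but lie outside the surveyed set (private facilities,
facilities in neighbouring districts) are retained as network nodes with a
reduced covariate set; isolates are retained too, because facilities with
no referral activity are themselves informative (the model carries an
isolates term).

## Descriptive statistics

* **Density** is the number of ties over the `n(n-1)` ordered dyads.
* **Tier flows** cross-tabulate ties by sender and receiver tier; the
  table also counts ties to private/faith-based receivers and ties
  crossing the district boundary.
* **Referral rates** relate tie counts to reported visit volumes
  (`ties / visits * scale`), e.g. per 10 000 outpatient visits.
* **In-degree** counts incoming referrals — how strongly a facility
  attracts referrals.
* **Betweenness** is the raw (unnormalised) directed betweenness: the
  number of shortest directed paths between ordered pairs of other
  facilities that pass through the focal facility, with fractional
  attribution when several shortest paths tie, endpoints excluded. In a
  chain dispensary → health centre → hospital, the health centre scores 1;
  this is precisely the gatekeeping position. Raw counts (rather than a
  normalised index) are used because on networks this sparse the scores
  are small integers and are easiest to read that way. We follow the
  mathematical definition throughout: interior nodes of shortest paths
  score, endpoints never do.

Rankings break score ties lexicographically by facility id, so reports
are deterministic.

## The model

The network is modelled as an exponential family over all
`2^{n(n-1)}` digraphs,

$$P(Y = y) = \frac{\exp(\theta^\top u(y))}{Z(\theta)},$$

with sufficient statistics `u(y)` assembled from a declarative term list:

* `edges`: overall tie propensity (the sparsity baseline).
* `isolates`: the number of facilities with zero total degree, capturing
  the excess of completely inactive facilities relative to an
  edges-only model.
* `gwidegree(α)`: geometrically weighted in-degree,
  $e^{\alpha} \sum_{k \ge 1} \bigl(1 - (1 - e^{-\alpha})^k\bigr) D_k$,
  where `D_k` is the number of nodes with in-degree `k`. It models the
  skewed popularity distribution (hospitals attracting most referrals).
  The decay `α` is **fixed**, not curved-estimated: one value per model,
  it is not counted among the free coefficients `k` in AIC/BIC, matching
  how the information criteria combine with the coefficient counts in the
  reference analysis. Typical values in that analysis range from 0.5
  to 2.25.
* `edgecov(x)`: a dyadic covariate, here road distance in km. The
  transform is configurable (`identity`, `log`, `log1p`) because distance
  effects of plausible magnitude on a per-km scale would make referrals
  over more than a few km vanishingly improbable; the package exposes the
  transform rather than presuming one.
* Facility covariates act on incoming ties (`node_cov_in`,
  `node_factor_in`), outgoing ties (`node_cov_out`), or both combined
  (`node_cov_combined`, `node_factor_combined`). Factor terms use
  `dispensary` as the implicit reference level. Count covariates use
  `log1p` when a log scale is wanted (they contain zeros); catchment
  population, guaranteed at least 1, can use a plain `log`.

The conditional log-odds of a single tie given the rest of the network is
`θᵀ δ_ij`, where the **change statistic**
`δ_ij = u(y⁺_ij) − u(y⁻_ij)` is the effect of toggling that tie. All
change statistics are computed incrementally (e.g. the gwidegree change
for a receiver with prior in-degree `d` is `(1 − e^{-α})^d`), and a
property-style test verifies them against global statistic differences
for every term on small random digraphs at machine precision.

## Estimation

**Maximum pseudolikelihood (MPLE).** Maximises
$\sum_{i \ne j} \bigl[ y_{ij}\,\theta^\top\delta_{ij} - \log(1 +
e^{\theta^\top\delta_{ij}}) \bigr]$, a logistic regression of the tie
indicators on the change statistics over all dyads (change statistics
evaluated with the focal tie removed). The maximisation is IRLS Newton
(`glm.fit`); standard errors come from the observed information of this
objective. Quasi-separation is flagged when the optimiser fails to
converge or any coefficient exceeds 20 in magnitude; a small ridge
penalty (`1e-4`, configurable) then keeps the reported coefficients
finite, with a warning. The reported `logLik` of an MPLE fit is the
maximised pseudolikelihood and is labelled as such; AIC/BIC comparisons
across estimation methods carry the method tag. For models built solely
from dyad-independent terms (everything except `isolates` and
`gwidegree`), the pseudolikelihood *is* the likelihood and MPLE is
exact maximum likelihood.

**Sampling.** Networks are simulated with a tie/no-tie (TNT) Metropolis
sampler (C++): with probability ½ propose toggling a uniformly chosen
existing tie, otherwise a uniformly chosen dyad; the acceptance ratio
combines `θᵀδ` with the proposal correction. TNT is the standard choice
for sparse networks because plain dyad sampling wastes almost all
proposals on empty dyads. All randomness flows through R's RNG, so every
run is reproducible from a single seed, which fits record.

**Monte-Carlo MLE.** Starting from the MPLE (or a user-supplied
`theta0`), the Geyer–Thompson iteration simulates a statistic sample at
the current estimate and maximises the importance-sampled log-likelihood
ratio by Newton steps. Two numerical guards matter: the per-round total
displacement is capped in the infinity norm (the importance approximation
is only trustworthy near the sampling point), and if any observed
statistic falls outside the simulated range the fit aborts with a classed
degeneracy error carrying a diagnostic payload — this is the signature of
a model placing its mass on near-empty or near-complete graphs.
Convergence is declared when the update falls below `tol`. Standard
errors use the inverse covariance of the simulated statistics (the
estimated Fisher information). The log-likelihood is estimated by
thermodynamic integration along the path `t·θ̂`, `t ∈ [0, 1]`:
`log Z(θ̂) − log Z(0) = ∫ θ̂ᵀ E_{tθ̂}[u] dt` with `Z(0) = 2^{n(n-1)}`,
using a midpoint rule (32 steps by default; the discretisation error of
the midpoint rule at 16 steps was measurable against the edges-only
closed form, at 32 it is a few tenths of a log-likelihood unit). The path
is walked from the fitted end towards the null so each step's chain
warm-starts near its stationary distribution.

**Information criteria.** `AIC = −2ℓ + 2k`, `BIC = −2ℓ + k log m` with
the sample size taken as the number of directed dyads `m = n(n−1)` — the
convention under which the published information criteria for this model
family reproduce from their log-likelihoods and coefficient counts.

## Interpretation: tie probabilities and scenarios

An inverse-logit transform turns the linear predictor into the
conditional probability of a tie,
`p_ij = 1 / (1 + exp(−θᵀδ_ij))`, with `δ_ij` evaluated on the observed
network with the focal tie absent. In an edges-only model this equals
the observed density for every dyad — a useful analytic identity that the
tests exploit for both estimators. Scenario prediction
(`scenario_delta()`) modifies sender and/or receiver attributes,
recomputes `δ_ij`, and reports the relative probability change. These
are *conditional* (not marginal) quantities: the same attribute change
moves different dyads by different amounts because the effect depends on
the dyad's initial change statistics. Marginal-effect curves are out of
scope.

## Goodness of fit and degeneracy

`gof()` simulates networks at the fitted coefficients and compares the
observed monitored statistics to the simulated 2.5/97.5 percentile
envelopes. Monitored statistics are the model statistics plus the full
in-degree and out-degree distributions; geodesic-based summaries are
deliberately excluded because on networks of density 0.02 most pairs are
unreachable and those statistics are unstable. A degeneracy flag is
raised when the simulated mean density falls below 0.1× or above 10× the
observed density, or when the simulations collapse to empty or complete
graphs.

## The synthetic-data generator

Because the reference study deposits no raw data, the package ships a
generator that emulates its structure, so that every pipeline stage is
testable end to end:

* `fixture_from_table4()` builds *deterministic* two-district fixtures:
  rosters with the published tier mixes (46 = 40/3/3 and 31 = 25/4/2,
  with 42 and 27 surveyed facilities respectively) and referral records
  reproducing the published tier-to-tier flow counts exactly. Published
  tables constrain only the tier-pair counts, not which facilities
  connect, so edges are assigned round-robin over the facilities of each
  tier in roster order — edge identity is deterministic and no RNG is
  involved. Ownership and district flags are set so the roster-level
  margins (three faith-based facilities in one district; one private and
  one faith-based receiver in the other) hold; the edge-level margins to
  private/out-of-district receivers are then whatever the round-robin
  induces, since both sets of margins cannot be satisfied simultaneously
  without knowledge of the true assignment.
* `generate_roster()` draws seeded rosters with configurable tier counts.
  Count covariates (rooms, beds, vehicles, deliveries) are truncated
  negative-binomial draws with tier-specific means inside the published
  marginal ranges (e.g. rooms in 1–36, a median-4 profile); catchment
  population is log-uniform within tier-specific ranges. Dispensaries
  scatter uniformly over a square of configurable extent; hospitals sit
  centrally (town-like geography) or at the edge (distant-hospital
  geography).
* `generate_distances()` is straight-line distance times a road factor
  (default 1.3). Real road networks are not metric multiples of
  Euclidean distance; the package accepts any externally supplied matrix,
  and whether distances are routed or straight-line is recorded by the
  user's provenance, not assumed.
* `generate_network()` draws one network from a ground-truth ERGM via the
  TNT sampler after a long burn-in (default `1e5` proposals), with a
  guard that errors if more than 90% of inspected draws are empty or
  complete.

### The parameter-recovery scenario

`recovery_config()` fixes the simulation study used for validating the
estimator: 40 facilities (34/3/3), ground truth
`edges = −3.5`, `edgecov(log1p distance) = −1.0`,
`nodeifactor(hospital) = +2.0`, 50 replicate networks, each fitted and
compared to the truth. The spatial extent (2 km before the road factor)
was chosen once so that this ground truth produces networks at the
sparsity of real referral networks — realised densities average 0.02 —
and was not revisited; with three hospitals and this geography a
replicate carries roughly 30 ties. Because all three terms are
dyad-independent, the MPLE used in the harness is the exact MLE, so the
study measures estimator error, not an MPLE/MLE gap. At these sizes the
absolute mean bias per coefficient stays well under 0.15 and the ±2 s.e.
coverage near its nominal 95%, but with 50 replicates both quantities
retain visible Monte-Carlo wobble (the standard error of the mean bias is
about 0.07 for the edges coefficient); the validation thresholds should
be read with that granularity in mind.

### What the generator does not emulate

Synthetic districts have uniform facility scatter, metric distances,
independent covariates, and tie formation that follows the fitted model
family exactly. Real referral systems have clustered settlements, road
networks with barriers, correlated infrastructure (big facilities have
more of everything), and behavioural drivers outside the model. Passing
tests therefore demonstrate that the *machinery* is correct — statistics,
sampler, estimators, coverage — not that the model family captures any
particular real system.

## Numerical and design choices

* CSV dialect: comma-separated, UTF-8, mandatory header, `.` decimal
  mark. Distance matrices are checked for symmetry within 1e-6 km, then
  symmetrised by averaging (a single dyadic distance coefficient implies
  a symmetric covariate).
* Dyad enumeration order is roster order, row-major; node order is roster
  order — all outputs are deterministic given inputs and seed.
* Betweenness and GraphML I/O delegate to igraph; betweenness is verified
  in the tests against an exhaustive shortest-path enumeration oracle on
  small digraphs.
* Sampler defaults: burn-in `1e5` proposals, interval `1e3`, 1000
  retained draws; bridge: 32 steps × 256 draws with the sampling interval
  widened to the dyad count to curb autocorrelation.
* Problem sizes in the test suite and validation scripts (40-node
  recovery networks, 50 replicates, 100 GOF simulations, 4-node
  enumeration oracles) were chosen as the smallest sizes at which the
  checked properties are statistically meaningful; the full suite runs in
  well under a minute.

## Limitations

* No valued, longitudinal or bipartite networks; no triadic terms — the
  reference model family does not use them, and sparse referral networks
  rarely support their estimation.
* The gwidegree decay is fixed by the analyst, not estimated; model
  selection over decays must be done by refitting.
* MPLE standard errors are exact only for dyad-independent models; for
  models with `isolates`/`gwidegree` the MCMC estimator should be
  preferred when inference matters.
* Scenario predictions are conditional on the observed network and the
  fitted coefficients; they are not causal estimates of the effect of
  expanding a facility.
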