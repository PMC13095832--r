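---
title: "Modelling the evolution of cutting preferences in leaf-cutting ants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the evolution of cutting preferences in leaf-cutting ants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cutevo)
```

## The question and the data

Leaf-cutting ants (*Acromyrmex*, *Amoimyrmex*, *Atta*) harvest fresh plant
material to feed a symbiotic fungus. Species differ in what they cut:
most are dicot specialists, a minority cut grasses, and a few switch
between the two. Whether grass cutting is one old innovation or a set of
independent, convergent responses to the spread of open grassy habitats is
a question about the history of a discrete character on a time-calibrated
phylogeny.

`cutevo` packages the standard comparative machinery for that question
around a compiled species-by-preference table. The table records, for all
46 valid leaf-cutting ant species, a verbatim preference annotation
(`Dicot`, `Grass`, `Dicot-Grass`, question-marked variants for poorly
documented preferences, and `?` for undocumented species), whether the
species is available for phylogenetic analysis, and literature reference
codes.

```{r}
traits <- load_trait_table()
dplyr::filter(count_by_state(traits), genus == "total")
```

Three normalization rules matter and are worth stating explicitly:

* **Question-marked annotations resolve to their stated state** and are
  flagged `uncertain`. The published per-state totals (27 dicot, 12 grass)
  are only reproducible under this rule — e.g. the grass total requires
  the `Grass?` record for *Amoimyrmex bruchi* to count as grass.
* **The social parasite** (*Acromyrmex ameliae*) gets its own bookkeeping
  state. It enters every likelihood computation as a fully ambiguous
  observation (an all-ones weight vector) rather than as a fourth Markov
  state: a 4-state model with a single observed tip in the fourth state
  would be unestimable. The species list treated this way is a
  configurable argument, not a hard-coded name.
* **Undocumented species** (`?`) are excluded from phylogenetic analysis
  by default; `include_unknown = TRUE` admits them as ambiguous tips.

Tip labels use `Genus_species` with underscores (newick-safe); matching
against the table is case-insensitive on both fields.

## The Mk model with equal rates

The character evolves along the tree as a continuous-time Markov chain on
k = 3 states. Under the equal-rates (ER) parameterization every
off-diagonal entry of the rate matrix is a single rate q (per Ma):
Q_ij = q for i ≠ j and Q_ii = −(k−1)q. ER admits a closed-form transition
probability,

P_ii(t) = 1/k + (1 − 1/k) e^(−kqt),  P_ij(t) = (1 − e^(−kqt))/k,

which the package uses everywhere (a general eigendecomposition fallback
exists for non-ER matrices). The stationary distribution is uniform, which
is also the default root prior; this keeps the chain time-reversible, a
property the re-rooting method below requires. The root prior is
configurable, but the reconstruction functions refuse non-stationary
priors rather than silently produce invalid marginals.

The likelihood of the tip data is computed by Felsenstein's pruning
algorithm: a postorder pass over the tree accumulating per-node
conditional likelihood vectors, with per-node rescaling (accumulated
log-scalers, not a single global rescale) so that trees several thousand
tips deep cannot underflow. Zero-length branches are legal and get an
identity transition matrix — consensus trees contain them.

`fit_er_rate()` maximizes the profile over q by bounded one-dimensional
optimization on the log scale. The bracket is scale-free:
q ∈ [1e−8/T, 1e3/T] with T the root age, spanning effectively-frozen to
fully saturated regimes regardless of the tree's time units. When every
tip carries the same certain state the likelihood is monotone decreasing
in q and the fit returns the lower bound with a warning rather than an
arbitrary interior value. The fitted rate is then held fixed: ancestral
states and stochastic maps condition on q̂ (the usual empirical-Bayes
practice of the methods this package implements) rather than re-optimizing
inside each downstream call.

## Marginal ancestral states by re-rooting

For a reversible chain at stationarity, the marginal posterior of the
state at any node equals the root marginal of the tree re-rooted at that
node. The production implementation (`marginal_asr_rerooting()`) computes
all of these in one inside–outside sweep: postorder "inside" partials
D_n(s), then a preorder "outside" pass U_n(s) carrying the evidence from
the rest of the tree, with

P(state(n) = s | data) ∝ π_s · D_n(s) · U_n(s).

Sibling products in the outside pass are recomputed by exclusion rather
than by division, because partials can contain exact zeros (e.g. in the
q → 0 limit). A literal implementation (`marginal_asr_direct()`) re-roots
the tree at every node as an undirected graph and reruns the recursion
from scratch; it shares no traversal code with the fast path and exists
so the two can be bound together in tests (they agree to 1e−8 per entry
over batteries of random instances, and to the established re-rooting
implementation in `phytools` on the study-scale fixture).

Marginals are reported at tips too: certain tips collapse to their
indicator, while ambiguous tips (the parasite, undocumented species)
receive a genuine posterior and are flagged `imputed_tip` in
`summarize_asr()` reports. Modal-state ties are broken by state-label
order and flagged explicitly; the support threshold defaults to 0.8.

## Stochastic character mapping

A stochastic map is one complete realization of the character history
conditioned on the tips. Sampling proceeds in the standard two stages:

1. **Node states jointly**: the root from π_s D_root(s); then each child
   in preorder from P(parent → s, t) D_child(s). Tips observed with
   certainty always receive their observed state.
2. **Branch paths** by uniformization, the endpoint-conditioned exact
   sampler: with dominating rate Λ = max|Q_ii|, the number of candidate
   jumps is drawn from the Poisson mixture conditioned on the endpoints,
   jump times are uniform order statistics, and jump states follow the
   uniformized chain bridged to the endpoint. Uniformization was chosen
   over rejection sampling as the production algorithm because its
   runtime is bounded when the endpoint pair is unlikely; a forward
   rejection sampler is retained in the test suite as the independent
   oracle (the two agree in distribution on transition counts).

Consecutive equal-state segments are merged: virtual jumps of the
uniformized chain are invisible in output, because histories are only
identifiable up to real transitions.

Reproducibility follows a documented substream scheme: realization i of
`stochastic_map(..., seed = s)` uses the substream seed
(48271·s + i − 1) mod (2³¹ − 1), so a set of maps is reproducible
regardless of how the loop is executed, prefixes of longer runs agree,
and distinct root seeds give distinct streams.

Maps serialize to the SIMMAP newick dialect (`{state,duration:...}` per
branch). On disk the segments are listed in the v1 convention
(child-to-parent within the braces), which is what the common readers in
the field parse; in memory, segment lists always run parent-to-child.

## The accumulation statistic

For each map, the package extracts every transition event with its time
measured *forward* from the root (t_f = 0 at the root, t_f = root age at
the present; "age" is the complementary coordinate, and both appear in
all reports). The accumulation curve is the cumulative count of
transitions **into** each state evaluated on a uniform grid of 200 points
spanning root to present, averaged across maps.

Two published phrasings of this statistic conflict: "lineages possessing
each trait" versus "lineages transitioning into each state". The
implemented statistic is cumulative transitions-into-state, because the
extraction step that feeds it collects transition timings, not
standing-lineage counts. A standing-lineage variant — the number of live
branches occupying each state at each grid time — is provided under a
clearly distinct name (`lineage_state_counts()`) for readers who want the
other quantity.

Grid conventions: endpoints inclusive (the root at t_f = 0 and the
present at t_f = root age are both grid points); events falling exactly
on a grid point count at that point (closed-left). Means are taken over
per-map cumulative counts; averaging per-bin increments and then
cumulating would give the identical result. Doubling the grid never
changes the value at shared grid times, and the final value of each curve
equals the mean transitions-into count from the per-map summaries — both
are asserted in the test suite.

## The synthetic-data generator

The chronogram underlying the empirical analysis is not deposited, so the
package ships a generator that emulates its statistical frame and gives
every stage a ground truth:

* `simulate_bd_tree()` runs a forward Gillespie birth–death simulation
  from a single stem lineage, prunes extinct lineages completely, and
  conditions on reaching the requested number of extant tips. At the
  moment the target count is reached, all extant branches are extended by
  the waiting time to the next (unexecuted) event, so the stopped tree
  has no zero-length cherry. Branch lengths are then rescaled to the
  requested root age. Under pure birth the mean lineage count at time t
  matches the Yule growth law e^(λt) (asserted against 500 replicates).
* `simulate_mk_history()` runs the ER chain forward down every branch
  from a known root state, recording the full true history.
* `study_scenario()` freezes the study-scale instance: 34 tips, root age
  16.72 Ma, birth 0.3 / death 0.1 per Ma, ER rate q = 0.03 per Ma,
  root state dicot, one tip relabelled as a fully ambiguous
  social-parasite analog. The birth and death rates are unconstrained by
  the empirical study (which dated its tree rather than estimating
  diversification); 0.3/0.1 per Ma gives mid-Miocene-scale trees with
  moderate extinction, a realistic regime for this clade. The rate
  q = 0.03 was fixed once so that tip compositions land near the
  empirical included-species composition (22 dicot / 9 grass /
  2 dicot-grass among 33 informative tips); candidate simulations are
  drawn from seed-derived substreams until the realized counts fall
  within ±30% of that composition, making the scenario deterministic
  given its seed (default 42).

What the generator does *not* emulate: fossilized-birth–death dating
uncertainty (no HPD intervals — the tree is known exactly), lineage-
specific diversification-rate variation, state-dependent diversification,
and rate heterogeneity across the character (the generator is exactly the
ER model the estimator assumes). Passing tests therefore demonstrate
correctness of the machinery under its own model, and calibration of the
pipeline at the study's scale — not robustness to model violation in real
data.

## Numerical choices

* Ultrametricity tolerance: 1e−6 relative to root age by default
  (dated trees carry rounding noise); the birth–death simulator's output
  passes a much stricter 1e−8 check.
* Node ids follow the `ape` convention (tips 1..N in input order, root
  N+1, internal nodes onward), which is deterministic for identical input
  text — the property node-indexed reports need.
* Per-branch segment lists must tile the branch to 1e−9; serialization
  and event extraction both verify this and refuse inconsistent
  histories.
* Optimization tolerance 1e−10 on log q; the optimizer's argmax matches a
  10^4-point grid search within grid spacing on instances with an
  identifiable interior optimum (saturated plateaus are compared on
  attained likelihood instead).
* Polytomies are supported throughout; nothing forces binary trees.

## Problem sizes in the validation suite

The shipped test battery exercises: exhaustive-enumeration likelihood
checks on 100 random trees with up to 6 internal nodes; re-rooting vs
literal re-rooting on 100 random instances of 4–50 tips; transition
probabilities against a series matrix exponential across kqt ∈ [0, 100];
10^4 stochastic maps against ASR marginals (total variation ≤ 0.02) and
10^5 endpoint-conditioned draws against the rejection oracle (chi-square);
rate recovery across 50 simulations on 200-tip trees with kq·depth in the
identifiable window [0.5, 3] (median q̂/q within [0.8, 1.25]); and a
byte-reproducibility check of the full pipeline on the frozen scenario at
the conventional settings (100 maps, 200-point grid).

## Limitations

* Only the equal-rates model is fitted; no SYM/ARD selection, hidden-rate
  models, or correlated-character tests. The general-Q code paths exist
  but are deliberately not surfaced.
* Marginal (not joint) reconstructions only; no Bayesian integration over
  q.
* The accumulation statistic counts transitions, not diversification: it
  says when shifts happened, not whether they changed speciation or
  extinction rates.
* Real chronograms come with dating uncertainty that a single tree —
  empirical or simulated — does not carry; all downstream probabilities
  are conditional on the tree.
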