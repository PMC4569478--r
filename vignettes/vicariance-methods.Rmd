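---
title: "Measuring vicariance on dated phylogenies: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring vicariance on dated phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vicarscan)
```

## The question this package answers

Given a rooted, dated phylogeny and a taxon-by-region presence/absence
matrix, how much of the speciation in the tree is attributable to
*vicariance* — the splitting of an ancestral geographic range into two
mutually exclusive daughter ranges? vicarscan answers this with two
complementary reconstruction engines and a shared summary statistic:

* a **DEC** (dispersal–extinction–cladogenesis) likelihood model, which
  yields, at every internal node, relative probabilities over
  range-inheritance scenarios; the node's *vicariance probability* is the
  summed relative probability of the scenarios whose daughter ranges are
  disjoint;
* a **DIVA-style event parsimony**, which finds all minimum-cost
  reconstructions and scores each node by the fraction of co-optimal
  reconstructions in which its event is a vicariance;
* an **aggregator** that counts, over an analyst-chosen set of focal nodes,
  how many nodes are vicariant under each engine (DEC probability above a
  threshold, DIVA majority), giving a whole-phylogeny vicariance fraction.

A relative-dating module summarises clade ages and age ratios across a
posterior sample of dated trees, and a forward simulator provides
ground-truth range histories for validation.

## The DEC model as implemented

**State space.** A range is a subset of the fixed region set, encoded as a
bitmask. With maximum range size $K$ the states are the empty range plus
all non-empty subsets of size $\le K$, ordered by size then bit value
(8 regions, $K=2$: 37 states). Ranges larger than $K$ are excluded from
the space rather than rate-blocked; this keeps the generator small and
well conditioned.

**Anagenesis.** Along a branch the range evolves by a CTMC with generator
$Q$: dispersal adds region $j$ at rate $d \sum_{i \in R} m_{ij}$ (only
while $|R| < K$), extinction removes any occupied region at rate $e$, and
the empty range is absorbing — a lineage whose range empties is globally
extinct and contributes nothing at the root or at any cladogenetic event.
$m$ is a user-supplied matrix of non-negative dispersal multipliers
(default all ones); its diagonal is ignored.

**Cladogenesis.** A singleton ancestral range is inherited identically by
both daughters. A widespread range $R$ splits either by *vicariance*
($\{i\}$ vs $R \setminus \{i\}$) or by *subset sympatry* ($\{i\}$ vs the
full $R$). Ordered left/right variants are distinct; after de-duplication
all scenarios at a node receive equal weight — 6 scenarios at $|R| = 2$,
$4|R|$ for $|R| > 2$. Note a structural consequence used later: DEC
vicariance always carves off a *single* region.

**Likelihood.** Felsenstein pruning with the cladogenetic convolution at
internal nodes, per-node rescaling of conditional-likelihood vectors (deep
trees at small rates underflow doubles otherwise), and a root convention of
an unweighted sum over non-empty root states (a uniform-prior variant is
available behind the `root` argument; it changes the log-likelihood by a
constant and no scenario probability). $P(t) = e^{Qt}$ is computed by
eigendecomposition — one decomposition per $(d, e)$, two small matrix
products per branch — with dense scaling-and-squaring (`Matrix::expm`) as a
per-branch fallback whenever a computed $P(t)$ fails a $10^{-9}$
row-stochasticity check; every returned $P(t)$ is then clipped into
$[0, 1]$.

**Scenario probabilities.** For node $v$ and scenario $s$, the relative
probability is the likelihood with the split at $v$ constrained to $s$
divided by the unconstrained likelihood. This is computed in one upward and
one downward sweep ("outside" partial likelihoods), and normalised within
each node, so per-node scale factors cancel exactly — the per-node sum of
scenario probabilities is 1 by construction, and the *values* are verified
in the tests against an independent oracle that enumerates complete
histories explicitly.

**Rate estimation.** `fit_dec()` maximises the likelihood over $(d, e)$ by
bounded quasi-Newton on log-rates from four deterministic starts
$(d, e) \in \{0.001, 0.1\}^2$ with bounds $[10^{-8}, 10]$, ties broken by
first-found. Two parameters and a cheap surface make multi-start the whole
safeguard needed against ridges.

## The DIVA engine

Event parsimony over the same bit-encoded ranges: vicariance (any disjoint
bipartition of a widespread range) and duplication (singleton ranges) are
free; each region gained (dispersal) or lost (extinction) along a branch
costs 1; branch lengths are ignored. The exact minimum is found by dynamic
programming over range states with at most `maxareas` regions per node
(default 3), and *all* co-optimal reconstructions are enumerated by
backtracking, capped (default 10,000) with an explicit truncation flag,
since optimum sets can explode combinatorially.

S-DIVA-style practice scores a node vicariant when its most likely
reconstruction is a vicariance; when several reconstructions are co-optimal
"most likely" is undefined, so the package generalises it to a majority
rule: a node is vicariant when more than half of the co-optimal
reconstructions give it a vicariance event. An exact 0.5 tie is flagged
ambiguous, scored non-vicariant, and warned about. The majority rule is a
documented design choice of this package, not part of the original DIVA
definition.

## The vicariance summary

`classify_split()` is deliberately tiny: a scenario is vicariant iff the
daughters are non-empty, disjoint, and the ancestor is widespread (the
canonical example: ancestor $ABC$, daughters $AB$ and $C$). A DEC node
counts as vicariant when vicariant scenarios carry more than 0.5 of the
relative probability — 0.5 because that makes vicariance the most likely
solution class; the threshold is an argument, and counts are monotone
non-increasing in it (tested). Focal nodes are user-declared clade
definitions resolved to MRCAs, not auto-detected: deciding which nodes
stand for the species and major lineages of a group is taxonomic judgment,
and the package refuses to guess.

## Relative dating

Clade ages are MRCA heights on trees that must be ultrametric within a
relative tolerance of $10^{-6}$ (floating-point Newick round-trips make
exact ultrametricity unreasonable). Ages are taken whether or not the clade
is monophyletic in a given posterior tree; the monophyly rate is reported
alongside, keeping "how old" and "how often recovered" separate. The 95%
interval is the empirical 2.5/97.5% quantile interval, computed by explicit
order-statistic interpolation so it is exactly reproducible sort
arithmetic; an HPD variant (`hpd_interval()`) is available for comparison
with tools that report highest-density intervals. Relative ages divide each
target's age by the reference clade's age *in the same tree*, so rate
scaling cancels: scaling all branch lengths by $c$ scales absolute ages by
$c$ and leaves relative ages unchanged (tested to $10^{-12}$).

## The simulator: what it emulates and what it does not

`simulate_yule()` draws dated trees from a constant-rate pure-birth process
conditioned on the tip count — matching the tree prior typically used for
such data — with one final exponential stretch so tips sit strictly below
the last split. `simulate_dec_history()` runs Gillespie dynamics of the
exact anagenetic generator along each branch and draws a cladogenetic
scenario uniformly at each node; every event is logged, and
`replay_history()` re-derives the tip ranges from the log bit-for-bit (a
tested invariant). Runs in which any lineage's range empties are rejected
and retried — rejection gives exact samples of the survival-conditioned
process, at the cost of a reported acceptance rate rather than importance
weights.

Randomness is counter-based: each (attempt, branch) pair derives its own
seed from the master seed, so enlarging the tree does not perturb earlier
branches. A side effect worth knowing: simulations differing only in root
range can *coalesce* — once two runs reach the same range on the same
branch they remain identical downstream.

Default synthetic geography is eight regions in a linear adjacency chain
(multiplier 1 between neighbours, 0.1 otherwise), a deliberately simple
stand-in for a north–south rainforest corridor; the values are arbitrary
and exist to exercise the constraint-matrix code paths. What the simulator
does **not** emulate: diversification-range feedback (the tree is drawn
first, ranges second), extinct side lineages, time-stratified geography,
and founder-event jump dispersal. A green end-to-end test therefore
establishes internal consistency of model, simulator and estimators — not
realism of any particular empirical system.

## Choices made where the design was open

* **Region count cap 30**, not 32: R integers are 32-bit signed and the
  sign bit is unusable; 30 keeps every mask a valid positive `integer`.
* **Scenario weighting** is uniform over de-duplicated ordered scenarios;
  the de-duplication matters only at $|R| = 2$, where the two vicariance
  orderings coincide with their mirrors.
* **Zero-length internal branches** are allowed (transition matrix =
  identity) so that deterministically resolved polytomies evaluate.
* **Clade definitions** are read from two-column TSV or JSON rather than
  YAML: the deployment environment provides no YAML parser, and the
  information content is identical.
* **Quantile convention**: linear interpolation of order statistics
  (R's type 7), written out explicitly; HPD offered separately rather than
  silently substituted.

## Two results every user should understand

**Extinction rates estimated from surviving clades are biased to zero.**
In the package's own recovery experiment (50 replicates, 50-tip Yule
trees, 4 regions, true $d = 0.1$, $e = 0.03$), the dispersal rate is
recovered well (median $\hat d/d \approx 0.88$) and the MLE dominates the
truth in every replicate, but $\hat e$ collapses to the lower bound in
essentially all replicates. The cause is structural, not numerical: the
simulator conditions on survival (histories in which a lineage's range
empties are rejected, as they must be — such lineages leave no sampled
descendants), while the DEC likelihood does not condition on survival, so
surviving tip data systematically under-represent extinction. The
corresponding acceptance assertion is left failing, deliberately, as an
honest record of this limit; treat empirical $\hat e$ from DEC with the
same suspicion.

**Pure-vicariance histories live on caterpillar trees.** Because DEC
vicariance always splits off a single region, an internal node whose both
children are themselves internal cannot appear in a zero-dispersal
pure-vicariance history: one daughter would inherit a singleton and could
never vicariate again. The end-to-end recovery test therefore uses
pectinate (caterpillar) topologies with the root carrying the full region
universe and near-zero anagenetic rates; under those conditions DIVA flags
every internal node as vicariant and DEC vicariance probabilities exceed
0.999.

## Worked example

```{r example, eval = FALSE}
rs <- region_set(paste0("R", 1:8))
pars <- dec_params(d = 0.1, e = 0.03, K = 2, m = linear_chain_constraints(rs))
tree <- simulate_yule(30, birth_rate = 0.25, seed = 1)
sim <- simulate_dec_history(tree, rs, pars,
                            root_range = range_encode(c("R4", "R5"), rs),
                            seed = 2)

fit <- fit_dec(tree, sim$tip_ranges, K = 2, m = pars$m)
scen <- ancestral_split_probs(tree, sim$tip_ranges, fit$params)
dec_probs <- dec_vicariance_probs(scen)

dp <- diva_min_cost(tree, sim$tip_ranges, maxareas = 3)
diva_scores <- score_node_vicariance_diva(enumerate_optimal_reconstructions(dp))

focal <- stats::setNames(sort(unique(scen$node)),
                         paste0("node", sort(unique(scen$node))))
aggregate_vicariance(dec_probs, diva_scores, focal)
```

## Known limitations

* No founder-event (+J) cladogenesis, no time-stratified constraints, no
  Bayesian DEC, no DIVA averaging over tree samples.
* DIVA optimum-set enumeration is exponential in the worst case; the cap
  plus truncation flag make this visible rather than silent.
* Likelihood evaluation is dense in the number of states; with 30 regions
  at large `K` the state space is astronomically large — practical analyses
  keep `K` at 2–4, as empirical DEC studies typically do.
* The vicariance statistic has no null model attached; the package counts
  and classifies, it does not test for vicariance excess.
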