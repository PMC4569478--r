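# vicarscan

Quantifying the vicariance signal in historical biogeography from dated
phylogenies.

## The problem

When a clade diversifies across a set of geographic regions — say, the
uplands of a fragmented tropical rainforest — each speciation event either
split an ancestral range into mutually exclusive daughter ranges
(**vicariance**) or happened within a range, with dispersal and local
extinction reshaping ranges along the way. Biogeographers want a
whole-phylogeny answer: *what fraction of the nodes in this tree are
vicariant?* vicarscan computes that statistic from two independent
reconstruction engines and provides the simulation machinery to validate
every step.

## What it computes

Given a rooted ultrametric phylogeny (Newick/Nexus) and a taxon × region
0/1 range matrix (TSV):

1. **DEC likelihood** (dispersal–extinction–cladogenesis). Ranges are
   subsets of the region set with at most *K* regions; along branches a
   CTMC adds regions at rate *d·Σᵢ mᵢⱼ* and drops them at rate *e*; at
   nodes the range is inherited by sympatry, vicariance ({i} vs R∖{i}) or
   subset sympatry ({i} vs R), all scenarios equally weighted. `fit_dec()`
   estimates (d, e) by ML; `ancestral_split_probs()` returns per-node
   relative probabilities of every scenario. A node's **vicariance
   probability** is the summed probability of scenarios with disjoint
   daughters.
2. **DIVA-style parsimony.** Free vicariance/duplication, unit cost per
   region gained or lost along a branch; `diva_min_cost()` solves the exact
   minimum by dynamic programming and
   `enumerate_optimal_reconstructions()` lists all co-optima. A node is
   flagged vicariant when a majority of co-optima make it one.
3. **Aggregation.** `aggregate_vicariance()` counts focal nodes (MRCAs of
   user-declared clades) with DEC vicariance probability > 0.5 and with
   the DIVA flag, yielding counts and fractions like "9 of 23 nodes
   vicariant under DEC, 14 of 23 under DIVA".
4. **Relative dating.** From a posterior sample of dated trees,
   `relative_age_distribution()` summarises clade ages and ratios to a
   reference clade (median, quartiles, empirical 95% interval, monophyly
   rate); `split_order_probability()` gives the posterior probability one
   divergence predates another.
5. **Simulation.** `simulate_yule()` + `simulate_dec_history()` generate
   dated trees and forward DEC range histories with a complete,
   replayable event log (`replay_history()`), used by the test suite as
   ground truth.

## Worked example

```r
library(vicarscan)

rs   <- region_set(paste0("R", 1:8))                  # 8 regions, order fixes bits
pars <- dec_params(d = 0.1, e = 0.03, K = 2,
                   m = linear_chain_constraints(rs))  # linear corridor geography
tree <- simulate_yule(30, birth_rate = 0.25, seed = 1)
sim  <- simulate_dec_history(tree, rs, pars,
                             root_range = range_encode(c("R4", "R5"), rs),
                             seed = 2)

fit  <- fit_dec(tree, sim$tip_ranges, K = 2, m = pars$m)
fit
#> DEC maximum-likelihood fit
#>   d (dispersal)  = 0.0956555
#>   e (extinction) = 0.00776559
#>   log-likelihood = -53.725718
#>   starts tried   = 4

scen  <- ancestral_split_probs(tree, sim$tip_ranges, fit$params)
probs <- dec_vicariance_probs(scen)
dp    <- diva_min_cost(tree, sim$tip_ranges, maxareas = 3)
sc    <- score_node_vicariance_diva(enumerate_optimal_reconstructions(dp))
#> Warning: vicariance frequency exactly 0.5 at node(s) 32, 45, 48; scored
#> non-vicariant

focal <- stats::setNames(sort(unique(scen$node)),
                         paste0("node", sort(unique(scen$node))))
aggregate_vicariance(probs, sc, focal)
#> Vicariance summary over 29 focal nodes
#>   DEC  (prob > 0.5): 5/29 (0.17)
#>   DIVA (majority) : 7/29 (0.24)
```

Here 5 of the 29 internal nodes carry more than half their DEC scenario
probability on vicariant splits, and 7 are vicariant in the majority of
minimum-cost DIVA reconstructions (three more sit exactly at a 50/50 tie
across co-optima and are flagged ambiguous rather than counted). DIVA, with
free vicariance, flags more nodes than DEC — the same qualitative gap seen
in empirical studies. The fitted rates land near the simulation truth for
dispersal (0.096 vs 0.1); see the methods vignette for why DEC's ê is
biased low on surviving clades.

A command-line interface wraps the same pipeline:

```sh
Rscript -e 'vicarscan::vicarscan_cli()' simulate --tips 30 --regions 8 \
    --d 0.1 --e 0.03 --max-range-size 2 --seed 42 --out simdir
Rscript -e 'vicarscan::vicarscan_cli()' dec --tree simdir/tree.nwk \
    --ranges simdir/ranges.tsv --max-range-size 2 --out dec.json
```

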