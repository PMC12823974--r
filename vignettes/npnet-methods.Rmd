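---
title: "Methods: classifying N-P coupling and building signed co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying N-P coupling and building signed co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npnet)
```

## The question and the inference chain

Soil nitrogen (N) and phosphorus (P) cycling can run synchronously
("coupled") or drift apart ("decoupled"), and particular microbial taxa
are hypothesised to drive each regime. `npnet` implements the full
inference chain from amplicon feature-count tables (16S bacteria, ITS
fungi, and the phoD-harboring alkaline-phosphatase community) plus seven
soil nutrient variables to three outputs:

1. **Site labels.** A site is N-P *coupled* when both stoichiometric
   ratios clear their thresholds strictly: $\mathrm{TN}/\mathrm{TP} > 3$
   and $\mathrm{netN_{min}}/\mathrm{AP} > 0.16$; otherwise *decoupled*
   (either the cycles are asynchronous or both too slow). Sites exactly
   at a threshold are decoupled; both thresholds are configurable.
2. **Taxon labels.** Each major taxon's relative abundance is correlated
   (Pearson, two-sided) with the four N-cycling variables (TN, NAG,
   net N mineralization, inorganic N) and the three P-cycling variables
   (TP, AP, AKP), with Bonferroni correction. A taxon significant in
   both families with all significant coefficients sharing one sign is
   *coupled* (positive or negative); significant in exactly one family,
   *decoupled* toward that family; significant in both families with
   mixed signs, *inconsistent*; otherwise *none*. Coupled taxa
   additionally get an OLS regression on
   $\mathrm{netN_{min}}/\mathrm{AP}$ (Bonferroni over the coupled taxa)
   and a one-sided Mann-Whitney test of enrichment in coupled sites
   (Benjamini-Hochberg across taxa).
3. **Networks.** Coupled taxa (and, separately, decoupled taxa) that are
   major ($>$ 0.1% mean relative abundance) and occur in strictly more
   than half the sites become nodes of an undirected signed network.
   Edges are pairwise Pearson correlations with $|r| > 0.6$ and
   BH-adjusted $p < 0.05$; the sign of the edge is the sign of $r$.
   Reported topology: connectance $E / \binom{V}{2}$, the
   positive:negative edge ratio, edge composition by marker-group pair,
   and composite-score keystone taxa.

## Preprocessing

The fixed order is: global abundance floor, averaged rarefaction,
marker-specific retention, aggregation, major-taxon selection.

| parameter | default | meaning |
|---|---|---|
| `global_floor` | 1e-5 | drop features below 0.001% of the grand total (strict `<`; a feature exactly at the floor stays) |
| `rarefy_fraction` | 0.9 | target depth = `floor(0.9 x min site depth)` |
| `rarefy_reps` | 100 | rarefaction draws averaged per cell |
| `prevalence_min` | 0.10 | 16S/phoD features must occur in `ceil(0.10 x n_sites)` sites (rounded up to whole sites) |
| `min_total_count` | 10 | ITS features need >= 10 reads summed over sites |
| `major_abund` | 0.001 | taxa with mean relative abundance > 0.1% (strict) are "major" |

Rarefaction draws are multivariate hypergeometric (sampling reads
without replacement), implemented as sequential conditional
`rhyper()` draws vectorised across replicates, so every replicate's site
total is exactly the target depth and so is every averaged row sum. One
seeded stream drives all replicates of a table; replicate-level
sub-seeding was considered and dropped because the vectorised draw order
already fixes the stream deterministically, which is the property that
matters (identical seed, identical table).

Two conventions are genuinely open and were fixed as follows: the 0.1%
"major" cutoff applies to the **mean** relative abundance across sites
(maximum or per-sample readings would be alternatives), and prevalence
is assessed **after** rarefaction, with occurrence meaning any nonzero
averaged abundance. Relative abundance is always computed within one
marker group, because the three amplicon universes are separately
sequenced compositions; pooled tables keep each group's rows summing
to 1 within that group.

## Correlation screening choices

The Bonferroni family defaults to **all computable taxon-by-variable
tests within one marker-group/rank analysis** (the most conservative
plausible reading); `family = "per_taxon"` (m = 7) is available as a
sensitivity mode. Constant abundance vectors are flagged non-computable
and excluded from the family size rather than counted. Mixed-sign
both-family taxa get the dedicated `inconsistent` label instead of being
forced into coupled or decoupled, and are excluded from both networks.
The net-Nmin/AP regression is an annotation of coupled taxa, not part of
the label definition. Significance is always judged on adjusted p at
`alpha = 0.05`.

## Network construction choices

The BH family is all computable candidate pairs of one network, and the
threshold $p < 0.05$ applies to the **adjusted** p-value (significance
is assessed after correction). All eligible candidates remain nodes even
when isolated - this is what reconciles low connectance values with
small edge counts in sparse networks. Edges between marker groups are
computed on the per-group relative abundances joined by site.

Centralities are computed on the unweighted, unsigned skeleton:

* degree;
* **harmonic** closeness normalised by $n - 1$, chosen because these
  networks are sparse and frequently disconnected, where classic
  closeness is undefined across components;
* betweenness normalised by $(n-1)(n-2)/2$.

Each metric is standardised across the network's nodes using the sample
(n-1) standard deviation; a zero-variance metric yields all-zero
z-scores. The keystone score is the **sum**
$z_{deg} + z_{clo} - z_{betw}$ with threshold $\geq 1$ - the composite
is described in the literature only as "high degree, high closeness, low
betweenness with threshold 1", so the sum with a negated betweenness
term is the simplest formula consistent with that description. A
positive:negative ratio with zero negative edges is reported as `Inf`;
an empty edge set gives `NA`.

One arithmetic caveat surfaced while reconciling reported four-network
topologies: a phylum-level network of 8 edges admits no nonnegative
integer split with a positive:negative ratio of 1.60 (5/3 rounds to
1.67). The package reproduces the ratio formula and the three
consistent splits (150:24 = 6.25, 4:3 = 1.33, 96:50 = 1.92); the fourth
printed ratio cannot be reproduced by any integer edge split and is
treated as unreproducible.

## The synthetic community generator

`generator_config()` defines the study conditions the test-suite runs
under: 35 sites of which 10 are coupled, 120/80/40 features for
16S/ITS/phoD grouped into genera of 4-5 features (at least 3, so
aggregation is exercised) and phyla of ~5 genera, per-site depths
uniform on [35454, 64657] (the observed 16S depth span), planted
correlation magnitude `target_r = 0.85`, and a 3x abundance boost of
coupled-positive taxa in coupled sites.

Nutrients come from two lognormal latent factors (N status and P
status, both elevated at coupled sites) with the stoichiometric ratios
drawn per site class; a per-site check then redraws any ratio that
landed on the wrong side of its threshold, so **exactly**
`n_coupled_sites` sites satisfy both thresholds. This construction makes
N-cycling variables cluster more tightly with each other than with
P-cycling ones, and puts the mean TN/TP of coupled sites near 4.5-4.7.

Planted taxa respond **linearly** to standardized raw anchor variables
(truncated at 5% of the base abundance to stay positive), not
log-normally. The log-normal alternative was implemented first and
rejected: with skewed anchors the exponential map attenuates raw-scale
Pearson correlations well below the target, and a taxon can correlate at
$r$ with one anchor from each family only if
$r \leq \sqrt{(1+\rho)/2}$ where $\rho$ is the anchor correlation - so
coupled taxa anchor on the most-correlated cross-family variable pair.
Because the 3x enrichment boost injects site-class signal of its own,
the anchor weights of the coupled site profile are solved numerically
(small-norm regularised, Nelder-Mead) so that the **expected**
correlation of the final boosted profile with each anchor equals
`target_r`; without the regularisation a second, truncation-dominated
root exists whose spiky profile lets planted taxa consume entire sites
and distorts every other taxon through compositional closure.
Feature-level residual dispersion around the genus profile is 0.15;
"none" taxa are pure truncated-Gaussian noise at `noise_sd` (0.5).
Counts are multinomial allocations of each site's depth, so column sums
equal the drawn depths exactly. Each marker group consumes its own
deterministic sub-seed, so adding taxa to one group leaves the others
bit-identical.

What the generator emulates: compositional count data with
heterogeneous depths, planted taxon-nutrient correlations of both
signs, nutrient tables spanning both sides of both thresholds, and
coupled-site enrichment. What it does not emulate: phylogenetic
structure, spatial autocorrelation among sites, realistic taxon-name
distributions, and effect-size distributions of real taxon-nutrient
relationships (no such distribution is documented; the defaults are
chosen for testability). Passing tests therefore demonstrate that the
pipeline recovers planted structure under controlled conditions, not
that real communities behave this way.

## Problem sizes and oracle coverage in the test-suite

The statistical acceptance checks run 50 synthetic communities at the
default conditions (about 20 s): pooled over seeds, the classifier must
recover at least 90% of planted coupled genera, mislabel at most 5% of
"none" genera as coupled, and the enrichment test must flag at least
80% of the boosted coupled-positive genera. Type-I control uses 200
null communities with no planted structure. Rarefaction calibration
uses 2000 replicates on a five-feature toy table, compared to the
hypergeometric mean within three Monte-Carlo standard errors.

Centrality correctness is checked against an independent matrix-power
oracle (distances and geodesic counts from powers of the adjacency
matrix): exhaustively over every graph on 3-5 nodes (1096 graphs) plus
a fixed-seed uniform sample of 2000 of the 32768 six-node graphs -
sampled rather than exhaustive to keep the check to seconds; the
six-node space contains only 156 isomorphism classes, so a 2000-graph
sample covers the structural variety many times over. Network edge sets
are checked against a textbook double-loop Pearson + longhand BH oracle
on 15-taxon tables.

## Known limitations

Pearson correlations on relative abundances are blind to compositional
artefacts (no SparCC/SPIEC-EASI-style correction is attempted - plain
Pearson is the method being implemented, not a recommendation), and the
generator's own closure effects bound how cleanly "independent" taxa
can behave. The keystone composite is one of several plausible
formulas. The enrichment test is descriptive; it inherits the usual
caveats of rank tests at n = 10 vs 25. All thresholds are surfaced as
parameters, but the defaults are the method's canonical values and the
test-suite only validates behaviour at or near them.
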