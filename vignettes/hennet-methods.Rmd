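---
title: "Methods: supply accounting, nutrient sufficiency, and network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supply accounting, nutrient sufficiency, and network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hennet)
```

# Overview

`hennet` implements a three-stage analysis of food-system data at country
scale:

1. a **four-tier mass balance** of agricultural food supplies,
2. **population-weighted nutrient sufficiency** and excess/deficit
   requirement-year headcounts, and
3. a **Gaussian Bayesian-network analysis** of per-capita country features
   (food-category production, nutrient supplies, greenhouse-gas emissions,
   agricultural water withdrawal).

Because the real statistical sources (national production, trade, population
and composition databases) cannot ship with a package, `hennet` also
includes a synthetic-world generator that emulates every input table with a
known ground truth, which is what the test suite and the acceptance script
run against.

# The four supply tiers

For each region, year and product, masses (kg; tonnes are converted with a
factor of 1000 at the I/O boundary) flow through four supply
representations:

* **P1** — raw agricultural production, *excluding* animal products;
* **P2** — `max(0, P1 − loss + imports − exports)`: production,
  postharvest and processing losses are removed *before* trade, and exports
  are bounded by domestic availability (the clip at zero);
* **P3** — `P2 − waste`, where `waste = P2 × waste_fraction`: consumer-side
  waste occurs *after* trade;
* **P4** — `max(0, P3 + livestock products − livestock feed)`: meat, milk
  and eggs are added, and the mass of crops fed to livestock is removed.

Loss and waste fractions are resolved per (region group, food category).
Livestock feed is computed from style-weighted average daily diets per
animal type (kg/head/day), multiplied by animal headcounts and annualised
with a factor of 365 (the sources give daily diets and annual fluxes
without stating the multiplier; 365 is the only consistent choice for
annual accounting). Three further accounting choices were genuinely open
and are resolved as follows:

* **Feed granularity.** Feed demand is specified per food category, not per
  product. It is allocated across the *plant* products of the category in
  proportion to their post-waste (P3) supply, and each product's P4 is
  floored at zero, consistent with the trade clip. Animal products are
  never debited for feed, since the diet tables are crop categories.
* **Missing cells are zeros.** A product or trade flow not reported for a
  country is treated as 0, not as missing.
* **Year averaging.** All fluxes are averaged arithmetically over the
  available years before reporting.

`reference_ledger()` recomputes the whole ledger with an independent
per-row loop and is compared against the vectorised engine on random worlds
in the tests.

# Nutrient sufficiency and headcounts

Product supplies map to nutrient supplies through per-kg composition
(products without composition, e.g. fibre or tobacco, are flagged and
excluded with a warning). The nutrient key set is fixed per run — by
default energy, protein, seven indicator amino acids, four fatty-acid keys
(DHA and EPA travel as one combined key), twelve vitamins and six minerals.

A population's annual requirement of a nutrient is
`sum over (sex, age-bin) cells of persons × daily requirement × 365`, using
the 42-cell pyramid structure (two sexes × 21 five-year age bins, 100+
open-ended). Requirements depend on age and sex only. Calendar years map to
pyramid reference dates piecewise (2008→2005, 2009–2013→2010,
2014–2016→2015, 2017→2020), and country requirements are averaged over the
year span with these weights. Dividing the annual requirement by 365
reproduces the daily schedule, which is exposed as a sense check.

The **sufficiency ratio** is supply over annual requirement; nutrients with
zero requirement are reported as supplies only. **Headcounts** are
person-equivalents of unmet or surplus requirement: per country and
nutrient the balance is `population × (ratio − 1)`, and deficits
(`max(0, −balance)`) and excesses (`max(0, balance)`) are summed separately
over countries. This is a deliberate semantic choice: a country 10% short
on energy with 50 million people contributes 5 million *requirement-years*,
not 50 million deficient persons. The alternative reading (populations of
deficient countries) is computable from the same country table but is not
the default. A scaled-population scenario (e.g. 10 billion people)
multiplies every pyramid cell by a common factor, so requirements scale
exactly linearly — the scenario changes no other structure.

Supplies are *availability*, not consumption: the ratios say nothing about
distribution within or between countries, bioavailability, or fortification.

# Network analysis

The third stage relates per-capita country features in a directed acyclic
graph. The feature matrix has one row per country and columns of three
roles: 13 food-category production masses (raw plant production plus
livestock output), nutrient supplies derived from those masses via
composition, and the four environmental variables (CH4, N2O, CO2eq, water
withdrawal), all divided by country population to control for population
size.

**Score.** Structure learning maximises the decomposable Gaussian BIC: for
node $y$ with parent set $P$ on $n$ countries,
$$\mathrm{score}(y \mid P) = -\tfrac{n}{2}\left(\log(2\pi\hat\sigma^2) + 1\right) - \tfrac{|P|+2}{2}\log n,$$
with $\hat\sigma^2$ the MLE residual variance of the regression of $y$ on
$P$. Columns are standardised before scoring (the BIC-optimal structure is
invariant to affine rescaling; standardisation only conditions the
arithmetic), and each local score is computed from the sample covariance
matrix with one small symmetric solve, memoised per (node, parent set).

**Search.** Hill climbing over single-arc additions, deletions and
reversals. Plain greedy ascent from the empty graph proved fragile on
strongly autocorrelated systems — the highest marginal correlation is often
an ancestor–descendant *shortcut*, and once added early it cannot be
disentangled by single moves (scores well below the known-truth graph in
simulation). The search therefore (a) applies the **best** improving move
each iteration rather than the first one found, with deterministic
lexicographic tie-breaking; (b) climbs from two deterministic starting
points — the empty graph and a maximum-|correlation| spanning tree oriented
by column order — keeping the higher-scoring result; and (c) follows each
ascent with a bounded **tabu phase** (up to 15 non-improving best moves
whose inverses are frozen for 10 steps, remembering the best graph seen)
and a final greedy polish, so the returned graph is always a single-move
local optimum. No random restarts are used; the whole search is a
deterministic function of the data.

**Expert knowledge.** Arcs from nutrient columns to food columns are
blacklisted: nutrient supplies are deterministic consequences of production
(milk production can drive calcium supply, never the reverse). Blacklisted
arcs are excluded from additions and reversals in every replicate.

**Model averaging.** Rows (countries) are resampled with replacement 200
times by default; a DAG is learned on each replicate. The **strength** of
an unordered pair is the fraction of replicates containing the edge in
either direction (direction-agnostic by choice; the directed convention is
recoverable from the direction counts, which are retained as an attribute).
The **direction probability** of an orientation is the fraction of
edge-containing replicates oriented that way. The averaged network keeps
pairs with strength strictly above the threshold (default 0.6), oriented by
majority direction (a 0.5 tie orients from the earlier data column). The
empirical distribution of strengths is attached for threshold diagnostics
rather than auto-selecting a cutoff. Majority orientations can in
principle form cycles; any residual cycle is broken by dropping its
weakest arc, so the final network is always acyclic and fully directed.

**Reporting.** `markov_blanket()` returns parents, children and co-parents
of children; `glance()` reports node count, arc count and mean
Markov-blanket size; `fit_local_models()` fits each node on its parents by
ordinary least squares on the original (unstandardised) scale, giving the
linear relationships and standard errors the network implies.

# The synthetic world

`generate_world()` emulates every source table: production and trade in
long format with display names that differ across vocabularies by case,
punctuation and comma-segment order (the mismatch classes the crosswalk
normalisation is designed for); loss/waste fractions per region group ×
category; style-structured livestock diets and headcounts; per-product
composition; an age/sex requirement schedule; population pyramids at the
four reference dates; and per-country environmental totals.

Per-capita food-category outputs and the environmental variables are drawn
from a linear-Gaussian structural equation model over a known DAG
(`default_true_dag()`): an oilseed-driven cascade of crops and livestock,
greenhouse gases as children of ruminant meat and milk (with an inverse
berry association), N2O driven by cereals, and water withdrawal driven by
vegetables and fruits. Nutrient columns are *never* free variables — they
arise from production × composition — so the ground truth is consistent
with the blacklist by construction. Requirement levels are calibrated to
the world's own per-capita supply scale and jittered (factors 0.4–1.4), so
sufficiency ratios spread around 1 and both deficits and excesses occur;
the jitter is part of the world definition, not a tuning knob.

Defaults: 120 countries, 10 years (2008–2017), 13 categories × 2–4
products plus two non-food products, 31 nutrients, trade intensity 0.2,
loss fractions 0.02–0.15, waste fractions 0.05–0.3. The generator
reproduces byte-identical worlds from identical configurations.

What the world does **not** emulate: real-world magnitudes or geographic
structure, intra-year dynamics, seafood, regional variation in composition,
prices, or industrial (non-food) uses of crops. Passing tests therefore
demonstrate the correctness of the accounting and the statistical machinery
under known conditions, not agreement with any real country's numbers.

# Benchmarks and problem sizes

The validation suite runs at sizes chosen to exercise every code path in
minutes on a single core:

* mass balance: 25 random worlds (4 countries × 2 years), engine vs the
  independent per-row reference, identities at 1e−6 relative tolerance
  (equality to the oracle holds to 1e−12);
* requirements: 100 random pyramids against a per-person brute-force sum;
  the headcount identity `excess − deficit = Σ population × (ratio − 1)`
  exactly; scenario linearity at 1e−9;
* search quality: 100 random 3–4-variable datasets (n = 200) against
  exhaustive enumeration of all DAGs (25 and 543 graphs); the climb must
  always end in a single-move local optimum and reach ≥ 99% of the
  optimum's score gap from the empty graph in ≥ 90 cases;
* structure recovery: the fixed ten-node benchmark (`benchmark_dag()`,
  |coefficients| 0.8–1.2, unit noise, n = 500, 50 bootstraps, threshold
  0.6) across 20 simulation seeds, requiring skeleton SHD ≤ 2 in ≥ 90% of
  seeds and zero blacklisted arcs in any replicate;
* local models: fitted coefficients within 3 standard errors of the
  generating coefficients for ≥ 95% of node–parent pairs recovered in the
  generating orientation, pooled over the same 20 seeds (a reversed arc —
  a Markov-equivalent orientation — has no generating coefficient to
  compare against);
* determinism: two full pipeline runs with the same world and seed must be
  byte-identical across every CSV, JSON and DOT artifact.

End-to-end demonstrations (the README example and the reproduction script)
run the bootstrap network on a reduced nutrient panel — 29 features (13
food categories + 12 nutrients + 4 environmental variables) over 25
replicates — which keeps a complete run in the minutes range on one core
while exercising the same code paths as the full 48-feature default world;
the accounting stages always run at the full default scale.

# Known limitations

* The score assumes linear-Gaussian local relationships; heavy-tailed or
  nonlinear dependence in real data would call for rank transforms before
  the network stage.
* With ~50 features and only ~200 countries the BIC is conservative;
  bootstrap strengths below the threshold should not be read as evidence of
  independence.
* Cycle breaking after majority orientation is a tie-resolution heuristic;
  it triggers rarely (never in the shipped benchmarks) but is not
  score-optimal.
* The headcount semantics count person-equivalents of requirement, which is
  not the number of people in deficient countries; both statistics are easy
  to conflate in prose.
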