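---
title: "Inferring DUF function from ecogenomic domain co-variation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring DUF function from ecogenomic domain co-variation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecodomnet)
```

## The problem and the approach

A large fraction of the protein domain families catalogued in Pfam are
"domains of unknown function" (DUFs): conserved, widespread, and
unannotated. Shotgun metagenomes of a single ecosystem offer indirect
evidence about them. If the abundance of a DUF across many sampling
sites rises and falls together with the abundances of domains of known
function, the DUF is a candidate participant in the same biological
process — a guilt-by-association argument at the level of whole
communities rather than genomes.

`ecodomnet` implements this analysis as a reusable pipeline:

1. **Ingest** — parse HMMER3 per-domain output of a search of
   translated reads against Pfam profile HMMs, keep well-supported
   hits, and cross-tabulate them into a site × family count matrix.
2. **Matrix preparation** — remove families listed in more than one
   metabolic category, prune rows and columns dominated by zeros, and
   fork the matrix into an unstandardized branch (UM) and a copy
   standardized by site maxima (SM).
3. **Correlation** — all-pairs Spearman rank correlation across sites,
   with a high correlation threshold and a Bonferroni-style p cutoff.
4. **Network and clusters** — connect qualifying pairs into a weighted
   association network and partition it into clique-like *transitivity
   clusters* by weighted cluster editing.
5. **Annotation** — per-DUF category-bias statistics and per-cluster
   taxonomic profiles.

Running both branches is deliberate. Raw counts co-vary partly because
libraries differ in size; site-maximum standardization removes that
shared factor. Comparing UM and SM results separates genuine ecological
co-variation from sampling-depth artifacts, and the package's synthetic
generator reproduces exactly this contrast (see below).

## Hit significance

A domain hit is retained when all four of the following hold, with
inclusive boundaries:

* per-domain independent E-value ≤ `max_i_evalue` (default `1e-3`);
* bias composition correction at least an order of magnitude below the
  full-sequence score: `bias * bias_ratio <= score` with
  `bias_ratio = 10` (a non-positive score always fails, since the ratio
  rule is meaningless there);
* alignment covering ≥ 20% of the query length (`ali_from`/`ali_to`
  alignment coordinates, not envelope coordinates);
* alignment covering ≥ 20% of the model length.

The bias rule reads the full-sequence score and bias columns by
default; `filter_thresholds(use_domain_score = TRUE)` switches it to
the per-domain columns. Every retained domain instance counts once in
the cross-tabulation, including repeated domains on one read; the
package does not attempt to de-overlap domains on a read.

## Matrix preparation

`prune_sparse()` removes families with fewer than 20 non-zero
abundances across sites and sites with fewer than 1,000 non-zero
abundances across families, evaluating both criteria on the *input*
matrix in a single pass and removing the flagged rows and columns
together. A sequential/iterative variant is available
(`iterative = TRUE`) but is not the default: the thresholds are stated
against the original matrix dimensions, and a single simultaneous pass
is the only reading that keeps them meaningful as stated. Both
thresholds are configurable because they are calibrated to a survey of
roughly 80 sites × 3,600 families; for narrower matrices we scale the
row threshold proportionally (tests and the acceptance script use 50
for ~180-column synthetic matrices, preserving the ~28% ratio).

`standardize_rows()` divides each row by its own maximum, leaving
all-zero rows as zeros (pruning normally removes them first, but the
operation is total). Standardizing an already standardized matrix is a
hard error rather than a silent renormalization, so a misconfigured
double-SM branch cannot slip through.

## Correlation and significance

`spearman_all_pairs()` ranks each family column (average ranks for
ties) and computes the product-moment correlation of the ranked
columns — the same convention as `Hmisc::rcorr()`. Two-sided p-values
use the t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
`n - 2` degrees of freedom, which is standard at the n ≈ 70 sites this
method targets; exact permutation p-values are out of scope. Pairs with
`|rho| = 1` get `p = 0`. Constant columns yield *undefined* (`NA`)
correlations that are excluded from masks and summaries — they never
leak downstream as NaN.

A pair qualifies when `rho > rho_min` (strictly, default 0.80; only
positive correlations, an absolute-value mode exists behind
`use_absolute`) and `p < cutoff` (strictly). The cutoff is
`alpha / m_tests` with `m_tests` defaulting to the number of unordered
family pairs; because published analyses of this kind typically quote
an absolute corrected cutoff of about `1e-6` without stating the number
of tests behind it (with ~1,900 retained families, `0.05 / C(1863, 2)`
would be ≈ 3e-8, not 1e-6), `significance_policy()` also accepts
`p_cutoff_override`, and `published_config()` sets it to `1e-6`.
Families with no qualifying partner are dropped
(`prune_uncorrelated()`), and `rho_summary()` reports the mean and
sample s.d. of the defined upper-triangle correlations (a single pair
has s.d. 0 by convention).

## The association network

`build_network()` creates an undirected simple graph: one node per
retained family (annotated with its metabolic category and a 0/1 DUF
flag), one edge per significant pair, weighted by rho. Layout is
presentation, not inference: the package exports GraphML/GML (loadable
by Cytoscape, where a spring-embedded layout will place strongly
correlated domains close together) and a plain edge TSV, and never
computes coordinates itself.

## Transitivity clustering (weighted cluster editing)

Clique-like substructure in the network is extracted by cluster
editing: find the partition of each connected component minimizing

    cost(P) = sum_{u,v same cluster} max(0, T - s(u,v))
            + sum_{u,v different clusters} max(0, s(u,v) - T)

where the similarity `s` is the edge weight (rho) for adjacent pairs,
the full correlation for non-adjacent pairs when a
`correlation_result` is supplied, and `missing_similarity` (default 0)
otherwise — absent pairs must still carry a join cost, or the editing
objective would happily merge everything. The threshold `T` defaults to
0.80, equal to the network threshold, since the clustered graph only
contains edges above it.

Two solvers sit behind `transitivity_cluster()`:

* **Exact** (components ≤ `exact_limit`, default 12): the
  intra-minus-inter cost of a pair reduces to `T - s`, so the objective
  decomposes over clusters up to a constant and a dynamic program over
  vertex subsets finds the global optimum in O(3^n). Ties (within a
  1e-9 cost tolerance, which absorbs floating-point summation order)
  prefer fewer clusters, then the lexicographically smallest canonical
  form — clusters ordered by smallest member, compared as flattened
  sequences with a sentinel, so for the classic tied triangle
  (`s = 0.9, 0.9, 0.5`) the solver deterministically returns
  `{A} {B, C}`.
* **Heuristic** (larger components): greedy agglomeration over pairs in
  descending similarity (merging whenever the merge lowers the cost),
  followed by single-node relocation local search until no improving
  move remains or the time budget (default 2 s per component loop) is
  spent. The result is clamped to never cost more than the
  all-singletons or single-cluster partitions. The procedure is
  deterministic; on random instances with n ≤ 8 it matches the exact
  optimum within 5% on well over 90% of cases (tested).

`max_subcluster` (default 50) caps cluster sizes: an oversized cluster
is re-clustered at `T + 0.01` increments until it splits, mirroring the
sub-cluster cap of TransClust-style tools whose internal semantics are
not published; since similarities are correlations ≤ 1, the raise
always terminates (at worst in singletons). Clusters with at least
`min_report_size` members (default 3) are labeled TC1, TC2, … in
decreasing size order with a canonical tie-break, so runs are
reproducible.

## DUF category bias and taxonomy

For each DUF node, `category_counts()` tallies its neighbors by
category; neighbors that are themselves DUFs or carry category `"NA"`
are excluded (a DUF's category is unknown by definition, so DUF–DUF
edges cannot witness a category) and tracked separately.
`detect_bias()` declares a primary category only when its count is at
least double that of every other category; a tie at the maximum means
no bias, because "a single dominant category" is then undefined. The
secondary category is the largest remainder with a positive count,
reported as a fraction of the primary — necessarily ≤ 0.5 whenever bias
holds. No minimum is imposed on the secondary fraction by default
(configurable), since published tables report secondaries down to a
third of the primary.

`cluster_tax_profile()` sums per-phylum instance counts over a
cluster's DUF members and reports phyla holding strictly more than 5%
of the total; percentages are computed over *all* phyla before
filtering (they sum to 100) and rounded to two decimals, matching the
precision of published cluster-taxonomy tables. By default only
clusters with ≥ 4 members and ≥ 2 DUFs are profiled.

## The synthetic generator

Real ocean-survey data behind this method is cluster-scale (tens of
millions of reads against thousands of profile HMMs), so the package
ships a generator that emulates the *structure* of the resulting
matrix and makes every pipeline stage testable:

* counts are Poisson with rate `f_s * mu_d * a_{m(d),s}`, where
  `f_s ~ LogNormal(0, site_factor_sd)` is a shared per-site library
  factor, `mu_d ~ LogNormal(base_mean_log_mean, base_mean_log_sd)` a
  per-family base mean, and `a_{m,s} ~ LogNormal(0, strength)` a
  per-module per-site activity shared by the module's families
  (background families have no activity term);
* each cell is then independently zeroed with probability
  `zero_inflation`;
* module members receive the module's category (some flagged DUF with
  category `"NA"`), background families random categories, a small
  slice a second category listing (exercising multi-category removal),
  and each module a dominant phylum in the emitted DUF taxonomy table.

This is the simplest mechanism producing both genuine co-varying
modules and the library-size artifact the SM branch removes: with a
strong site factor and no module signal, the UM branch retains two
orders of magnitude more families than the SM branch (the acceptance
script measures this ratio), reproducing qualitatively the published
UM-versus-SM retention asymmetry.

**Defaults, chosen once.** 80 sites; six 10-family modules of strength
1.0 with distinct categories and 30% DUF members; 120 background
families (DUF fraction 0.3, close to the ~36% DUF share of a pruned
real matrix); `site_factor_sd = 0.3` (a moderate residual depth spread;
stronger confounding is exercised explicitly at 1.0);
`base_mean_log_mean = log(20)` and `base_mean_log_sd = 1` (typical
family hits per site in the tens, spread over about an order of
magnitude, so the lognormal tail supplies genuinely rare families and
natural Poisson zeros); `zero_inflation = 0.05`. The last value
deserves emphasis: most sparsity in a real site × family matrix comes
from rare families — natural zeros — and the inflation term models only
*excess technical dropout*, for which a few percent is realistic.

**What the generator does not emulate, and why it matters.**
Independent per-cell dropout is brutal to rank correlations: if two
columns carry an identical noiseless signal but each cell is zeroed
independently with probability 0.3, only ~49% of sites carry the
signal in both columns and the tied zeros destroy rank concordance —
across 80 sites the expected Spearman rho is ≈ 0.25 and even the
maximum over hundreds of draws stays near 0.54, far below a 0.80
threshold. Heavy *independent* technical dropout therefore defeats
this method's thresholds outright; the method is only informative when
missingness is modest or shared between co-varying families (as
biological absence is). The generator also omits compositional
closure, phylogenetic correlation between families, spatial
autocorrelation between sites, and read-level artifacts; passing tests
demonstrate correct mechanics and recoverability under the stated
model, not performance on real surveys.

Randomness is split into per-stage substreams seeded from the master
seed, so changing, say, the taxonomy draw cannot perturb the counts;
the same seed always reproduces the same survey byte for byte.

## Evaluation metrics

`adjusted_rand()` is the standard pair-counting ARI (cross-checked in
the test suite against an independent implementation).
`recovery_report()` computes the ARI between reportable clusters and
planted modules over the families assigned to any reportable cluster —
families pruned for lack of a strong partner are not counted against
the clustering — plus the fraction of DUFs planted in single-category
modules whose detected primary bias equals the planted category. When
no reportable cluster exists the ARI is reported as 0 with a
`degenerate` flag rather than as undefined.

On the default spec the pipeline's UM branch recovers planted modules
at a seed-averaged ARI above 0.9 with module-pure clusters (tested over
fixed seeds); the residual distance from 1 comes from rare background
families whose presence/absence pattern tracks the library factor and
who therefore form their own small clusters — a faithful miniature of
the artifact the SM branch exists to remove.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` work at 80 × 180 matrices,
5–20 replicate seeds per property, 200 random instances (n ≤ 8) for
the exact-versus-exhaustive cluster-editing check, and 50 random
20 × 30 matrices for the Spearman oracle check — sizes at which every
statistical property we assert is stable across reruns of the fixed
seeds while the whole suite stays fast on one CPU. All randomness is
seed-controlled; pipelines rerun byte-identically for a given seed.

## Known limitations

* Correlation is not function: shared habitat preference, taxonomic
  restriction, or linkage on the same replicon all produce co-variation
  without shared mechanism. The taxonomy reports exist precisely to
  flag clusters whose coherence is taxonomic rather than functional.
* The Bonferroni-style cutoff treats the all-pairs test family
  conservatively; no FDR mode is provided because the published
  procedure this package operationalizes does not use one.
* The exact solver is limited to components of ~12 nodes (O(3^n));
  larger components rely on the heuristic, whose quality is verified
  only against small-instance optima.
* Heavy independent dropout attenuates Spearman rho (see above); users
  with such data should lower the correlation threshold deliberately
  rather than expect the defaults to perform.
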