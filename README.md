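# ecodomnet

Domain co-occurrence networks from metagenomic abundance profiles, for
inferring candidate functions of **domains of unknown function (DUFs)**
by guilt-by-association.

Shotgun metagenomes sampled across many sites of one ecosystem (the
motivating case: epipelagic ocean surveys) yield, after a HMMER search
of translated reads against Pfam profile HMMs, a **site × family count
matrix**. Protein domain families whose abundances rise and fall
together across sites are candidates for participation in the same
biological process — so a DUF that co-varies tightly with, say,
photosystem domains earns a photobiology hypothesis worth testing.

## What the package computes

For a site × family matrix `X` (raw counts, the *UM* branch, and a copy
standardized by site maxima, the *SM* branch — the comparison separates
ecological signal from library-size artifacts):

1. **Hit filter (ingest):** domain hits are kept when
   `i-Evalue ≤ 1e-3`, `10 · bias ≤ score`, and the alignment covers
   ≥ 20% of both query and model; retained hits are cross-tabulated
   into `X`.
2. **Pruning:** families with `< 20` non-zero abundances and sites with
   `< 1000` non-zero abundances (defaults for ~3,600-family matrices;
   scale for narrower data) are removed in a single simultaneous pass;
   multi-category families are dropped first.
3. **Correlation:** all-pairs Spearman `ρ` (average ranks for ties),
   two-sided p from `t = ρ√((n−2)/(1−ρ²))` with `n−2` df. A pair is
   significant when `ρ > 0.80` and `p < cutoff` (Bonferroni `α/m`, or
   an absolute override such as `1e-6`); families with no significant
   partner are dropped.
4. **Network & transitivity clusters:** significant pairs form a
   weighted graph, partitioned into clique-like clusters by weighted
   **cluster editing** — minimize
   `Σ_intra max(0, T−s) + Σ_inter max(0, s−T)` with `T = 0.80` — using
   an exact O(3ⁿ) subset dynamic program for components ≤ 12 nodes and
   a greedy + relocation heuristic (2 s budget, sub-cluster cap 50)
   above that. Clusters with ≥ 3 members are labeled TC1, TC2, …
5. **DUF annotation:** a DUF is *biased* toward a metabolic category
   when its significant correlations to that category are at least
   **double** those to any other category; clusters with ≥ 4 members
   and ≥ 2 DUFs get phylum-level taxonomic profiles (phyla > 5% of DUF
   instances shown).

A **planted-module synthetic generator** (Poisson-lognormal counts,
shared per-site library factor, per-module shared activity, independent
zero-inflation) makes the whole pipeline testable end to end, with an
adjusted-Rand-index recovery report against the planted truth. See the
methods vignette (`vignettes/domain-covariation.Rmd`) for the model,
parameter rationale, and limitations.

## Worked example

```r
library(ecodomnet)

spec <- synthetic_spec(seed = 7)              # 80 sites, 6 planted modules + background
cfg  <- published_config(synthetic = spec, seed = 7,
                           branch = "both", min_row_nonzero = 50)
res  <- run_pipeline(cfg)

res$pruned_matrix
#> abundance_matrix: 80 sites x 176 families (counts)

round(res$um$rho_summary, 3)
#>  mean    sd
#> 0.337 0.218

res$um$clusters
#> tc_set: 36 clusters (8 reportable, >= 3 members), total cost 1.808

head(cluster_report(res$um$clusters, res$um$network)[, c("cluster_id", "size", "n_duf", "exact")], 4)
#>   cluster_id size n_duf exact
#> 1        TC1   10     6 FALSE
#> 2        TC2    6     2  TRUE
#> 3        TC3    5     2  TRUE
#> 4        TC4    4     2  TRUE

b <- res$um$bias
head(b[!is.na(b$primary), c("duf", "primary", "n_category_links")], 3)
#>      duf primary n_category_links
#> 2 DUF102   Photo                3
#> 3 DUF103   Photo                3
#> 4 DUF201       E                3

unlist(recovery_report(res$truth, res$um$clusters, res$um$network)[c("ari", "bias_recall")])
#>       ari bias_recall
#> 0.9454912   0.6666667
```

Reading the output: the all-pairs correlation distribution is roughly
Gaussian (mean ≈ 0.34, s.d. ≈ 0.22); eight transitivity clusters reach
the 3-member reporting threshold; the DUFs planted in the photobiology
module (`DUF102`, `DUF103`) come back with `Photo` as their primary
bias; and the reportable clusters match the planted modules at
ARI ≈ 0.95. The largest cluster (TC1, heuristic-solved) collects
background families whose presence/absence tracks the shared library
factor — exactly the artifact the SM branch removes.

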