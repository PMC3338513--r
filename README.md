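# paraclust

Detection of **paraclusters**: groups of ancestrally related (paralogous or
domain-sharing) genes lying closer together along a chromosome than expected
by chance.

Gene duplication leaves genomes with clusters of structurally related genes —
tandem arrays of recent duplicates, but also ancient, highly diverged
families whose members are still in proximity despite interspersed unrelated
genes. `paraclust` quantifies this organisation for any genome given only a
gene position table and one or more structural annotation datasets (protein
domains, protein families, or explicit paralog pairs), and is aimed at
comparative genomicists studying gene-family evolution and at anyone who
needs a statistically controlled alternative to distance-cutoff cluster
calls.

## The method

1. **Rank order.** The protein-coding genes are placed in rank order along
   chromosomes; all proximity statistics use rank distance, not base pairs,
   which removes gene-density artifacts. The span *n* between two genes
   counts both endpoints, so *n* = 2 means adjacent.
2. **Chaining.** For each annotation dataset, a greedy forward scan chains
   together genes that share at least one of the chain's common annotations;
   the chain is represented by the least common subset of annotations shared
   by all members. Runs of more than `max_gap` (default 15) consecutive
   non-sharing genes close a chain, and a nested tandem array of a different
   family inside a gap counts as a single gap space. Each gene joins at most
   one chain per dataset.
3. **Significance.** A chain of *k* successive genes (counting
   interstitials) of which *l* share an annotation carried by *m* genes
   genome-wide is scored with the hypergeometric tail

   P(X ≥ l) = Σ_{i=l}^{min(k,m)} C(m,i) C(N−m,k−i) / C(N,k),

   where *N* is the genome's gene count. Correcting for the number of
   opportunities to see such a chain — practically *N* — gives the
   expectation value *e* = *p* · *N*; chains with *e* < 0.01 are significant.
4. **Merging.** Significant chains from different datasets whose member sets
   intersect are merged (transitively) into paraclusters; merging recovers
   members that any single dataset misses through incomplete annotation.

Permuted-genome controls (gene order shuffled, annotations untouched) supply
the null for the chromosome-walk proximity profiles and for the expectation
threshold itself.

Everything is testable without downloads through a seeded synthetic-genome
generator (`simulate_genome()`) that emulates a vertebrate-like annotation
structure — singleton-dominated family sizes, a few very large families,
planted tandem/gapped/nested clusters, per-dataset annotation dropout and
high-frequency domains — and records a ground-truth ledger.

## Worked example

```r
library(paraclust)

sim <- simulate_genome(sim_config(n_genes = 5000, n_planted = 30, seed = 42))
res <- run_pipeline(run_config(
  genes = sim$genes, annotations = sim$annotations, pairs = sim$pairs,
  do_walk = FALSE, seed = 42
))
res
#> paraclust pipeline result
#>   genes: 5000
#>   datasets: domains_a, domains_b, families_a, families_b, paralogs
#>   candidate chains: 747
#>   significant chains (e < 0.01 ): 162
#>   merged paraclusters: 33
#>   genes in paraclusters: 430 (8.6%)

res$metrics$summary
#> # A tibble: 6 × 4
#>   dataset    paracluster_count genes_in_paraclusters percent_genes
#>   <chr>                  <int>                 <int>         <dbl>
#> 1 domains_a                 32                   388          7.76
#> 2 domains_b                 33                   389          7.78
#> 3 families_a                33                   387          7.74
#> 4 families_b                32                   386          7.72
#> 5 paralogs                  32                   387          7.74
#> 6 merged                    33                   430          8.6

tidy(res)[1:3, c("cluster_id", "chromosome", "start_rank", "end_rank",
                 "n_members", "n_interstitial")]
#> # A tibble: 3 × 6
#>   cluster_id chromosome start_rank end_rank n_members n_interstitial
#> 1 pc0001     chr1              198      216        19              0
#> 2 pc0002     chr2              568      581         6              8
#> 3 pc0003     chr2              569      571         3              0
```

Each per-dataset row counts the significant chains of that dataset and the
genes they contain; the `merged` row counts cross-dataset paraclusters,
whose gene total exceeds every single dataset because each dataset misses
~10% of annotations. Note `pc0003` nested inside the span of `pc0002`:
membership-based merging keeps unrelated nested clusters separate while the
gap-collapsing rule keeps the outer chain intact.

`autoplot()`/`plot_walk_profile()`/`plot_size_distribution()`/`plot_sweep()`
draw the proximity profiles, size distributions and parameter sweeps;
`tidy()` and `glance()` give the paracluster table and a one-row summary.
A thin command-line interface with subcommands `simulate`, `run`, `walk`,
`detect`, `merge`, `metrics`, `compare` and `audit` is installed at
`inst/cli/paraclust`.

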