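# ecoassembly

Microbial communities are assembled by a mix of deterministic processes
(environmental selection) and stochastic ones (dispersal and ecological
drift). `ecoassembly` quantifies the relative contribution of five assembly
subprocesses — heterogeneous selection, homogeneous selection, dispersal
limitation, homogenizing dispersal and drift — from an ASV-by-sample count
table and a rooted phylogeny, using the two-step null-model framework
standard in microbial ecology:

1. the **beta nearest-taxon index** (βNTI), the standardized deviation of
   the abundance-weighted beta mean nearest-taxon distance (βMNTD) from a
   tip-shuffling null over the regional pool — βNTI < −2 indicates
   homogeneous selection, βNTI > +2 heterogeneous selection;
2. the **Raup–Crick index on Bray–Curtis** (RC_bray), which ranks the
   observed dissimilarity against communities reassembled from the pool
   under richness and abundance constraints — for pairs with |βNTI| < 2,
   RC > +0.95 indicates dispersal limitation, RC < −0.95 homogenizing
   dispersal, and |RC| ≤ 0.95 drift.

Fractions are estimated over repeated random subgroups of samples
(mean ± SD). Around this core the package provides Bayesian microbial
source tracking (collapsed Gibbs sampler with an Unknown source),
gene-assembly analysis via weighted/unweighted Raup–Crick, core-taxon
detection, Spearman co-occurrence networks, hierarchical clustering of
assembly profiles, correlation of assembly determinism with
community-internal factors (alpha diversity, network edges, gene-set
abundance), and a synthetic-community generator with known assembly regimes
that the whole pipeline is validated against. It is aimed at microbial
ecologists analysing amplicon surveys (tables in BIOM v1 JSON or TSV, trees
in newick, mapping files with nested environment ontology labels).

## Worked example

Simulate two known regimes at the default study scale (200 taxa, 40 samples
per regime, 5,000 reads per sample) and ask the classifier what it sees:

```r
library(ecoassembly)

suite <- simulate_regime_suite(seed = 42, n_taxa = 200, n_samples = 40,
                               depth = 5000,
                               regimes = c("homogeneous_selection", "drift"))
plan <- subsampling_plan(n_subgroups = 5, subgroup_size = 20,
                         depth = 5000, n_null = 199, seed = 42)
profile <- quantify_assembly(suite$counts, suite$tree, suite$metadata,
                             plan = plan)
profile
#> Assembly profile over 2 group(s); 5 subgroups x 20 samples, 199 randomizations
#>   drift                        deterministic   7.6% +/-  1.5%
#>   homogeneous_selection        deterministic 100.0% +/-  0.0%
glance(profile)
#> # A tibble: 2 x 4
#>   group                 deterministic_mean deterministic_sd modal_process
#>   <chr>                              <dbl>            <dbl> <fct>
#> 1 drift                             0.0758           0.0147 drift
#> 2 homogeneous_selection             1                0      homogeneous_selecti...
```

The drift block is classified as drift (deterministic fraction 7.6 % ± 1.5 %
of sample pairs), and the homogeneous-selection block as homogeneous
selection (100 % of pairs deterministic) — each subgroup's modal process
recovers the generating regime. `tidy(profile)` returns the full five-way
fraction table and `autoplot(profile)` a stacked-bar figure. The same
profile objects feed `cluster_environments()` (Bray–Curtis UPGMA of
subprocess fractions) and `correlate_determinism()` (Spearman tests against
per-environment factors). `run_full(run_config(...))` orchestrates the whole
pipeline — assembly, gene assembly, source tracking, core taxa, networks,
clustering, correlations — into a directory of TSV/JSON artifacts plus a
markdown report, byte-reproducible for a fixed seed.

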