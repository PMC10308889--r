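---
title: "Quantifying community assembly processes with ecoassembly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying community assembly processes with ecoassembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoassembly)
```

## The model

Microbial community composition is shaped by a mix of deterministic processes
(environmental selection) and stochastic ones (dispersal and ecological
drift). `ecoassembly` quantifies their relative contributions with the
two-step null-model framework that has become standard in microbial ecology:

1. **Phylogenetic turnover.** For a pair of communities the
   abundance-weighted *beta mean nearest-taxon distance* is

   $$\beta\mathrm{MNTD} = \tfrac{1}{2}\Big[\sum_{i \in A} f_{iA}\,
   \min_{j \in B} d_{ij} \;+\; \sum_{j \in B} f_{jB}\, \min_{i \in A} d_{ij}\Big],$$

   with $f$ the within-sample relative abundances and $d$ the patristic
   distance. The *beta nearest-taxon index* standardizes the observed value
   against a null in which tip labels are shuffled among the regional pool's
   taxa (abundances ride with the labels):
   $\beta\mathrm{NTI} = (\beta\mathrm{MNTD}_{obs} - \mu_{null})/\sigma_{null}$.
   Because nearest-taxon distances respond to *who replaces whom*, a pair
   whose turnover happens between close relatives scores
   $\beta\mathrm{NTI} < -2$ (consistent environmental filtering: homogeneous
   selection), while turnover between distant clades scores $> +2$
   (divergent filtering: heterogeneous selection).

2. **Taxonomic turnover.** Pairs without a selection signal are tested with
   the Raup–Crick index on Bray–Curtis. Each null replicate reassembles both
   communities from the regional pool — membership drawn without replacement
   proportional to occupancy, reads distributed proportional to pool relative
   abundance — and the observed dissimilarity is ranked against the null
   (ties at half weight), rescaled to $[-1, 1]$. $RC > +0.95$ means more
   turnover than random assembly (dispersal limitation, acting with drift);
   $RC < -0.95$ means less (homogenizing dispersal); anything between is
   indistinguishable from drift.

Boundary convention: the selection calls require $|\beta\mathrm{NTI}|$
*strictly* greater than 2 and the dispersal calls $|RC|$ strictly greater
than 0.95; exact boundary values fall to the inner (stochastic) region. A
degenerate null ($\sigma_{null}=0$, possible on tiny pools) flags the pair
and classifies it by $RC$ alone rather than dropping it, which would bias
fractions on small problems.

The analysis is run on random **subgroups** of samples (default 50 subgroups
of 40 samples rarefied to 5,000 reads, 999 randomizations): a subgroup's
pooled taxa form the regional pool, all of its pairs are classified, and the
five process fractions are reported as mean ± SD over subgroups. One shared
set of randomizations per subgroup is reused for all of its pairs; per-pair
nulls are available by calling `bnti()`/`rc_bray()` directly. Whether nulls
are shared or per-pair is genuinely open in the literature; sharing reduces
cost by roughly the number of pairs and leaves the per-pair null
distribution unchanged, so it is the default.

```{r, eval = FALSE}
plan <- subsampling_plan(n_subgroups = 50, subgroup_size = 40,
                         depth = 5000, n_null = 999, seed = 1)
profile <- quantify_assembly(counts, tree, metadata, group_by = "empo_3",
                             plan = plan)
tidy(profile)     # per-group process fractions, mean +/- SD
glance(profile)   # deterministic fraction and modal process per group
autoplot(profile)
```

## The synthetic-community generator

The paper-scale datasets this method is usually applied to are not
reproducible at desk scale, so the package ships a generator whose regimes
carry known ground truth. The paper-style workflow only *classifies*
communities; it prescribes no generative model, so the generator is this
package's own construction and its design is documented here.

Every sample is a zero-sum local community: roughly `local_richness` member
taxa drawn from a regional pool (lognormal relative abundances,
`pool_lognorm_sd = 0.75`), observed as one multinomial draw of `depth`
reads, plus a thin "seed bank" tail (8 taxa at 2 reads, half drawn in
proportion to pool abundance, half uniformly). The tail mimics the trace
detections that give real tables their breadth: it keeps the regional pool
large without adding analytical weight, and it gives the Raup–Crick null its
occupancy freedom. The regimes differ in how membership and abundance are
determined:

* **Selection** (`homogeneous_selection`, `heterogeneous_selection`):
  establishment is a lottery over *lineages* weighted by a Gaussian niche
  filter $\exp(-(x - E)^2 / 2\sigma^2)$ on a rank-uniform niche axis
  ($\sigma$ = `selection_strength` × trait range, default 0.15), with at
  most `max_variants_per_lineage` coexisting variants per lineage (limiting
  similarity). Homogeneous selection shares one optimum across samples and
  excludes congeners entirely (broad generalist communities,
  `establishment_sharpness = 2`, one variant per lineage); heterogeneous
  selection draws a fresh optimum per sample and allows narrower, more
  specialized communities (`establishment_sharpness = 8`, up to three
  variants). Under a shared optimum, samples share lineages but swap
  variants, so observed βMNTD collapses toward the within-radiation scale
  while the null stays at the tree-wide scale — the homogeneous-selection
  signature. Divergent optima put pairs in different clades — the
  heterogeneous-selection signature.
* **Drift**: membership is an iid lottery proportional to pool abundance and
  fills follow the pool — precisely the kind of random assembly the
  Raup–Crick null describes. This is deliberate: in this framework "drift"
  *means* turnover consistent with random assembly from the pool.
  `n_generations = 0` degenerates to iid multinomial draws of the pool, per
  the generator's contract.
* **Dispersal limitation**: local pools drift apart along a sampling
  transect as a per-taxon log-abundance random walk (`spatial_walk_sd`,
  default 1.8 per step); membership follows the local pool, while member
  abundances are iid lognormal so that distant pairs share almost no mass.
  Distant samples then exceed the turnover of random assembly ($RC \to +1$)
  while the weak adjacent migration (m = 0.001 accumulated over
  `n_generations`) keeps neighbours correlated.
* **Homogenizing dispersal**: mass effects — one realized community
  (membership and abundances drawn once) is replicated across all samples,
  mixed with each sample's own lottery at the cumulative migration weight
  $1-(1-m)^{t}$, which is ≈ 1 at the default m = 0.5. Samples then share
  membership exactly, while the occupancy-driven null keeps re-drawing
  membership from the pool's patchy tail — the $RC \to -1$ signature.

The default phylogeny (`simulate_phylogeny()`) is a two-level birth–death
tree: a pure-birth backbone of `n_taxa/4` lineages whose tips end in shallow
fans of near-identical variants. Marker-gene data look exactly like this —
exact sequence variants cluster into recent radiations of the same organism
— and the fan structure is what gives the nearest-taxon metric its contrast:
a non-shared variant usually has a same-fan partner in the other community.
During design we measured the reachable range of the βNTI z-score at the
study scale (200 taxa): because observed βMNTD is bounded below by zero, the
negative side saturates near $-\mu_{null}/\sigma_{null} \approx -3.5$, so
homogeneous selection is only detectable when communities are sparse
relative to the pool (richness ≈ 15 % of pool taxa), non-shared weights are
spread over many taxa, and replacements happen within radiations. Those
three requirements shaped the defaults above. Niche positions come from a
Brownian trait on the backbone, rank-transformed to a uniform axis so niche
windows are evenly populated; `evolve_trait()` itself is plain Brownian
motion (variance = rate × root-to-tip distance), with `conservatism`
implementing an early-burst rescaling that concentrates variance on deep
branches.

What the generator does *not* emulate: sequencing error and chimeras,
compositional biases of extraction/PCR, taxon-specific copy-number
variation, temporal autocorrelation, and the deep uneven richness of real
surveys (hundreds of thousands of taxa). Passing the recovery checks
therefore shows the *classifier logic* is sound under controlled
assumptions, not that any particular real dataset will be classified
correctly.

## Gene assembly

Gene-by-sample tables (e.g. predicted functional profiles) have no
phylogeny, so their deterministic fraction is the proportion of sample
pairs with $|RC| > 0.95$, using the unweighted Raup–Crick (shared-gene
count, the default) or the weighted Bray–Curtis variant on rounded
abundances (prediction tools emit non-integers; rounding is the default
resolution). The synthetic gene tables evolve per-gene presence as a
thresholded Brownian latent on the tree, so related taxa share repertoires,
and aggregate to samples as a gene × taxon by taxon × sample matrix product.

## Source tracking

`estimate_sources()` is a collapsed Gibbs sampler over per-read source
assignments $z_i \in \{1..V, \mathrm{Unknown}\}$ with

$$P(z_i = v \mid \cdot) \propto
\frac{m_{v,t_i} + n_{v,t_i}^{-i} + \alpha_v}
     {m_{v,\cdot} + n_{v,\cdot}^{-i} + T\,\alpha_v} \,(n_v^{-i} + \beta),$$

where $m$ are source training counts (zero for Unknown), $n$ the current
sink assignments, and $\alpha_v$ = `alpha_known` (0.001) for trained sources
and `alpha_unknown` (0.1) for the Unknown source. Defaults (10 restarts,
100 burn-in sweeps, 1 retained draw, sinks rarefied to 1,000 reads) follow
the canonical tool's published configuration. `track_all()` runs
leave-one-environment-out with environment-aggregated sources (per-sample
sinks averaged afterwards are available via `sink_mode = "per_sample"`).

## Community statistics

* **Core taxa**: occurrence strictly above one half of the environment's
  samples *and* mean relative abundance strictly above 0.1 %. Both
  thresholds are strict, so boundary cases are excluded.
* **Alpha diversity**: observed richness; Shannon entropy with natural log
  (some survey releases use log2 — configurable via `shannon_base`);
  bias-corrected Chao1 $S + F_1(F_1-1)/(2(F_2+1))$; Faith's PD including the
  path to the root (affects absolute values, not correlations).
* **Co-occurrence networks**: top 500 taxa by summed relative abundance
  (lexicographic tie-break for determinism), pairwise Spearman on relative
  abundances, edges at $|\rho| > 0.5$ and raw two-sided $p < 0.05$
  (t-approximation on $n-2$ df with mid-rank ties, no multiple-testing
  correction — matching the survey convention this mirrors). Note the
  relative-abundance transform matters despite ranks: a raw-constant taxon
  varies inversely with sample depth after normalization unless depths are
  even.
* **Profile clustering**: Bray–Curtis on the five-fraction vectors,
  average linkage (UPGMA; the linkage is not dictated by the framework —
  configurable), serialized to newick.
* **Factor correlations**: Spearman between per-environment deterministic
  fractions and any factor (alpha diversity, network edge count — the
  operationalization of "interaction degree" — or gene-set relative
  abundance), with explicit exclusion bookkeeping.

## Numerical choices and limitations

* Every stochastic operation takes a seed; subgroup $k$ of group $g$ uses
  `seed + (g-1) * n_subgroups + k`, so any subgroup is reproducible in
  isolation. RNG state is restored after each call (`withr::with_seed`).
* Problem sizes used in the shipped validation: regime recovery runs 10
  subgroups of 20 samples per regime at `n_null = 199` over three replicate
  datasets; calibration checks use 200 pairs at `n_null = 999`. These sizes
  put the Monte-Carlo error comfortably inside the test tolerances while
  keeping a full validation run in minutes on one core.
* Rarefaction is sampling *without* replacement; samples below depth are
  dropped with a warning, not padded.
* Ties in the Raup–Crick rank count at half weight, so an all-tie null gives
  exactly 0.
* The homogeneous-selection call is intrinsically the least sensitive: its
  z-score is bounded by the null's coefficient of variation, so datasets
  with few taxa, saturated per-sample richness, or weak within-clade
  replacement will under-detect homogeneous selection long before the other
  four classes degrade.
* `make_report()`/`run_full()` write plain TSV/JSON/markdown artifacts and
  are byte-reproducible for a fixed config and seed.
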