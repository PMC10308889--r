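#' Specification of a synthetic assembly regime
#'
#' Bundles and validates the parameters of the synthetic-community generator.
#' The five regimes mirror the five assembly subprocesses the null-model
#' classifier distinguishes, so that every downstream stage can be validated
#' against known ground truth.
#'
#' @param regime one of `"homogeneous_selection"`, `"heterogeneous_selection"`,
#'   `"dispersal_limitation"`, `"homogenizing_dispersal"`, `"drift"`.
#' @param n_taxa number of taxa in the regional pool (>= 4).
#' @param n_samples number of samples (>= 2).
#' @param depth reads per sample (>= 100); every generated column sums to it.
#' @param selection_strength Gaussian niche width as a fraction of the trait
#'   range (the sigma of the fitness filter).
#' @param trait_conservatism early-burst decay rate of trait evolution on the
#'   tree; larger values concentrate trait variance on deep branches so that
#'   niches align with clades.
#' @param migration_rate per-generation migration probability m in \[0, 1\];
#'   adjacent-sample migration under dispersal limitation, global under
#'   homogenizing dispersal.
#' @param n_generations Wright-Fisher generations the migration acts over;
#'   `0` degenerates drift to iid multinomial sampling of the pool.
#' @param local_richness number of locally coexisting member taxa per sample;
#'   defaults to 30 for the selection regimes and 24 otherwise.
#' @param n_lineages lineages (terminal radiations) in the default phylogeny.
#' @param pool_lognorm_sd lognormal sd of regional pool relative abundances.
#' @param establishment_sharpness exponent applied to the Gaussian niche
#'   filter when lineages are drawn for establishment; defaults to 2 under a
#'   shared optimum (generalist communities) and 8 under per-sample optima
#'   (divergent specialists).
#' @param max_variants_per_lineage cap on coexisting variants of one lineage
#'   (limiting similarity); defaults to 1 under homogeneous and 3 under
#'   heterogeneous selection.
#' @param spatial_walk_sd per-step sd of the log-abundance random walk that
#'   differentiates local pools along the sampling transect under dispersal
#'   limitation.
#' @param tail_taxa,tail_reads per-sample count of low-abundance "seed bank"
#'   taxa and reads given to each; keeps the regional pool broad without
#'   adding weight.
#' @param abundance_lognorm_sd lognormal sd of within-sample member abundances.
#' @param seed integer master seed.
#' @return a validated list of class `"regime_spec"`.
#' @export
regime_spec <- function(regime,
                        n_taxa = 200L,
                        n_samples = 40L,
                        depth = 5000L,
                        selection_strength = 0.15,
                        trait_conservatism = 25,
                        migration_rate = NULL,
                        n_generations = 200L,
                        local_richness = NULL,
                        n_lineages = NULL,
                        pool_lognorm_sd = 0.75,
                        establishment_sharpness = NULL,
                        max_variants_per_lineage = NULL,
                        spatial_walk_sd = 1.8,
                        tail_taxa = 8L,
                        tail_reads = 2L,
                        abundance_lognorm_sd = 1,
                        seed = 1L) {
  regime <- match.arg(regime, process_levels())
  selection <- regime %in% c("homogeneous_selection", "heterogeneous_selection")
  migration_rate <- migration_rate %||%
    switch(regime, dispersal_limitation = 0.001, homogenizing_dispersal = 0.5, 0)
  local_richness <- local_richness %||% (if (selection) 30L else 24L)
  establishment_sharpness <- establishment_sharpness %||%
    (if (regime == "heterogeneous_selection") 8 else 2)
  max_variants_per_lineage <- max_variants_per_lineage %||%
    (if (regime == "heterogeneous_selection") 3L else 1L)
  n_lineages <- n_lineages %||% max(2L, min(as.integer(round(n_taxa / 4)), n_taxa))
  stopifnot(n_taxa >= 4, n_samples >= 2, depth >= 100,
            migration_rate >= 0, migration_rate <= 1,
            local_richness >= 2, n_lineages >= 2, n_lineages <= n_taxa,
            tail_taxa * tail_reads < depth)
  structure(list(
    regime = regime, n_taxa = as.integer(n_taxa),
    n_samples = as.integer(n_samples), depth = as.integer(depth),
    selection_strength = selection_strength,
    trait_conservatism = trait_conservatism,
    migration_rate = migration_rate, n_generations = as.integer(n_generations),
    local_richness = as.integer(local_richness),
    n_lineages = as.integer(n_lineages),
    pool_lognorm_sd = pool_lognorm_sd,
    establishment_sharpness = establishment_sharpness,
    max_variants_per_lineage = as.integer(max_variants_per_lineage),
    spatial_walk_sd = spatial_walk_sd,
    tail_taxa = as.integer(tail_taxa), tail_reads = as.integer(tail_reads),
    abundance_lognorm_sd = abundance_lognorm_sd,
    seed = as.integer(seed)
  ), class = "regime_spec")
}

#' Simulate a rooted ultrametric phylogeny
#'
#' The default (`mode = "radiation"`) builds a two-level birth-death tree: a
#' pure-birth backbone of `n_lineages` deep lineages, each terminating in a
#' shallow fan of near-identical variant tips. This mirrors marker-gene data,
#' where exact sequence variants cluster into recent radiations of the same
#' organism, and is what gives nearest-taxon phylogenetic turnover its
#' contrast. `mode = "birth_death"` returns a plain reconstructed birth-death
#' tree.
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @param mode `"radiation"` (default) or `"birth_death"`.
#' @param n_lineages backbone lineages for the radiation mode.
#' @param fan_depth height of the terminal radiations (tree depth is 1).
#' @param birth,death rates for `mode = "birth_death"`.
#' @param tip_prefix tips are labelled `ASV_0001`, ... by default.
#' @return an ultrametric [ape::phylo]; radiation trees carry an integer
#'   `lineage` attribute mapping each tip (in `ASV_...` order) to its backbone
#'   lineage.
#' @export
simulate_phylogeny <- function(n_taxa, seed, mode = c("radiation", "birth_death"),
                               n_lineages = max(2L, round(n_taxa / 4)),
                               fan_depth = 0.03, birth = 1, death = 0,
                               tip_prefix = "ASV_") {
  mode <- match.arg(mode)
  stopifnot(n_taxa >= 2)
  labels <- sprintf("%s%04d", tip_prefix, seq_len(n_taxa))
  withr::with_seed(seed, {
    if (mode == "birth_death" || n_lineages >= n_taxa) {
      tr <- ape::rphylo(n_taxa, birth, death)
      tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
      tr$tip.label <- labels
      attr(tr, "lineage") <- stats::setNames(seq_len(n_taxa), labels)
      return(tr)
    }
    n_lineages <- min(n_lineages, n_taxa)
    bb <- ape::rphylo(n_lineages, birth, 0)
    bb$edge.length <- bb$edge.length /
      max(ape::node.depth.edgelength(bb)) * (1 - fan_depth)
    bb$tip.label <- sprintf("LIN%04d", seq_len(n_lineages))
    extra <- as.vector(rmultinom(1, n_taxa - n_lineages, rep(1, n_lineages)))
    sizes <- 1L + extra
    tip_of <- split(seq_len(n_taxa), rep(seq_len(n_lineages), sizes))
    tr <- bb
    for (L in seq_len(n_lineages)) {
      k <- sizes[L]
      lab <- labels[tip_of[[L]]]
      wh <- which(tr$tip.label == sprintf("LIN%04d", L))
      if (k == 1L) {
        tr$tip.label[wh] <- lab
      } else {
        fan <- ape::stree(k, "star")
        fan$tip.label <- lab
        ei <- which(tr$edge[, 2L] == wh)
        h <- min(fan_depth, 0.9 * tr$edge.length[ei])
        fan$edge.length <- rep(h, k)
        tr$edge.length[ei] <- tr$edge.length[ei] - h
        tr <- ape::bind.tree(tr, fan, where = wh)
      }
    }
    lineage <- stats::setNames(rep(seq_len(n_lineages), sizes)[order(unlist(tip_of))],
                               labels)
    attr(tr, "lineage") <- lineage
    attr(tr, "backbone") <- bb
    tr
  })
}

#' Evolve a continuous trait on a phylogeny by Brownian motion
#'
#' Plain Brownian motion from a root value of 0: a tip's trait variance equals
#' `rate` times its root-to-tip distance. `conservatism > 0` rescales branch
#' lengths by an early-burst decay `exp(-conservatism * t0 / T)` (with `t0`
#' the branch's starting depth and `T` the tree height) before the draw, which
#' concentrates trait variance on deep branches and makes trait similarity
#' track clade membership.
#'
#' @param tree [ape::phylo] with branch lengths.
#' @param rate Brownian rate (variance per unit branch length), > 0.
#' @param seed integer seed.
#' @param conservatism early-burst decay rate (0 = plain BM).
#' @return named numeric vector of tip trait values.
#' @export
evolve_trait <- function(tree, rate, seed, conservatism = 0) {
  stopifnot(rate > 0)
  tr2 <- tree
  if (conservatism > 0) {
    depths <- ape::node.depth.edgelength(tree)
    t0 <- depths[tree$edge[, 1L]]
    tr2$edge.length <- tree$edge.length * exp(-conservatism * t0 / max(depths))
  }
  withr::with_seed(seed, {
    x <- ape::rTraitCont(tr2, model = "BM", sigma = sqrt(rate), root.value = 0)
    stats::setNames(as.numeric(x), tree$tip.label)
  })
}

#' Lineage niche positions for a radiation phylogeny
#'
#' Evolves a Brownian trait on the backbone (early burst per the spec's
#' conservatism), then rank-transforms lineage values to a uniform niche axis
#' on \[0, 1\] so niche windows are evenly populated. Tips inherit their
#' lineage's position.
#'
#' @param tree a radiation phylogeny from [simulate_phylogeny()].
#' @param seed integer seed.
#' @return named numeric vector of per-tip niche positions in \[0, 1\].
#' @export
niche_positions <- function(tree, seed) {
  lineage <- attr(tree, "lineage")
  bb <- attr(tree, "backbone")
  if (is.null(lineage)) stop("tree carries no lineage attribute", call. = FALSE)
  L <- max(lineage)
  if (is.null(bb)) {
    ranks <- seq_len(L)
  } else {
    bt <- withr::with_seed(seed,
      as.numeric(ape::rTraitCont(bb, model = "BM", sigma = 1, root.value = 0)))
    ranks <- rank(bt, ties.method = "first")
  }
  pos <- (ranks - 1) / (L - 1)
  stats::setNames(pos[lineage], names(lineage))
}

## seed-bank tail: add tail_reads to tail_taxa taxa (half pool-weighted so
## regional dominants are ubiquitous at trace density, half uniform so the
## pool union stays broad)
add_tail <- function(cnt, pool, tail_taxa, tail_reads) {
  if (tail_taxa == 0L) return(cnt)
  S <- length(cnt)
  tl1 <- sample.int(S, ceiling(tail_taxa / 2), prob = pool)
  rest <- setdiff(seq_len(S), tl1)
  tl2 <- sample(rest, min(floor(tail_taxa / 2), length(rest)))
  tl <- c(tl1, tl2)
  cnt[tl] <- cnt[tl] + tail_reads
  cnt
}

## one multinomial observation of depth reads honoring the seed-bank tail
observe_sample <- function(w, depth, pool, tail_taxa, tail_reads) {
  cnt <- as.vector(rmultinom(1, depth - tail_reads * tail_taxa, w / sum(w)))
  add_tail(cnt, pool, tail_taxa, tail_reads)
}

## lineage-level establishment lottery with limiting similarity
draw_members_selection <- function(lineage, lranks, E, sigma, estab, vmax,
                                   n_c, tilt) {
  L <- max(lineage)
  loglw <- -estab * (lranks - E)^2 / (2 * sigma^2)
  lw <- exp(loglw - max(loglw))   # log-space: safe for very narrow niches
  members <- integer(0)
  used <- integer(L)
  while (length(members) < n_c && any(lw > 0)) {
    Lg <- sample.int(L, 1L, prob = lw)
    v <- setdiff(which(lineage == Lg), members)
    pick <- if (length(v) == 1L) v else sample(v, 1L, prob = tilt[v])
    members <- c(members, pick)
    used[Lg] <- used[Lg] + 1L
    if (used[Lg] >= min(vmax, sum(lineage == Lg))) lw[Lg] <- 0
  }
  members
}

#' Simulate a community table under a known assembly regime
#'
#' Generates an ASV-by-sample count table whose between-sample turnover
#' embodies one assembly subprocess, together with sample metadata labelling
#' the regime. All columns sum exactly to `spec$depth`. The generative
#' mechanisms are described in the methods vignette; in brief, every sample is
#' a zero-sum local community of `local_richness` member taxa drawn from the
#' regional pool, and the regimes differ in how membership and abundance are
#' determined (niche-guild lotteries under selection, iid pool lotteries under
#' drift, spatially random-walking pools under dispersal limitation, one
#' shared realized community under homogenizing dispersal).
#'
#' @param spec a [regime_spec()].
#' @param tree phylogeny from [simulate_phylogeny()] (radiation mode); built
#'   from `spec` when `NULL`.
#' @param traits per-tip niche positions; derived via [niche_positions()] when
#'   `NULL`.
#' @return list with `counts` (matrix, taxa x samples), `metadata` (tibble
#'   with `sample_id`, `empo_1`, `empo_2`, `empo_3`), `tree`, `traits`, `pool`.
#' @export
simulate_dataset <- function(spec, tree = NULL, traits = NULL) {
  stopifnot(inherits(spec, "regime_spec"))
  tree <- tree %||% simulate_phylogeny(spec$n_taxa, seed = spec$seed,
                                       n_lineages = spec$n_lineages)
  traits <- traits %||% niche_positions(tree, seed = spec$seed + 1L)
  lineage <- attr(tree, "lineage")
  S <- length(tree$tip.label)
  labels <- names(traits)
  lineage <- lineage[labels]
  counts <- withr::with_seed(spec$seed + 2L, {
    pool <- exp(rnorm(S, 0, spec$pool_lognorm_sd))
    pool <- pool / sum(pool)
    sim_regime_counts(spec, lineage, traits, pool)
  })
  rownames(counts) <- labels
  colnames(counts) <- sprintf("%s_s%03d", abbreviate_regime(spec$regime),
                              seq_len(spec$n_samples))
  metadata <- tibble(
    sample_id = colnames(counts),
    empo_1 = "synthetic",
    empo_2 = if (spec$regime %in% c("homogeneous_selection",
                                    "heterogeneous_selection"))
      "deterministic" else "stochastic",
    empo_3 = spec$regime
  )
  list(counts = counts, metadata = metadata, tree = tree, traits = traits,
       pool = NULL)
}

abbreviate_regime <- function(regime) {
  c(heterogeneous_selection = "hetsel", homogeneous_selection = "homsel",
    dispersal_limitation = "displim", homogenizing_dispersal = "homdisp",
    drift = "drift")[[regime]]
}

## core engine; assumes RNG state is managed by the caller
sim_regime_counts <- function(spec, lineage, traits, pool) {
  S <- length(pool)
  ns <- spec$n_samples
  n_c <- min(spec$local_richness, S)
  tilt_sd <- spec$abundance_lognorm_sd
  sigma <- spec$selection_strength * max(diff(range(traits)), .Machine$double.eps)
  lranks <- tapply(traits, lineage, mean)[as.character(seq_len(max(lineage)))]
  comm <- matrix(0L, S, ns)
  regime <- spec$regime

  if (regime %in% c("homogeneous_selection", "heterogeneous_selection")) {
    E0 <- runif(1)
    for (s in seq_len(ns)) {
      E <- if (regime == "homogeneous_selection") E0 else runif(1)
      tilt <- exp(rnorm(S, 0, tilt_sd))
      members <- draw_members_selection(lineage, lranks, E, sigma,
                                        spec$establishment_sharpness,
                                        spec$max_variants_per_lineage, n_c, tilt)
      filt <- exp(-(traits - E)^2 / (2 * sigma^2))
      w <- numeric(S)
      w[members] <- (pool * tilt * pmax(filt, 1e-12))[members]^0.1
      comm[, s] <- observe_sample(w, spec$depth, pool, spec$tail_taxa,
                                  spec$tail_reads)
    }
  } else if (regime == "drift") {
    if (spec$n_generations == 0L) {
      # degenerate contract: iid multinomial draws straight from the pool
      for (s in seq_len(ns)) comm[, s] <- as.vector(rmultinom(1, spec$depth, pool))
    } else {
      for (s in seq_len(ns)) {
        tilt <- exp(rnorm(S, 0, tilt_sd))
        members <- sample.int(S, n_c, prob = pool * tilt)
        w <- numeric(S)
        w[members] <- (pool * tilt)[members]
        comm[, s] <- observe_sample(w, spec$depth, pool, spec$tail_taxa,
                                    spec$tail_reads)
      }
    }
  } else if (regime == "dispersal_limitation") {
    g <- matrix(0, S, ns)
    if (ns > 1) for (s in 2:ns) g[, s] <- g[, s - 1] + rnorm(S, 0, spec$spatial_walk_sd)
    m_eff <- 1 - (1 - spec$migration_rate)^spec$n_generations
    loc <- sapply(seq_len(ns), function(s) pool^0.5 * exp(g[, s]))
    if (ns > 1 && m_eff > 0) {
      mixed <- loc
      for (s in seq_len(ns)) {
        nb <- intersect(c(s - 1, s + 1), seq_len(ns))
        mixed[, s] <- (1 - m_eff) * loc[, s] +
          m_eff * rowMeans(loc[, nb, drop = FALSE])
      }
      loc <- mixed
    }
    for (s in seq_len(ns)) {
      members <- sample.int(S, n_c, prob = loc[, s] * exp(rnorm(S, 0, tilt_sd)))
      w <- numeric(S)
      w[members] <- exp(rnorm(n_c, 0, 1.2))
      comm[, s] <- observe_sample(w, spec$depth, pool, spec$tail_taxa,
                                  spec$tail_reads)
    }
  } else if (regime == "homogenizing_dispersal") {
    m_eff <- 1 - (1 - spec$migration_rate)^spec$n_generations
    tilt0 <- exp(rnorm(S, 0, tilt_sd))
    members0 <- sample.int(S, n_c, prob = pool * tilt0)
    base <- numeric(S)
    base[members0] <- (pool * tilt0)[members0]
    base <- base / sum(base)
    shared_tail <- 6e-4 * exp(rnorm(S, 0, 1.5))
    for (s in seq_len(ns)) {
      tilt <- exp(rnorm(S, 0, tilt_sd))
      members <- sample.int(S, n_c, prob = pool * tilt)
      own <- numeric(S)
      own[members] <- (pool * tilt)[members]
      own <- own / sum(own)
      w <- (1 - m_eff) * own + m_eff * base + shared_tail
      comm[, s] <- as.vector(rmultinom(1, spec$depth, w / sum(w)))
    }
  }
  storage.mode(comm) <- "integer"
  comm
}

#' Simulate all five assembly regimes into one dataset
#'
#' Builds one shared phylogeny and regional pool, then one block of samples
#' per regime, concatenated into a single count table with nested environment
#' labels (`empo_3` = regime, `empo_2` = deterministic/stochastic,
#' `empo_1` = "synthetic").
#'
#' @param seed master seed; per-regime child seeds are derived from it.
#' @param regimes character vector of regimes (default all five).
#' @param n_taxa,n_samples,depth dimensions shared by all regimes.
#' @param ... further arguments forwarded to [regime_spec()].
#' @return list with `counts`, `metadata`, `tree`, `traits`.
#' @export
simulate_regime_suite <- function(seed, regimes = process_levels(),
                                  n_taxa = 200L, n_samples = 40L,
                                  depth = 5000L, ...) {
  tree <- simulate_phylogeny(n_taxa, seed = seed)
  traits <- niche_positions(tree, seed = seed + 1L)
  blocks <- lapply(seq_along(regimes), function(i) {
    sp <- regime_spec(regimes[i], n_taxa = n_taxa, n_samples = n_samples,
                      depth = depth, seed = seed + 100L * i, ...)
    simulate_dataset(sp, tree = tree, traits = traits)
  })
  counts <- do.call(cbind, lapply(blocks, `[[`, "counts"))
  metadata <- bind_rows(lapply(blocks, `[[`, "metadata"))
  list(counts = counts, metadata = metadata, tree = tree, traits = traits)
}

#' Simulate gene content for the taxa of a phylogeny
#'
#' Gene presence evolves on the tree as a thresholded Brownian latent
#' variable, so related taxa share gene repertoires; a chosen number of genes
#' are flagged as predatory-specific.
#'
#' @param tree [ape::phylo].
#' @param n_genes number of genes.
#' @param n_predatory number of genes flagged predatory-specific
#'   (`<= n_genes`).
#' @param conservatism early-burst decay passed to [evolve_trait()]; higher
#'   values make gene content more clade-conserved.
#' @param seed integer seed.
#' @param prevalence expected fraction of taxa carrying an average gene.
#' @return list with `gene_matrix` (genes x taxa, 0/1), `predatory` (logical
#'   per gene), `gene_ids`.
#' @export
simulate_gene_content <- function(tree, n_genes, n_predatory, conservatism = 4,
                                  seed = 1L, prevalence = 0.5) {
  stopifnot(n_predatory <= n_genes)
  S <- length(tree$tip.label)
  gm <- matrix(0L, n_genes, S,
               dimnames = list(sprintf("gene_%05d", seq_len(n_genes)),
                               tree$tip.label))
  for (gidx in seq_len(n_genes)) {
    lat <- evolve_trait(tree, rate = 1, seed = seed + gidx,
                        conservatism = conservatism)
    thr <- quantile(lat, 1 - prevalence)
    gm[gidx, ] <- as.integer(lat >= thr)
  }
  predatory <- rep(FALSE, n_genes)
  predatory[withr::with_seed(seed, sample.int(n_genes, n_predatory))] <- TRUE
  list(gene_matrix = gm, predatory = predatory, gene_ids = rownames(gm))
}

#' Aggregate gene content to a gene-by-sample table
#'
#' The sample-level gene table is the matrix product of per-taxon gene copy
#' numbers and the taxon count table, mirroring how marker-gene functional
#' prediction tools aggregate profiles.
#'
#' @param gene_content result of [simulate_gene_content()].
#' @param counts taxa x samples count table (taxa must match columns of the
#'   gene matrix).
#' @return genes x samples numeric matrix.
#' @export
gene_table <- function(gene_content, counts) {
  shared <- intersect(colnames(gene_content$gene_matrix), rownames(counts))
  if (!length(shared)) stop("gene content and count table share no taxa", call. = FALSE)
  gene_content$gene_matrix[, shared, drop = FALSE] %*%
    counts[shared, , drop = FALSE]
}

#' Wright-Fisher resampling of a finite community
#'
#' One neutral drift trajectory: each generation the community of
#' `community_size` individuals is multinomially resampled from its own
#' frequencies (births and deaths at fixed community size).
#'
#' @param freqs initial relative abundances (will be normalized).
#' @param n_generations number of resampling steps.
#' @param community_size number of individuals.
#' @param seed integer seed.
#' @return final relative-abundance vector.
#' @export
wright_fisher_drift <- function(freqs, n_generations, community_size, seed) {
  withr::with_seed(seed, {
    x <- as.vector(rmultinom(1, community_size, freqs / sum(freqs)))
    for (g in seq_len(n_generations)) {
      x <- as.vector(rmultinom(1, community_size, x / community_size))
    }
    x / community_size
  })
}

#' Simulate a table with planted correlated taxon pairs
#'
#' Background taxa fluctuate independently across samples; each planted pair
#' shares a latent lognormal driver, giving strongly rank-correlated
#' abundances. Used to validate co-occurrence network recovery.
#'
#' @param n_noise independent background taxa.
#' @param n_pairs planted correlated pairs.
#' @param n_samples samples.
#' @param depth reads per sample.
#' @param driver_sd sd of the shared log-driver (correlation strength).
#' @param noise_sd residual lognormal noise on each partner.
#' @param seed integer seed.
#' @return list with `counts` and `pairs` (tibble of planted partner ids).
#' @export
simulate_correlated_table <- function(n_noise = 200L, n_pairs = 20L,
                                      n_samples = 30L, depth = 5000L,
                                      driver_sd = 2, noise_sd = 0.25,
                                      seed = 1L) {
  S <- n_noise + 2L * n_pairs
  ids <- sprintf("ASV_%04d", seq_len(S))
  counts <- withr::with_seed(seed, {
    w <- matrix(0, S, n_samples)
    base <- exp(rnorm(S, 0, 1))
    for (s in seq_len(n_samples)) {
      drivers <- rnorm(n_pairs, 0, driver_sd)
      lw <- log(base) + rnorm(S, 0, driver_sd)
      for (p in seq_len(n_pairs)) {
        i <- n_noise + 2L * p - 1L
        lw[i] <- log(base[i]) + drivers[p] + rnorm(1, 0, noise_sd)
        lw[i + 1L] <- log(base[i + 1L]) + drivers[p] + rnorm(1, 0, noise_sd)
      }
      w[, s] <- exp(lw)
    }
    sapply(seq_len(n_samples), function(s)
      as.vector(rmultinom(1, depth, w[, s] / sum(w[, s]))))
  })
  dimnames(counts) <- list(ids, sprintf("s%03d", seq_len(n_samples)))
  pairs <- tibble(
    taxon_a = ids[n_noise + 2L * seq_len(n_pairs) - 1L],
    taxon_b = ids[n_noise + 2L * seq_len(n_pairs)]
  )
  list(counts = counts, pairs = pairs)
}
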