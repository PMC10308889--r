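test_that("simulated phylogenies are ultrametric, labelled, reproducible", {
  tr2 <- simulate_phylogeny(2, seed = 1)
  expect_equal(length(tr2$tip.label), 2L)

  t64a <- simulate_phylogeny(64, seed = 9)
  t64b <- simulate_phylogeny(64, seed = 9)
  expect_identical(ape::write.tree(t64a), ape::write.tree(t64b))
  depths <- ape::node.depth.edgelength(t64a)[seq_len(64)]
  expect_lt(max(depths) - min(depths), 1e-9)   # ultrametric by traversal
  expect_true(all(grepl("^ASV_\\d{4}$", t64a$tip.label)))
  lin <- attr(t64a, "lineage")
  expect_identical(names(lin), t64a$tip.label)

  bd <- simulate_phylogeny(32, seed = 2, mode = "birth_death", death = 0.5)
  expect_equal(length(bd$tip.label), 32L)
})

test_that("Brownian traits have the right variance scaling", {
  tr <- simulate_phylogeny(10, seed = 3, mode = "birth_death")
  depth <- max(ape::node.depth.edgelength(tr))
  rate <- 0.7
  tips <- vapply(1:1000, function(s) evolve_trait(tr, rate, seed = s)[1L],
                 numeric(1))
  ratio <- stats::var(tips) / (rate * depth)
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 1.1)

  # zero patristic distance implies identical traits
  tr0 <- ape::read.tree(text = "((a:0,b:0):1,c:2);")
  x <- evolve_trait(tr0, 1, seed = 5)
  expect_equal(x[["a"]], x[["b"]])

  # vanishing rate collapses all traits to the root value
  y <- evolve_trait(tr, 1e-12, seed = 5)
  expect_true(all(abs(y) < 1e-4))
})

test_that("every regime yields exact-depth, reproducible tables", {
  tr <- simulate_phylogeny(80, seed = 4)
  traits <- niche_positions(tr, seed = 5)
  for (regime in c("homogeneous_selection", "heterogeneous_selection", "drift",
                   "dispersal_limitation", "homogenizing_dispersal")) {
    sp <- regime_spec(regime, n_taxa = 80, n_samples = 6, depth = 400, seed = 11)
    d1 <- simulate_dataset(sp, tree = tr, traits = traits)
    expect_true(all(colSums(d1$counts) == 400), label = regime)
    d2 <- simulate_dataset(sp, tree = tr, traits = traits)
    expect_identical(d1$counts, d2$counts)
    expect_equal(d1$metadata$empo_3[1], regime)
  }
})

test_that("degenerate limits behave as specified", {
  tr <- simulate_phylogeny(40, seed = 6)
  traits <- niche_positions(tr, seed = 7)
  # near-zero niche width: samples collapse onto the taxa nearest the optimum
  sp <- regime_spec("homogeneous_selection", n_taxa = 40, n_samples = 4,
                    depth = 300, selection_strength = 1e-4,
                    tail_taxa = 0L, seed = 21)
  d <- simulate_dataset(sp, tree = tr, traits = traits)
  rel <- relative_abundance(d$counts)
  # every sample collapses onto the lineage whose niche sits at the optimum:
  # dominant taxa are variants of one radiation, so phylogenetic turnover
  # between samples vanishes even where the exact variant differs
  lin <- attr(tr, "lineage")
  dom <- apply(rel, 2, which.max)
  expect_equal(length(unique(lin[rownames(rel)[dom]])), 1L)
  expect_gt(max(rel[, 1]), 0.9)
  bm <- bmntd_all(d$counts[rowSums(d$counts) > 0, ], tr)
  expect_lt(max(bm[upper.tri(bm)]), 0.1)
  # drift with zero generations: iid multinomial draws from the shared pool
  sp0 <- regime_spec("drift", n_taxa = 40, n_samples = 5, depth = 300,
                     n_generations = 0L, seed = 22)
  d0 <- simulate_dataset(sp0, tree = tr, traits = traits)
  expect_true(all(colSums(d0$counts) == 300))
  expect_gt(mean(colSums(d0$counts > 0)), 15)  # broad support, no lottery
})

test_that("homogenizing dispersal is more homogeneous than limited dispersal", {
  tr <- simulate_phylogeny(80, seed = 8)
  traits <- niche_positions(tr, seed = 9)
  diffs <- vapply(1:5, function(s) {
    hom <- simulate_dataset(regime_spec("homogenizing_dispersal", n_taxa = 80,
                                        n_samples = 10, depth = 500,
                                        seed = 30 + s), tr, traits)$counts
    lim <- simulate_dataset(regime_spec("dispersal_limitation", n_taxa = 80,
                                        n_samples = 10, depth = 500,
                                        seed = 60 + s), tr, traits)$counts
    mean(vegan::vegdist(t(hom), "bray")) - mean(vegan::vegdist(t(lim), "bray"))
  }, numeric(1))
  expect_true(all(diffs < 0))
})

test_that("gene content is clade-conserved and aggregates multiplicatively", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.1):0.9,(c:0.1,d:0.1):0.9);")
  sims <- vapply(1:40, function(s) {
    gc <- simulate_gene_content(tr, n_genes = 30, n_predatory = 5,
                                conservatism = 4, seed = 100 + s)
    gm <- gc$gene_matrix
    jac <- function(x, y) sum(x & y) / max(1, sum(x | y))
    jac(gm[, "a"], gm[, "b"]) - jac(gm[, "a"], gm[, "c"])
  }, numeric(1))
  expect_gt(mean(sims), 0)   # sisters share more genes than distant tips

  gc <- simulate_gene_content(tr, n_genes = 10, n_predatory = 2, seed = 1)
  expect_equal(sum(gc$predatory), 2L)
  counts <- matrix(c(3L, 1L, 0L, 2L, 5L, 0L, 1L, 1L), 4, 2,
                   dimnames = list(c("a", "b", "c", "d"), c("s1", "s2")))
  gt <- gene_table(gc, counts)
  expect_equal(unname(gt[, "s1"]),
               as.vector(gc$gene_matrix %*% counts[, "s1"]))
})

test_that("the regime suite has nested metadata and shared dimensions", {
  suite <- simulate_regime_suite(seed = 13, n_taxa = 60, n_samples = 4,
                                 depth = 300)
  expect_equal(ncol(suite$counts), 20L)
  expect_equal(sort(unique(suite$metadata$empo_3)), sort(process_levels()))
  n2 <- tapply(suite$metadata$empo_2, suite$metadata$empo_3,
               function(x) length(unique(x)))
  expect_true(all(n2 == 1L))
  expect_true(all(colSums(suite$counts) == 300))
})

test_that("Wright-Fisher drift preserves frequencies in expectation", {
  f <- c(0.5, 0.3, 0.2)
  reps <- vapply(1:200, function(s)
    wright_fisher_drift(f, n_generations = 5, community_size = 500, seed = s),
    numeric(3))
  expect_equal(rowMeans(reps), f, tolerance = 0.05)
  expect_identical(wright_fisher_drift(f, 5, 500, seed = 3),
                   wright_fisher_drift(f, 5, 500, seed = 3))
})
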