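test_that("core membership applies both strict thresholds exactly", {
  # taxon at 50% abundance in all samples: core
  m <- matrix(c(500, 500, 500, 500,
                495, 495, 495, 495,
                5, 5, 5, 5), 3, 4, byrow = TRUE,
              dimnames = list(c("big", "mid", "small"), paste0("s", 1:4)))
  core <- find_core(m)
  expect_true("big" %in% core$observation_id)

  # occurrence exactly 0.5 is NOT core (strictly more than half required)
  m2 <- matrix(c(10, 10, 0, 0,
                 90, 90, 100, 100), 2, 4, byrow = TRUE,
               dimnames = list(c("half", "filler"), paste0("s", 1:4)))
  expect_false("half" %in% find_core(m2)$observation_id)

  # mean relative abundance exactly 0.1% is NOT core
  m3 <- matrix(c(1, 1, 1, 1,
                 999, 999, 999, 999), 2, 4, byrow = TRUE,
               dimnames = list(c("thin", "filler"), paste0("s", 1:4)))
  stats3 <- attr(find_core(m3), "all_taxa")
  expect_equal(unname(stats3$mean_rel_abundance[stats3$observation_id == "thin"]), 0.001)
  expect_false("thin" %in% find_core(m3)$observation_id)

  # printed toy: {0.2%, 0.2%, 0, 0.2%} -> core; {0.5%, 0, 0, 0} -> not
  m4 <- matrix(c(2, 2, 0, 2,
                 5, 0, 0, 0,
                 993, 998, 1000, 998), 3, 4, byrow = TRUE,
               dimnames = list(c("patchy", "rareburst", "filler"),
                               paste0("s", 1:4)))
  core4 <- find_core(m4)
  st4 <- attr(core4, "all_taxa")
  expect_equal(unname(st4$occurrence[st4$observation_id == "patchy"]), 0.75)
  expect_equal(unname(st4$mean_rel_abundance[st4$observation_id == "patchy"]), 0.0015)
  expect_true("patchy" %in% core4$observation_id)
  expect_false("rareburst" %in% core4$observation_id)
})

test_that("core detection is monotone in both thresholds", {
  set.seed(12)
  m <- matrix(rpois(40 * 8, 3), 40, 8,
              dimnames = list(paste0("t", 1:40), paste0("s", 1:8)))
  base <- find_core(m, 0.4, 0.005)$observation_id
  stricter_occ <- find_core(m, 0.6, 0.005)$observation_id
  stricter_ab <- find_core(m, 0.4, 0.02)$observation_id
  expect_true(all(stricter_occ %in% base))
  expect_true(all(stricter_ab %in% base))
})

test_that("core specificity counts environments per core taxon", {
  cs <- list(
    A = tibble::tibble(observation_id = c("x", "y")),
    B = tibble::tibble(observation_id = c("y", "z")),
    C = tibble::tibble(observation_id = c("y"))
  )
  hist_tbl <- core_specificity(cs)
  per <- attr(hist_tbl, "per_taxon")
  expect_equal(per$n_environments[per$observation_id == "y"], 3L)
  expect_equal(sum(hist_tbl$n_taxa), 3L)  # union of core sets
  expect_equal(hist_tbl$n_taxa[hist_tbl$n_environments == 1], 2L)
})

test_that("alpha diversity matches closed forms", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  m <- matrix(c(25, 25, 25, 25), 4, 1, dimnames = list(letters[1:4], "s1"))
  ad <- alpha_diversity(m, tr)
  expect_equal(ad$shannon, log(4), tolerance = 1e-12)
  expect_equal(ad$observed, 4)
  expect_equal(ad$chao1, 4, tolerance = 1e-12)      # no singletons/doubletons
  expect_equal(ad$faith_pd, sum(tr$edge.length), tolerance = 1e-12)

  # chao1 with singletons/doubletons: S + F1(F1-1)/(2(F2+1))
  m2 <- matrix(c(1, 1, 1, 2, 2, 10), 6, 1,
               dimnames = list(paste0("t", 1:6), "s1"))
  tr6 <- ape::rphylo(6, 1, 0); tr6$tip.label <- paste0("t", 1:6)
  ad2 <- alpha_diversity(m2, tr6)
  expect_equal(ad2$chao1, 6 + 3 * 2 / (2 * 3), tolerance = 1e-12)
  expect_gte(ad2$chao1, ad2$observed)
  expect_lte(ad2$shannon, log(ad2$observed))
  # faith_pd requires a tree
  expect_false("faith_pd" %in% names(alpha_diversity(m2)))
})

test_that("networks recover planted correlated pairs with few false edges", {
  sim <- simulate_correlated_table(n_noise = 200, n_pairs = 20, n_samples = 30,
                                   seed = 17)
  net <- build_network(sim$counts, top_n = nrow(sim$counts))
  edges <- tidy(net)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  planted <- key(sim$pairs$taxon_a, sim$pairs$taxon_b)
  found <- key(edges$taxon_a, edges$taxon_b)
  expect_gte(sum(planted %in% found), 18)
  n_tested <- choose(net$features$n_nodes, 2)
  false_edges <- sum(!found %in% planted)
  expect_lt(false_edges / n_tested, 0.02)
  expect_true(all(abs(edges$rho) > 0.5 & edges$p < 0.05))
  gl <- glance(net)
  expect_equal(gl$n_edges, nrow(edges))
})

test_that("network edges are rank-based and handle degenerate taxa", {
  set.seed(3)
  m <- matrix(rpois(20 * 10, 5) + 1, 20, 10,
              dimnames = list(paste0("t", 1:20), paste0("s", 1:10)))
  m[1, ] <- 1:10 * 3           # identical rank order with t2
  m[2, ] <- (1:10)^2
  m[3, ] <- 7                   # constant -> no edges
  m[20, ] <- m[20, ] + (max(colSums(m)) - colSums(m))  # equalize depths
  expect_message(net <- build_network(m, top_n = 20, rho_min = 0.5),
                 "constant")
  edges <- tidy(net)
  expect_true(any(edges$taxon_a == "t1" & edges$taxon_b == "t2" |
                  edges$taxon_a == "t2" & edges$taxon_b == "t1"))
  expect_false(any(edges$taxon_a == "t3" | edges$taxon_b == "t3"))
  # permuting sample order leaves the edge set unchanged
  net2 <- suppressMessages(build_network(m[, sample(10)], top_n = 20))
  expect_setequal(paste(edges$taxon_a, edges$taxon_b),
                  paste(tidy(net2)$taxon_a, tidy(net2)$taxon_b))
  expect_error(build_network(m[, 1:3]), "at least 4")
})

test_that("profile clustering produces a valid average-linkage dendrogram", {
  prof <- rbind(A = c(1, 0, 0, 0, 0),
                B = c(0, 1, 0, 0, 0),
                C = c(0.98, 0.02, 0, 0, 0))
  colnames(prof) <- process_levels()
  cl <- cluster_environments(prof)
  expect_equal(sort(cl$hclust$height)[1],
               as.numeric(vegan::vegdist(prof, "bray")[2]), tolerance = 1e-12)
  # A and C (near-identical) merge first; B joins at height ~ 1
  first_pair <- rownames(prof)[abs(cl$hclust$merge[1, ])]
  expect_setequal(first_pair, c("A", "C"))
  expect_false(is.unsorted(cl$hclust$height))   # ultrametric merge heights
  expect_match(cl$newick, "^\\(")
  # identical profiles merge at height zero
  cl0 <- cluster_environments(rbind(A = prof[1, ], B = prof[1, ]))
  expect_equal(cl0$hclust$height, 0)
})

test_that("determinism correlations behave at the rank extremes", {
  det <- tibble::tibble(group = letters[1:6],
                        mean = c(0.1, 0.3, 0.4, 0.55, 0.7, 0.9))
  up <- setNames(det$mean, det$group)
  expect_equal(correlate_determinism(det, up, factor_name = "same")$spearman_rho, 1)
  expect_equal(correlate_determinism(det, rev(up) * -1 + 1,
                                     factor_name = "rev")$spearman_rho, -1)
  ex <- correlate_determinism(det, up, exclude = "a", factor_name = "x")
  expect_equal(ex$n, 5L)
  expect_equal(ex$excluded, "a")
  expect_error(correlate_determinism(det[1:2, ], up[1:2]), "fewer than 3")
})

test_that("planted monotone factors are detected across seeds", {
  ok <- vapply(1:5, function(s) {
    set.seed(s)
    det <- tibble::tibble(group = paste0("e", 1:16),
                          mean = seq(0.1, 0.9, length.out = 16))
    noisy <- setNames(det$mean * 100 + rnorm(16, 0, 8), det$group)
    res <- correlate_determinism(det, noisy, factor_name = "alpha")
    res$spearman_rho > 0.6 && res$p_value < 0.05
  }, logical(1))
  expect_true(all(ok))
})

test_that("gene-set relative abundance sums and averages correctly", {
  g <- matrix(c(10, 10, 0, 0,
                30, 10, 50, 10,
                60, 80, 50, 90), 3, 4, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  all_set <- predatory_gene_abundance(g, c("g1", "g2", "g3"))
  expect_equal(all_set$rel_abundance, rep(1, 4))
  one <- predatory_gene_abundance(g, "g1")
  expect_equal(one$rel_abundance, c(0.1, 0.1, 0, 0))
  expect_warning(predatory_gene_abundance(g, c("g1", "nope")), "missing")
  expect_error(predatory_gene_abundance(g, "nope"), "none")

  md <- tibble::tibble(sample_id = paste0("s", 1:4),
                       empo_3 = c("A", "A", "B", "B"))
  withmd <- suppressWarnings(predatory_gene_abundance(g, "g1", metadata = md))
  env <- attr(withmd, "by_environment")
  expect_equal(env$rel_abundance[env$environment == "A"], 0.1)

  # planted 5% predatory reads come back at ~5%
  tr <- simulate_phylogeny(40, seed = 2)
  gc <- simulate_gene_content(tr, n_genes = 100, n_predatory = 5, seed = 3)
  counts <- simulate_dataset(regime_spec("drift", n_taxa = 40, n_samples = 6,
                                         depth = 2000, seed = 4), tr,
                             niche_positions(tr, 5))$counts
  gt <- gene_table(gc, counts)
  pg <- predatory_gene_abundance(gt, gc$gene_ids[gc$predatory])
  expect_equal(mean(pg$rel_abundance), 0.05, tolerance = 0.04)
})
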