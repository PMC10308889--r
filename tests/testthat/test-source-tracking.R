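test_that("a sink identical to its single source is attributed to it", {
  set.seed(1)
  S <- 60
  ids <- paste0("t", 1:S)
  src_prof <- as.vector(rmultinom(1, 5000, exp(rnorm(S, 0, 1))))
  props <- vapply(1:3, function(s) {
    sink <- setNames(as.vector(rmultinom(1, 1000, src_prof / sum(src_prof))), ids)
    sources <- matrix(src_prof, S, 1, dimnames = list(ids, "envA"))
    est <- estimate_sources(sink, sources,
                            st_params(alpha_unknown = 1e-4), seed = 40 + s)
    est$proportion[est$source == "envA"]
  }, numeric(1))
  expect_true(all(props > 0.9))
})

test_that("novel-taxa sinks are attributed to Unknown", {
  set.seed(2)
  ids <- paste0("t", 1:40)
  sources <- matrix(rpois(40 * 2, 50), 40, 2,
                    dimnames = list(ids, c("envA", "envB")))
  sink <- setNames(rep(0L, 40), ids)
  novel <- setNames(as.vector(rmultinom(1, 1000, rep(1, 10))), paste0("x", 1:10))
  est <- estimate_sources(c(sink, novel)[c(paste0("x", 1:10))], sources,
                          seed = 7)
  expect_gt(est$proportion[est$source == "Unknown"], 0.9)
  expect_equal(sum(est$proportion), 1, tolerance = 1e-9)
})

test_that("planted two-source mixtures are recovered within 0.10", {
  set.seed(3)
  S <- 80
  ids <- paste0("t", 1:S)
  pa <- exp(rnorm(S, 0, 1.5)); pa <- pa / sum(pa)
  pb <- exp(rnorm(S, 0, 1.5)); pb <- pb / sum(pb)
  errs <- vapply(1:3, function(s) {
    srcA <- as.vector(rmultinom(1, 5000, pa))
    srcB <- as.vector(rmultinom(1, 5000, pb))
    sink <- setNames(as.vector(rmultinom(1, 2000, 0.7 * pa + 0.3 * pb)), ids)
    sources <- matrix(c(srcA, srcB), S, 2, dimnames = list(ids, c("A", "B")))
    est <- estimate_sources(sink, sources, st_params(sink_depth = 2000),
                            seed = 50 + s)
    abs(est$proportion[est$source == "A"] - 0.7)
  }, numeric(1))
  expect_true(all(errs < 0.10))
})

test_that("proportions are invariant to relabeling and source-depth scaling", {
  set.seed(4)
  S <- 50
  ids <- paste0("t", 1:S)
  pa <- exp(rnorm(S)); pa <- pa / sum(pa)
  pb <- exp(rnorm(S)); pb <- pb / sum(pb)
  sources <- matrix(c(rmultinom(1, 4000, pa), rmultinom(1, 4000, pb)), S, 2,
                    dimnames = list(ids, c("A", "B")))
  sink <- setNames(as.vector(rmultinom(1, 1500, 0.5 * pa + 0.5 * pb)), ids)
  base <- estimate_sources(sink, sources, seed = 9)
  # relabel taxa (same permutation of sink and sources)
  perm <- sample(S)
  ids2 <- paste0("r", 1:S)
  sources2 <- sources[perm, ]; rownames(sources2) <- ids2
  sink2 <- setNames(sink[perm], ids2)
  rel <- estimate_sources(sink2, sources2, seed = 9)
  expect_equal(rel$proportion, base$proportion, tolerance = 0.06)
  # scale all source depths 3x
  scl <- estimate_sources(sink, sources * 3, seed = 9)
  expect_equal(scl$proportion, base$proportion, tolerance = 0.06)
})

test_that("a huge beta prior forces proportions toward uniform", {
  set.seed(5)
  S <- 40
  ids <- paste0("t", 1:S)
  pa <- exp(rnorm(S)); pa <- pa / sum(pa)
  sources <- matrix(c(rmultinom(1, 4000, pa), rmultinom(1, 4000, rev(pa))),
                    S, 2, dimnames = list(ids, c("A", "B")))
  sink <- setNames(as.vector(rmultinom(1, 1000, pa)), ids)
  sharp <- estimate_sources(sink, sources, st_params(beta = 10), seed = 3)
  flat <- estimate_sources(sink, sources, st_params(beta = 1e6), seed = 3)
  dev <- function(p) max(abs(p - 1 / 3))
  expect_lt(dev(flat$proportion), dev(sharp$proportion))
})

test_that("track_all returns a row-normalized sink x source matrix", {
  set.seed(6)
  S <- 50
  ids <- paste0("t", 1:S)
  # three environments, two sharing a pool and one disjoint
  shared <- exp(rnorm(S)); shared[26:50] <- 0
  other <- exp(rnorm(S)); other[1:25] <- 0
  mk <- function(p, n) vapply(seq_len(n), function(i)
    as.vector(rmultinom(1, 800, p / sum(p))), numeric(S))
  counts <- cbind(mk(shared, 3), mk(shared, 3), mk(other, 3))
  dimnames(counts) <- list(ids, paste0("s", 1:9))
  md <- tibble::tibble(sample_id = paste0("s", 1:9),
                       empo_3 = rep(c("A", "B", "C"), each = 3))
  tracked <- track_all(counts, md, params = st_params(n_restarts = 4), seed = 2)
  sm <- source_matrix(tracked)
  expect_equal(unname(rowSums(sm)), rep(1, 3), tolerance = 1e-9)
  expect_equal(colnames(sm)[ncol(sm)], "Unknown")
  # B is resampled from A's pool: A must be B's top known source
  expect_equal(names(which.max(sm["B", setdiff(colnames(sm), "Unknown")])), "A")
  # C's taxa are disjoint from A and B: known-source proportions near zero
  expect_gt(sm["C", "Unknown"], 0.8)
})
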