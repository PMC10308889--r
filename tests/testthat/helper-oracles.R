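# Independent oracles, coded without reference to the package implementation.

# brute-force bMNTD: scan every taxon of one side for its nearest relative on
# the other, using a patristic matrix computed here from the tree
oracle_bmntd <- function(a, b, tree, weighted = TRUE) {
  D <- ape::cophenetic.phylo(tree)
  ia <- names(a)[a > 0]
  ib <- names(b)[b > 0]
  fa <- if (weighted) a[ia] / sum(a[ia]) else rep(1 / length(ia), length(ia))
  fb <- if (weighted) b[ib] / sum(b[ib]) else rep(1 / length(ib), length(ib))
  da <- vapply(ia, function(i) min(D[i, ib]), numeric(1))
  db <- vapply(ib, function(j) min(D[j, ia]), numeric(1))
  0.5 * (sum(fa * da) + sum(fb * db))
}

# all permutations of 1..n (recursive; fine for n <= 7)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# exhaustive null moments of bMNTD under tip-label permutation of the pool
oracle_null_moments <- function(a, b, tree, pool) {
  D <- ape::cophenetic.phylo(tree)[pool, pool]
  perms <- all_perms(length(pool))
  av <- a[pool]; bv <- b[pool]
  vals <- apply(perms, 1L, function(p) {
    Dp <- D[p, p, drop = FALSE]
    dimnames(Dp) <- list(pool, pool)
    ia <- pool[av > 0]; ib <- pool[bv > 0]
    fa <- av[av > 0] / sum(av[av > 0])
    fb <- bv[bv > 0] / sum(bv[bv > 0])
    da <- vapply(ia, function(i) min(Dp[i, ib]), numeric(1))
    db <- vapply(ib, function(j) min(Dp[j, ia]), numeric(1))
    0.5 * (sum(fa * da) + sum(fb * db))
  })
  list(mean = mean(vals), sd = sd(vals), values = vals)
}

# small fixed fixtures
toy_tree <- function() ape::read.tree(text = "((a:1,b:1):1,c:2);")

toy_counts <- function() {
  m <- matrix(c(5L, 0L, 3L, 2L, 0L, 1L), nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  m
}
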