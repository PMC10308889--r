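#' Beta mean nearest-taxon distance between two communities
#'
#' For each taxon present in one community, the patristic distance to its
#' nearest relative present in the other community is found; bMNTD is the
#' average of these nearest-taxon distances over both directions, weighted by
#' relative abundance (`weighted = TRUE`) or equally over present taxa.
#'
#' @param a,b named non-negative abundance vectors (names are taxon ids).
#' @param tree rooted [ape::phylo] containing every present taxon.
#' @param weighted abundance-weighted (default) or presence-based.
#' @return non-negative scalar in branch-length units; 0 iff every taxon of
#'   each community is present in the other.
#' @export
bmntd <- function(a, b, tree, weighted = TRUE) {
  if (all(a <= 0) || all(b <= 0))
    stop("bmntd is undefined for an empty community", call. = FALSE)
  taxa <- union(names(a)[a > 0], names(b)[b > 0])
  missing_tips <- setdiff(taxa, tree$tip.label)
  if (length(missing_tips))
    stop("taxa missing from tree: ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  sub <- if (length(taxa) < length(tree$tip.label)) ape::keep.tip(tree, taxa) else tree
  D <- ape::cophenetic.phylo(sub)
  comm <- matrix(0, length(taxa), 2L, dimnames = list(rownames(D), c("a", "b")))
  comm[names(a)[a > 0][names(a)[a > 0] %in% rownames(D)], 1L] <- a[a > 0][names(a)[a > 0] %in% rownames(D)]
  comm[names(b)[b > 0][names(b)[b > 0] %in% rownames(D)], 2L] <- b[b > 0][names(b)[b > 0] %in% rownames(D)]
  bmntd_pairs_cpp(D, comm, matrix(0:1, 1L), weighted, seq_len(nrow(D)) - 1L)[1L]
}

#' bMNTD for all sample pairs of a community matrix
#'
#' @param comm taxa x samples matrix (rownames = taxon ids).
#' @param tree rooted [ape::phylo] covering all taxa of `comm`.
#' @param weighted abundance-weighted (default) or presence-based.
#' @return a `dist`-like symmetric matrix of bMNTD values.
#' @export
bmntd_all <- function(comm, tree, weighted = TRUE) {
  al <- align_table_tree(comm, tree)
  D <- ape::cophenetic.phylo(al$tree)
  comm <- al$counts[rownames(D), , drop = FALSE]
  ns <- ncol(comm)
  pairs <- t(combn(ns, 2L)) - 1L
  v <- bmntd_pairs_cpp(D, comm, pairs, weighted, seq_len(nrow(D)) - 1L)
  out <- matrix(0, ns, ns, dimnames = list(colnames(comm), colnames(comm)))
  out[lower.tri(out)] <- NA
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L] + 1L; j <- pairs[k, 2L] + 1L
    out[i, j] <- out[j, i] <- v[k]
  }
  out
}

#' Beta nearest-taxon index for one sample pair
#'
#' Standardized deviation of the observed bMNTD from a null distribution in
#' which tip labels are randomly permuted among the taxa of the regional pool
#' (abundances ride with the labels): `(obs - mean(null)) / sd(null)`.
#' Values below -2 indicate less phylogenetic turnover than expected
#' (homogeneous selection), above +2 more (heterogeneous selection).
#'
#' @param a,b named abundance vectors.
#' @param tree rooted [ape::phylo].
#' @param regional_pool character vector of pool taxon ids (must contain all
#'   present taxa); defaults to the union of the pair.
#' @param n_null number of label permutations (>= 99).
#' @param seed integer seed.
#' @param weighted abundance-weighted bMNTD (default).
#' @return scalar bNTI; `NaN`-free — a degenerate null (sd 0) returns `NA`
#'   with attribute `degenerate = TRUE`.
#' @export
bnti <- function(a, b, tree, regional_pool = NULL, n_null = 999L, seed = 1L,
                 weighted = TRUE) {
  if (n_null < 99L) stop("n_null must be at least 99", call. = FALSE)
  pool <- regional_pool %||% union(names(a)[a > 0], names(b)[b > 0])
  present <- union(names(a)[a > 0], names(b)[b > 0])
  if (!all(present %in% pool))
    stop("regional pool must contain all present taxa", call. = FALSE)
  comm <- matrix(0, length(pool), 2L, dimnames = list(pool, c("a", "b")))
  comm[names(a)[a > 0], 1L] <- a[a > 0]
  comm[names(b)[b > 0], 2L] <- b[b > 0]
  res <- bnti_pairs(comm, tree, n_null = n_null, seed = seed, weighted = weighted)
  out <- res$bnti[1L]
  if (res$degenerate[1L]) {
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' bNTI for all sample pairs of a community matrix, with shared nulls
#'
#' Computes observed bMNTD for all pairs plus `n_null` tip-label permutations
#' of the pooled taxa. One shared set of permutations is reused for every pair
#' (the standard economy for this framework); per-pair nulls are available by
#' calling [bnti()] pairwise.
#'
#' @param comm taxa x samples matrix; its rownames define the regional pool.
#' @param tree rooted [ape::phylo].
#' @param n_null permutations (>= 99).
#' @param seed integer seed.
#' @param weighted abundance-weighted bMNTD (default).
#' @return tibble with `sample_a`, `sample_b`, `bmntd_obs`, `null_mean`,
#'   `null_sd`, `bnti`, `degenerate` (logical; null sd of 0).
#' @export
bnti_pairs <- function(comm, tree, n_null = 999L, seed = 1L, weighted = TRUE) {
  if (n_null < 99L) stop("n_null must be at least 99", call. = FALSE)
  al <- align_table_tree(comm, tree)
  if (nrow(al$counts) < nrow(comm))
    stop("taxa missing from tree: ",
         paste(head(setdiff(rownames(comm), tree$tip.label)), collapse = ", "),
         call. = FALSE)
  D <- ape::cophenetic.phylo(al$tree)
  comm <- al$counts[rownames(D), , drop = FALSE]
  S <- nrow(comm)
  ns <- ncol(comm)
  pairs <- t(combn(ns, 2L)) - 1L
  perms <- withr::with_seed(seed,
    vapply(seq_len(n_null), function(r) sample.int(S) - 1L, integer(S)))
  all_vals <- bmntd_null_matrix_cpp(D, comm, pairs, weighted,
                                    matrix(perms, nrow = S))
  obs <- all_vals[, 1L]
  nulls <- all_vals[, -1L, drop = FALSE]
  nm <- rowMeans(nulls)
  nsd <- apply(nulls, 1L, sd)
  degenerate <- nsd == 0
  z <- (obs - nm) / ifelse(degenerate, NA_real_, nsd)
  tibble(
    sample_a = colnames(comm)[pairs[, 1L] + 1L],
    sample_b = colnames(comm)[pairs[, 2L] + 1L],
    bmntd_obs = obs,
    null_mean = nm,
    null_sd = nsd,
    bnti = z,
    degenerate = degenerate
  )
}
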