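#' Bray-Curtis dissimilarity between two count vectors
#' @param x,y non-negative numeric vectors of equal length.
#' @return scalar in \[0, 1\]: `1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))`.
#' @export
bray_curtis <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

## assemble one null community: draw `richness` taxa without replacement with
## probability proportional to occupancy, then distribute `reads` over the
## drawn taxa with probability proportional to pool relative abundance
assemble_null <- function(richness, reads, occupancy, pool_abund) {
  S <- length(occupancy)
  if (richness > S)
    stop("observed richness exceeds regional pool size", call. = FALSE)
  idx <- sample.int(S, richness, prob = occupancy)
  cnt <- numeric(S)
  cnt[idx] <- as.vector(rmultinom(1, reads, pool_abund[idx]))
  cnt
}

#' Raup-Crick index on Bray-Curtis for one sample pair
#'
#' Each null replicate reassembles both communities from the regional pool:
#' the observed richness of each sample is drawn without replacement with
#' probability proportional to pool occupancy, and its observed read total is
#' then distributed over the drawn taxa with probability proportional to pool
#' relative abundance. The observed Bray-Curtis is ranked against the null
#' Bray-Curtis values with ties counted at half weight and rescaled to
#' \[-1, 1\]: values above +0.95 mean more turnover than random assembly
#' (dispersal limitation), below -0.95 less (homogenizing dispersal).
#'
#' @param a,b integer count vectors over the pool's taxa (equal length).
#' @param occupancy per-taxon occupancy in the regional pool (fraction of the
#'   pool's samples containing the taxon); defaults to presence in `a`/`b`.
#' @param pool_abund per-taxon pool relative abundance; defaults to
#'   `(a + b)` normalized.
#' @param n_null null replicates (>= 99).
#' @param seed integer seed.
#' @return scalar in \[-1, 1\].
#' @export
rc_bray <- function(a, b, occupancy = NULL, pool_abund = NULL,
                    n_null = 999L, seed = 1L) {
  if (n_null < 99L) stop("n_null must be at least 99", call. = FALSE)
  if (any(abs(c(a, b) - round(c(a, b))) > 1e-8))
    stop("rc_bray requires integer counts", call. = FALSE)
  occupancy <- occupancy %||% (((a > 0) + (b > 0)) / 2)
  pool_abund <- pool_abund %||% ((a + b) / sum(a + b))
  obs <- bray_curtis(a, b)
  withr::with_seed(seed, {
    less <- ties <- 0L
    for (r in seq_len(n_null)) {
      na_ <- assemble_null(sum(a > 0), sum(a), occupancy, pool_abund)
      nb_ <- assemble_null(sum(b > 0), sum(b), occupancy, pool_abund)
      nv <- bray_curtis(na_, nb_)
      if (nv < obs) less <- less + 1L else if (nv == obs) ties <- ties + 1L
    }
    2 * ((less + 0.5 * ties) / n_null) - 1
  })
}

#' RC-bray for all sample pairs of a community matrix, with shared nulls
#'
#' The regional pool (occupancy and relative abundance) is taken from the
#' matrix itself. One set of `n_null` reassemblies per sample is shared across
#' all pairs involving that sample.
#'
#' @param comm taxa x samples integer matrix.
#' @param n_null null replicates (>= 99).
#' @param seed integer seed.
#' @return tibble with `sample_a`, `sample_b`, `rc_bray`.
#' @export
rc_bray_pairs <- function(comm, n_null = 999L, seed = 1L) {
  if (n_null < 99L) stop("n_null must be at least 99", call. = FALSE)
  if (any(abs(comm - round(comm)) > 1e-8))
    stop("rc_bray requires integer counts", call. = FALSE)
  S <- nrow(comm)
  ns <- ncol(comm)
  occupancy <- rowMeans(comm > 0)
  pool_abund <- rowSums(comm) / sum(comm)
  richness <- colSums(comm > 0)
  totals <- colSums(comm)
  withr::with_seed(seed, {
    nullc <- array(0, c(S, ns, n_null))
    for (r in seq_len(n_null)) for (s in seq_len(ns)) {
      nullc[, s, r] <- assemble_null(richness[s], totals[s], occupancy, pool_abund)
    }
    pairs <- t(combn(ns, 2L))
    rc <- vapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      obs <- bray_curtis(comm[, i], comm[, j])
      nv <- vapply(seq_len(n_null), function(r)
        bray_curtis(nullc[, i, r], nullc[, j, r]), numeric(1))
      2 * ((sum(nv < obs) + 0.5 * sum(nv == obs)) / n_null) - 1
    }, numeric(1))
    tibble(sample_a = colnames(comm)[pairs[, 1L]],
           sample_b = colnames(comm)[pairs[, 2L]],
           rc_bray = rc)
  })
}

#' Unweighted Raup-Crick index for one pair of presence/absence vectors
#'
#' Null communities draw each sample's observed richness without replacement
#' with probability proportional to pool occupancy; the comparison metric is
#' the number of shared taxa. The sign convention matches the weighted index:
#' RC above +0.95 means the pair shares fewer taxa than random assembly (more
#' dissimilar; dispersal-limitation analog), below -0.95 more.
#'
#' @param a,b binary (0/1) vectors over the pool's taxa.
#' @param occupancy per-taxon pool occupancy; defaults to `(a + b) / 2`.
#' @param n_null null replicates (>= 99).
#' @param seed integer seed.
#' @return scalar in \[-1, 1\].
#' @export
rc_unweighted <- function(a, b, occupancy = NULL, n_null = 999L, seed = 1L) {
  if (n_null < 99L) stop("n_null must be at least 99", call. = FALSE)
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stop("rc_unweighted requires binary inputs", call. = FALSE)
  occupancy <- occupancy %||% ((a + b) / 2)
  S <- length(a)
  ra <- sum(a); rb <- sum(b)
  if (ra > S || rb > S)
    stop("observed richness exceeds regional pool size", call. = FALSE)
  obs <- sum(a > 0 & b > 0)
  withr::with_seed(seed, {
    more <- ties <- 0L
    for (r in seq_len(n_null)) {
      ia <- sample.int(S, ra, prob = occupancy)
      ib <- sample.int(S, rb, prob = occupancy)
      shared <- length(intersect(ia, ib))
      if (shared > obs) more <- more + 1L else if (shared == obs) ties <- ties + 1L
    }
    2 * ((more + 0.5 * ties) / n_null) - 1
  })
}

#' Unweighted Raup-Crick for all sample pairs, with shared nulls
#'
#' @param comm taxa x samples matrix; values are reduced to presence/absence.
#' @param n_null null replicates (>= 99).
#' @param seed integer seed.
#' @return tibble with `sample_a`, `sample_b`, `rc`.
#' @export
rc_unweighted_pairs <- function(comm, n_null = 999L, seed = 1L) {
  if (n_null < 99L) stop("n_null must be at least 99", call. = FALSE)
  pa <- comm > 0
  S <- nrow(pa)
  ns <- ncol(pa)
  occupancy <- rowMeans(pa)
  richness <- colSums(pa)
  withr::with_seed(seed, {
    nullm <- array(FALSE, c(S, ns, n_null))
    for (r in seq_len(n_null)) for (s in seq_len(ns)) {
      nullm[sample.int(S, richness[s], prob = occupancy), s, r] <- TRUE
    }
    pairs <- t(combn(ns, 2L))
    rc <- vapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      obs <- sum(pa[, i] & pa[, j])
      nv <- colSums(nullm[, i, ] & nullm[, j, ])
      2 * ((sum(nv > obs) + 0.5 * sum(nv == obs)) / n_null) - 1
    }, numeric(1))
    tibble(sample_a = colnames(comm)[pairs[, 1L]],
           sample_b = colnames(comm)[pairs[, 2L]],
           rc = rc)
  })
}
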