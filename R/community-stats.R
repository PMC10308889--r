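#' Core taxa of one environment
#'
#' A taxon is core when it occurs in more than half of the environment's
#' samples (occurrence strictly > 0.5) and its mean relative abundance exceeds
#' 0.1% (strictly > 0.001). Both thresholds are configurable.
#'
#' @param counts taxa x samples matrix restricted to one environment
#'   (>= 2 samples).
#' @param min_occurrence occurrence threshold (strict; default 0.5).
#' @param min_mean_abundance mean relative-abundance threshold (strict;
#'   default 0.001).
#' @return tibble of class `"core_set"` with one row per core taxon:
#'   `observation_id`, `occurrence`, `mean_rel_abundance`; the per-taxon table
#'   for all taxa is in attribute `all_taxa`, and the summed relative
#'   abundance of the core set in attribute `core_abundance`.
#' @export
find_core <- function(counts, min_occurrence = 0.5, min_mean_abundance = 0.001) {
  validate_count_table(counts)
  if (ncol(counts) < 2L) stop("need at least 2 samples", call. = FALSE)
  rel <- relative_abundance(counts)
  stats_tbl <- tibble(
    observation_id = rownames(counts),
    occurrence = rowMeans(counts > 0),
    mean_rel_abundance = rowMeans(rel)
  )
  core <- filter(stats_tbl, .data$occurrence > min_occurrence,
                 .data$mean_rel_abundance > min_mean_abundance)
  attr(core, "all_taxa") <- stats_tbl
  attr(core, "core_abundance") <- sum(core$mean_rel_abundance)
  class(core) <- c("core_set", class(core))
  core
}

#' Environment specificity of core taxa
#'
#' Counts, for every taxon that is core anywhere, the number of environments
#' in which it is core.
#'
#' @param core_sets named list of [find_core()] results (names = environments).
#' @return tibble with `n_environments` and `n_taxa`; per-taxon environment
#'   counts in attribute `per_taxon`.
#' @export
core_specificity <- function(core_sets) {
  if (length(core_sets) < 2L) stop("need at least 2 environments", call. = FALSE)
  ids <- unlist(lapply(core_sets, `[[`, "observation_id"), use.names = FALSE)
  per_taxon <- tibble(observation_id = names(table(ids)),
                      n_environments = as.integer(table(ids)))
  hist_tbl <- per_taxon |>
    dplyr::count(.data$n_environments, name = "n_taxa")
  attr(hist_tbl, "per_taxon") <- per_taxon
  hist_tbl
}

#' Alpha diversity of each sample
#'
#' Observed richness, Shannon entropy (natural log by default), bias-corrected
#' Chao1 `S + F1(F1 - 1) / (2(F2 + 1))` from singleton/doubleton counts, and
#' Faith's phylogenetic diversity (total branch length spanning the present
#' tips, including the path to the root).
#'
#' @param counts taxa x samples matrix (integer counts for Chao1).
#' @param tree optional rooted phylogeny; required for `faith_pd`.
#' @param shannon_base base of the Shannon logarithm (default `exp(1)`).
#' @return tibble with `sample_id`, `observed`, `shannon`, `chao1` and, when a
#'   tree is given, `faith_pd`.
#' @export
alpha_diversity <- function(counts, tree = NULL, shannon_base = exp(1)) {
  validate_count_table(counts)
  if (any(colSums(counts) == 0)) stop("sample with zero total", call. = FALSE)
  observed <- colSums(counts > 0)
  shannon <- vegan::diversity(t(counts), index = "shannon", base = shannon_base)
  f1 <- colSums(counts == 1)
  f2 <- colSums(counts == 2)
  chao1 <- observed + f1 * (f1 - 1) / (2 * (f2 + 1))
  out <- tibble(sample_id = colnames(counts),
                observed = as.numeric(observed),
                shannon = as.numeric(shannon),
                chao1 = as.numeric(chao1))
  if (!is.null(tree)) {
    al <- align_table_tree(counts, tree)
    pd <- picante::pd(t(al$counts), al$tree, include.root = TRUE)
    out$faith_pd <- pd$PD[match(out$sample_id, rownames(pd))]
  }
  out
}

## Spearman correlation matrix with two-sided t-approximation p-values
spearman_matrix <- function(relab) {
  rho <- suppressWarnings(cor(t(relab), method = "spearman"))
  n <- ncol(relab)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  list(rho = rho, p = p)
}

#' Co-occurrence network of an environment's dominant taxa
#'
#' Ranks taxa by total relative abundance, keeps the `top_n` most abundant
#' (ties broken lexicographically by id), computes pairwise Spearman
#' correlations of per-sample relative abundances, and keeps edges with
#' `|rho| > rho_min` and two-sided `p < alpha` (raw, no multiple-testing
#' correction). Constant-abundance taxa yield undefined correlations and
#' receive no edges.
#'
#' @param counts taxa x samples matrix restricted to one environment
#'   (>= 4 samples).
#' @param top_n taxa retained (default 500).
#' @param rho_min absolute Spearman threshold (strict; default 0.5).
#' @param alpha p-value threshold (strict; default 0.05).
#' @return object of class `"cooccurrence_network"`: list with `edges`
#'   (tibble: `taxon_a`, `taxon_b`, `rho`, `p`), `nodes`, and `features`
#'   (n_nodes, n_edges, mean_degree, density, top_abundance_fraction).
#' @export
build_network <- function(counts, top_n = 500L, rho_min = 0.5, alpha = 0.05) {
  validate_count_table(counts)
  if (ncol(counts) < 4L)
    stop("need at least 4 samples for Spearman p-values", call. = FALSE)
  rel <- relative_abundance(counts)
  score <- rowSums(rel)
  ord <- order(-score, rownames(counts))
  keep <- ord[seq_len(min(top_n, nrow(counts)))]
  if (length(keep) < 2L) stop("fewer than 2 taxa retained", call. = FALSE)
  sub <- rel[keep, , drop = FALSE]
  top_fraction <- sum(score[keep]) / sum(score)
  sm <- spearman_matrix(sub)
  constant <- apply(sub, 1L, function(x) length(unique(x)) == 1L)
  if (any(constant))
    message(sum(constant), " constant-abundance taxa excluded from edges")
  adj <- abs(sm$rho) > rho_min & sm$p < alpha
  adj[constant, ] <- FALSE
  adj[, constant] <- FALSE
  adj[is.na(adj)] <- FALSE
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- tibble(taxon_a = rownames(sub)[idx[, 1L]],
                  taxon_b = rownames(sub)[idx[, 2L]],
                  rho = sm$rho[idx],
                  p = sm$p[idx])
  nn <- nrow(sub)
  ne <- nrow(edges)
  features <- list(n_nodes = nn, n_edges = ne,
                   mean_degree = 2 * ne / nn,
                   density = ne / (nn * (nn - 1) / 2),
                   top_abundance_fraction = top_fraction)
  structure(list(edges = edges, nodes = rownames(sub), features = features),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("Co-occurrence network:", x$features$n_nodes, "nodes,",
      x$features$n_edges, "edges (density",
      signif(x$features$density, 3), ")\n")
  invisible(x)
}

#' @describeIn build_network tidy method: the edge list.
#' @param x a `cooccurrence_network`.
#' @param ... unused.
#' @export
tidy.cooccurrence_network <- function(x, ...) x$edges

#' @describeIn build_network glance method: one-row topological features.
#' @export
glance.cooccurrence_network <- function(x, ...) as_tibble(x$features)

#' Hierarchical clustering of assembly-subprocess profiles
#'
#' Bray-Curtis distances between the per-environment five-subprocess fraction
#' vectors, agglomerated with average linkage (UPGMA) and serialized as a
#' newick string with heights.
#'
#' @param profiles environments x processes matrix of fractions (rows sum
#'   to 1), or the `summary` tibble of an [quantify_assembly()] result.
#' @param method linkage (default `"average"`).
#' @return list with `hclust`, `phylo`, `newick`.
#' @export
cluster_environments <- function(profiles, method = "average") {
  if (inherits(profiles, "assembly_profile")) profiles <- profiles$summary
  if (is.data.frame(profiles)) {
    wide <- tidyr::pivot_wider(profiles, id_cols = "group",
                               names_from = "process", values_from = "mean")
    m <- as.matrix(wide[, -1L, drop = FALSE])
    rownames(m) <- wide$group
    profiles <- m
  }
  if (nrow(profiles) < 2L) stop("need at least 2 environments", call. = FALSE)
  d <- vegan::vegdist(profiles, method = "bray")
  hc <- hclust(d, method = method)
  ph <- ape::as.phylo(hc)
  list(hclust = hc, phylo = ph, newick = ape::write.tree(ph))
}

#' Correlate deterministic fractions with a community-internal factor
#'
#' Spearman rank correlation (two-sided, t-approximation with mid-rank ties)
#' between per-environment deterministic-process fractions and a factor such
#' as alpha diversity, network edge count, or the relative abundance of a
#' gene set. Environments can be excluded (recorded in the output).
#'
#' @param profile an `assembly_profile` or a tibble with `group` and a
#'   deterministic-fraction column `mean`.
#' @param factor named numeric vector (names = environment labels).
#' @param exclude environment labels to drop before the test.
#' @param factor_name label recorded in the output.
#' @return one-row tibble of class `"factor_correlation"`: `factor`,
#'   `spearman_rho`, `p_value`, `n`, `excluded`.
#' @export
correlate_determinism <- function(profile, factor, exclude = character(),
                                  factor_name = deparse(substitute(factor))) {
  det <- if (inherits(profile, "assembly_profile")) profile$deterministic
         else profile
  det <- det[!det$group %in% exclude, , drop = FALSE]
  shared <- intersect(det$group, names(factor))
  if (length(shared) < 3L)
    stop("fewer than 3 environments after exclusions", call. = FALSE)
  xv <- det$mean[match(shared, det$group)]
  yv <- factor[shared]
  ct <- suppressWarnings(cor.test(xv, yv, method = "spearman", exact = FALSE))
  tibble(factor = factor_name,
         spearman_rho = unname(ct$estimate),
         p_value = ct$p.value,
         n = length(shared),
         excluded = paste(exclude, collapse = ";"))
}

#' Relative abundance of a gene set per sample
#'
#' Per-sample summed relative abundance of the listed genes (e.g. the
#' predatory-specific set); optionally averaged per environment.
#'
#' @param gene_counts genes x samples matrix.
#' @param gene_set character vector of gene ids (warns on ids missing from
#'   the table; errors when none are present).
#' @param metadata optional tibble with `sample_id` and `level` for
#'   environment means.
#' @param level metadata column for the environment average.
#' @return tibble with `sample_id` and `rel_abundance`; when metadata is
#'   given, attribute `by_environment` holds the per-environment means.
#' @export
predatory_gene_abundance <- function(gene_counts, gene_set, metadata = NULL,
                                     level = "empo_3") {
  if (!length(gene_set)) stop("gene_set is empty", call. = FALSE)
  present <- intersect(gene_set, rownames(gene_counts))
  if (!length(present))
    stop("none of the gene_set ids are in the table", call. = FALSE)
  if (length(present) < length(gene_set))
    warning(length(gene_set) - length(present),
            " gene id(s) missing from the table", call. = FALSE)
  tot <- colSums(gene_counts)
  tot[tot == 0] <- 1
  frac <- colSums(gene_counts[present, , drop = FALSE]) / tot
  out <- tibble(sample_id = colnames(gene_counts),
                rel_abundance = as.numeric(frac))
  if (!is.null(metadata)) {
    env <- metadata[[level]][match(out$sample_id, metadata$sample_id)]
    by_env <- out |>
      mutate(environment = env) |>
      filter(!is.na(.data$environment)) |>
      group_by(.data$environment) |>
      summarise(rel_abundance = mean(.data$rel_abundance), .groups = "drop")
    attr(out, "by_environment") <- by_env
  }
  out
}
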