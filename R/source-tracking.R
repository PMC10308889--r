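#' Parameters for Bayesian source tracking
#'
#' Defaults follow the canonical tool's published configuration.
#'
#' @param alpha_known Dirichlet pseudocount for known sources.
#' @param alpha_unknown pseudocount for the Unknown source.
#' @param beta prior count on the mixing proportions.
#' @param burn_in Gibbs sweeps discarded per restart.
#' @param n_restarts independent restarts averaged.
#' @param n_draws retained sweeps per restart after burn-in.
#' @param sink_depth sink reads are rarefied to at most this many before
#'   sampling (runtime control).
#' @return list of class `"st_params"`.
#' @export
st_params <- function(alpha_known = 0.001, alpha_unknown = 0.1, beta = 10,
                      burn_in = 100L, n_restarts = 10L, n_draws = 1L,
                      sink_depth = 1000L) {
  structure(list(alpha_known = alpha_known, alpha_unknown = alpha_unknown,
                 beta = beta, burn_in = as.integer(burn_in),
                 n_restarts = as.integer(n_restarts),
                 n_draws = as.integer(n_draws),
                 sink_depth = as.integer(sink_depth)),
            class = "st_params")
}

#' Estimate mixing proportions of a sink community over source environments
#'
#' Collapsed Gibbs sampler over per-read source assignments. Each sink read of
#' taxon t is assigned to a source environment v with probability proportional
#' to `theta_vt * (n_v + beta)`, where `theta_vt` combines the source's
#' training counts, the current sink assignments and a Dirichlet pseudocount
#' (`alpha_known` for the trained sources, `alpha_unknown` for the reserved
#' "Unknown" source, which has no training counts). Proportions are the
#' posterior mean occupancy of each source over retained draws and restarts.
#'
#' @param sink named integer count vector.
#' @param sources taxa x sources count matrix; rownames must cover the sink's
#'   taxa ids (missing taxa are treated as zero-count rows).
#' @param params an [st_params()].
#' @param seed integer seed.
#' @return tibble with `source` (including `"Unknown"`) and `proportion`
#'   summing to 1; diagnostics in attributes `n_reads`, `params`.
#' @export
estimate_sources <- function(sink, sources, params = st_params(), seed = 1L) {
  if (sum(sink) < 1) stop("sink has no reads", call. = FALSE)
  if (is.null(dim(sources)) || ncol(sources) < 1L)
    stop("need at least one source profile", call. = FALSE)
  if (is.null(names(sink)) || is.null(rownames(sources)))
    stop("sink and sources must carry taxon ids", call. = FALSE)
  taxa <- union(names(sink), rownames(sources))
  m <- matrix(0, length(taxa), ncol(sources),
              dimnames = list(taxa, colnames(sources)))
  m[rownames(sources), ] <- sources
  x <- stats::setNames(numeric(length(taxa)), taxa)
  x[names(sink)] <- sink
  x <- round(x)
  withr::with_seed(seed, {
    if (sum(x) > params$sink_depth) {
      x <- suppressWarnings(
        as.vector(t(vegan::rrarefy(t(matrix(x)), params$sink_depth))))
      names(x) <- taxa
    }
    reads <- rep.int(seq_along(taxa), x) - 1L
    props <- gibbs_sources_cpp(as.integer(reads), m,
                               params$alpha_known, params$alpha_unknown,
                               params$beta, params$burn_in,
                               params$n_restarts, params$n_draws)
  })
  out <- tibble(source = c(colnames(sources), "Unknown"),
                proportion = as.numeric(props))
  attr(out, "n_reads") <- sum(x)
  attr(out, "params") <- params
  out
}

#' Source-track every environment against all others
#'
#' Leave-one-environment-out: for each environment, the sink is the
#' environment's aggregated counts (or each sample separately, averaged) and
#' the sources are the per-environment aggregated profiles of all other
#' environments.
#'
#' @param counts taxa x samples matrix.
#' @param metadata tibble with `sample_id` and the environment column.
#' @param level environment column (default `"empo_3"`).
#' @param params an [st_params()].
#' @param seed integer seed.
#' @param sink_mode `"aggregate"` (default) or `"per_sample"` (average of
#'   per-sample estimates).
#' @return tibble with `sink`, `source`, `proportion`; proportions sum to 1
#'   within each sink.
#' @export
track_all <- function(counts, metadata, level = "empo_3",
                      params = st_params(), seed = 1L,
                      sink_mode = c("aggregate", "per_sample")) {
  sink_mode <- match.arg(sink_mode)
  metadata <- metadata[metadata$sample_id %in% colnames(counts), , drop = FALSE]
  envs <- unique(metadata[[level]])
  if (length(envs) < 2L) stop("need at least 2 environments", call. = FALSE)
  env_of <- stats::setNames(metadata[[level]], metadata$sample_id)
  agg <- vapply(envs, function(e) {
    ids <- names(env_of)[env_of == e]
    rowSums(counts[, ids, drop = FALSE])
  }, numeric(nrow(counts)))
  rownames(agg) <- rownames(counts)
  rows <- list()
  for (ei in seq_along(envs)) {
    e <- envs[ei]
    sources <- agg[, setdiff(envs, e), drop = FALSE]
    if (sink_mode == "aggregate") {
      est <- estimate_sources(agg[, e], sources, params, seed = seed + ei)
    } else {
      ids <- names(env_of)[env_of == e]
      ests <- lapply(seq_along(ids), function(si)
        estimate_sources(counts[, ids[si]], sources, params,
                         seed = seed + ei * 1000L + si))
      est <- ests[[1L]]
      est$proportion <- rowMeans(vapply(ests, `[[`, numeric(nrow(est)),
                                        "proportion"))
    }
    rows[[ei]] <- mutate(est, sink = e, .before = 1L)
  }
  bind_rows(rows)
}

#' Source proportions as a sink-by-source matrix
#' @param tracked tibble from [track_all()].
#' @return matrix with sinks as rows; `"Unknown"` is the last column.
#' @export
source_matrix <- function(tracked) {
  wide <- tidyr::pivot_wider(tracked, id_cols = "sink", names_from = "source",
                             values_from = "proportion", values_fill = 0)
  m <- as.matrix(wide[, -1L, drop = FALSE])
  rownames(m) <- wide$sink
  ord <- c(setdiff(colnames(m), "Unknown"), "Unknown")
  m[, ord, drop = FALSE]
}

#' Heatmap of source-tracking proportions
#' @param object tibble from [track_all()].
#' @param ... unused.
#' @export
plot_source_matrix <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$source, y = .data$sink,
                                       fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "source environment", y = "sink environment",
                  fill = "proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
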