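#' Subsampling plan for assembly-process quantification
#'
#' The null-model analysis runs on random subgroups of samples rather than the
#' whole dataset: a subgroup's taxa form the regional pool, all its sample
#' pairs are classified, and fractions are averaged over subgroups.
#'
#' @param n_subgroups random subgroups drawn per group (default 50).
#' @param subgroup_size samples per subgroup (default 40; >= 3).
#' @param depth rarefaction depth applied within subgroups (default 5000).
#' @param n_null null randomizations per subgroup (default 999; >= 99).
#' @param seed master seed; child seeds are `seed + subgroup index`.
#' @return list of class `"subsampling_plan"`.
#' @export
subsampling_plan <- function(n_subgroups = 50L, subgroup_size = 40L,
                             depth = 5000L, n_null = 999L, seed = 1L) {
  stopifnot(subgroup_size >= 3L, n_null >= 99L, n_subgroups >= 1L)
  structure(list(n_subgroups = as.integer(n_subgroups),
                 subgroup_size = as.integer(subgroup_size),
                 depth = as.integer(depth),
                 n_null = as.integer(n_null),
                 seed = as.integer(seed)),
            class = "subsampling_plan")
}

## per-subgroup process fractions from a classified pair table
process_fractions <- function(process) {
  tab <- table(factor(process, levels = process_levels()))
  as.numeric(tab) / length(process)
}

#' Quantify assembly processes per environment group
#'
#' For each level of the grouping column, draws `n_subgroups` random subgroups
#' of `subgroup_size` samples, computes abundance-weighted bMNTD/bNTI
#' (tip-shuffling null over the subgroup's pooled taxa) and RC-bray
#' (richness- and abundance-constrained assembly null) for every sample pair,
#' classifies each pair into one of the five subprocesses, and reports the
#' mean and SD of the per-subgroup process fractions.
#'
#' @param counts taxa x samples count matrix (rarefied or rarefiable to
#'   `plan$depth`).
#' @param tree rooted phylogeny covering the table's taxa.
#' @param metadata tibble with `sample_id` and the grouping column.
#' @param group_by metadata column defining groups (default `"empo_3"`).
#' @param plan a [subsampling_plan()].
#' @param groups optional subset of group levels to analyse.
#' @param keep_pairs keep the pair-level records (default TRUE).
#' @return an object of class `"assembly_profile"`: a list with `summary`
#'   (group x process mean/sd fractions), `deterministic` (per group),
#'   `subgroups` (per-subgroup fractions), `pairs` (pair-level records if
#'   kept) and `plan`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
quantify_assembly <- function(counts, tree, metadata, group_by = "empo_3",
                              plan = subsampling_plan(), groups = NULL,
                              keep_pairs = TRUE) {
  validate_count_table(counts)
  if (!group_by %in% colnames(metadata))
    stop("metadata lacks grouping column '", group_by, "'", call. = FALSE)
  metadata <- metadata[metadata$sample_id %in% colnames(counts), , drop = FALSE]
  levels_all <- unique(metadata[[group_by]])
  groups <- groups %||% levels_all
  subgroup_rows <- list()
  pair_rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    ids <- metadata$sample_id[metadata[[group_by]] == g]
    if (length(ids) < 3L)
      stop("group '", g, "' has fewer than 3 samples", call. = FALSE)
    size <- plan$subgroup_size
    if (length(ids) < size) {
      warning("group '", g, "' has ", length(ids), " samples; lowering ",
              "subgroup size from ", size, call. = FALSE)
      size <- length(ids)
    }
    for (k in seq_len(plan$n_subgroups)) {
      seed_k <- plan$seed + (gi - 1L) * plan$n_subgroups + k
      chosen <- withr::with_seed(seed_k, sample(ids, size))
      sub <- counts[, chosen, drop = FALSE]
      if (any(colSums(sub) != plan$depth)) {
        sub <- rarefy_counts(sub, plan$depth, seed = seed_k)
      }
      sub <- sub[rowSums(sub) > 0, , drop = FALSE]   # regional pool
      bn <- bnti_pairs(sub, tree, n_null = plan$n_null, seed = seed_k)
      rc <- rc_bray_pairs(sub, n_null = plan$n_null, seed = seed_k + 500000L)
      stopifnot(identical(bn$sample_a, rc$sample_a))
      process <- classify_pair(bn$bnti, rc$rc_bray)
      fr <- process_fractions(process)
      subgroup_rows[[length(subgroup_rows) + 1L]] <- tibble(
        group = g, subgroup = k, process = process_levels(), fraction = fr)
      if (keep_pairs) {
        pair_rows[[length(pair_rows) + 1L]] <- tibble(
          group = g, subgroup = k,
          sample_a = bn$sample_a, sample_b = bn$sample_b,
          bmntd_obs = bn$bmntd_obs, bnti = bn$bnti,
          degenerate = bn$degenerate,
          rc_bray = rc$rc_bray, process = process)
      }
    }
  }
  subgroups <- bind_rows(subgroup_rows)
  summary <- subgroups |>
    group_by(.data$group, .data$process) |>
    summarise(mean = mean(.data$fraction), sd = sd(.data$fraction),
              .groups = "drop") |>
    mutate(process = factor(.data$process, levels = process_levels())) |>
    arrange(.data$group, .data$process)
  deterministic <- subgroups |>
    group_by(.data$group, .data$subgroup) |>
    summarise(det = sum(.data$fraction[is_deterministic(.data$process)]),
              .groups = "drop") |>
    group_by(.data$group) |>
    summarise(mean = mean(.data$det), sd = sd(.data$det), .groups = "drop")
  structure(list(summary = summary,
                 deterministic = deterministic,
                 subgroups = subgroups,
                 pairs = if (keep_pairs) bind_rows(pair_rows) else NULL,
                 group_by = group_by,
                 plan = plan),
            class = "assembly_profile")
}

#' @export
print.assembly_profile <- function(x, ...) {
  cat("Assembly profile over", length(unique(x$summary$group)), "group(s);",
      x$plan$n_subgroups, "subgroups x", x$plan$subgroup_size, "samples,",
      x$plan$n_null, "randomizations\n")
  det <- x$deterministic
  for (i in seq_len(nrow(det))) {
    cat(sprintf("  %-28s deterministic %5.1f%% +/- %4.1f%%\n",
                det$group[i], 100 * det$mean[i], 100 * det$sd[i]))
  }
  invisible(x)
}

#' @describeIn quantify_assembly tidy method: per-group process fractions.
#' @param x an `assembly_profile`.
#' @param ... unused.
#' @export
tidy.assembly_profile <- function(x, ...) x$summary

#' @describeIn quantify_assembly glance method: per-group deterministic
#'   fraction with the modal process.
#' @export
glance.assembly_profile <- function(x, ...) {
  modal <- x$summary |>
    group_by(.data$group) |>
    summarise(modal_process = .data$process[which.max(.data$mean)],
              .groups = "drop")
  left_join(x$deterministic, modal, by = "group") |>
    dplyr::rename(deterministic_mean = "mean", deterministic_sd = "sd")
}

#' @describeIn quantify_assembly stacked-bar plot of mean process fractions.
#' @param object an `assembly_profile`.
#' @export
autoplot.assembly_profile <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$group, y = .data$mean,
                               fill = .data$process)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "subprocess") +
    ggplot2::labs(x = NULL, y = "mean fraction of sample pairs") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}

#' Deterministic vs stochastic fractions of gene assembly
#'
#' Same subgrouping as [quantify_assembly()], but on a gene-by-sample table
#' and without a phylogeny: a pair is deterministic when |RC| > 0.95, with RC
#' from the unweighted (shared-gene-count) or weighted (Bray-Curtis)
#' Raup-Crick null.
#'
#' @param gene_counts genes x samples matrix (non-integer profiles are rounded
#'   for the weighted mode).
#' @param metadata tibble with `sample_id` and the grouping column.
#' @param group_by metadata column defining groups.
#' @param plan a [subsampling_plan()]; `depth` is ignored (gene tables are
#'   aggregates, not rarefied reads).
#' @param mode `"unweighted"` (default) or `"weighted"`.
#' @param groups optional subset of group levels.
#' @return tibble with per-group `deterministic_mean`, `deterministic_sd`,
#'   `stochastic_mean`, `stochastic_sd`, `n_subgroups`, `subgroup_size`.
#' @export
gene_assembly_fractions <- function(gene_counts, metadata, group_by = "empo_3",
                                    plan = subsampling_plan(),
                                    mode = c("unweighted", "weighted"),
                                    groups = NULL) {
  mode <- match.arg(mode)
  validate_count_table(gene_counts)
  metadata <- metadata[metadata$sample_id %in% colnames(gene_counts), , drop = FALSE]
  groups <- groups %||% unique(metadata[[group_by]])
  rows <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    ids <- metadata$sample_id[metadata[[group_by]] == g]
    if (length(ids) < 3L)
      stop("group '", g, "' has fewer than 3 samples", call. = FALSE)
    size <- min(plan$subgroup_size, length(ids))
    det <- vapply(seq_len(plan$n_subgroups), function(k) {
      seed_k <- plan$seed + (gi - 1L) * plan$n_subgroups + k
      chosen <- withr::with_seed(seed_k, sample(ids, size))
      sub <- gene_counts[, chosen, drop = FALSE]
      sub <- sub[rowSums(sub) > 0, , drop = FALSE]
      rc <- if (mode == "unweighted") {
        rc_unweighted_pairs(sub, n_null = plan$n_null, seed = seed_k)$rc
      } else {
        rc_bray_pairs(round(sub), n_null = plan$n_null, seed = seed_k)$rc_bray
      }
      mean(abs(rc) > 0.95)
    }, numeric(1))
    rows[[gi]] <- tibble(group = g,
                         deterministic_mean = mean(det),
                         deterministic_sd = sd(det),
                         stochastic_mean = mean(1 - det),
                         stochastic_sd = sd(1 - det),
                         n_subgroups = plan$n_subgroups,
                         subgroup_size = size)
  }
  bind_rows(rows)
}
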