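#' Configuration of a full pipeline run
#'
#' Either paths to real inputs (`table`, `tree`, `mapping`, optional
#' `gene_table`) or a simulation block must be present. Can be written to /
#' read from YAML.
#'
#' @param out_dir output directory.
#' @param seed master seed (required; every stochastic stage derives from it).
#' @param table,tree,mapping,gene_table_path input file paths (real-data mode).
#' @param simulate list of arguments for [simulate_regime_suite()]
#'   (simulation mode); `NULL` disables simulation.
#' @param plan a [subsampling_plan()].
#' @param st an [st_params()].
#' @param network list with `top_n`, `rho_min`, `alpha`.
#' @param genes list with `n_genes`, `n_predatory`, `conservatism` for the
#'   synthetic gene tables (simulation mode).
#' @return list of class `"run_config"`.
#' @export
run_config <- function(out_dir, seed,
                       table = NULL, tree = NULL, mapping = NULL,
                       gene_table_path = NULL,
                       simulate = list(n_taxa = 200L, n_samples = 40L,
                                       depth = 5000L),
                       plan = subsampling_plan(),
                       st = st_params(),
                       network = list(top_n = 500L, rho_min = 0.5, alpha = 0.05),
                       genes = list(n_genes = 120L, n_predatory = 12L,
                                    conservatism = 4)) {
  if (is.null(simulate) && (is.null(table) || is.null(tree) || is.null(mapping)))
    stop("config needs either input paths or a simulation block", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 table = table, tree = tree, mapping = mapping,
                 gene_table_path = gene_table_path,
                 simulate = simulate, plan = plan, st = st,
                 network = network, genes = genes),
            class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(out_dir = y$out_dir, seed = y$seed,
             table = y$table, tree = y$tree, mapping = y$mapping,
             gene_table_path = y$gene_table_path,
             simulate = y$simulate,
             plan = do.call(subsampling_plan, y$plan %||% list()),
             st = do.call(st_params, y$st %||% list()),
             network = y$network %||% list(top_n = 500L, rho_min = 0.5,
                                           alpha = 0.05),
             genes = y$genes %||% list(n_genes = 120L, n_predatory = 12L,
                                       conservatism = 4))
}

write_tsv_det <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full assembly-analysis pipeline
#'
#' Simulates (or loads) the dataset, quantifies assembly processes per
#' environment, runs gene assembly, source tracking, core detection,
#' co-occurrence networks, profile clustering and factor correlations, and
#' writes every artifact plus a machine-readable manifest and a markdown
#' report into `config$out_dir`. Byte-identical outputs for identical
#' (config, seed).
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return named list of artifact paths, invisibly; the in-memory results are
#'   returned in attribute `results`.
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  results <- list()
  stage_files <- character()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      for (f in stage_files) {
        if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
      }
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- function(name) {
    p <- file.path(config$out_dir, name)
    stage_files <<- c(stage_files, p)
    p
  }

  ## -- data ------------------------------------------------------------
  run_stage("data", {
    if (!is.null(config$simulate)) {
      sim <- do.call(simulate_regime_suite,
                     c(list(seed = config$seed), config$simulate))
      counts <- sim$counts; tree <- sim$tree; metadata <- sim$metadata
      gc <- withr::with_seed(config$seed + 71L,
        simulate_gene_content(tree, n_genes = config$genes$n_genes,
                              n_predatory = config$genes$n_predatory,
                              conservatism = config$genes$conservatism,
                              seed = config$seed + 71L))
      genes <- gene_table(gc, counts)
      predatory_ids <- gc$gene_ids[gc$predatory]
    } else {
      counts <- read_count_table(config$table)
      tree <- read_tree(config$tree)
      metadata <- read_sample_metadata(config$mapping)
      al <- align_table_tree(counts, tree)
      counts <- al$counts; tree <- al$tree
      genes <- if (!is.null(config$gene_table_path))
        read_count_table(config$gene_table_path) else NULL
      predatory_ids <- character()
    }
    stage_files <- character()
    paths$table <- write_tsv_det(
      data.frame(`#OTU ID` = rownames(counts), counts, check.names = FALSE),
      out("table.tsv"))
    ape::write.tree(tree, out("tree.nwk"))
    paths$tree <- file.path(config$out_dir, "tree.nwk")
    paths$mapping <- write_tsv_det(metadata, out("mapping.tsv"))
    if (!is.null(genes)) {
      paths$gene_table <- write_tsv_det(
        data.frame(`#GENE ID` = rownames(genes), genes, check.names = FALSE),
        out("gene_table.tsv"))
    }
    results$counts <- counts; results$tree <- tree
    results$metadata <- metadata; results$genes <- genes
    results$predatory_ids <- predatory_ids
  })

  ## -- assembly --------------------------------------------------------
  run_stage("assembly", {
    stage_files <- character()
    prof <- quantify_assembly(results$counts, results$tree, results$metadata,
                              group_by = "empo_3", plan = config$plan)
    results$profile <- prof
    paths$profile <- write_tsv_det(tidy(prof), out("profile.tsv"))
    paths$pairs <- write_tsv_det(prof$pairs, out("pairs.tsv"))
  })

  ## -- gene assembly ---------------------------------------------------
  if (!is.null(results$genes)) run_stage("gene_assembly", {
    stage_files <- character()
    gplan <- config$plan
    ga <- gene_assembly_fractions(results$genes, results$metadata,
                                  group_by = "empo_3", plan = gplan,
                                  mode = "unweighted")
    results$gene_assembly <- ga
    paths$gene_assembly <- write_tsv_det(ga, out("gene_assembly.tsv"))
  })

  ## -- source tracking -------------------------------------------------
  run_stage("source_tracking", {
    stage_files <- character()
    tracked <- track_all(results$counts, results$metadata, level = "empo_3",
                         params = config$st, seed = config$seed + 17L)
    results$sources <- tracked
    sm <- source_matrix(tracked)
    paths$sources <- write_tsv_det(
      data.frame(sink = rownames(sm), sm, check.names = FALSE),
      out("sources.tsv"))
  })

  ## -- core taxa -------------------------------------------------------
  run_stage("core", {
    stage_files <- character()
    envs <- unique(results$metadata$empo_3)
    cores <- lapply(envs, function(e) {
      ids <- results$metadata$sample_id[results$metadata$empo_3 == e]
      find_core(results$counts[, ids, drop = FALSE])
    })
    names(cores) <- envs
    results$cores <- cores
    core_tbl <- bind_rows(lapply(envs, function(e)
      mutate(as_tibble(cores[[e]]), environment = e, .before = 1L)))
    paths$core <- write_tsv_det(core_tbl, out("core.tsv"))
    results$core_specificity <- core_specificity(cores)
  })

  ## -- networks --------------------------------------------------------
  run_stage("network", {
    stage_files <- character()
    envs <- unique(results$metadata$empo_3)
    nets <- lapply(envs, function(e) {
      ids <- results$metadata$sample_id[results$metadata$empo_3 == e]
      build_network(results$counts[, ids, drop = FALSE],
                    top_n = config$network$top_n,
                    rho_min = config$network$rho_min,
                    alpha = config$network$alpha)
    })
    names(nets) <- envs
    results$networks <- nets
    edges <- bind_rows(lapply(envs, function(e)
      mutate(nets[[e]]$edges, environment = e, .before = 1L)))
    paths$edges <- write_tsv_det(edges, out("network_edges.tsv"))
    feats <- lapply(nets, `[[`, "features")
    jsonlite::write_json(feats, out("network_features.json"),
                         auto_unbox = TRUE, digits = NA)
    paths$network_features <- file.path(config$out_dir, "network_features.json")
  })

  ## -- clustering ------------------------------------------------------
  run_stage("cluster", {
    stage_files <- character()
    if (length(unique(results$profile$summary$group)) >= 2L) {
      cl <- cluster_environments(results$profile)
      results$dendrogram <- cl
      writeLines(cl$newick, out("dendrogram.nwk"))
      paths$dendrogram <- file.path(config$out_dir, "dendrogram.nwk")
    }
  })

  ## -- correlations ----------------------------------------------------
  run_stage("correlate", {
    stage_files <- character()
    md <- results$metadata
    adiv <- alpha_diversity(results$counts, results$tree)
    env_of <- stats::setNames(md$empo_3, md$sample_id)
    env_mean <- function(v) tapply(v, env_of[adiv$sample_id], mean)
    corrs <- bind_rows(
      correlate_determinism(results$profile, env_mean(adiv$observed),
                            factor_name = "observed"),
      correlate_determinism(results$profile, env_mean(adiv$shannon),
                            factor_name = "shannon"),
      correlate_determinism(results$profile, env_mean(adiv$chao1),
                            factor_name = "chao1"),
      correlate_determinism(results$profile, env_mean(adiv$faith_pd),
                            factor_name = "faith_pd"),
      correlate_determinism(
        results$profile,
        vapply(results$networks, function(n) n$features$n_edges, numeric(1)),
        factor_name = "network_edges")
    )
    if (length(results$predatory_ids)) {
      pg <- predatory_gene_abundance(results$genes, results$predatory_ids,
                                     metadata = md)
      by_env <- attr(pg, "by_environment")
      corrs <- bind_rows(corrs, correlate_determinism(
        results$profile,
        stats::setNames(by_env$rel_abundance, by_env$environment),
        factor_name = "predatory_genes"))
    }
    results$correlations <- corrs
    paths$correlations <- write_tsv_det(corrs, out("correlations.tsv"))
  })

  ## -- manifest + report ----------------------------------------------
  run_stage("manifest", {
    stage_files <- character()
    manifest <- list(
      seed = config$seed,
      config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
      package_version = as.character(utils::packageVersion("ecoassembly")),
      plan = unclass(config$plan),
      st = unclass(config$st),
      artifacts = vapply(paths, basename, character(1))
    )
    jsonlite::write_json(manifest, out("manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    paths$manifest <- file.path(config$out_dir, "manifest.json")
    paths$report <- make_report(config$out_dir)
  })

  attr(paths, "results") <- results
  invisible(paths)
}

#' Render a human-readable summary of a pipeline run
#'
#' Re-reads the artifacts of [run_full()] and writes `report.md` with process
#' fractions (2 decimals, +/- SD), the source matrix, core-set sizes and the
#' factor correlations. Regenerating from the same artifacts is byte-identical.
#'
#' @param out_dir pipeline output directory.
#' @return the report path, invisibly.
#' @export
make_report <- function(out_dir) {
  need <- c("profile.tsv", "sources.tsv", "core.tsv", "correlations.tsv")
  missing_files <- need[!file.exists(file.path(out_dir, need))]
  if (length(missing_files))
    stop("missing pipeline outputs: ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  prof <- utils::read.table(file.path(out_dir, "profile.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  src <- utils::read.table(file.path(out_dir, "sources.tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  core <- utils::read.table(file.path(out_dir, "core.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE)
  corrs <- utils::read.table(file.path(out_dir, "correlations.tsv"),
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  lines <- c("# Assembly analysis report", "",
             "## Process fractions per environment", "")
  for (g in unique(prof$group)) {
    lines <- c(lines, paste0("### ", g), "")
    pg <- prof[prof$group == g, ]
    lines <- c(lines, sprintf("- %s: %.2f +/- %.2f", pg$process, pg$mean, pg$sd),
               "")
  }
  lines <- c(lines, "## Source tracking (rows = sinks)", "",
             paste0("| sink | ", paste(colnames(src)[-1L], collapse = " | "),
                    " |"),
             paste0("|", paste(rep("---", ncol(src)), collapse = "|"), "|"))
  for (i in seq_len(nrow(src))) {
    lines <- c(lines, paste0("| ", src$sink[i], " | ",
                             paste(sprintf("%.2f", as.numeric(src[i, -1L])),
                                   collapse = " | "), " |"))
  }
  core_counts <- table(core$environment)
  lines <- c(lines, "", "## Core taxa", "",
             sprintf("- %s: %d core taxa", names(core_counts),
                     as.integer(core_counts)), "")
  edge_file <- file.path(out_dir, "network_features.json")
  if (file.exists(edge_file)) {
    feats <- jsonlite::read_json(edge_file)
    lines <- c(lines, "## Networks", "",
               vapply(names(feats), function(e)
                 sprintf("- %s: %d edges over %d nodes", e,
                         as.integer(feats[[e]]$n_edges),
                         as.integer(feats[[e]]$n_nodes)), character(1)), "")
  }
  lines <- c(lines, "## Correlations with deterministic fraction", "",
             sprintf("- %s: Spearman rho = %.2f (p = %.3g, n = %d)",
                     corrs$factor, corrs$spearman_rho, corrs$p_value, corrs$n))
  report_path <- file.path(out_dir, "report.md")
  writeLines(lines, report_path)
  invisible(report_path)
}
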