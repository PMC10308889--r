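#' Construct and validate a count table
#'
#' A count table is the package's universal abundance container: a numeric
#' matrix of non-negative values with observations (ASVs or genes) as rows and
#' samples as columns, both uniquely named.
#'
#' @param counts numeric matrix, observations x samples, non-negative.
#' @param observation_ids,sample_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return a validated numeric matrix with class kept as plain matrix; ids are
#'   stored in dimnames.
#' @export
count_table <- function(counts, observation_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.null(observation_ids)) rownames(counts) <- observation_ids
  if (!is.null(sample_ids)) colnames(counts) <- sample_ids
  validate_count_table(counts)
  counts
}

validate_count_table <- function(counts) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("count table must have observation and sample ids (dimnames)", call. = FALSE)
  if (nrow(counts) < 1L || ncol(counts) < 1L)
    stop("count table needs at least one observation and one sample", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate observation ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(counts) || any(counts < 0))
    stop("count table values must be non-negative and non-missing", call. = FALSE)
  invisible(counts)
}

#' Read a count table from TSV or BIOM (v1 JSON)
#'
#' The TSV dialect has observations as rows, the first column holding
#' observation ids and the header row holding sample ids. The BIOM dialect is
#' the JSON (format version 1) specification, dense or sparse.
#'
#' @param path file path.
#' @param format `"tsv"` or `"biom-json"`; `"auto"` guesses from the file
#'   extension (`.biom`/`.json` vs anything else).
#' @return observations x samples numeric matrix.
#' @export
read_count_table <- function(path, format = c("auto", "tsv", "biom-json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(biom|json)$", path, ignore.case = TRUE)) "biom-json" else "tsv"
  }
  if (format == "tsv") read_count_tsv(path) else read_count_biom(path)
}

read_count_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", quote = "", stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("malformed TSV count table (need id column + >= 1 sample): ", path,
         call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate observation id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1)))[1L]
    stop("non-numeric counts in column '", colnames(df)[-1L][bad], "' of ", path,
         call. = FALSE)
  }
  rownames(m) <- ids
  count_table(m)
}

read_count_biom <- function(path) {
  b <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = TRUE)
  need <- c("rows", "columns", "data", "matrix_type", "shape")
  if (!all(need %in% names(b)))
    stop("not a BIOM v1 JSON file (missing field ",
         paste(setdiff(need, names(b)), collapse = ", "), "): ", path, call. = FALSE)
  obs <- b$rows$id
  smp <- b$columns$id
  m <- matrix(0, length(obs), length(smp), dimnames = list(obs, smp))
  if (identical(b$matrix_type, "dense")) {
    dat <- b$data
    if (is.list(dat)) dat <- do.call(rbind, dat)
    m[, ] <- dat
  } else {
    dat <- b$data
    if (is.list(dat)) dat <- do.call(rbind, dat)
    # sparse triples are 0-indexed [row, col, value]
    m[cbind(dat[, 1L] + 1L, dat[, 2L] + 1L)] <- dat[, 3L]
  }
  count_table(m)
}

#' Write a count table
#'
#' @param counts observations x samples matrix.
#' @param path output path.
#' @param format `"tsv"` (default) or `"biom-json"`.
#' @param id_header header of the observation-id column in the TSV dialect.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path, format = c("tsv", "biom-json"),
                              id_header = "#OTU ID") {
  format <- match.arg(format)
  validate_count_table(counts)
  if (format == "tsv") {
    df <- data.frame(id = rownames(counts), counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- id_header
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    b <- list(
      id = NULL, format = "Biological Observation Matrix 1.0.0",
      format_url = "http://biom-format.org",
      type = "OTU table", generated_by = "ecoassembly",
      date = "1970-01-01T00:00:00",
      rows = data.frame(id = rownames(counts), metadata = NA),
      columns = data.frame(id = colnames(counts), metadata = NA),
      matrix_type = "dense", matrix_element_type = "float",
      shape = dim(counts),
      data = unname(apply(counts, 1L, function(r) unname(r), simplify = FALSE))
    )
    jsonlite::write_json(b, path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Read a rooted phylogeny from newick
#'
#' @param path newick file; every edge must carry a branch length.
#' @return an [ape::phylo] object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick: ", path, call. = FALSE)
  validate_tree(tr)
  tr
}

validate_tree <- function(tr) {
  if (is.null(tr$edge.length) ||
      (length(tr$tip.label) > 1L && length(tr$edge.length) < nrow(tr$edge)))
    stop("tree is missing branch lengths (no silent zero-fill)", call. = FALSE)
  if (anyNA(tr$edge.length) || any(tr$edge.length < 0))
    stop("tree has missing or negative branch lengths", call. = FALSE)
  if (anyDuplicated(tr$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  invisible(tr)
}

#' Read a sample metadata mapping file
#'
#' A TSV with one row per sample. The environment ontology columns are nested
#' three-level labels; their file column names are configurable because they
#' vary between releases of the major surveys.
#'
#' @param path TSV path.
#' @param column_map named character vector mapping the canonical names
#'   `sample_id`, `empo_1`, `empo_2`, `empo_3` to the file's column names.
#' @return a tibble with canonical column names first, extra columns retained.
#' @export
read_sample_metadata <- function(path,
                                 column_map = c(sample_id = "sample_id",
                                                empo_1 = "empo_1",
                                                empo_2 = "empo_2",
                                                empo_3 = "empo_3")) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          comment.char = "", quote = "", stringsAsFactors = FALSE)
  missing_cols <- setdiff(unname(column_map), colnames(df))
  if (length(missing_cols))
    stop("mapping file lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  out <- df
  for (canon in names(column_map)) {
    names(out)[names(out) == column_map[[canon]]] <- canon
  }
  if (anyDuplicated(out$sample_id))
    stop("duplicate sample_id in mapping file", call. = FALSE)
  # nesting: each empo_3 maps to exactly one empo_2, each empo_2 to one empo_1
  n3 <- tapply(out$empo_2, out$empo_3, function(x) length(unique(x)))
  n2 <- tapply(out$empo_1, out$empo_2, function(x) length(unique(x)))
  if (any(n3 > 1L) || any(n2 > 1L))
    stop("environment ontology labels are not nested", call. = FALSE)
  as_tibble(out)
}

#' Write a sample metadata mapping file
#' @param metadata tibble/data frame with a `sample_id` column.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rarefy a count table to even depth
#'
#' Subsamples each sample without replacement to exactly `depth` reads
#' (multivariate hypergeometric); samples with fewer than `depth` reads are
#' dropped with a warning.
#'
#' @param counts observations x samples integer matrix.
#' @param depth target reads per sample (> 0).
#' @param seed integer seed; rarefaction is the pipeline's first stochastic
#'   step and the seed is required for reproducibility.
#' @return rarefied matrix; every column sums to `depth`.
#' @export
rarefy_counts <- function(counts, depth, seed) {
  validate_count_table(counts)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("rarefaction requires integer counts", call. = FALSE)
  keep <- colSums(counts) >= depth
  if (!any(keep)) stop("no sample reaches depth ", depth, call. = FALSE)
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(counts)[!keep], collapse = ", "), call. = FALSE)
  m <- counts[, keep, drop = FALSE]
  out <- withr::with_seed(seed, t(vegan::rrarefy(t(m), depth)))
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(m)
  out
}

#' Align a count table and a phylogeny to their shared taxa
#'
#' @param counts observations x samples matrix.
#' @param tree rooted [ape::phylo] with tip labels matching observation ids.
#' @return list with elements `counts` (pruned, original row order preserved)
#'   and `tree` (pruned).
#' @export
align_table_tree <- function(counts, tree) {
  validate_count_table(counts)
  shared <- intersect(rownames(counts), tree$tip.label)
  if (!length(shared))
    stop("count table and tree share no taxa", call. = FALSE)
  counts2 <- counts[rownames(counts) %in% shared, , drop = FALSE]
  tree2 <- if (length(shared) == length(tree$tip.label)) tree else
    ape::keep.tip(tree, shared)
  list(counts = counts2, tree = tree2)
}

#' Relative-abundance view of a count table
#' @param counts observations x samples matrix.
#' @return matrix whose positive columns each sum to 1.
#' @export
relative_abundance <- function(counts) {
  cs <- colSums(counts)
  cs[cs == 0] <- 1
  sweep(counts, 2L, cs, "/")
}
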