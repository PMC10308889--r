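test_that("TSV count tables round-trip losslessly and validate ids", {
  m <- toy_counts()
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(m, tf)
  back <- read_count_table(tf)
  expect_identical(rownames(back), rownames(m))
  expect_identical(colnames(back), colnames(m))
  expect_equal(unname(back), unname(m), ignore_attr = TRUE)
  expect_equal(colSums(back), c(s1 = 8, s2 = 3))

  writeLines(c("#OTU ID\ts1\ts2", "a\t1\t2", "a\t3\t4"), tf)
  expect_error(read_count_table(tf), "duplicate")
})

test_that("BIOM v1 JSON tables round-trip, dense and sparse", {
  m <- toy_counts()
  tf <- withr::local_tempfile(fileext = ".biom")
  write_count_table(m, tf, format = "biom-json")
  back <- read_count_table(tf)
  expect_equal(back[rownames(m), colnames(m)], m, ignore_attr = TRUE)

  sparse <- list(
    id = NULL, format = "Biological Observation Matrix 1.0.0",
    format_url = "http://biom-format.org", type = "OTU table",
    generated_by = "x", date = "now",
    rows = data.frame(id = rownames(m)), columns = data.frame(id = colnames(m)),
    matrix_type = "sparse", matrix_element_type = "int", shape = dim(m),
    data = {
      idx <- which(m > 0, arr.ind = TRUE)
      lapply(seq_len(nrow(idx)), function(k)
        c(idx[k, 1] - 1L, idx[k, 2] - 1L, m[idx[k, 1], idx[k, 2]]))
    })
  jsonlite::write_json(sparse, tf, auto_unbox = TRUE)
  back2 <- read_count_table(tf, format = "biom-json")
  expect_equal(back2[rownames(m), colnames(m)], m, ignore_attr = TRUE)
})

test_that("trees are validated on read", {
  tf <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1):1,C:2);", tf)
  tr <- read_tree(tf)
  D <- ape::cophenetic.phylo(tr)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)

  writeLines("(A:1);", tf)
  expect_equal(length(read_tree(tf)$tip.label), 1L)

  writeLines("((A:1,B:1),C:2);", tf)   # missing a branch length
  expect_error(read_tree(tf), "branch length")

  writeLines("((A:1,A:1):1,C:2);", tf)
  expect_error(read_tree(tf), "duplicate")
})

test_that("sample metadata readers enforce nesting and accept column maps", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  md <- data.frame(`#SampleID` = c("x", "y"), level1 = "free-living",
                   level2 = "non-saline", level3 = c("soil", "water"),
                   ph = c(6, 7), check.names = FALSE)
  utils::write.table(md, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_sample_metadata(tf, column_map = c(sample_id = "#SampleID",
                                                 empo_1 = "level1",
                                                 empo_2 = "level2",
                                                 empo_3 = "level3"))
  expect_named(got, c("sample_id", "empo_1", "empo_2", "empo_3", "ph"))

  md$level1 <- c("free-living", "host-associated")   # breaks nesting via level2
  utils::write.table(md, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(
    read_sample_metadata(tf, column_map = c(sample_id = "#SampleID",
                                            empo_1 = "level1", empo_2 = "level2",
                                            empo_3 = "level3")),
    "nested")
})

test_that("rarefaction hits depth exactly, preserves support, is seeded", {
  set.seed(9)
  m <- matrix(rpois(60, 40), 6, 10,
              dimnames = list(paste0("t", 1:6), paste0("s", 1:10)))
  r1 <- rarefy_counts(m, 100, seed = 5)
  expect_true(all(colSums(r1) == 100))
  expect_true(all(m[r1 > 0] > 0))
  r2 <- rarefy_counts(m, 100, seed = 5)
  expect_identical(r1, r2)

  one <- matrix(10L, 1, 1, dimnames = list("t1", "s1"))
  expect_equal(as.vector(rarefy_counts(one, 5, seed = 1)), 5L)

  m[, 1] <- 0L
  expect_warning(r3 <- rarefy_counts(m, 100, seed = 1), "dropped")
  expect_equal(ncol(r3), 9L)
  expect_error(rarefy_counts(m, 0, seed = 1), "positive")
})

test_that("table/tree alignment prunes to the shared taxa", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  m <- matrix(1L, 3, 2, dimnames = list(c("A", "B", "X"), c("s1", "s2")))
  al <- align_table_tree(m, tr)
  expect_setequal(rownames(al$counts), c("A", "B"))
  expect_setequal(al$tree$tip.label, c("A", "B"))
  expect_identical(rownames(al$counts), c("A", "B"))  # table order preserved

  m2 <- m[1:2, ]
  tr2 <- ape::keep.tip(tr, c("A", "B"))
  al2 <- align_table_tree(m2, tr2)
  expect_identical(al2$counts, m2)

  m3 <- matrix(1L, 1, 1, dimnames = list("Z", "s1"))
  expect_error(align_table_tree(m3, tr), "no taxa")
})
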