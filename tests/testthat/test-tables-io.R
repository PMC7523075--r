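test_that("write/read round-trip preserves counts and labels", {
  t <- tiny_design_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(t, path)
  t2 <- read_otu_table(path)
  expect_identical(unname(t2$counts), unname(t$counts))
  expect_identical(rownames(t2$counts), rownames(t$counts))
  expect_identical(colnames(t2$counts), colnames(t$counts))
  expect_equal(t2$metadata, t$metadata)
})

test_that("TSV reader normalizes orientation and validates cells", {
  t <- tiny_design_table()
  path <- withr::local_tempfile(fileext = ".tsv")
  # write transposed (samples as rows)
  df <- data.frame(sample_id = colnames(t$counts), t(t$counts),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  t2 <- read_otu_table(path)
  expect_identical(dim(t2$counts), dim(t$counts))
  expect_identical(t2$counts, t$counts)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu\ts1\ts2", "Otu1\t5\t2", "Otu2\t-3\t1"), bad)
  expect_error(read_otu_table(bad), "Otu2")
})

test_that("per-sample totals from a toy file match hand sums", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("otu\ts1\ts2", "Otu1\t3\t0", "Otu2\t1\t1", "Otu3\t0\t2"), path)
  t <- read_otu_table(path)
  expect_equal(unname(colSums(t$counts)), c(4, 3))
})

test_that("mothur shared and BIOM v1 dialects are readable", {
  shared <- withr::local_tempfile(fileext = ".shared")
  writeLines(c("label\tGroup\tnumOtus\tOtu1\tOtu2",
               "0.03\tC1aS\t2\t7\t3",
               "0.03\tC1aR\t2\t1\t9"), shared)
  t <- read_otu_table(shared, dialect = "mothur-shared")
  expect_equal(unname(t$counts["Otu1", ]), c(7, 1))
  expect_equal(t$metadata$compartment, c("rhizosphere", "root"))

  biom <- withr::local_tempfile(fileext = ".biom")
  writeLines(jsonlite::toJSON(list(
    id = "toy", format = "1.0", matrix_type = "sparse",
    rows = list(list(id = "Otu1"), list(id = "Otu2")),
    columns = list(list(id = "s1"), list(id = "s2")),
    data = list(list(0L, 0L, 5L), list(1L, 1L, 2L))
  ), auto_unbox = TRUE), biom)
  tb <- read_otu_table(biom, dialect = "biom")
  expect_equal(unname(tb$counts), matrix(c(5, 0, 0, 2), 2))
})

test_that("sample-name parsing maps design codes and rejects bad codes", {
  keys <- parse_sample_name(c("C96bN", "F1aS"))
  expect_equal(keys$soil, c("Corsica", "France"))
  expect_equal(keys$genotype, c("G96", "G1"))
  expect_equal(keys$replicate, c("b", "a"))
  expect_equal(keys$compartment, c("nodule", "rhizosphere"))
  expect_equal(keys$plant_id, c("C96b", "F1a"))
  expect_error(parse_sample_name("X7zQ"), "Valid codes")
})

test_that("plant_id is shared across one plant's compartments", {
  t <- tiny_design_table()
  meta <- sample_metadata(t)
  expect_equal(as.vector(table(meta$plant_id)), c(4L, 4L))
})

test_that("rare-OTU filtering thresholds totals and is idempotent", {
  counts <- cbind(s1 = c(5, 4, 9, 0, 12), s2 = c(5, 5, 0, 1, 3))
  rownames(counts) <- paste0("Otu", 1:5)
  t <- otu_table(counts)
  expect_identical(filter_rare_otus(t, 0)$counts, t$counts)
  f <- filter_rare_otus(t, 10)
  # totals: 10, 9, 9, 1, 15 -> keep Otu1 and Otu5
  expect_setequal(rownames(f$counts), c("Otu1", "Otu5"))
  expect_identical(ncol(f$counts), ncol(t$counts))
  expect_identical(filter_rare_otus(f, 10)$counts, f$counts)
})

test_that("relative abundance columns sum to one and zero samples error", {
  counts <- cbind(s1 = c(3, 1, 0), s2 = c(0, 0, 7))
  rownames(counts) <- paste0("Otu", 1:3)
  rel <- to_relative_abundance(otu_table(counts))
  expect_equal(rel[, "s1"], c(Otu1 = 0.75, Otu2 = 0.25, Otu3 = 0))
  expect_equal(rel[, "s2"], c(Otu1 = 0, Otu2 = 0, Otu3 = 1))
  expect_equal(unname(colSums(rel)), c(1, 1))
  bad <- cbind(s1 = c(1, 1), s2 = c(0, 0))
  rownames(bad) <- c("a", "b")
  expect_error(to_relative_abundance(otu_table(bad)), "s2")
})

test_that("subsampling draws without replacement with correct margins", {
  col <- c(9000, 1000)
  expect_error(subsample_counts(col, 10001), "exceeds")
  expect_identical(subsample_counts(col, 10000), as.integer(col))
  draws <- replicate(400, subsample_counts(col, 1500))
  expect_true(all(colSums(draws) == 1500))
  # hypergeometric expectation 150, SE of the mean over 400 draws
  se <- sqrt(1500 * 0.1 * 0.9 * (10000 - 1500) / (10000 - 1)) / sqrt(400)
  expect_lt(abs(mean(draws[2, ]) - 150), 3 * se)
  expect_identical(subsample_counts(col, 100, seed = 7),
                   subsample_counts(col, 100, seed = 7))
})
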