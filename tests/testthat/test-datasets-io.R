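test_that("a small labelled CSV loads with the expected shape", {
  path <- withr::local_tempfile(fileext = ".csv")
  toy_csv(path)
  ds <- load_expression_matrix(path)
  expect_s3_class(ds, "expression_dataset")
  expect_equal(nrow(ds$matrix), 3L)
  expect_equal(ncol(ds$matrix), 4L)
  expect_equal(ds$class_names, c("A", "B"))
  expect_equal(ds$labels, c(0L, 0L, 1L))
  expect_equal(ds$gene_ids, paste0("g", 1:4))
  expect_equal(unname(ds$matrix[1, 1]), 1.5)
})

test_that("a transposed file loads to the identical dataset", {
  p1 <- withr::local_tempfile(fileext = ".csv")
  toy_csv(p1)
  ds <- load_expression_matrix(p1)
  raw <- t(as.matrix(read.table(p1, sep = ",", colClasses = "character")))
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(apply(raw, 1, paste, collapse = ","), p2)
  ds2 <- load_expression_matrix(p2, orientation = "genes_by_samples")
  expect_equal(ds2, ds)
})

test_that("tab-delimited input is auto-detected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  toy_csv(path, sep = "\t")
  ds <- load_expression_matrix(path)
  expect_equal(ncol(ds$matrix), 4L)
})

test_that("malformed inputs are rejected with context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,g1,g2,class",
               "s1,1,NA,A", "s2,2,3,B"), path)
  expect_error(load_expression_matrix(path), "s1.*g2")

  writeLines(c("sample_id,g1,g2,label",
               "s1,1,2,A", "s2,2,3,B"), path)
  expect_error(load_expression_matrix(path), "label column")

  writeLines(c("sample_id,g1,g1,class",
               "s1,1,2,A", "s2,2,3,B"), path)
  expect_error(load_expression_matrix(path), "duplicate gene")
})

test_that("dataset validation enforces the container invariants", {
  m <- matrix(1:6, 2, 3)
  expect_error(expression_dataset(m, c(0L, 2L), class_names = c("a", "b")),
               "class codes")
  expect_error(expression_dataset(m, c(0L, 0L), class_names = c("a", "b")),
               "occur at least once")
  m[1, 1] <- NA
  expect_error(expression_dataset(m, c(0L, 1L)), "non-finite")
})

test_that("minmax normalization maps genes onto [0,1]", {
  m <- cbind(c(2, 4, 6), c(5, 5, 5), c(-1, 0, 3))
  ds <- expression_dataset(m, c(0L, 0L, 1L))
  nm <- normalize_expression(ds, "minmax")
  expect_equal(unname(nm$matrix[, 1]), c(0, 0.5, 1))
  expect_equal(unname(nm$matrix[, 2]), c(0, 0, 0))
  expect_true(all(nm$matrix >= 0 & nm$matrix <= 1))
  expect_equal(nm$labels, ds$labels)
})

test_that("minmax normalization is idempotent", {
  set.seed(5)
  ds <- expression_dataset(matrix(rnorm(40), 8, 5), rep(0:1, 4))
  once <- normalize_expression(ds, "minmax")
  twice <- normalize_expression(once, "minmax")
  expect_equal(twice$matrix, once$matrix)
})

test_that("zscore normalization centres and scales by the n-1 sd", {
  ds <- expression_dataset(cbind(c(1, 3), c(7, 7)), c(0L, 1L))
  z <- normalize_expression(ds, "zscore")
  # sample sd of (1,3) is sqrt(2), so the scores are +/- 1/sqrt(2)
  expect_equal(unname(z$matrix[, 1]), c(-1, 1) / sqrt(2))
  expect_equal(unname(z$matrix[, 2]), c(0, 0))
  expect_equal(unname(colMeans(z$matrix)), c(0, 0))
  expect_equal(sd(z$matrix[, 1]), 1)
})

test_that("load -> write -> load round-trips bit-identically", {
  set.seed(9)
  ds <- expression_dataset(matrix(rnorm(30) * 1e3, 5, 6),
                           c(0L, 1L, 0L, 1L, 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_expression_matrix(ds, path)
  back <- load_expression_matrix(path)
  expect_identical(back$matrix, ds$matrix)
  expect_identical(back$labels, ds$labels)
  write_expression_matrix(back, paste0(path, "2"))
  expect_identical(readLines(path), readLines(paste0(path, "2")))
})

test_that("selection reports round-trip through JSON", {
  set.seed(2)
  ds <- expression_dataset(matrix(runif(60), 10, 6), rep(0:1, 5))
  pool <- tiny_pool(4L, p = 6L)
  res <- run_cssmo(ds, pool, tiny_config())
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_report(res, path)
  back <- read_selection_report(path)
  expect_equal(back$best_mask, res$best_mask)
  expect_equal(back$best_fitness, res$best_fitness)
  expect_equal(back$fitness_trace, res$fitness_trace)
  expect_equal(back$evaluations, res$evaluations)
  expect_equal(back$seed, res$seed)
  expect_equal(unclass(back$config), unclass(res$config))

  res$best_mask[] <- FALSE
  expect_error(write_selection_report(res, path), "empty")
})
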