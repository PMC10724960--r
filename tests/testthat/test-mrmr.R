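test_that("quantile and width binning follow their definitions", {
  d <- discretize_expression(matrix(1:6, 6, 1), n_bins = 3,
                             strategy = "quantile")
  expect_equal(d$codes[, 1], c(0L, 0L, 1L, 1L, 2L, 2L))

  d <- discretize_expression(matrix(c(0, 0.4, 0.6, 1.0), 4, 1), n_bins = 2,
                             strategy = "width")
  expect_equal(d$codes[, 1], c(0L, 0L, 1L, 1L))

  d <- discretize_expression(matrix(rep(7, 5), 5, 1), n_bins = 3)
  expect_equal(d$codes[, 1], rep(0L, 5))
  expect_length(d$bin_edges[[1]], 0L)

  expect_error(discretize_expression(matrix(1:6, 6, 1), n_bins = 1),
               "n_bins")
  # per-gene edges are strictly increasing
  set.seed(8)
  d <- discretize_expression(matrix(rnorm(200), 20, 10), n_bins = 4)
  for (e in d$bin_edges) expect_true(all(diff(e) > 0))
  expect_true(all(d$codes >= 0L & d$codes < 4L))
})

test_that("mutual information matches entropy, symmetry and the oracle", {
  x <- rep(0:2, each = 4)
  expect_equal(mutual_information(x, x), log(3), tolerance = 1e-12)
  expect_equal(mutual_information(rep(1L, 10), sample(0:1, 10, TRUE)), 0)

  # frozen oracle value: joint counts [[5,1],[1,5]], n = 12
  x <- rep(0:1, each = 6)
  y <- c(rep(0, 5), 1, 0, rep(1, 5))
  expect_equal(mutual_information(x, y), 0.24258597169364066,
               tolerance = 1e-12)
  expect_equal(mi_oracle(x, y), 0.24258597169364066, tolerance = 1e-12)

  set.seed(31)
  for (i in 1:20) {
    a <- sample(0:3, 40, TRUE)
    b <- sample(0:2, 40, TRUE)
    expect_equal(mutual_information(a, b), mutual_information(b, a),
                 tolerance = 1e-12)
    expect_gte(mutual_information(a, b), 0)
    h <- function(v) mutual_information(v, v)
    expect_lte(mutual_information(a, b), min(h(a), h(b)) + 1e-12)
    expect_equal(mutual_information(a, b), mi_oracle(a, b),
                 tolerance = 1e-12)
  }
  expect_error(mutual_information(0:3, 0:4), "equal length")
})

test_that("independent variables have near-zero estimated MI", {
  set.seed(1000)
  a <- sample(0:2, 10000, TRUE)
  b <- sample(0:2, 10000, TRUE)
  expect_lt(mutual_information(a, b), 0.02)
})

test_that("greedy selection matches the exhaustive per-step oracle", {
  set.seed(17)
  out <- generate_synthetic_dataset(synthetic_spec(
    n_samples = 40, n_genes = 12, n_informative = 3,
    n_redundant_per_informative = 1, effect_size = 2, seed = 17))
  disc <- discretize_expression(out$dataset, n_bins = 3)
  for (scheme in c("MID", "MIQ")) {
    pool <- mrmr_select(disc, out$dataset$labels, k = 4, scheme = scheme)
    expect_equal(pool$selected_idx,
                 mrmr_oracle(disc$codes, out$dataset$labels, 4, scheme))
  }
})

test_that("k = 1 picks the most relevant gene; k = p permutes all genes", {
  set.seed(18)
  out <- generate_synthetic_dataset(synthetic_spec(
    n_samples = 30, n_genes = 10, n_informative = 2,
    n_redundant_per_informative = 0, effect_size = 3, seed = 18))
  disc <- discretize_expression(out$dataset)
  pool1 <- mrmr_select(disc, out$dataset$labels, k = 1)
  expect_equal(pool1$selected_idx, which.max(pool1$relevance))
  expect_equal(pool1$score_at_selection, max(pool1$relevance))

  poolp <- mrmr_select(disc, out$dataset$labels, k = 10)
  expect_equal(sort(poolp$selected_idx), 1:10)

  expect_error(mrmr_select(disc, out$dataset$labels, k = 11), "k must")
})

test_that("an exact duplicate of a selected gene is penalized out", {
  # gene 1 informative, gene 2 its exact duplicate, gene 3 equally relevant
  # but flipped on different samples (so MI(g1, g3) < H(g1)), genes 4-5 noise
  set.seed(23)
  y <- rep(0:1, each = 12)
  g1 <- y; g1[c(1, 13)] <- 1 - g1[c(1, 13)]
  g3 <- y; g3[c(2, 14)] <- 1 - g3[c(2, 14)]
  X <- cbind(g1, g1, g3, runif(24), runif(24))
  disc <- discretize_expression(X, n_bins = 2)
  pool <- mrmr_select(disc, y, k = 2)
  expect_equal(pool$selected_idx[1], 1L)
  # the duplicate (gene 2) must not be the second pick: its redundancy
  # penalty equals its full self-entropy
  expect_false(pool$selected_idx[2] == 2L)
})

test_that("the one-call filter carries gene identifiers", {
  out <- generate_synthetic_dataset(synthetic_spec(
    n_samples = 30, n_genes = 20, n_informative = 2,
    n_redundant_per_informative = 0, seed = 5))
  pool <- mrmr_filter(out$dataset, k = 6)
  expect_length(pool$selected_idx, 6L)
  expect_equal(pool$gene_ids,
               out$dataset$gene_ids[pool$selected_idx])
})
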