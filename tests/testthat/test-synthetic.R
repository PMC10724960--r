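test_that("generator bookkeeping matches the spec dimensions", {
  out <- generate_synthetic_dataset(synthetic_spec(
    n_samples = 60, n_genes = 500, n_informative = 5,
    n_redundant_per_informative = 4, seed = 3))
  expect_equal(dim(out$dataset$matrix), c(60L, 500L))
  expect_length(out$truth$informative_idx, 5L)
  expect_length(out$truth$redundant_idx, 20L)
  expect_length(out$truth$noise_idx, 475L)
  # the three index sets partition the gene space
  expect_equal(sort(c(out$truth$informative_idx, out$truth$redundant_idx,
                      out$truth$noise_idx)), 1:500)
  expect_true(all((0:1) %in% out$dataset$labels))
})

test_that("generation is deterministic in the seed", {
  a <- generate_synthetic_dataset(synthetic_spec(n_samples = 30,
                                                 n_genes = 40, seed = 77))
  b <- generate_synthetic_dataset(synthetic_spec(n_samples = 30,
                                                 n_genes = 40, seed = 77))
  expect_identical(a$dataset$matrix, b$dataset$matrix)
  expect_identical(a$truth, b$truth)
  c_ <- generate_synthetic_dataset(synthetic_spec(n_samples = 30,
                                                  n_genes = 40, seed = 78))
  expect_false(identical(a$dataset$matrix, c_$dataset$matrix))
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_spec(n_genes = 10, n_informative = 4,
                              n_redundant_per_informative = 3),
               "infeasible")
  expect_error(synthetic_spec(class_proportions = c(0.6, 0.6)),
               "simplex")
  expect_error(synthetic_spec(redundancy_corr = 1.2), "redundancy_corr")
})

test_that("informative genes separate classes; noise genes do not", {
  out <- generate_synthetic_dataset(synthetic_spec(
    n_samples = 2000, n_genes = 10, n_informative = 3,
    n_redundant_per_informative = 0, effect_size = 2, seed = 21))
  y <- out$dataset$labels
  tstat <- function(g) {
    unname(t.test(out$dataset$matrix[y == 1, g],
                  out$dataset$matrix[y == 0, g])$statistic)
  }
  # at effect 2 sd and ~1000 per class the t statistic is ~ 2/sqrt(2/1000) ~ 45
  for (g in out$truth$informative_idx) expect_gt(abs(tstat(g)), 10)
  for (g in out$truth$noise_idx) expect_lt(abs(tstat(g)), 4)
})

test_that("permuting labels destroys informativeness", {
  out <- generate_synthetic_dataset(synthetic_spec(
    n_samples = 2000, n_genes = 10, n_informative = 3,
    n_redundant_per_informative = 0, effect_size = 2, seed = 22))
  set.seed(99)
  y <- sample(out$dataset$labels)
  tstat <- function(g) {
    unname(t.test(out$dataset$matrix[y == 1, g],
                  out$dataset$matrix[y == 0, g])$statistic)
  }
  t_inf <- mean(abs(vapply(out$truth$informative_idx, tstat, numeric(1))))
  t_noise <- mean(abs(vapply(out$truth$noise_idx, tstat, numeric(1))))
  expect_lt(t_inf, 3)
  expect_lt(abs(t_inf - t_noise), 2)
})

test_that("redundant copies reach the target correlation at large n", {
  out <- generate_synthetic_dataset(synthetic_spec(
    n_samples = 5000, n_genes = 8, n_informative = 2,
    n_redundant_per_informative = 1, redundancy_corr = 0.8, seed = 13))
  tr <- out$truth
  for (j in seq_along(tr$redundant_idx)) {
    rho <- cor(out$dataset$matrix[, tr$redundant_parent[j]],
               out$dataset$matrix[, tr$redundant_idx[j]])
    expect_lt(abs(rho - 0.8), 0.05)
  }
})

test_that("recovery scoring credits parents and their copies", {
  out <- generate_synthetic_dataset(synthetic_spec(
    n_samples = 20, n_genes = 50, n_informative = 5,
    n_redundant_per_informative = 2, seed = 4))
  tr <- out$truth
  p <- 50L

  mask <- logical(p)
  mask[tr$informative_idx] <- TRUE
  sc <- planted_recovery_score(mask, tr)
  expect_equal(sc$informative_hit_fraction, 1)
  expect_equal(sc$selected_size, 5L)
  expect_equal(sc$noise_fraction, 0)

  # select one redundant copy for 4 of the 5 parents only
  mask <- logical(p)
  for (g in tr$informative_idx[1:4]) {
    mask[tr$redundant_idx[tr$redundant_parent == g][1]] <- TRUE
  }
  expect_equal(planted_recovery_score(mask, tr)$informative_hit_fraction,
               0.8)

  empty <- planted_recovery_score(logical(p), tr)
  expect_equal(empty$informative_hit_fraction, 0)
  expect_equal(empty$selected_size, 0L)

  expect_error(planted_recovery_score(logical(p - 1L), tr), "length")
})
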