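#' Deterministic k-nearest-neighbour prediction
#'
#' Euclidean k-NN with fully deterministic tie handling: equal distances
#' resolve to the lowest training index (stable ordering) and vote ties
#' resolve to the lowest class code. Determinism matters here because the
#' optimizer's bit-reproducibility guarantee extends through the fitness
#' function.
#'
#' @param train_x Numeric training matrix (samples x features).
#' @param train_y Integer class codes of the training samples.
#' @param test_x Numeric test matrix with matching feature count.
#' @param k Number of neighbours, `1 <= k <= nrow(train_x)`.
#' @return Integer vector of predicted class codes.
#' @export
knn_predict <- function(train_x, train_y, test_x, k = 1L) {
  train_x <- as.matrix(train_x)
  test_x <- as.matrix(test_x)
  k <- as.integer(k)
  if (k < 1L || k > nrow(train_x)) stop("k must lie in [1, nrow(train_x)]")
  if (ncol(train_x) != ncol(test_x)) stop("feature count mismatch")
  d2 <- sq_dist(test_x, train_x)
  apply_knn_votes(d2, as.integer(train_y), k)
}

# squared Euclidean distances, rows of a vs rows of b
sq_dist <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

apply_knn_votes <- function(d2, train_y, k) {
  n_class <- max(train_y) + 1L
  if (k == 1L) {
    nn <- max.col(-d2, ties.method = "first")
    return(train_y[nn])
  }
  vapply(seq_len(nrow(d2)), function(i) {
    nb <- order(d2[i, ])[seq_len(k)]  # order() is stable: distance ties -> lowest index
    votes <- tabulate(train_y[nb] + 1L, n_class)
    which.max(votes) - 1L             # vote ties -> lowest class code
  }, integer(1))
}

#' Assemble a fitness result
#'
#' The accuracy is `100 * CC / N` where `CC` is the number of correctly
#' classified samples — integer arithmetic, so the identity holds exactly.
#'
#' @param predicted,actual Integer class-code vectors of equal length.
#' @return An object of class `fitness_result`: `accuracy` in `[0, 100]`,
#'   `CC`, `N`, `per_sample_pred`.
#' @export
fitness_result <- function(predicted, actual) {
  predicted <- as.integer(predicted)
  actual <- as.integer(actual)
  stopifnot(length(predicted) == length(actual))
  cc <- sum(predicted == actual)
  n <- length(actual)
  structure(list(accuracy = 100 * cc / n, CC = cc, N = n,
                 per_sample_pred = predicted),
            class = "fitness_result")
}

#' @export
print.fitness_result <- function(x, ...) {
  cat("fitness_result: accuracy ", format(x$accuracy, digits = 6),
      " (", x$CC, "/", x$N, " correct)\n", sep = "")
  invisible(x)
}

loocv_knn <- function(X, y, k = 1L) {
  n <- nrow(X)
  d2 <- sq_dist(X, X)
  diag(d2) <- Inf
  preds <- apply_knn_votes(d2, y, k)
  fitness_result(preds, y)
}

#' Leave-one-out cross-validation fitness
#'
#' For each sample, the classifier is trained on the other `N - 1` samples
#' restricted to the masked genes and predicts the held-out sample; the
#' fitness is `100 * CC / N`. The `"knn"` surrogate is deterministic and fast
#' enough to sit inside the optimizer's loop; `"cnn"` trains the
#' convolutional classifier once per fold and is intended for final
#' evaluation of a chosen subset, not for search.
#'
#' @param dataset An [expression_dataset()].
#' @param mask Non-empty logical mask over the dataset's genes.
#' @param classifier `"knn"` (default) or `"cnn"`.
#' @param k Neighbour count for the k-NN surrogate.
#' @param ... For `"cnn"`: arguments forwarded to the internal trainer
#'   (`arch`, `epochs`, `learning_rate`, `batch_size`, `seed`).
#' @return A [fitness_result()].
#' @export
loocv_fitness <- function(dataset, mask, classifier = c("knn", "cnn"),
                          k = 1L, ...) {
  classifier <- match.arg(classifier)
  mask <- as.logical(mask)
  if (length(mask) != n_genes(dataset)) {
    stop("mask length must equal the gene count")
  }
  if (!any(mask)) stop("mask must select at least one gene")
  if (n_samples(dataset) < 2L) stop("LOOCV needs at least 2 samples")
  X <- dataset$matrix[, mask, drop = FALSE]
  y <- dataset$labels
  if (classifier == "knn") return(loocv_knn(X, y, k = k))
  loocv_cnn(X, y, n_classes(dataset), ...)
}

#' Build a pool-local k-NN fitness function
#'
#' Returns the closure the optimizer calls: it takes a pool-local mask and
#' returns the 1-NN (or k-NN) LOOCV accuracy on the corresponding genes.
#'
#' @param dataset An [expression_dataset()] (normalize first; see
#'   [normalize_expression()]).
#' @param pool A `gene_pool` from [mrmr_filter()] / [mrmr_select()].
#' @param k Neighbour count.
#' @return `function(mask) -> accuracy in [0, 100]`.
#' @export
make_knn_fitness <- function(dataset, pool, k = 1L) {
  Xp <- dataset$matrix[, pool$selected_idx, drop = FALSE]
  y <- dataset$labels
  function(mask) {
    if (!any(mask)) stop("fitness called on an empty mask")
    loocv_knn(Xp[, mask, drop = FALSE], y, k = k)$accuracy
  }
}
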