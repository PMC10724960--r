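#' Specification for a synthetic expression dataset
#'
#' Describes a high-dimensional expression matrix (genes >> samples) with a
#' small planted set of class-informative genes, correlated redundant copies
#' of them, and many label-independent noise genes — the structure wrapper
#' gene selectors are meant to exploit.
#'
#' Informative gene values for a sample of class `c` are drawn
#' `Normal(c * effect_size * noise_sd, noise_sd^2)`, a monotone ladder of
#' class means that extends naturally to more than two classes. A redundant
#' copy equals its parent plus `Normal(0, tau^2)` noise, with `tau` chosen
#' from the parent's realized variance so that `cor(parent, copy)` converges
#' to `redundancy_corr`. Noise genes are `Normal(0, noise_sd^2)` independent
#' of the labels.
#'
#' @param n_samples Number of samples.
#' @param n_genes Total number of genes.
#' @param n_classes Number of classes (>= 2).
#' @param n_informative Number of planted informative genes.
#' @param n_redundant_per_informative Correlated copies per informative gene.
#' @param effect_size Class-mean separation in units of `noise_sd`.
#' @param redundancy_corr Target correlation between a parent and each copy,
#'   in `[0, 1]`.
#' @param class_proportions Simplex vector of class proportions (default
#'   uniform). Class counts are fixed to the proportions (largest-remainder
#'   rounding, every class at least once) and then shuffled across samples.
#' @param noise_sd Within-class standard deviation.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 60L, n_genes = 500L, n_classes = 2L,
                           n_informative = 5L,
                           n_redundant_per_informative = 4L,
                           effect_size = 2, redundancy_corr = 0.8,
                           class_proportions = NULL, noise_sd = 1,
                           seed = 1L) {
  if (is.null(class_proportions)) {
    class_proportions <- rep(1 / n_classes, n_classes)
  }
  spec <- list(n_samples = as.integer(n_samples),
               n_genes = as.integer(n_genes),
               n_classes = as.integer(n_classes),
               n_informative = as.integer(n_informative),
               n_redundant_per_informative =
                 as.integer(n_redundant_per_informative),
               effect_size = effect_size,
               redundancy_corr = redundancy_corr,
               class_proportions = class_proportions,
               noise_sd = noise_sd,
               seed = as.integer(seed))
  with(spec, {
    if (n_samples < 2L || n_genes < 1L) stop("invalid dataset dimensions")
    if (n_classes < 2L) stop("n_classes must be >= 2")
    if (n_informative < 1L) stop("n_informative must be >= 1")
    if (n_redundant_per_informative < 0L) {
      stop("n_redundant_per_informative must be >= 0")
    }
    if (n_informative * (1L + n_redundant_per_informative) > n_genes) {
      stop("infeasible spec: informative + redundant genes exceed n_genes")
    }
    if (length(class_proportions) != n_classes ||
        any(class_proportions <= 0) ||
        abs(sum(class_proportions) - 1) > 1e-12) {
      stop("class_proportions must be a positive simplex vector of length ",
           n_classes)
    }
    if (redundancy_corr < 0 || redundancy_corr > 1) {
      stop("redundancy_corr must lie in [0, 1]")
    }
    if (noise_sd <= 0) stop("noise_sd must be positive")
  })
  structure(spec, class = "synthetic_spec")
}

largest_remainder_counts <- function(n, props) {
  raw <- n * props
  counts <- floor(raw)
  counts <- pmax(counts, 1)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - floor(raw), decreasing = TRUE)
    for (i in seq_len(short)) {
      j <- extra[(i - 1L) %% length(props) + 1L]
      counts[j] <- counts[j] + 1
    }
  } else if (short < 0) {
    over <- order(counts, decreasing = TRUE)
    i <- 1L
    while (short < 0) {
      j <- over[(i - 1L) %% length(props) + 1L]
      if (counts[j] > 1) {
        counts[j] <- counts[j] - 1
        short <- short + 1
      }
      i <- i + 1L
    }
  }
  as.integer(counts)
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return A list with components `dataset` (an [expression_dataset()]) and
#'   `truth` (class `ground_truth`: sorted `informative_idx`, `redundant_idx`,
#'   `noise_idx` partitioning the gene index space, plus `redundant_parent`
#'   mapping each redundant gene to its informative parent).
#' @examples
#' out <- generate_synthetic_dataset(synthetic_spec(n_samples = 20,
#'   n_genes = 50, n_informative = 3, n_redundant_per_informative = 2,
#'   seed = 7))
#' length(out$truth$informative_idx)
#' @export
generate_synthetic_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_samples
  p <- spec$n_genes
  counts <- largest_remainder_counts(n, spec$class_proportions)
  labels <- sample(rep.int(seq_len(spec$n_classes) - 1L, counts))

  n_inf <- spec$n_informative
  n_red <- n_inf * spec$n_redundant_per_informative
  placement <- sample.int(p, n_inf + n_red)
  informative_idx <- placement[seq_len(n_inf)]
  redundant_idx <- placement[n_inf + seq_len(n_red)]
  redundant_parent <- rep(informative_idx,
                          each = spec$n_redundant_per_informative)

  X <- matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
  means <- labels * spec$effect_size * spec$noise_sd
  for (g in informative_idx) X[, g] <- X[, g] + means
  rho <- spec$redundancy_corr
  if (n_red > 0L) {
    for (j in seq_len(n_red)) {
      g <- redundant_idx[j]
      parent <- X[, redundant_parent[j]]
      if (rho == 0) {
        X[, g] <- stats::rnorm(n, sd = stats::sd(parent))
      } else {
        # tau^2 = Var(parent) * (1 - rho^2) / rho^2  =>  cor(parent, copy) -> rho
        tau <- stats::sd(parent) * sqrt(1 - rho^2) / rho
        X[, g] <- parent + stats::rnorm(n, sd = tau)
      }
    }
  }
  ds <- expression_dataset(X, labels,
                           gene_ids = paste0("g", seq_len(p)),
                           sample_ids = paste0("s", seq_len(n)),
                           class_names = paste0("class", seq_len(spec$n_classes) - 1L))
  truth <- structure(list(informative_idx = sort(informative_idx),
                          redundant_idx = sort(redundant_idx),
                          noise_idx = setdiff(seq_len(p), placement),
                          redundant_parent =
                            redundant_parent[order(redundant_idx)]),
                     class = "ground_truth")
  list(dataset = ds, truth = truth, spec = spec)
}

#' Score a gene mask against planted ground truth
#'
#' An informative gene counts as recovered if it *or any of its redundant
#' copies* is selected — the copies carry the same signal, so selecting a copy
#' is as good as selecting the parent.
#'
#' @param mask Logical (or 0/1) vector over the full gene index space.
#' @param truth A `ground_truth` from [generate_synthetic_dataset()].
#' @return A list: `informative_hit_fraction` in `[0, 1]`, `selected_size`,
#'   and `noise_fraction` (share of the selection that is noise genes).
#' @export
planted_recovery_score <- function(mask, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  mask <- as.logical(mask)
  p <- length(truth$informative_idx) + length(truth$redundant_idx) +
    length(truth$noise_idx)
  if (length(mask) != p) {
    stop("mask length ", length(mask), " does not match gene count ", p)
  }
  hit <- vapply(truth$informative_idx, function(g) {
    copies <- truth$redundant_idx[truth$redundant_parent == g]
    mask[g] || any(mask[copies])
  }, logical(1))
  selected <- sum(mask)
  list(informative_hit_fraction =
         if (length(hit)) mean(hit) else 0,
       selected_size = selected,
       noise_fraction = if (selected > 0) sum(mask[truth$noise_idx]) / selected
                        else 0)
}
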