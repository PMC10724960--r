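#' Discretize expression values per gene
#'
#' Plug-in mutual information needs discrete codes; expression values are
#' binned per gene, independently of the labels. `"quantile"` (the default
#' used by the mRMR filter) gives near-equal bin occupancy; `"width"` splits
#' each gene's range into equal-width bins. A constant gene maps to code 0.
#' Duplicate quantile edges (heavily tied genes) are collapsed, so such genes
#' may occupy fewer than `n_bins` codes.
#'
#' @param x An [expression_dataset()] or a numeric matrix (samples x genes).
#' @param n_bins Number of bins (>= 2).
#' @param strategy `"quantile"` or `"width"`.
#' @return An object of class `discretized_matrix`: integer `codes`
#'   (samples x genes, values in `[0, n_bins)`), `n_bins`, and per-gene
#'   `bin_edges` (strictly increasing interior cut points).
#' @export
discretize_expression <- function(x, n_bins = 3L,
                                  strategy = c("quantile", "width")) {
  strategy <- match.arg(strategy)
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  X <- if (inherits(x, "expression_dataset")) x$matrix else as.matrix(x)
  if (strategy == "quantile" && nrow(X) < n_bins) {
    stop("quantile binning needs n_samples >= n_bins")
  }
  p <- ncol(X)
  codes <- matrix(0L, nrow(X), p)
  edges <- vector("list", p)
  for (j in seq_len(p)) {
    v <- X[, j]
    lo <- min(v)
    hi <- max(v)
    if (hi == lo) {
      edges[[j]] <- numeric(0)
      next
    }
    cuts <- if (strategy == "quantile") {
      stats::quantile(v, probs = seq(0, 1, length.out = n_bins + 1L),
                      names = FALSE, type = 7)
    } else {
      seq(lo, hi, length.out = n_bins + 1L)
    }
    cuts <- unique(cuts[-c(1L, length(cuts))])
    cuts <- cuts[cuts > lo & cuts <= hi]
    edges[[j]] <- cuts
    codes[, j] <- findInterval(v, cuts)
  }
  structure(list(codes = codes, n_bins = n_bins, bin_edges = edges,
                 strategy = strategy),
            class = "discretized_matrix")
}

#' Plug-in mutual information between two discrete vectors
#'
#' Computes `sum p(x,y) log( p(x,y) / (p(x) p(y)) )` in nats from the joint
#' contingency table, with the `0 log 0 := 0` convention. Non-negative and
#' symmetric; equals the entropy `H(X)` when `y == x`.
#'
#' @param x,y Integer code vectors of equal length.
#' @return Mutual information in nats (>= 0).
#' @examples
#' x <- rep(0:2, 4)
#' all.equal(mutual_information(x, x), log(3))
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")")
  }
  n <- length(x)
  if (n < 1L) stop("x and y must be non-empty")
  xi <- as.integer(x)
  yi <- as.integer(y)
  xi <- xi - min(xi) + 1L
  yi <- yi - min(yi) + 1L
  nx <- max(xi)
  ny <- max(yi)
  if (nx == 1L || ny == 1L) return(0)
  joint <- tabulate((xi - 1L) * ny + yi, nbins = nx * ny)
  pxy <- matrix(joint, nrow = ny, ncol = nx) / n  # [y, x]
  py <- rowSums(pxy)
  px <- colSums(pxy)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * (log(pxy[nz]) - log(outer(py, px))[nz]))
  max(mi, 0)
}

#' Greedy minimum-redundancy maximum-relevance gene ranking
#'
#' Forward selection on discretized expression codes. The first pick maximizes
#' relevance `MI(gene, label)`; pick `t` maximizes the MID score
#' `MI(g, label) - mean over selected s of MI(g, s)` (difference form), or the
#' MIQ quotient `MI(g, label) / max(mean MI(g, s), 1e-12)`. All argmax ties
#' break to the lowest gene index, making the ranking deterministic.
#'
#' @param disc A `discretized_matrix` from [discretize_expression()].
#' @param labels Integer class codes (used as-is; labels are already
#'   discrete).
#' @param k Number of genes to retain, `1 <= k <= n_genes`.
#' @param scheme `"MID"` (default) or `"MIQ"`.
#' @param gene_ids Optional gene identifiers carried into the pool.
#' @return An object of class `gene_pool`: `selected_idx` (in selection
#'   order), `relevance` (MI with the label, all genes, nats),
#'   `score_at_selection` (the winning score at each step), `scheme`, and
#'   `gene_ids` (of the selected genes, when supplied).
#' @export
mrmr_select <- function(disc, labels, k, scheme = c("MID", "MIQ"),
                        gene_ids = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(disc, "discretized_matrix"))
  codes <- disc$codes
  p <- ncol(codes)
  k <- as.integer(k)
  if (k < 1L || k > p) stop("k must lie in [1, n_genes]")
  labels <- as.integer(labels)
  if (length(labels) != nrow(codes)) {
    stop("labels must have one entry per sample")
  }

  relevance <- vapply(seq_len(p), function(j) {
    mutual_information(codes[, j], labels)
  }, numeric(1))

  selected <- integer(k)
  score_at <- numeric(k)
  remaining <- rep(TRUE, p)
  red_sum <- numeric(p)  # running sum of MI(gene, each selected gene)

  first <- which.max(relevance)  # ties -> lowest index
  selected[1L] <- first
  score_at[1L] <- relevance[first]
  remaining[first] <- FALSE

  if (k > 1L) {
    for (t in 2:k) {
      last <- selected[t - 1L]
      idx <- which(remaining)
      red_sum[idx] <- red_sum[idx] + vapply(idx, function(j) {
        mutual_information(codes[, j], codes[, last])
      }, numeric(1))
      mean_red <- red_sum[idx] / (t - 1)
      score <- if (scheme == "MID") {
        relevance[idx] - mean_red
      } else {
        relevance[idx] / pmax(mean_red, 1e-12)
      }
      win <- idx[which.max(score)]
      selected[t] <- win
      score_at[t] <- score[which.max(score)]
      remaining[win] <- FALSE
    }
  }
  structure(list(selected_idx = selected,
                 relevance = relevance,
                 score_at_selection = score_at,
                 scheme = scheme,
                 gene_ids = if (!is.null(gene_ids)) gene_ids[selected]),
            class = "gene_pool")
}

#' @export
print.gene_pool <- function(x, ...) {
  cat("gene_pool (", x$scheme, "): ", length(x$selected_idx),
      " genes retained of ", length(x$relevance), "\n", sep = "")
  cat("top relevance (nats):",
      paste(signif(x$relevance[x$selected_idx[seq_len(min(5,
            length(x$selected_idx)))]], 4), collapse = ", "), "\n")
  invisible(x)
}

#' One-call mRMR prefilter for an expression dataset
#'
#' Convenience wrapper: discretizes the dataset and runs [mrmr_select()],
#' carrying the dataset's gene identifiers into the pool.
#'
#' @param dataset An [expression_dataset()].
#' @param k Pool size; default `min(200, n_genes)`.
#' @param n_bins,strategy Passed to [discretize_expression()].
#' @param scheme Passed to [mrmr_select()].
#' @return A `gene_pool`.
#' @export
mrmr_filter <- function(dataset, k = min(200L, n_genes(dataset)),
                        n_bins = 3L, strategy = "quantile", scheme = "MID") {
  disc <- discretize_expression(dataset, n_bins = n_bins, strategy = strategy)
  mrmr_select(disc, dataset$labels, k = k, scheme = scheme,
              gene_ids = dataset$gene_ids)
}
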