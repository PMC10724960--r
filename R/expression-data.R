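#' Construct an expression dataset
#'
#' The canonical container used throughout the package: a numeric
#' samples-by-genes matrix with integer class codes, unique gene and sample
#' identifiers, and human-readable class names. Class codes are 0-based
#' (`0 .. C-1`) so they round-trip unchanged through reports and CLIs.
#'
#' @param matrix Numeric matrix, samples in rows, genes in columns. All values
#'   must be finite; missing values are rejected.
#' @param labels Class labels: either integer codes in `0 .. C-1` or a
#'   character/factor vector (coded in sorted level order).
#' @param gene_ids Unique gene identifiers (default: column names, or
#'   `g1, g2, ...`).
#' @param sample_ids Unique sample identifiers (default: row names, or
#'   `s1, s2, ...`).
#' @param class_names Names of the classes, length `C`. Derived from `labels`
#'   when omitted.
#' @return An object of class `expression_dataset` with fields `matrix`,
#'   `labels`, `gene_ids`, `sample_ids`, `class_names`.
#' @examples
#' x <- matrix(rnorm(12), 3, 4)
#' ds <- expression_dataset(x, labels = c("A", "A", "B"))
#' ds$class_names
#' @export
expression_dataset <- function(matrix, labels, gene_ids = NULL,
                               sample_ids = NULL, class_names = NULL) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  n <- nrow(matrix)
  p <- ncol(matrix)
  if (any(!is.finite(matrix))) {
    bad <- which(!is.finite(matrix), arr.ind = TRUE)[1L, ]
    stop("expression matrix contains a missing/non-finite value at sample ",
         bad[1L], ", gene ", bad[2L])
  }
  if (is.null(gene_ids)) gene_ids <- colnames(matrix)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(p))
  if (is.null(sample_ids)) sample_ids <- rownames(matrix)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(n))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != p) stop("gene_ids must have length n_genes")
  if (length(sample_ids) != n) stop("sample_ids must have length n_samples")
  if (anyDuplicated(gene_ids)) {
    stop("duplicate gene ids: ", paste(unique(gene_ids[duplicated(gene_ids)]),
                                       collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }

  if (is.factor(labels) || is.character(labels)) {
    lev <- if (is.null(class_names)) sort(unique(as.character(labels))) else class_names
    codes <- as.integer(factor(as.character(labels), levels = lev)) - 1L
    if (anyNA(codes)) stop("labels contain values outside class_names")
    labels <- codes
    class_names <- lev
  } else {
    labels <- as.integer(labels)
    if (is.null(class_names)) {
      class_names <- as.character(sort(unique(labels)))
    }
  }
  if (length(labels) != n) stop("labels must have length n_samples")
  C <- length(class_names)
  if (C < 1L) stop("at least one class required")
  if (any(labels < 0L | labels >= C)) stop("class codes must lie in [0, C)")
  if (!all((seq_len(C) - 1L) %in% labels)) {
    stop("every class code in [0, C) must occur at least once")
  }
  dimnames(matrix) <- list(sample_ids, gene_ids)
  structure(list(matrix = matrix, labels = labels, gene_ids = gene_ids,
                 sample_ids = sample_ids, class_names = class_names),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset: ", nrow(x$matrix), " samples x ", ncol(x$matrix),
      " genes, ", length(x$class_names), " classes (",
      paste(x$class_names, collapse = ", "), ")\n", sep = "")
  cat("class counts:", paste(tabulate(x$labels + 1L, length(x$class_names)),
                             collapse = "/"), "\n")
  invisible(x)
}

#' Number of samples / genes / classes
#' @param dataset An `expression_dataset`.
#' @return Integer count.
#' @export
n_samples <- function(dataset) nrow(dataset$matrix)

#' @rdname n_samples
#' @export
n_genes <- function(dataset) ncol(dataset$matrix)

#' @rdname n_samples
#' @export
n_classes <- function(dataset) length(dataset$class_names)

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Load a delimited expression matrix
#'
#' Reads a CSV/TSV expression table (delimiter auto-detected) into an
#' [expression_dataset()]. The canonical layout is samples in rows: the header
#' names an id column, then one column per gene, plus one label column
#' (default: a column named `"class"`, matched case-insensitively). Files in
#' the common genes-as-rows microarray layout are handled by
#' `orientation = "genes_by_samples"`, which transposes before parsing, so a
#' file and its transpose load to the identical dataset.
#'
#' @param path Path to the delimited file.
#' @param label Name of the label column (case-insensitive). Use `NULL` to
#'   fall back to the last column.
#' @param orientation `"samples_by_genes"` (default) or `"genes_by_samples"`.
#' @param normalization Normalization applied after loading: `"none"`
#'   (default), `"minmax"` or `"zscore"` (see [normalize_expression()]).
#' @return An [expression_dataset()].
#' @export
load_expression_matrix <- function(path,
                                   label = "class",
                                   orientation = c("samples_by_genes",
                                                   "genes_by_samples"),
                                   normalization = c("none", "minmax",
                                                     "zscore")) {
  orientation <- match.arg(orientation)
  normalization <- match.arg(normalization)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- detect_sep(path)
  raw <- as.matrix(utils::read.table(path, sep = sep, header = FALSE,
                                     colClasses = "character",
                                     check.names = FALSE,
                                     stringsAsFactors = FALSE,
                                     comment.char = ""))
  if (orientation == "genes_by_samples") raw <- t(raw)
  if (nrow(raw) < 2L || ncol(raw) < 3L) {
    stop("format error: need at least one sample row, one gene column and a ",
         "label column")
  }
  header <- trimws(raw[1L, ])
  body <- raw[-1L, , drop = FALSE]
  sample_ids <- trimws(body[, 1L])

  if (is.null(label)) {
    lab_col <- ncol(raw)
  } else {
    lab_col <- which(tolower(header) == tolower(label))
    if (length(lab_col) != 1L) {
      stop("format error: no label column named '", label, "' in ", path)
    }
  }
  gene_cols <- setdiff(seq_len(ncol(raw))[-1L], lab_col)
  gene_ids <- header[gene_cols]
  labels <- trimws(body[, lab_col])

  cells <- body[, gene_cols, drop = FALSE]
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(vals))
  if (length(bad)) {
    b <- bad[1L]
    r <- (b - 1L) %% nrow(cells) + 1L
    c_ <- (b - 1L) %/% nrow(cells) + 1L
    stop("parse error: non-numeric expression value '", cells[r, c_],
         "' for sample '", sample_ids[r], "', gene '", gene_ids[c_], "'")
  }
  mat <- matrix(vals, nrow = nrow(cells), ncol = ncol(cells))
  ds <- expression_dataset(mat, labels = labels, gene_ids = gene_ids,
                           sample_ids = sample_ids)
  if (normalization != "none") ds <- normalize_expression(ds, normalization)
  ds
}

#' Write an expression dataset as delimited text
#'
#' Inverse of [load_expression_matrix()] for the samples-by-genes layout.
#' Values are serialized with 17 significant digits so that load -> write ->
#' load round-trips bit-identically.
#'
#' @param dataset An [expression_dataset()].
#' @param path Output path.
#' @param sep Field delimiter (`","` or `"\t"`).
#' @export
write_expression_matrix <- function(dataset, path, sep = ",") {
  header <- c("sample_id", dataset$gene_ids, "class")
  vals <- matrix(sprintf("%.17g", dataset$matrix),
                 nrow = nrow(dataset$matrix))
  rows <- cbind(dataset$sample_ids, vals,
                dataset$class_names[dataset$labels + 1L])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = sep), con)
  writeLines(apply(rows, 1L, paste, collapse = sep), con)
  invisible(path)
}

#' Normalize expression values per gene
#'
#' `minmax` linearly rescales every gene to `[0, 1]` (a constant gene maps to
#' 0), matching the unit hypercube the optimizer searches in. `zscore` centres
#' each gene to mean 0 and scales to unit sample standard deviation (n-1
#' denominator; a constant gene maps to 0). Normalization is computed on the
#' full matrix, before any cross-validation split; this mild leakage is a
#' deliberate, documented simplification (see the methods vignette).
#'
#' @param dataset An [expression_dataset()].
#' @param method `"minmax"`, `"zscore"` or `"none"`.
#' @return A new [expression_dataset()] with the same labels and identifiers.
#' @export
normalize_expression <- function(dataset,
                                 method = c("minmax", "zscore", "none")) {
  method <- match.arg(method)
  if (method == "none") return(dataset)
  if (nrow(dataset$matrix) < 2L) stop("need at least 2 samples to normalize")
  x <- dataset$matrix
  if (method == "minmax") {
    lo <- apply(x, 2L, min)
    hi <- apply(x, 2L, max)
    rng <- hi - lo
    rng[rng == 0] <- 1
    x <- sweep(sweep(x, 2L, lo, "-"), 2L, rng, "/")
    x[, hi == lo] <- 0
  } else {
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    const <- sdv == 0
    sdv[const] <- 1
    x <- sweep(sweep(x, 2L, mu, "-"), 2L, sdv, "/")
    x[, const] <- 0
  }
  expression_dataset(x, dataset$labels, dataset$gene_ids, dataset$sample_ids,
                     dataset$class_names)
}

#' Write a gene-selection report
#'
#' Serializes a [selection_result] to JSON: the selected gene identifiers and
#' indices, final fitness, fitness trace, evaluation count, seed and the full
#' configuration echo. Numbers are written at full precision so the report can
#' be re-loaded into an equivalent result with [read_selection_report()].
#'
#' @param result A `selection_result` (see [run_cssmo()]).
#' @param path Output path for the JSON report.
#' @export
write_selection_report <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  if (!any(result$best_mask)) stop("selection result has an empty gene mask")
  obj <- list(
    format = "cssmo-selection/1",
    algorithm = result$algorithm,
    seed = result$seed,
    best_fitness = result$best_fitness,
    n_genes = length(result$best_mask),
    selected_idx = which(result$best_mask),
    selected_genes = result$selected_genes,
    subset_size = sum(result$best_mask),
    fitness_trace = result$fitness_trace,
    evaluations = result$evaluations,
    config = unclass(result$config),
    pool = list(selected_idx = result$pool$selected_idx,
                relevance = result$pool$relevance,
                score_at_selection = result$pool$score_at_selection,
                scheme = result$pool$scheme,
                gene_ids = result$pool$gene_ids)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a gene-selection report
#'
#' @param path Path to a JSON report written by [write_selection_report()].
#' @return A `selection_result` equivalent to the one written.
#' @export
read_selection_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "cssmo-selection/1")) {
    stop("not a cssmo selection report: ", path)
  }
  mask <- logical(obj$n_genes)
  mask[obj$selected_idx] <- TRUE
  pool <- structure(list(selected_idx = as.integer(obj$pool$selected_idx),
                         relevance = as.numeric(obj$pool$relevance),
                         score_at_selection =
                           as.numeric(obj$pool$score_at_selection),
                         scheme = obj$pool$scheme,
                         gene_ids = obj$pool$gene_ids),
                    class = "gene_pool")
  cfg <- do.call(cssmo_config, obj$config)
  new_selection_result(best_mask = mask, best_fitness = obj$best_fitness,
                       fitness_trace = as.numeric(obj$fitness_trace),
                       evaluations = as.integer(obj$evaluations),
                       config = cfg, pool = pool, seed = as.integer(obj$seed),
                       algorithm = obj$algorithm,
                       selected_genes = obj$selected_genes)
}
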