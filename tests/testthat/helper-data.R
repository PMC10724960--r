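# Small builders shared across test files. Everything is generated in code;
# no fixture files.

toy_csv <- function(path, sep = ",") {
  lines <- c(paste(c("sample_id", paste0("g", 1:4), "class"), collapse = sep),
             paste(c("s1", "1.5", "2", "3", "4", "A"), collapse = sep),
             paste(c("s2", "1", "2.5", "3", "4", "A"), collapse = sep),
             paste(c("s3", "9", "8", "7", "6", "B"), collapse = sep))
  writeLines(lines, path)
  path
}

# deterministic mask-level fitness: weighted count of selected coordinates,
# scaled into [0, 100]
make_linear_fitness <- function(d, seed = 1) {
  set.seed(seed)
  w <- runif(d)
  w <- 100 * w / sum(w)
  function(mask) sum(w[mask])
}

tiny_pool <- function(d, p = d) {
  structure(list(selected_idx = seq_len(d),
                 relevance = c(rev(seq_len(d)) / d, numeric(p - d)),
                 score_at_selection = rev(seq_len(d)) / d,
                 scheme = "MID",
                 gene_ids = paste0("g", seq_len(d))),
            class = "gene_pool")
}

tiny_config <- function(...) {
  defaults <- list(swarm_size = 8L, n_nests = 8L, n_generations = 5L,
                   n_eggs = 2L, global_leader_limit = 2L,
                   local_leader_limit = 3L, n_runs = 2L, seed = 1L)
  do.call(cssmo_config, utils::modifyList(defaults, list(...)))
}

# plug-in MI by direct summation over the joint table -- the independent
# oracle used against the package implementation
mi_oracle <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pxy <- tab[i, j] / n
      if (pxy > 0) {
        mi <- mi + pxy * log(pxy / (sum(tab[i, ]) / n * sum(tab[, j]) / n))
      }
    }
  }
  mi
}

# exhaustive per-step mRMR re-scoring, independent of the greedy
# implementation: every candidate's score is recomputed by direct summation
# at every step
mrmr_oracle <- function(codes, labels, k, scheme = "MID") {
  p <- ncol(codes)
  rel <- vapply(seq_len(p), function(j) mi_oracle(codes[, j], labels),
                numeric(1))
  selected <- integer(0)
  for (t in seq_len(k)) {
    cand <- setdiff(seq_len(p), selected)
    score <- vapply(cand, function(j) {
      if (!length(selected)) return(rel[j])
      red <- mean(vapply(selected, function(s) {
        mi_oracle(codes[, j], codes[, s])
      }, numeric(1)))
      if (scheme == "MID") rel[j] - red else rel[j] / max(red, 1e-12)
    }, numeric(1))
    selected <- c(selected, cand[which.max(score)])
  }
  selected
}
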