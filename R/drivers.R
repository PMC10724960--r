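finalize_result <- function(swarm, trace, cache, config, pool, algorithm,
                            fitness_fn = NULL) {
  pool_mask <- binarize(swarm$gl_pos, config$binarize_threshold)
  p <- length(pool$relevance)
  best_mask <- logical(p)
  best_mask[pool$selected_idx[pool_mask]] <- TRUE
  genes <- if (!is.null(pool$gene_ids)) pool$gene_ids[pool_mask]
  new_selection_result(best_mask = best_mask, best_fitness = swarm$gl_fit,
                       fitness_trace = trace, evaluations = cache$evals,
                       config = config, pool = pool, seed = config$seed,
                       algorithm = algorithm, selected_genes = genes)
}

#' Run the hybrid cuckoo-search / spider-monkey gene selector
#'
#' The main loop. A swarm of `swarm_size` continuous positions in
#' `[0, 1]^d` (`d` = pool size) is initialized uniformly; the global leader is
#' picked greedily and the initial local leader is refined by cuckoo search
#' (the hybrid replaces the spider-monkey local mechanism with the cuckoo
#' one). Each generation then applies: local leader phase with greedy
#' acceptance, selection probabilities, global leader phase, greedy leader
#' updates, local leader decision via cuckoo search, and the global leader
#' decision (group fission/fusion). The egg-discovery probability follows
#' [pa_schedule()]. The run stops after `n_generations` or as soon as the
#' fitness reaches 100 (accuracy cannot exceed it). The fitness trace records
#' the global leader per generation and is non-decreasing by construction
#' (elitism).
#'
#' @param dataset An [expression_dataset()]. May be `NULL` when `fitness_fn`
#'   is supplied directly.
#' @param pool A `gene_pool` restricting the search space.
#' @param config A [cssmo_config()].
#' @param fitness_fn Optional mask-level fitness (default: 1-NN LOOCV via
#'   [make_knn_fitness()]).
#' @return A `selection_result`: `best_mask` over the original gene space,
#'   `best_fitness`, `fitness_trace`, `evaluations` (distinct masks
#'   evaluated), `config`, `pool`, `seed`.
#' @export
run_cssmo <- function(dataset, pool, config, fitness_fn = NULL) {
  stopifnot(inherits(pool, "gene_pool"), inherits(config, "cssmo_config"))
  d <- length(pool$selected_idx)
  if (d < 1L) stop("gene pool is empty")
  if (is.null(fitness_fn)) fitness_fn <- make_knn_fitness(dataset, pool)
  set.seed(config$seed)
  cache <- new_fitness_cache()
  swarm <- init_swarm(config$swarm_size, d, config, cache, fitness_fn)

  # hybrid initialization: cuckoo search selects/refines the local leader
  pa0 <- pa_schedule(0, config$n_generations, config$pa_min, config$pa_max)
  res <- cuckoo_local_search(swarm$pos, swarm$fit, swarm$ll_pos[[1L]],
                             swarm$ll_fit[1L], fitness_fn, cache, config, pa0)
  swarm$pos <- res$positions
  swarm$fit <- res$fits
  swarm$ll_pos[[1L]] <- res$leader_pos
  swarm$ll_fit[1L] <- res$leader_fit
  swarm <- promote_global(swarm, res$leader_pos, res$leader_fit)

  trace <- numeric(0)
  for (gen in seq_len(config$n_generations)) {
    pa <- pa_schedule(gen, config$n_generations, config$pa_min,
                      config$pa_max)
    swarm <- local_leader_phase(swarm, config, cache, fitness_fn)
    swarm <- global_leader_phase(swarm, config, cache, fitness_fn)
    swarm <- update_leaders(swarm)
    swarm <- local_leader_decision(swarm, config, cache, fitness_fn, pa)
    swarm <- global_leader_decision(swarm, config)
    trace[gen] <- swarm$gl_fit
    if (swarm$gl_fit >= 100) break
  }
  finalize_result(swarm, trace, cache, config, pool, "cssmo")
}

run_smo <- function(dataset, pool, config, fitness_fn = NULL) {
  d <- length(pool$selected_idx)
  if (d < 1L) stop("gene pool is empty")
  if (is.null(fitness_fn)) fitness_fn <- make_knn_fitness(dataset, pool)
  set.seed(config$seed)
  cache <- new_fitness_cache()
  swarm <- init_swarm(config$swarm_size, d, config, cache, fitness_fn)
  trace <- numeric(0)
  for (gen in seq_len(config$n_generations)) {
    swarm <- local_leader_phase(swarm, config, cache, fitness_fn)
    swarm <- global_leader_phase(swarm, config, cache, fitness_fn)
    swarm <- update_leaders(swarm)
    swarm <- local_leader_decision(swarm, config, cache, fitness_fn,
                                   pa = 0, classic = TRUE)
    swarm <- global_leader_decision(swarm, config)
    trace[gen] <- swarm$gl_fit
    if (swarm$gl_fit >= 100) break
  }
  finalize_result(swarm, trace, cache, config, pool, "smo")
}

run_csa <- function(dataset, pool, config, fitness_fn = NULL) {
  d <- length(pool$selected_idx)
  if (d < 1L) stop("gene pool is empty")
  if (is.null(fitness_fn)) fitness_fn <- make_knn_fitness(dataset, pool)
  set.seed(config$seed)
  cache <- new_fitness_cache()
  n <- config$n_nests
  pos <- matrix(stats::runif(n * d), n, d)
  fit <- vapply(seq_len(n), function(i) {
    position_fitness(cache, pos[i, ], config, fitness_fn)
  }, numeric(1))
  best <- which.max(fit)
  gl_pos <- pos[best, ]
  gl_fit <- fit[best]
  trace <- numeric(0)
  for (gen in seq_len(config$n_generations)) {
    pa <- pa_schedule(gen, config$n_generations, config$pa_min,
                      config$pa_max)
    for (i in seq_len(n)) {
      egg <- generate_cuckoo(pos[i, ], gl_pos, config$levy_beta,
                             config$alpha_step)
      f <- position_fitness(cache, egg, config, fitness_fn)
      j <- sample.int(n, 1L)
      if (f > fit[j]) {
        pos[j, ] <- egg
        fit[j] <- f
      }
      if (f > gl_fit) {
        gl_pos <- egg
        gl_fit <- f
      }
    }
    ab <- abandon_nests(pos, pa, best = which.max(fit))
    pos <- ab$positions
    for (i in which(ab$abandoned)) {
      fit[i] <- position_fitness(cache, pos[i, ], config, fitness_fn)
      if (fit[i] > gl_fit) {
        gl_pos <- pos[i, ]
        gl_fit <- fit[i]
      }
    }
    trace[gen] <- gl_fit
    if (gl_fit >= 100) break
  }
  swarm <- list(gl_pos = gl_pos, gl_fit = gl_fit)
  finalize_result(swarm, trace, cache, config, pool, "csa")
}

#' Run a single-algorithm baseline
#'
#' `"csa"` is pure cuckoo search (nests, Levy-flight eggs guided by the global
#' best, abandonment) and `"smo"` the classic six-phase spider-monkey
#' optimizer with random-reinitialization local leader decision. Both satisfy
#' the same elitism and bounds invariants as the hybrid and share its
#' encoding, fitness and termination rules, so their traces are directly
#' comparable.
#'
#' @param algorithm `"csa"` or `"smo"`.
#' @inheritParams run_cssmo
#' @return A `selection_result`.
#' @export
run_baseline <- function(algorithm = c("csa", "smo"), dataset, pool, config,
                         fitness_fn = NULL) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
         csa = run_csa(dataset, pool, config, fitness_fn),
         smo = run_smo(dataset, pool, config, fitness_fn))
}

#' Repeat a selector over sequential seeds
#'
#' Runs the chosen algorithm `n_runs` times with seeds
#' `config$seed + 0 .. n_runs - 1` and summarizes the per-run best fitness:
#' mean, sample standard deviation (n-1 denominator; 0 for a single run), and
#' the best overall result.
#'
#' @inheritParams run_cssmo
#' @param n_runs Number of repeats (default `config$n_runs`).
#' @param algorithm `"cssmo"`, `"csa"` or `"smo"`.
#' @return An object of class `run_summary`: `per_run_best_fitness`, `mean`,
#'   `sd`, `best` (a `selection_result`), `algorithm`.
#' @export
run_many <- function(dataset, pool, config, n_runs = config$n_runs,
                     algorithm = c("cssmo", "csa", "smo"),
                     fitness_fn = NULL) {
  algorithm <- match.arg(algorithm)
  if (n_runs < 1L) stop("n_runs must be >= 1")
  runner <- switch(algorithm, cssmo = run_cssmo, csa = run_csa,
                   smo = run_smo)
  results <- lapply(seq_len(n_runs) - 1L, function(offset) {
    cfg <- config
    cfg$seed <- config$seed + offset
    runner(dataset, pool, cfg, fitness_fn)
  })
  per_run <- vapply(results, function(r) r$best_fitness, numeric(1))
  structure(list(per_run_best_fitness = per_run,
                 mean = mean(per_run),
                 sd = if (length(per_run) > 1L) stats::sd(per_run) else 0,
                 best = results[[which.max(per_run)]],
                 algorithm = algorithm),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat("run_summary [", x$algorithm, "]: ",
      length(x$per_run_best_fitness), " runs, mean best fitness ",
      format(x$mean, digits = 6), " (sd ", format(x$sd, digits = 4), ")\n",
      sep = "")
  invisible(x)
}

#' The bundled planted-recovery benchmark
#'
#' A scaled-down benchmark used throughout the package's own validation:
#' 60 samples x 500 genes with 5 informative genes at effect size 2 (in noise
#' standard deviations) and 4 redundant copies each; min-max normalization;
#' an mRMR pool of 50; a swarm of 20 searched for 30 generations with 1-NN
#' LOOCV fitness. The leader limits are scaled so the decision phases engage
#' within 30 generations (see the methods vignette).
#'
#' @param seed Integer seed controlling both data generation and the search.
#' @param algorithm `"cssmo"`, `"csa"` or `"smo"`.
#' @param pool_size mRMR pool size.
#' @return A list: `result` (a `selection_result`), `recovery` (from
#'   [planted_recovery_score()]), `truth`, `pool`, `dataset`.
#' @export
run_recovery_benchmark <- function(seed, algorithm = "cssmo",
                                   pool_size = 50L) {
  spec <- synthetic_spec(n_samples = 60L, n_genes = 500L, n_classes = 2L,
                         n_informative = 5L,
                         n_redundant_per_informative = 4L,
                         effect_size = 2, redundancy_corr = 0.8,
                         noise_sd = 1, seed = seed)
  gen <- generate_synthetic_dataset(spec)
  ds <- normalize_expression(gen$dataset, "minmax")
  pool <- mrmr_filter(ds, k = pool_size)
  config <- recovery_benchmark_config(seed)
  runner <- switch(algorithm, cssmo = run_cssmo, csa = run_csa,
                   smo = run_smo, stop("unknown algorithm: ", algorithm))
  result <- runner(ds, pool, config)
  list(result = result,
       recovery = planted_recovery_score(result$best_mask, gen$truth),
       truth = gen$truth, pool = pool, dataset = ds)
}

#' @rdname run_recovery_benchmark
#' @export
recovery_benchmark_config <- function(seed = 1L) {
  cssmo_config(swarm_size = 20L, n_nests = 20L, n_generations = 30L,
               global_leader_limit = 8L, local_leader_limit = 15L,
               n_runs = 10L, seed = seed)
}
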