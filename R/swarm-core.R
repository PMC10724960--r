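#' Control parameters for the hybrid optimizer
#'
#' Collects every control parameter of the hybrid cuckoo-search /
#' spider-monkey optimizer. The defaults are the full-scale study settings:
#' population 50, 10 cuckoo rounds per local search, 200 generations, egg
#' discovery probability ramped from 0.3 to 0.5, Levy step size 1, at most 5
#' groups, global leader limit 50, local leader limit 1500, 100 runs. The
#' perturbation rate `pr` (per-dimension update probability in the local
#' leader phase) defaults to 0.3 and the Levy index `beta` to 1.5; both are
#' standard values, stated in the methods vignette.
#'
#' @param n_nests Cuckoo-search population size (nests).
#' @param n_eggs Cuckoo rounds per local-search invocation (each member
#'   proposes one egg per round).
#' @param n_generations Generation cap (termination criterion, together with
#'   early stop at fitness 100).
#' @param pa_min,pa_max Minimum / maximum probability of an egg being
#'   discovered (nest abandoned); interpolated linearly over generations by
#'   [pa_schedule()].
#' @param alpha_step Levy flight step-size scale.
#' @param swarm_size Spider-monkey swarm size N.
#' @param max_groups Maximum number of groups MG.
#' @param global_leader_limit,local_leader_limit Stagnation thresholds that
#'   trigger the global / local leader decision phases.
#' @param n_runs Number of independent repeats used by [run_many()].
#' @param pr Perturbation rate in `(0, 1)`.
#' @param levy_beta Levy stability index in `(1, 2]`.
#' @param binarize_threshold Coordinate threshold decoding a position into a
#'   gene mask, in `(0, 1)`.
#' @param glp_all_dims If `TRUE` the global leader phase updates every
#'   dimension of a selected member instead of one (ablation switch).
#' @param seed Integer seed; a run consumes a single seeded RNG stream in a
#'   fixed order, so results are bit-reproducible.
#' @return An object of class `cssmo_config`.
#' @export
cssmo_config <- function(n_nests = 50L, n_eggs = 10L, n_generations = 200L,
                         pa_min = 0.3, pa_max = 0.5, alpha_step = 1,
                         swarm_size = 50L, max_groups = 5L,
                         global_leader_limit = 50L,
                         local_leader_limit = 1500L, n_runs = 100L,
                         pr = 0.3, levy_beta = 1.5,
                         binarize_threshold = 0.5, glp_all_dims = FALSE,
                         seed = 1L) {
  cfg <- list(n_nests = as.integer(n_nests), n_eggs = as.integer(n_eggs),
              n_generations = as.integer(n_generations), pa_min = pa_min,
              pa_max = pa_max, alpha_step = alpha_step,
              swarm_size = as.integer(swarm_size),
              max_groups = as.integer(max_groups),
              global_leader_limit = as.integer(global_leader_limit),
              local_leader_limit = as.integer(local_leader_limit),
              n_runs = as.integer(n_runs), pr = pr, levy_beta = levy_beta,
              binarize_threshold = binarize_threshold,
              glp_all_dims = isTRUE(glp_all_dims), seed = as.integer(seed))
  with(cfg, {
    if (!(pa_min >= 0 && pa_min <= pa_max && pa_max <= 1)) {
      stop("need 0 <= pa_min <= pa_max <= 1")
    }
    if (pr <= 0 || pr >= 1) stop("pr must lie in (0, 1)")
    if (binarize_threshold <= 0 || binarize_threshold >= 1) {
      stop("binarize_threshold must lie in (0, 1)")
    }
    if (levy_beta <= 1 || levy_beta > 2) stop("levy_beta must lie in (1, 2]")
    counts <- c(n_nests, n_eggs, n_generations, swarm_size, max_groups,
                global_leader_limit, local_leader_limit, n_runs)
    if (any(counts < 1L)) stop("all counts must be positive")
    if (alpha_step < 0) stop("alpha_step must be >= 0")
  })
  structure(cfg, class = "cssmo_config")
}

#' @export
print.cssmo_config <- function(x, ...) {
  cat("cssmo_config:\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

clip01 <- function(x) pmin(1, pmax(0, x))

#' Decode a continuous position into a gene mask
#'
#' A pool-local coordinate selects its gene iff it is strictly greater than
#' the threshold. An empty decode is repaired deterministically by selecting
#' the pool's first (top-ranked mRMR) gene, so the downstream classifier
#' always sees a non-empty subset.
#'
#' @param coords Numeric vector in `[0, 1]^d`.
#' @param threshold Threshold in `(0, 1)`; default 0.5.
#' @return Logical mask of length `d`, guaranteed non-empty.
#' @export
binarize <- function(coords, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  mask <- coords > threshold
  if (!any(mask)) mask[1L] <- TRUE
  mask
}

#' Member selection probabilities for the global leader phase
#'
#' The standard spider-monkey rule
#' `prob_i = 0.9 * fitness_i / max(fitness) + 0.1`: probabilities lie in
#' `[0.1, 1.0]` and the fittest member gets exactly 1.0. If every fitness is
#' zero the floor 0.1 is returned for all members.
#'
#' @param fitness Non-negative fitness vector.
#' @return Probability vector in `[0.1, 1.0]`.
#' @export
compute_selection_probability <- function(fitness) {
  if (any(fitness < 0)) stop("fitness values must be non-negative")
  m <- max(fitness)
  if (m == 0) return(rep(0.1, length(fitness)))
  # ratio first so the maximum maps to exactly 1.0
  pmin(1, pmax(0.1, 0.9 * (fitness / m) + 0.1))
}

#' Create a fitness cache
#'
#' Fitness depends only on the decoded gene mask, so two positions decoding to
#' the same subset share one classifier evaluation. The cache counts distinct
#' evaluations (`cache$evals`), which is the optimizer's real cost.
#'
#' @return An environment with fields `map` (mask-keyed store) and `evals`.
#' @export
new_fitness_cache <- function() {
  e <- new.env(parent = emptyenv())
  e$map <- new.env(hash = TRUE, parent = emptyenv())
  e$evals <- 0L
  e
}

#' Evaluate a gene mask through the cache
#'
#' @param cache A cache from [new_fitness_cache()].
#' @param mask Logical gene mask (pool-local).
#' @param fitness_fn Function mapping a non-empty mask to a fitness in
#'   `[0, 100]`.
#' @return The (possibly cached) fitness value.
#' @export
mask_fitness <- function(cache, mask, fitness_fn) {
  key <- paste(which(mask), collapse = ".")
  hit <- cache$map[[key]]
  if (!is.null(hit)) return(hit)
  f <- fitness_fn(mask)
  cache$map[[key]] <- f
  cache$evals <- cache$evals + 1L
  f
}

position_fitness <- function(cache, coords, config, fitness_fn) {
  mask_fitness(cache, binarize(coords, config$binarize_threshold), fitness_fn)
}

#' Initialize a swarm
#'
#' Positions are drawn uniformly in `[0, 1]^d`; the swarm starts as a single
#' group whose local leader and the global leader are the fittest member
#' (greedy selection). Groups emerge later through the global leader decision.
#'
#' @param n Swarm size.
#' @param d Dimension (pool size).
#' @param config A [cssmo_config()].
#' @param cache Fitness cache ([new_fitness_cache()]).
#' @param fitness_fn Mask-level fitness function.
#' @return A swarm: positions, fitness, group assignment, local/global
#'   leaders with stagnation counters.
#' @export
init_swarm <- function(n, d, config, cache, fitness_fn) {
  pos <- matrix(stats::runif(n * d), n, d)
  fit <- vapply(seq_len(n), function(i) {
    position_fitness(cache, pos[i, ], config, fitness_fn)
  }, numeric(1))
  best <- which.max(fit)
  list(pos = pos, fit = fit,
       group_of = rep(1L, n), n_groups = 1L,
       ll_pos = list(pos[best, ]), ll_fit = fit[best], ll_count = 0L,
       gl_pos = pos[best, ], gl_fit = fit[best], gl_count = 0L)
}

# Fold an improvement into the elitist global leader record.
promote_global <- function(swarm, pos, fit) {
  if (fit > swarm$gl_fit) {
    swarm$gl_pos <- pos
    swarm$gl_fit <- fit
  }
  swarm
}

new_selection_result <- function(best_mask, best_fitness, fitness_trace,
                                 evaluations, config, pool, seed, algorithm,
                                 selected_genes = NULL) {
  structure(list(best_mask = best_mask, best_fitness = best_fitness,
                 fitness_trace = fitness_trace, evaluations = evaluations,
                 config = config, pool = pool, seed = seed,
                 algorithm = algorithm,
                 selected_genes = selected_genes),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("selection_result [", x$algorithm, "]: ", sum(x$best_mask),
      " genes, fitness ", format(x$best_fitness, digits = 6),
      " after ", length(x$fitness_trace), " generations (",
      x$evaluations, " classifier evaluations, seed ", x$seed, ")\n",
      sep = "")
  if (!is.null(x$selected_genes)) {
    show <- utils::head(x$selected_genes, 10L)
    cat("genes:", paste(show, collapse = ", "),
        if (sum(x$best_mask) > 10L) "..." else "", "\n")
  }
  invisible(x)
}
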