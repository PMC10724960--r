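#' Local leader phase
#'
#' Every member updates each dimension independently with probability `pr`
#' (the perturbation rate) using its own experience, the group's local leader
#' and a random group-mate:
#' `new_j = x_j + U(0,1) (LL_j - x_j) + U(-1,1) (x_rj - x_j)`.
#' In a singleton group the group-mate term is skipped. Proposals are clipped
#' to `[0, 1]` and accepted greedily: a member only moves to a strictly
#' fitter position.
#'
#' @param swarm A swarm from [init_swarm()].
#' @param config A [cssmo_config()] (supplies `pr` and the threshold).
#' @param cache Fitness cache.
#' @param fitness_fn Mask-level fitness function.
#' @return The updated swarm.
#' @export
local_leader_phase <- function(swarm, config, cache, fitness_fn) {
  n <- nrow(swarm$pos)
  d <- ncol(swarm$pos)
  for (i in seq_len(n)) {
    upd <- stats::runif(d) < config$pr
    if (!any(upd)) next
    g <- swarm$group_of[i]
    cur <- swarm$pos[i, ]
    ll <- swarm$ll_pos[[g]]
    delta <- stats::runif(d) * (ll - cur)
    mates <- setdiff(which(swarm$group_of == g), i)
    if (length(mates)) {
      r <- if (length(mates) == 1L) mates else sample(mates, 1L)
      delta <- delta + stats::runif(d, -1, 1) * (swarm$pos[r, ] - cur)
    }
    new <- cur
    new[upd] <- cur[upd] + delta[upd]
    new <- clip01(new)
    f <- position_fitness(cache, new, config, fitness_fn)
    if (f > swarm$fit[i]) {
      swarm$pos[i, ] <- new
      swarm$fit[i] <- f
      swarm <- promote_global(swarm, new, f)
    }
  }
  swarm
}

#' Global leader phase
#'
#' Members are selected with probability `prob_i`
#' ([compute_selection_probability()]); a selected member updates one
#' uniformly chosen dimension toward the global leader with a random
#' group-mate term, clipped and accepted greedily. With
#' `config$glp_all_dims = TRUE` every dimension is updated instead (ablation
#' variant).
#'
#' @inheritParams local_leader_phase
#' @return The updated swarm, with the `prob` vector stored on it.
#' @export
global_leader_phase <- function(swarm, config, cache, fitness_fn) {
  n <- nrow(swarm$pos)
  d <- ncol(swarm$pos)
  prob <- compute_selection_probability(swarm$fit)
  for (i in seq_len(n)) {
    if (stats::runif(1) >= prob[i]) next
    g <- swarm$group_of[i]
    cur <- swarm$pos[i, ]
    dims <- if (config$glp_all_dims) seq_len(d) else sample.int(d, 1L)
    mates <- setdiff(which(swarm$group_of == g), i)
    new <- cur
    for (j in dims) {
      term <- stats::runif(1) * (swarm$gl_pos[j] - cur[j])
      if (length(mates)) {
        r <- if (length(mates) == 1L) mates else sample(mates, 1L)
        term <- term + stats::runif(1, -1, 1) * (swarm$pos[r, j] - cur[j])
      }
      new[j] <- cur[j] + term
    }
    new <- clip01(new)
    f <- position_fitness(cache, new, config, fitness_fn)
    if (f > swarm$fit[i]) {
      swarm$pos[i, ] <- new
      swarm$fit[i] <- f
      swarm <- promote_global(swarm, new, f)
    }
  }
  swarm$prob <- prob
  swarm
}

#' Leader learning (greedy leader updates)
#'
#' Each group's local leader is replaced by the group's best member only on a
#' strict improvement; otherwise the group's stagnation counter increments.
#' The global leader is handled the same way. Ties count as non-improvement,
#' which lets the counters drive the decision phases.
#'
#' @param swarm A swarm.
#' @return The updated swarm.
#' @export
update_leaders <- function(swarm) {
  for (g in seq_len(swarm$n_groups)) {
    members <- which(swarm$group_of == g)
    bi <- members[which.max(swarm$fit[members])]
    if (swarm$fit[bi] > swarm$ll_fit[g]) {
      swarm$ll_pos[[g]] <- swarm$pos[bi, ]
      swarm$ll_fit[g] <- swarm$fit[bi]
      swarm$ll_count[g] <- 0L
    } else {
      swarm$ll_count[g] <- swarm$ll_count[g] + 1L
    }
  }
  bi <- which.max(swarm$fit)
  if (swarm$fit[bi] > swarm$gl_fit) {
    swarm$gl_pos <- swarm$pos[bi, ]
    swarm$gl_fit <- swarm$fit[bi]
    swarm$gl_count <- 0L
  } else {
    swarm$gl_count <- swarm$gl_count + 1L
  }
  swarm
}

#' Local leader decision via cuckoo search
#'
#' The hybrid's signature move: any group whose local leader has stagnated
#' past `local_leader_limit` is sent foraging with [cuckoo_local_search()]
#' (guided by its local leader), its counter is reset and the refined leader
#' installed. An improvement found there is folded into the elitist global
#' leader record. Setting `classic = TRUE` gives the classic spider-monkey
#' decision instead (used by the standalone baseline): the stagnant group's
#' members are re-randomized uniformly.
#'
#' @inheritParams local_leader_phase
#' @param pa Abandonment probability passed to the cuckoo rounds.
#' @param classic Use the classic random-reinitialization decision instead of
#'   cuckoo search.
#' @return The updated swarm.
#' @export
local_leader_decision <- function(swarm, config, cache, fitness_fn, pa,
                                  classic = FALSE) {
  for (g in seq_len(swarm$n_groups)) {
    if (swarm$ll_count[g] <= config$local_leader_limit) next
    idx <- which(swarm$group_of == g)
    if (classic) {
      for (i in idx) {
        swarm$pos[i, ] <- stats::runif(ncol(swarm$pos))
        swarm$fit[i] <- position_fitness(cache, swarm$pos[i, ], config,
                                         fitness_fn)
        swarm <- promote_global(swarm, swarm$pos[i, ], swarm$fit[i])
      }
      bi <- idx[which.max(swarm$fit[idx])]
      if (swarm$fit[bi] > swarm$ll_fit[g]) {
        swarm$ll_pos[[g]] <- swarm$pos[bi, ]
        swarm$ll_fit[g] <- swarm$fit[bi]
      }
    } else {
      res <- cuckoo_local_search(swarm$pos[idx, , drop = FALSE],
                                 swarm$fit[idx],
                                 swarm$ll_pos[[g]], swarm$ll_fit[g],
                                 fitness_fn, cache, config, pa)
      swarm$pos[idx, ] <- res$positions
      swarm$fit[idx] <- res$fits
      swarm$ll_pos[[g]] <- res$leader_pos
      swarm$ll_fit[g] <- res$leader_fit
      swarm <- promote_global(swarm, res$leader_pos, res$leader_fit)
    }
    swarm$ll_count[g] <- 0L
  }
  swarm
}

repartition <- function(swarm, n_groups) {
  n <- nrow(swarm$pos)
  base <- n %/% n_groups
  sizes <- rep(base, n_groups) + (seq_len(n_groups) <= n %% n_groups)
  swarm$group_of <- rep.int(seq_len(n_groups), sizes)
  swarm$n_groups <- as.integer(n_groups)
  swarm$ll_pos <- vector("list", n_groups)
  swarm$ll_fit <- numeric(n_groups)
  swarm$ll_count <- integer(n_groups)
  for (g in seq_len(n_groups)) {
    members <- which(swarm$group_of == g)
    bi <- members[which.max(swarm$fit[members])]
    swarm$ll_pos[[g]] <- swarm$pos[bi, ]
    swarm$ll_fit[g] <- swarm$fit[bi]
  }
  swarm
}

#' Global leader decision (group fission / fusion)
#'
#' When the global leader has stagnated past `global_leader_limit` the swarm
#' splits: the group count grows by one (members repartitioned contiguously
#' into near-equal groups) until `max_groups` is reached, at which point all
#' groups fuse back into one. Local leaders are re-learned from the new
#' groups' best members and the global counter resets.
#'
#' @param swarm A swarm.
#' @param config A [cssmo_config()].
#' @return The updated swarm.
#' @export
global_leader_decision <- function(swarm, config) {
  if (swarm$gl_count <= config$global_leader_limit) return(swarm)
  ng <- if (swarm$n_groups < config$max_groups) swarm$n_groups + 1L else 1L
  swarm <- repartition(swarm, ng)
  swarm$gl_count <- 0L
  swarm
}
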