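#' Mantegna scale for Levy flights
#'
#' Closed-form standard deviation of the Gaussian numerator in Mantegna's
#' algorithm:
#' `sigma_u(beta) = [ Gamma(1+beta) sin(pi beta / 2) /
#'                    ( Gamma((1+beta)/2) beta 2^((beta-1)/2) ) ]^(1/beta)`.
#' At the default `beta = 1.5`, `sigma_u` is about 0.6966.
#'
#' @param beta Stability index in `(1, 2]`.
#' @return The scale `sigma_u`.
#' @export
levy_sigma <- function(beta) {
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Draw a heavy-tailed Levy flight step
#'
#' Mantegna's method: `step_j = alpha_step * u_j / |v_j|^(1/beta)` with
#' `u ~ Normal(0, sigma_u^2)` and `v ~ Normal(0, 1)`. The resulting steps are
#' heavy-tailed, producing the occasional long jumps that let cuckoo search
#' escape local optima.
#'
#' @param d Dimension.
#' @param beta Stability index in `(1, 2]`.
#' @param alpha_step Step-size scale (0 gives a zero vector).
#' @return Numeric vector of length `d`.
#' @export
levy_step <- function(d, beta = 1.5, alpha_step = 1) {
  if (d < 1L) stop("d must be >= 1")
  u <- stats::rnorm(d, sd = levy_sigma(beta))
  v <- stats::rnorm(d)
  alpha_step * u / abs(v)^(1 / beta)
}

#' Propose a cuckoo egg from a current position
#'
#' `new = current + levy_step * (current - guide)`, clipped to `[0, 1]^d`.
#' The guide is the group's local leader in hybrid use and the global best in
#' the standalone cuckoo-search driver; a position sitting exactly on its
#' guide does not move.
#'
#' @param current,guide Positions of equal dimension in `[0, 1]^d`.
#' @param beta,alpha_step Levy parameters, see [levy_step()].
#' @return A new position in `[0, 1]^d`.
#' @export
generate_cuckoo <- function(current, guide, beta = 1.5, alpha_step = 1) {
  if (length(current) != length(guide)) {
    stop("current and guide must have the same dimension")
  }
  clip01(current + levy_step(length(current), beta, alpha_step) *
           (current - guide))
}

#' Abandon discovered nests
#'
#' Each non-best position is independently re-randomized uniformly in
#' `[0, 1]^d` with probability `pa`; the best nest is never abandoned
#' (elitism).
#'
#' @param positions Matrix of positions (rows).
#' @param pa Abandonment probability in `[0, 1]`.
#' @param best Row index of the protected best nest (`NULL` protects none).
#' @return List: `positions` (updated matrix) and `abandoned` (logical per
#'   row).
#' @export
abandon_nests <- function(positions, pa, best = NULL) {
  if (pa < 0 || pa > 1) stop("pa must lie in [0, 1]")
  n <- nrow(positions)
  abandoned <- stats::runif(n) < pa
  if (!is.null(best)) abandoned[best] <- FALSE
  for (i in which(abandoned)) {
    positions[i, ] <- stats::runif(ncol(positions))
  }
  list(positions = positions, abandoned = abandoned)
}

#' Egg-discovery probability schedule
#'
#' Linear ramp from `pa_min` at generation 0 to `pa_max` at the final
#' generation: early generations keep more nests (exploitation), later
#' generations re-randomize more aggressively (exploration).
#'
#' @param gen Current generation in `[0, total_gens]`.
#' @param total_gens Total generations (>= 1).
#' @param pa_min,pa_max Schedule endpoints.
#' @return The abandonment probability at `gen`.
#' @export
pa_schedule <- function(gen, total_gens, pa_min = 0.3, pa_max = 0.5) {
  if (total_gens < 1L) stop("total_gens must be >= 1")
  if (gen < 0 || gen > total_gens) stop("gen must lie in [0, total_gens]")
  pa_min + (pa_max - pa_min) * gen / total_gens
}

#' Cuckoo-search local refinement of a group
#'
#' The hybrid's local engine: `n_eggs` rounds over the group. Each round every
#' member proposes one egg guided by the current leader
#' ([generate_cuckoo()]); the egg greedily replaces a uniformly chosen nest if
#' fitter, and the round ends with [abandon_nests()] at probability `pa`. The
#' returned leader is the best position observed, so its fitness never
#' decreases.
#'
#' @param positions Matrix of group positions (rows).
#' @param fits Fitness per row.
#' @param leader_pos,leader_fit Current local leader.
#' @param fitness_fn Mask-level fitness function.
#' @param cache Fitness cache.
#' @param config A [cssmo_config()] (supplies `n_eggs`, Levy parameters and
#'   the binarization threshold).
#' @param pa Abandonment probability for this invocation.
#' @return List with updated `positions`, `fits`, `leader_pos`, `leader_fit`.
#' @export
cuckoo_local_search <- function(positions, fits, leader_pos, leader_fit,
                                fitness_fn, cache, config, pa) {
  m <- nrow(positions)
  if (m < 1L) stop("group must be non-empty")
  d <- ncol(positions)
  for (round in seq_len(config$n_eggs)) {
    for (i in seq_len(m)) {
      egg <- generate_cuckoo(positions[i, ], leader_pos,
                             config$levy_beta, config$alpha_step)
      f <- position_fitness(cache, egg, config, fitness_fn)
      j <- sample.int(m, 1L)
      if (f > fits[j]) {
        positions[j, ] <- egg
        fits[j] <- f
      }
      if (f > leader_fit) {
        leader_pos <- egg
        leader_fit <- f
      }
    }
    ab <- abandon_nests(positions, pa, best = which.max(fits))
    positions <- ab$positions
    for (i in which(ab$abandoned)) {
      fits[i] <- position_fitness(cache, positions[i, ], config, fitness_fn)
      if (fits[i] > leader_fit) {
        leader_pos <- positions[i, ]
        leader_fit <- fits[i]
      }
    }
  }
  list(positions = positions, fits = fits, leader_pos = leader_pos,
       leader_fit = leader_fit)
}
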