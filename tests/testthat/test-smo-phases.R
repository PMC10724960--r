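make_swarm <- function(n = 8L, d = 5L, fn, cfg, cache, seed = 1) {
  set.seed(seed)
  init_swarm(n, d, cfg, cache, fn)
}

test_that("the local leader phase is greedy and respects pr = 0", {
  cfg <- tiny_config()
  cache <- new_fitness_cache()
  fn <- make_linear_fitness(5)
  sw <- make_swarm(fn = fn, cfg = cfg, cache = cache)

  cfg0 <- cfg
  cfg0$pr <- 0  # no dimension is ever perturbed
  sw2 <- local_leader_phase(sw, cfg0, cache, fn)
  expect_identical(sw2$pos, sw$pos)
  expect_identical(sw2$fit, sw$fit)

  before <- sw$fit
  sw3 <- local_leader_phase(sw, cfg, cache, fn)
  expect_true(all(sw3$fit >= before))           # greedy acceptance
  expect_true(all(sw3$pos >= 0 & sw3$pos <= 1))
})

test_that("the global leader phase is greedy and stores probabilities", {
  cfg <- tiny_config()
  cache <- new_fitness_cache()
  fn <- make_linear_fitness(5)
  sw <- make_swarm(fn = fn, cfg = cfg, cache = cache)
  before <- sw$fit
  sw2 <- global_leader_phase(sw, cfg, cache, fn)
  expect_true(all(sw2$fit >= before))
  expect_true(all(sw2$pos >= 0 & sw2$pos <= 1))
  expect_true(all(sw2$prob >= 0.1 & sw2$prob <= 1.0))
  expect_equal(sw2$prob[which.max(before)], 1.0)
})

test_that("a member sitting on the global leader can only improve", {
  cfg <- tiny_config()
  cache <- new_fitness_cache()
  fn <- make_linear_fitness(5)
  sw <- make_swarm(fn = fn, cfg = cfg, cache = cache)
  i <- which.max(sw$fit)
  sw$pos[i, ] <- sw$gl_pos
  sw$fit[i] <- sw$gl_fit
  sw2 <- global_leader_phase(sw, cfg, cache, fn)
  expect_gte(sw2$fit[i], sw$fit[i])
})

test_that("leader learning counts stagnation and resets on improvement", {
  cfg <- tiny_config()
  cache <- new_fitness_cache()
  fn <- make_linear_fitness(5)
  sw <- make_swarm(fn = fn, cfg = cfg, cache = cache)

  # no change in members -> both counters increment by exactly 1
  sw1 <- update_leaders(sw)
  expect_equal(sw1$ll_count, sw$ll_count + 1L)
  expect_equal(sw1$gl_count, sw$gl_count + 1L)

  # a tie does not replace the leader (non-improvement convention)
  sw_tie <- sw1
  sw_tie$pos[1, ] <- sw_tie$gl_pos
  sw_tie$fit[1] <- sw_tie$gl_fit
  sw2 <- update_leaders(sw_tie)
  expect_equal(sw2$gl_count, sw1$gl_count + 1L)

  # strict improvement replaces the leader and resets the counter
  sw_imp <- sw2
  sw_imp$fit[2] <- sw_imp$gl_fit + 5
  sw3 <- update_leaders(sw_imp)
  expect_equal(sw3$gl_fit, sw_imp$fit[2])
  expect_equal(sw3$gl_count, 0L)
  expect_equal(sw3$ll_count[1], 0L)
})

test_that("the local leader decision triggers only past the limit", {
  cfg <- tiny_config(local_leader_limit = 3L)
  cache <- new_fitness_cache()
  fn <- make_linear_fitness(5)
  sw <- make_swarm(fn = fn, cfg = cfg, cache = cache)

  sw$ll_count[1] <- 3L  # at the limit: no trigger
  sw1 <- local_leader_decision(sw, cfg, cache, fn, pa = 0.3)
  expect_identical(sw1$pos, sw$pos)
  expect_equal(sw1$ll_count[1], 3L)

  sw$ll_count[1] <- 4L  # past the limit: cuckoo search fires
  before <- sw$ll_fit[1]
  set.seed(2)
  sw2 <- local_leader_decision(sw, cfg, cache, fn, pa = 0.3)
  expect_equal(sw2$ll_count[1], 0L)
  expect_gte(sw2$ll_fit[1], before)
  expect_true(all(sw2$pos >= 0 & sw2$pos <= 1))

  # classic variant re-randomizes the stagnant group
  sw$ll_count[1] <- 4L
  set.seed(3)
  sw3 <- local_leader_decision(sw, cfg, cache, fn, pa = 0, classic = TRUE)
  expect_equal(sw3$ll_count[1], 0L)
  expect_true(all(sw3$pos >= 0 & sw3$pos <= 1))
})

test_that("the global leader decision splits and then merges groups", {
  cfg <- tiny_config(global_leader_limit = 2L)
  cache <- new_fitness_cache()
  fn <- make_linear_fitness(5)
  sw <- make_swarm(n = 9L, fn = fn, cfg = cfg, cache = cache)

  sw$gl_count <- 2L  # at the limit: unchanged
  expect_equal(global_leader_decision(sw, cfg)$n_groups, 1L)

  sw$gl_count <- 3L  # past the limit at 1 group -> split into 2
  sw2 <- global_leader_decision(sw, cfg)
  expect_equal(sw2$n_groups, 2L)
  expect_equal(as.vector(table(sw2$group_of)), c(5L, 4L))  # ceil/floor of 9
  expect_equal(sw2$gl_count, 0L)
  expect_length(sw2$ll_fit, 2L)
  # each new local leader is its group's best member
  for (g in 1:2) {
    expect_equal(sw2$ll_fit[g], max(sw2$fit[sw2$group_of == g]))
  }

  # walking up to max_groups and triggering once more merges to one group
  sw3 <- sw2
  for (i in 1:10) {
    sw3$gl_count <- cfg$global_leader_limit + 1L
    sw3 <- global_leader_decision(sw3, cfg)
  }
  expect_lte(sw3$n_groups, cfg$max_groups)
  sw4 <- sw2
  sw4$n_groups <- cfg$max_groups
  sw4 <- cssmo:::repartition(sw4, cfg$max_groups)
  sw4$gl_count <- cfg$global_leader_limit + 1L
  sw5 <- global_leader_decision(sw4, cfg)
  expect_equal(sw5$n_groups, 1L)
  expect_true(all(sw5$group_of == 1L))
})
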