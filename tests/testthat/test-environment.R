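make_guidance_env <- function(split = NULL, phase = "train") {
  arena <- arena_config(side_length = 2.0, node_spacing = 0.5)
  grid <- build_grid(arena)
  arena$goal_node <- default_goal_node(grid)
  nav_env("guidance", arena, grid, build_action_space("allocentric"),
          episode_config(max_steps = 20L), split = split, phase = phase)
}

make_aiming_env <- function(split = NULL, phase = "train") {
  arena <- arena_config(side_length = 2.0, node_spacing = 0.5)
  grid <- build_grid(arena)
  nav_env("aiming", arena, grid, build_action_space("egocentric"),
          episode_config(max_steps = 20L), split = split, phase = phase)
}

test_that("train/test splits are disjoint, exhaustive and size-correct", {
  ids <- 1:100
  for (seed in 1:20) {
    sp <- make_split(ids, 0.8, seed = seed)
    expect_length(sp$train_nodes, 80L)
    expect_length(sp$test_nodes, 20L)
    expect_length(intersect(sp$train_nodes, sp$test_nodes), 0L)
    expect_setequal(c(sp$train_nodes, sp$test_nodes), ids)
  }
  expect_identical(make_split(ids, seed = 3), make_split(ids, seed = 3))
  sp5 <- make_split(1:5, 0.8, seed = 1)
  expect_length(sp5$train_nodes, 4L)
  expect_length(sp5$test_nodes, 1L)
})

test_that("guidance starts are uniform over the training nodes", {
  env <- make_guidance_env()
  pool <- setdiff(env$grid$nodes$id, env$goal_node)
  set.seed(11)
  draws <- replicate(8000, { env_reset(env); env$pose$node })
  expect_true(all(draws %in% pool))
  expect_false(any(draws == env$goal_node))
  tab <- table(factor(draws, levels = pool))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.01)
})

test_that("aiming relocates the cue every ten trials, within the phase's nodes", {
  env <- make_aiming_env()
  set.seed(5)
  cues <- integer(40)
  for (tr in 1:40) { env_reset(env); cues[tr] <- env$cue_node }
  for (block in split(cues, rep(1:4, each = 10L))) {
    expect_identical(length(unique(block)), 1L)
  }
  expect_gt(length(unique(cues)), 1L)
  # with a split, test-phase cues never come from the training set
  sp <- make_split(env$grid$nodes$id, 0.8, seed = 2)
  env2 <- make_aiming_env(split = sp, phase = "test")
  set.seed(6)
  for (tr in 1:30) {
    env_reset(env2)
    expect_true(env2$cue_node %in% sp$test_nodes)
  }
})

test_that("rewards and termination follow the task rules", {
  env <- make_guidance_env()
  set.seed(3)
  env_reset(env)
  # walk to the goal along a breadth-first path using allocentric moves
  repeat {
    cur <- env$pose$node
    if (cur == env$goal_node) break
    dists <- vapply(1:6, function(d) {
      nb <- env$grid$adjacency[cur, d]
      if (is.na(nb)) Inf else oracle_bfs_dist(env$grid, nb, env$goal_node)
    }, numeric(1L))
    st <- env_step(env, which.min(dists))  # allo_move actions are indices 1..6
    expect_true(st$reward %in% c(-1, 1))
    if (st$terminal) break
  }
  expect_true(env$success)
  expect_identical(st$reward, 1)           # +1 alone on the goal step
  expect_error(env_step(env, 1L), "finished")

  # a blocked move is penalized and does not end the episode
  env_reset(env)
  boundary <- env$grid$nodes$id[rowSums(!is.na(env$grid$adjacency)) < 6L]
  bn <- setdiff(boundary, env$goal_node)[1L]
  env$pose <- pose(bn, 0L)
  blocked <- which(is.na(env$grid$adjacency[bn, ]))[1L]
  st <- env_step(env, blocked)
  expect_identical(st$reward, -1)
  expect_true(st$collided)
  expect_false(st$terminal)
  expect_identical(env$pose$node, bn)
})

test_that("episode returns match the reward scheme", {
  env <- make_guidance_env()
  set.seed(9)
  # failed episode: rotate in place until the step budget runs out
  env_reset(env)
  total <- 0
  repeat {
    st <- env_step(env, 7L)  # a rotation, never reaches the goal
    total <- total + st$reward
    if (st$terminal) break
  }
  expect_false(env$success)
  expect_identical(env$steps, 20L)
  expect_identical(total, -20)
  # successful L-step episode returns -(L-1) + 1
  env_reset(env)
  cur <- env$pose$node
  total <- 0
  L <- 0L
  repeat {
    dists <- vapply(1:6, function(d) {
      nb <- env$grid$adjacency[env$pose$node, d]
      if (is.na(nb)) Inf else oracle_bfs_dist(env$grid, nb, env$goal_node)
    }, numeric(1L))
    st <- env_step(env, which.min(dists))
    total <- total + st$reward
    L <- L + 1L
    if (st$terminal) break
  }
  expect_true(env$success)
  expect_identical(total, -(L - 1L) + 1)
})

test_that("the goal is reachable from every node within the step budget", {
  for (L in c(2.75, 4.0, 5.5)) {
    arena <- arena_config(side_length = L, node_spacing = 0.25)
    grid <- build_grid(arena)
    goal <- default_goal_node(grid)
    d <- vapply(grid$nodes$id, function(n) oracle_bfs_dist(grid, n, goal),
                numeric(1L))
    expect_true(all(is.finite(d)))
    expect_lt(max(d), 100)
  }
})

test_that("environmental manipulations set walls and lighting as specified", {
  base <- arena_config()
  med <- configure_manipulation(base, info_level = "medium")
  expect_false(med$walls_present)
  expect_identical(med$lighting_mode, "medium")
  low <- configure_manipulation(base, info_level = "low")
  expect_false(low$walls_present)
  expect_identical(low$lighting_mode, "low")
  big <- configure_manipulation(base, arena_size = 5.5)
  expect_gt(nrow(build_grid(big)$nodes), nrow(build_grid(base)$nodes))
  expect_error(configure_manipulation(base), "unknown manipulation")
  expect_error(configure_manipulation(base, info_level = "none"),
               "unknown manipulation")
})
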