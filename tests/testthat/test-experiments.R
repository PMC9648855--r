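micro_cfg <- function(task = "guidance", space = "full") {
  experiment_config(task, space, "desk", n_trials = 12L, max_steps = 15L,
                    train_every = 4L)
}

test_that("identical configuration and seed reproduce a run exactly", {
  a <- run_full_model(micro_cfg(), seed = 81)
  b <- run_full_model(micro_cfg(), seed = 81)
  expect_identical(a$training$curve, b$training$curve)
  pa <- hexnav:::dqn_get_params(a$training$agent$ptr)
  pb <- hexnav:::dqn_get_params(b$training$agent$ptr)
  expect_identical(pa, pb)
  c2 <- run_full_model(micro_cfg(), seed = 82)
  expect_false(identical(a$training$curve, c2$training$curve))
})

test_that("strategy-preference fractions are well-formed", {
  a <- run_full_model(micro_cfg(), seed = 83)
  fr <- a$training$curve$frac_allocentric
  expect_true(all(fr >= 0 & fr <= 1))
  expect_gte(a$preference, 0)
  expect_lte(a$preference, 1)
})

test_that("generalization keeps held-out nodes out of training", {
  cfg <- micro_cfg("aiming", "egocentric")
  res <- run_generalization(cfg, seed = 84)
  sp <- res$split
  expect_length(intersect(sp$train_nodes, sp$test_nodes), 0L)
  # training episodes only ever drew cues from the training split
  env <- build_experiment(cfg, split = sp, phase = "train")$env
  set.seed(85)
  for (k in 1:20) {
    env_reset(env)
    expect_true(env$cue_node %in% sp$train_nodes)
  }
  expect_gte(res$train_success, 0)
  expect_lte(res$test_success, 1)
})

test_that("the dropout sweep reports one row per rate and class with sane proportions", {
  cfg <- micro_cfg("guidance", "allocentric")
  sweep <- run_dropout_sweep(cfg, rates = c(0, 0.35), seed = 86)
  expect_identical(nrow(sweep), 10L)  # 2 rates x 5 classes
  for (rate in c(0, 0.35)) {
    block <- sweep[sweep$dropout_rate == rate, ]
    expect_equal(sum(block$proportion), 1)
    expect_identical(sum(block$count), 50L)
  }
})

test_that("experiment logs round-trip through CSV and YAML", {
  res <- run_full_model(micro_cfg(), seed = 87, compute_maps = FALSE)
  dir <- tempfile("logs")
  on.exit(unlink(dir, recursive = TRUE))
  write_experiment_logs(res, dir)
  curve <- utils::read.csv(file.path(dir, "curve.csv"))
  expect_identical(nrow(curve), 12L)
  expect_true(all(c("trial", "total_reward", "steps", "success",
                    "frac_allocentric") %in% names(curve)))
  acts <- utils::read.csv(file.path(dir, "actions.csv"))
  expect_identical(nrow(acts), 24L)
  cfg_back <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfg_back$seed, 87)
  expect_identical(cfg_back$task, "guidance")
})

test_that("trajectory logs and map tables have the documented schemas", {
  cfg <- micro_cfg("guidance", "allocentric")
  parts <- build_experiment(cfg)
  set.seed(88)
  agent <- dqn_network(n_actions(parts$space))
  log <- record_trajectories(agent, parts$env, n_trials = 3L, seed = 89)
  expect_named(log, c("trial", "step", "node", "heading", "action_index",
                      "reward", "terminal"))
  expect_setequal(unique(log$trial), 1:3)
  expect_true(all(log$reward %in% c(-1, 1)))
  # exactly one terminal step per trial, at its end
  expect_identical(sum(log$terminal), 3L)

  maps <- hexnav:::new_activity_maps(array(stats::runif(50 * 625 * 6),
                                           c(50L, 25L, 25L, 6L)),
                                     "position_maps", parts$arena)
  tab <- activity_maps_table(maps)
  expect_identical(nrow(tab), 50L * 625L * 6L)
  expect_equal(tab$value[1L], maps$values[1L, 1L, 1L, 1L])
})
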