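#' Experiment configuration
#'
#' Bundles everything that determines a training run: task, action
#' space, arena, network regularization and training schedule. Together
#' with a seed this fully determines the run.
#'
#' Two scale presets are provided. `"paper"` uses the full study
#' conditions (2.75 m arena at 0.25 m spacing, 4000 trials, 100-step
#' episodes, one gradient update per environment step). `"desk"` is a
#' scaled-down variant for interactive work and automated checks: a
#' smaller, coarser arena (2 m at 0.5 m spacing, about a dozen nodes),
#' shorter episodes, fewer trials and one update every second step,
#' chosen so that a run finishes in well under a minute while the
#' qualitative phenomena (task-dependent strategy preference,
#' generalization gaps, representation classes) remain expressed.
#'
#' @param task `"guidance"` or `"aiming"`.
#' @param action_space `"full"`, `"allocentric"` or `"egocentric"`.
#' @param scale `"desk"` or `"paper"`.
#' @param side_length,node_spacing Arena geometry overrides (meters).
#' @param info_level `"high"`, `"medium"` or `"low"`.
#' @param dropout_rate Dropout on the 50-unit layer.
#' @param n_trials,max_steps,train_every,epsilon Training overrides.
#' @param target_sync_interval Gradient updates between target-network
#'   syncs. The desk preset uses 200 (slower target drift stabilizes the
#'   short-schedule regime); the paper preset uses 100.
#' @param batch_size Replay minibatch size (default 32).
#' @param cue_relocation_period Aiming cue relocation period (trials).
#' @param split_fraction Training fraction for generalization splits.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(task = c("guidance", "aiming"),
                              action_space = c("full", "allocentric", "egocentric"),
                              scale = c("desk", "paper"),
                              side_length = NULL, node_spacing = NULL,
                              info_level = "high",
                              dropout_rate = 0.35,
                              n_trials = NULL, max_steps = NULL,
                              train_every = NULL, epsilon = 0.3,
                              target_sync_interval = NULL,
                              batch_size = NULL,
                              cue_relocation_period = 10L,
                              split_fraction = 0.8) {
  task <- match.arg(task)
  action_space <- match.arg(action_space)
  scale <- match.arg(scale)
  def <- if (scale == "desk") {
    list(side = 2.0, spacing = 0.5, trials = 300L, steps = 40L, every = 2L,
         sync = 200L, batch = 32L)
  } else {
    list(side = 2.75, spacing = 0.25, trials = 4000L, steps = 100L, every = 1L,
         sync = 100L, batch = 32L)
  }
  structure(list(
    task = task, action_space = action_space, scale = scale,
    side_length = side_length %||% def$side,
    node_spacing = node_spacing %||% def$spacing,
    info_level = info_level,
    dropout_rate = dropout_rate,
    n_trials = as.integer(n_trials %||% def$trials),
    max_steps = as.integer(max_steps %||% def$steps),
    train_every = as.integer(train_every %||% def$every),
    epsilon = epsilon,
    target_sync_interval = as.integer(target_sync_interval %||% def$sync),
    batch_size = as.integer(batch_size %||% def$batch),
    cue_relocation_period = as.integer(cue_relocation_period),
    split_fraction = split_fraction), class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat(sprintf("<experiment_config> %s / %s (%s scale): %.3g m arena, %d trials\n",
              x$task, x$action_space, x$scale, x$side_length, x$n_trials))
  invisible(x)
}

#' Materialize the pieces of an experiment
#'
#' Builds the arena, grid, action space and environment described by a
#' configuration.
#'
#' @param config An [experiment_config()].
#' @param split Optional node split from [make_split()].
#' @param phase `"train"` or `"test"`.
#' @return List with `arena`, `grid`, `space`, `env`, `hyper`.
#' @export
build_experiment <- function(config, split = NULL, phase = "train") {
  arena <- arena_config(side_length = config$side_length,
                        node_spacing = config$node_spacing)
  arena <- configure_manipulation(arena, info_level = config$info_level)
  grid <- build_grid(arena)
  if (config$task == "guidance") arena$goal_node <- default_goal_node(grid)
  space <- build_action_space(config$action_space)
  ep <- episode_config(max_steps = config$max_steps,
                       cue_relocation_period = config$cue_relocation_period)
  env <- nav_env(config$task, arena, grid, space, ep, split = split,
                 phase = phase)
  hyper <- hyper_params(n_trials = config$n_trials,
                        epsilon = config$epsilon,
                        train_every = config$train_every,
                        target_sync_interval = config$target_sync_interval,
                        batch_size = config$batch_size)
  list(arena = arena, grid = grid, space = space, env = env, hyper = hyper)
}

maps_for_task <- function(agent, config, parts) {
  if (config$task == "aiming") {
    compute_cue_maps(agent, parts$arena)
  } else {
    compute_position_maps(agent, parts$arena, parts$grid)
  }
}

#' Train the unconstrained (full action space) model
#'
#' Trains an agent that can freely mix allocentric and egocentric
#' actions and records, per episode, the fraction of chosen actions
#' that were allocentric (the strategy-preference curve; duplicated
#' egocentric copies count as egocentric). Optionally computes activity
#' maps and a unit classification at the end of training and at
#' checkpoints.
#'
#' @param config An [experiment_config()] with `action_space = "full"`.
#' @param seed Integer seed; the run is fully determined by
#'   (config, seed).
#' @param compute_maps Compute final maps and classification.
#' @param n_checkpoints If positive, additionally classify at this many
#'   evenly spaced training checkpoints.
#' @return List of class `experiment_result`: `training`, `preference`
#'   (final-100-trial mean allocentric fraction), `maps`,
#'   `classification`, `config`, `seed`.
#' @export
run_full_model <- function(config, seed, compute_maps = FALSE,
                           n_checkpoints = 0L) {
  stopifnot(config$action_space == "full")
  run_experiment(config, seed, compute_maps, n_checkpoints)
}

#' Train a strategy-constrained model
#'
#' As [run_full_model()] but with a single-copy allocentric (12 actions)
#' or egocentric (3 actions) action space.
#'
#' @param config An [experiment_config()] with `action_space` set to
#'   `"allocentric"` or `"egocentric"`.
#' @inheritParams run_full_model
#' @return An `experiment_result`.
#' @export
run_constrained <- function(config, seed, compute_maps = FALSE,
                            n_checkpoints = 0L) {
  stopifnot(config$action_space %in% c("allocentric", "egocentric"))
  run_experiment(config, seed, compute_maps, n_checkpoints)
}

run_experiment <- function(config, seed, compute_maps = FALSE,
                           n_checkpoints = 0L) {
  parts <- build_experiment(config)
  ckpts <- if (n_checkpoints > 0L) {
    unique(round(seq_len(n_checkpoints) * config$n_trials / n_checkpoints))
  } else integer(0)
  ckpt_fn <- if (n_checkpoints > 0L) {
    function(agent, trial) classify_population(maps_for_task(agent, config, parts))
  } else NULL
  training <- train_dqn(parts$env, parts$hyper,
                        dropout_rate = config$dropout_rate, seed = seed,
                        checkpoints = ckpts, checkpoint_fn = ckpt_fn)
  n <- nrow(training$curve)
  last <- training$curve[max(1L, n - 99L):n, ]
  maps <- NULL
  classification <- NULL
  if (compute_maps) {
    maps <- maps_for_task(training$agent, config, parts)
    classification <- classify_population(maps)
  }
  structure(list(training = training,
                 preference = mean(last$frac_allocentric),
                 final_success = mean(last$success),
                 maps = maps, classification = classification,
                 parts = parts, config = config, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf(
    "<experiment_result> %s/%s seed %s: final success %.2f, allocentric fraction %.2f\n",
    x$config$task, x$config$action_space, format(x$seed), x$final_success,
    x$preference))
  invisible(x)
}

#' Generalization experiment
#'
#' Trains on 80% of nodes (start locations in guidance, cued goal
#' locations in aiming) and evaluates greedy success separately on the
#' training set and on the held-out 20%. Guidance tests start the agent
#' once from each node of each set; aiming draws a fresh held-out (or
#' training) cue every test trial.
#'
#' @param config An [experiment_config()].
#' @param seed Integer seed (also used, offset, for the split).
#' @param n_eval_trials Aiming evaluation trials per phase.
#' @param eval_max_steps Optional tighter step budget for the evaluation
#'   trials. In small arenas an undirected policy can still diffuse to
#'   the goal within the training budget; a budget of roughly twice the
#'   arena diameter makes held-out success reflect directed navigation.
#' @return List of class `generalization_result` with `train_success`,
#'   `test_success`, `split`, `training`.
#' @export
run_generalization <- function(config, seed, n_eval_trials = 25L,
                               eval_max_steps = NULL) {
  parts0 <- build_experiment(config)
  split <- make_split(parts0$grid$nodes$id, config$split_fraction,
                      seed = seed + 10000L)
  parts <- build_experiment(config, split = split, phase = "train")
  training <- train_dqn(parts$env, parts$hyper,
                        dropout_rate = config$dropout_rate, seed = seed)
  agent <- training$agent
  eval_phase <- function(phase) {
    env <- parts$env
    set_phase(env, phase)
    if (!is.null(eval_max_steps)) env$cfg$max_steps <- as.integer(eval_max_steps)
    on.exit(env$cfg$max_steps <- config$max_steps, add = TRUE)
    if (config$task == "guidance") {
      nodes <- if (phase == "train") split$train_nodes else split$test_nodes
      nodes <- setdiff(nodes, env$goal_node)
      evaluate_agent(agent, env, seed = seed + 20000L, start_nodes = nodes)
    } else {
      env$cfg$cue_relocation_period <- 1L  # fresh cue every test trial
      env$cue_node <- NA_integer_
      evaluate_agent(agent, env, n_trials = n_eval_trials, seed = seed + 20000L)
    }
  }
  test_res <- eval_phase("test")
  train_res <- eval_phase("train")
  set_phase(parts$env, "train")
  structure(list(train_success = train_res$success_fraction,
                 test_success = test_res$success_fraction,
                 split = split, training = training, config = config,
                 seed = seed),
            class = "generalization_result")
}

#' @export
print.generalization_result <- function(x, ...) {
  cat(sprintf("<generalization_result> %s/%s: train %.2f, test %.2f\n",
              x$config$task, x$config$action_space, x$train_success,
              x$test_success))
  invisible(x)
}

#' Dropout sweep
#'
#' Trains one agent per dropout rate and reports the class proportions
#' of the emerging spatial representations.
#'
#' @param config An [experiment_config()].
#' @param rates Dropout rates in \[0, 0.6\].
#' @param seed Integer seed (shared across rates so only the rate
#'   varies).
#' @return A data.frame with one row per (rate, class):
#'   `dropout_rate`, `label`, `count`, `proportion`, `final_success`.
#' @export
run_dropout_sweep <- function(config, rates, seed) {
  stopifnot(all(rates >= 0), all(rates <= 0.6))
  rows <- lapply(rates, function(rate) {
    cfg <- config
    cfg$dropout_rate <- rate
    res <- run_experiment(cfg, seed, compute_maps = TRUE)
    counts <- res$classification$counts
    data.frame(dropout_rate = rate, label = names(counts),
               count = as.integer(counts),
               proportion = as.numeric(res$classification$proportions),
               final_success = res$final_success)
  })
  do.call(rbind, rows)
}

#' Write experiment logs as CSV
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly. Writes `curve.csv`
#'   (per-trial learning curve), `actions.csv` (action table) and
#'   `config.yaml`.
#' @export
write_experiment_logs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$training$curve, file.path(dir, "curve.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(result$parts$space),
                   file.path(dir, "actions.csv"), row.names = FALSE)
  cfg <- unclass(result$config)
  cfg$seed <- result$seed
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  if (!is.null(result$classification)) {
    utils::write.csv(result$classification$table,
                     file.path(dir, "classification.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Record a greedy trajectory log
#'
#' Runs evaluation episodes with a greedy policy and returns a step-level
#' log suitable for auditing or plotting trajectories.
#'
#' @param agent A trained `dqn_agent`.
#' @param env A [nav_env()].
#' @param n_trials Number of episodes.
#' @param seed Optional seed for the start/cue draws.
#' @return A data.frame with one row per step: `trial`, `step`, `node`,
#'   `heading`, `action_index`, `reward`, `terminal`.
#' @export
record_trajectories <- function(agent, env, n_trials = 10L, seed = NULL) {
  run <- function() {
    rows <- list()
    for (tr in seq_len(n_trials)) {
      env_reset(env)
      step_i <- 0L
      repeat {
        q <- dqn_qvalues(agent$ptr, matrix(env_observation(env), ncol = 1L))[, 1L]
        best <- which(q == max(q))
        a <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
        node <- env$pose$node
        heading <- env$pose$heading
        st <- env_step(env, a)
        step_i <- step_i + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          trial = tr, step = step_i, node = node, heading = heading,
          action_index = a, reward = st$reward, terminal = st$terminal)
        if (st$terminal) break
      }
    }
    do.call(rbind, rows)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
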