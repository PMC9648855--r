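#' Episode configuration
#'
#' Reward and termination scheme shared by both tasks: +1 for reaching
#' the goal, -1 for every other step (including steps blocked by a
#' collision, which leave the agent in place), and termination when the
#' goal is reached or after `max_steps` steps, whichever comes first.
#' Goal arrival exactly on the last allowed step counts as a success.
#'
#' @param max_steps Step budget per trial (default 100).
#' @param goal_reward Reward on the step that reaches the goal (+1; the
#'   step penalty is not added on that step).
#' @param step_reward Reward for an ordinary step (-1).
#' @param collision_reward Reward for a blocked step (-1).
#' @param cue_relocation_period Aiming only: the cue (and with it the
#'   goal) is moved to a new random node every this many trials.
#' @return An object of class `episode_config`.
#' @export
episode_config <- function(max_steps = 100L,
                           goal_reward = 1,
                           step_reward = -1,
                           collision_reward = -1,
                           cue_relocation_period = 10L) {
  stopifnot(max_steps > 0L, cue_relocation_period > 0L)
  structure(list(max_steps = as.integer(max_steps),
                 goal_reward = goal_reward,
                 step_reward = step_reward,
                 collision_reward = collision_reward,
                 cue_relocation_period = as.integer(cue_relocation_period)),
            class = "episode_config")
}

#' Random train/test split of lattice nodes
#'
#' Partitions node ids into a training set of `round(fraction * N)` nodes
#' and a disjoint, exhaustive test set, reproducibly from `seed`. In
#' guidance the split applies to start locations, in aiming to cued goal
#' locations.
#'
#' @param node_ids Integer vector of node ids (>= 2).
#' @param fraction Training fraction (default 0.8).
#' @param seed Optional integer seed; if given, the caller's RNG state is
#'   left untouched.
#' @return List with `train_nodes`, `test_nodes`, `fraction_train`.
#' @export
make_split <- function(node_ids, fraction = 0.8, seed = NULL) {
  stopifnot(length(node_ids) >= 2L, fraction > 0, fraction < 1)
  draw <- function() sample(node_ids, size = round(fraction * length(node_ids)))
  train <- if (is.null(seed)) draw() else with_seed(seed, draw())
  list(train_nodes = sort(train),
       test_nodes = sort(setdiff(node_ids, train)),
       fraction_train = fraction)
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Environmental manipulations
#'
#' Derives a modified arena configuration for the generalization
#' experiments: larger arena sizes (guidance) or reduced
#' spatial-information levels (aiming). Information levels: `"high"` has
#' walls and point lights, `"medium"` removes the walls but keeps the
#' point lights, `"low"` has neither and is lit by a uniform distant
#' light source; the cue remains visible at all levels.
#'
#' @param base An [arena_config()].
#' @param arena_size Optional new side length in meters.
#' @param info_level Optional: `"high"`, `"medium"` or `"low"`.
#' @return A new `arena_config`. Changing the arena size invalidates the
#'   goal/cue node ids (the grid must be rebuilt), so they are reset.
#' @export
configure_manipulation <- function(base, arena_size = NULL, info_level = NULL) {
  stopifnot(inherits(base, "arena_config"))
  if (is.null(arena_size) && is.null(info_level))
    stop("unknown manipulation: give arena_size or info_level")
  out <- base
  if (!is.null(arena_size)) {
    stopifnot(is.numeric(arena_size), arena_size > 0)
    out$side_length <- arena_size
    out$goal_node <- NA_integer_
    out$cue_node <- NA_integer_
  }
  if (!is.null(info_level)) {
    if (!info_level %in% c("high", "medium", "low"))
      stop("unknown manipulation: info_level must be high, medium or low")
    out$walls_present <- info_level == "high"
    out$lighting_mode <- info_level
  }
  out
}

#' Create a navigation task environment
#'
#' Builds a mutable episodic environment for one of the two tasks:
#' * `"guidance"`: the goal is a single fixed, unmarked node; the agent
#'   must localize itself from the distal landmarks. Starts are drawn
#'   uniformly from the phase's node set.
#' * `"aiming"`: the goal coincides with a visible red cue cylinder that
#'   moves to a new random node (from the phase's node set) every
#'   `cue_relocation_period` trials; starts are drawn uniformly from all
#'   nodes.
#'
#' Start draws equal to the goal node are redrawn. Observations are
#' rendered lazily and cached per (node, heading, cue) triple.
#'
#' @param task `"guidance"` or `"aiming"`.
#' @param arena An [arena_config()]. For guidance, `goal_node` is used if
#'   set, else [default_goal_node()] is taken.
#' @param grid The `hex_grid` built from `arena`.
#' @param space An `action_space`.
#' @param episode An [episode_config()].
#' @param split Optional split from [make_split()]; if `NULL`, all nodes
#'   are eligible in both phases.
#' @param phase `"train"` or `"test"`.
#' @return An environment object of class `nav_env`.
#' @export
nav_env <- function(task = c("guidance", "aiming"), arena, grid, space,
                    episode = episode_config(), split = NULL,
                    phase = c("train", "test")) {
  task <- match.arg(task)
  phase <- match.arg(phase)
  e <- new.env(parent = emptyenv())
  e$task <- task
  e$arena <- arena
  e$grid <- grid
  e$space <- space
  e$cfg <- episode
  e$split <- split
  e$phase <- phase
  e$trial <- 0L
  e$steps <- 0L
  e$done <- TRUE
  e$goal_node <- if (task == "guidance") {
    if (!is.na(arena$goal_node)) arena$goal_node else default_goal_node(grid)
  } else NA_integer_
  e$cue_node <- NA_integer_
  e$cache <- new.env(parent = emptyenv())
  class(e) <- c("nav_env", "environment")
  e
}

#' @export
print.nav_env <- function(x, ...) {
  cat(sprintf("<nav_env> %s task, %d nodes, %s phase, trial %d\n",
              x$task, nrow(x$grid$nodes), x$phase, x$trial))
  invisible(x)
}

phase_nodes <- function(env) {
  if (is.null(env$split)) return(env$grid$nodes$id)
  if (env$phase == "train") env$split$train_nodes else env$split$test_nodes
}

#' Set the evaluation phase of an environment
#'
#' @param env A `nav_env`.
#' @param phase `"train"` or `"test"`.
#' @return The environment, invisibly. Resets the trial counter so that
#'   aiming redraws its cue immediately.
#' @export
set_phase <- function(env, phase = c("train", "test")) {
  env$phase <- match.arg(phase)
  env$trial <- 0L
  invisible(env)
}

#' Start a new trial
#'
#' Draws the start pose (uniform node from the eligible set, uniform
#' heading) and, for aiming, relocates the cue when due. Uses the current
#' R random number generator state.
#'
#' @param env A `nav_env`.
#' @return The initial observation as a flat numeric vector, invisibly
#'   accessible again through [env_observation()].
#' @export
env_reset <- function(env) {
  env$trial <- env$trial + 1L
  if (env$task == "aiming" &&
      (is.na(env$cue_node) ||
       (env$trial - 1L) %% env$cfg$cue_relocation_period == 0L)) {
    eligible <- phase_nodes(env)
    env$cue_node <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    env$goal_node <- env$cue_node
    env$arena$cue_node <- env$cue_node
  }
  start_pool <- if (env$task == "guidance") phase_nodes(env) else env$grid$nodes$id
  repeat {
    node <- if (length(start_pool) == 1L) start_pool else sample(start_pool, 1L)
    if (node != env$goal_node) break
    if (length(start_pool) == 1L) stop("cannot draw a start distinct from the goal")
  }
  heading <- sample(0:5, 1L)
  env$pose <- pose(node, heading)
  env$steps <- 0L
  env$done <- FALSE
  env$success <- FALSE
  invisible(env_observation(env))
}

#' Current observation of an environment
#'
#' Rendered at the agent's pose; cached per (node, heading, cue-node)
#' since the scene within a trial is static.
#'
#' @param env A `nav_env`.
#' @return Flat numeric vector of length 1728.
#' @export
env_observation <- function(env) {
  key <- paste0(env$pose$node, "_", env$pose$heading, "_",
                ifelse(is.na(env$cue_node), 0L, env$cue_node))
  hit <- env$cache[[key]]
  if (!is.null(hit)) return(hit)
  v <- obs_to_vec(render_pose(env$pose, env$arena, env$grid))
  env$cache[[key]] <- v
  v
}

#' Advance the environment by one action
#'
#' @param env A `nav_env` with an active trial.
#' @param action_index Integer index into the environment's action space.
#' @return List with `reward`, `terminal`, `collided`, `success`. The
#'   environment's pose and counters are updated in place.
#' @export
env_step <- function(env, action_index) {
  if (env$done) stop("episode finished: call env_reset() first")
  action <- env$space$actions[action_index, ]
  out <- apply_action(env$pose, action, env$grid)
  env$pose <- out$new_pose
  env$steps <- env$steps + 1L
  reached <- out$new_pose$node == env$goal_node
  reward <- if (reached) env$cfg$goal_reward
            else if (out$collided) env$cfg$collision_reward
            else env$cfg$step_reward
  terminal <- reached || env$steps >= env$cfg$max_steps
  env$done <- terminal
  env$success <- reached
  list(reward = reward, terminal = terminal, collided = out$collided,
       success = reached)
}
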