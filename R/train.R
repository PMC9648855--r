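#' Training hyperparameters
#'
#' Defaults follow the study protocol: learning rate 0.001, discount
#' 0.99, a constant epsilon-greedy exploration rate of 0.3, a FIFO
#' experience-replay buffer of 3000 transitions, and 4000 training
#' trials. Batch size, target-network sync interval and the number of
#' environment steps between gradient updates are free implementation
#' choices exposed here.
#'
#' @param learning_rate Adam step size.
#' @param gamma Discount factor.
#' @param epsilon Exploration probability (constant over training).
#' @param replay_capacity Replay buffer capacity (FIFO).
#' @param n_trials Number of training episodes.
#' @param batch_size Minibatch size per gradient update.
#' @param target_sync_interval Gradient updates between target-network
#'   synchronizations.
#' @param train_every Environment steps between gradient updates.
#' @return An object of class `hyper_params`.
#' @export
hyper_params <- function(learning_rate = 0.001,
                         gamma = 0.99,
                         epsilon = 0.3,
                         replay_capacity = 3000L,
                         n_trials = 4000L,
                         batch_size = 32L,
                         target_sync_interval = 100L,
                         train_every = 1L) {
  stopifnot(gamma >= 0, gamma <= 1, epsilon >= 0, epsilon <= 1,
            replay_capacity >= batch_size, n_trials >= 1, train_every >= 1)
  structure(list(learning_rate = learning_rate, gamma = gamma,
                 epsilon = epsilon,
                 replay_capacity = as.integer(replay_capacity),
                 n_trials = as.integer(n_trials),
                 batch_size = as.integer(batch_size),
                 target_sync_interval = as.integer(target_sync_interval),
                 train_every = as.integer(train_every)),
            class = "hyper_params")
}

#' FIFO experience-replay buffer
#'
#' Stores (s, a, r, s', terminal) transitions in preallocated arrays;
#' once full, the oldest transition is overwritten first.
#'
#' @param capacity Maximum number of transitions.
#' @param obs_dim Observation dimensionality.
#' @return A mutable buffer environment of class `replay_buffer`.
#' @export
replay_buffer <- function(capacity, obs_dim = 1728L) {
  b <- new.env(parent = emptyenv())
  b$capacity <- as.integer(capacity)
  b$obs <- matrix(0, obs_dim, capacity)
  b$nxt <- matrix(0, obs_dim, capacity)
  b$action <- integer(capacity)
  b$reward <- numeric(capacity)
  b$terminal <- integer(capacity)
  b$pos <- 0L      # next write slot (0-based circular)
  b$size <- 0L
  class(b) <- c("replay_buffer", "environment")
  b
}

#' @rdname replay_buffer
#' @param buffer A `replay_buffer`.
#' @param obs,nxt Flat observation vectors before/after the transition.
#' @param action Chosen action index.
#' @param reward Scalar reward.
#' @param terminal Logical.
#' @export
buffer_push <- function(buffer, obs, action, reward, nxt, terminal) {
  i <- buffer$pos + 1L
  fill_column(buffer$obs, i, obs)   # in-place: the buffer is never copied
  fill_column(buffer$nxt, i, nxt)
  buffer$action[i] <- action
  buffer$reward[i] <- reward
  buffer$terminal[i] <- as.integer(terminal)
  buffer$pos <- (buffer$pos + 1L) %% buffer$capacity
  buffer$size <- min(buffer$size + 1L, buffer$capacity)
  invisible(buffer)
}

#' @rdname replay_buffer
#' @param n Minibatch size.
#' @export
buffer_sample <- function(buffer, n) {
  idx <- sample.int(buffer$size, n, replace = FALSE)
  list(obs = buffer$obs[, idx, drop = FALSE],
       nxt = buffer$nxt[, idx, drop = FALSE],
       action = buffer$action[idx],
       reward = buffer$reward[idx],
       terminal = buffer$terminal[idx])
}

#' Train a DQN agent on a navigation environment
#'
#' Runs episodic training: every environment step the transition is
#' stored in the replay buffer and (every `train_every` steps, once the
#' buffer holds a full batch) a uniformly sampled minibatch drives one
#' Adam step on the squared temporal-difference error with double-Q
#' targets. Credit is assigned only to the chosen action index, hence
#' only to the chosen copy of a duplicated egocentric action.
#'
#' @param env A [nav_env()].
#' @param hyper A [hyper_params()].
#' @param agent Optional existing `dqn_agent` to continue training;
#'   by default a fresh network is created with `dropout_rate`.
#' @param dropout_rate Dropout on the 50-unit layer for a fresh network.
#' @param seed Optional integer seed governing weight initialization,
#'   exploration, start draws, dropout and replay sampling.
#' @param checkpoints Optional integer vector of trial numbers after
#'   which `checkpoint_fn(agent, trial)` is called.
#' @param checkpoint_fn Callback for checkpoints.
#' @return List of class `dqn_training` with elements `agent`, `curve`
#'   (data.frame: `trial`, `total_reward`, `steps`, `success`,
#'   `frac_allocentric`, `mean_loss`), `hyper`, and `checkpoint_results`.
#' @export
train_dqn <- function(env, hyper = hyper_params(), agent = NULL,
                      dropout_rate = 0.35, seed = NULL,
                      checkpoints = integer(0), checkpoint_fn = NULL) {
  run <- function() {
    if (is.null(agent)) agent <- dqn_network(n_actions(env$space), dropout_rate)
    dqn_set_sync_interval(agent$ptr, hyper$target_sync_interval)
    allo <- is_allocentric(env$space)
    nA <- n_actions(env$space)
    buf <- replay_buffer(hyper$replay_capacity)
    curve <- data.frame(trial = seq_len(hyper$n_trials), total_reward = NA_real_,
                        steps = NA_integer_, success = NA, frac_allocentric = NA_real_,
                        mean_loss = NA_real_)
    ckpt_results <- list()
    gstep <- 0L
    for (trial in seq_len(hyper$n_trials)) {
      env_reset(env)
      obs <- env_observation(env)
      total <- 0
      n_allo <- 0L
      losses <- 0
      n_loss <- 0L
      repeat {
        a <- if (stats::runif(1L) < hyper$epsilon) {
          sample.int(nA, 1L)
        } else {
          q <- dqn_qvalues(agent$ptr, matrix(obs, ncol = 1L))[, 1L]
          best <- which(q == max(q))
          if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
        }
        step <- env_step(env, a)
        nxt <- env_observation(env)
        buffer_push(buf, obs, a, step$reward, nxt, step$terminal)
        total <- total + step$reward
        if (allo[a]) n_allo <- n_allo + 1L
        gstep <- gstep + 1L
        if (buf$size >= hyper$batch_size && gstep %% hyper$train_every == 0L) {
          mb <- buffer_sample(buf, hyper$batch_size)
          loss <- dqn_train_batch(agent$ptr, mb$obs, mb$nxt, mb$action,
                                  mb$reward, mb$terminal, hyper$gamma,
                                  hyper$learning_rate)
          losses <- losses + loss
          n_loss <- n_loss + 1L
        }
        obs <- nxt
        if (step$terminal) break
      }
      curve$total_reward[trial] <- total
      curve$steps[trial] <- env$steps
      curve$success[trial] <- env$success
      curve$frac_allocentric[trial] <- n_allo / env$steps
      curve$mean_loss[trial] <- if (n_loss > 0L) losses / n_loss else NA_real_
      if (trial %in% checkpoints && !is.null(checkpoint_fn)) {
        ckpt_results[[as.character(trial)]] <- checkpoint_fn(agent, trial)
      }
    }
    structure(list(agent = agent, curve = curve, hyper = hyper,
                   checkpoint_results = ckpt_results),
              class = "dqn_training")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' @export
print.dqn_training <- function(x, ...) {
  n <- nrow(x$curve)
  last <- x$curve[max(1L, n - 99L):n, ]
  cat(sprintf("<dqn_training> %d trials; final-100 success %.2f, reward %.1f\n",
              n, mean(last$success), mean(last$total_reward)))
  invisible(x)
}

#' Evaluate an agent
#'
#' Runs `n_trials` episodes with dropout off and reports the success
#' fraction. By default the policy is greedy (`epsilon = 0`); setting
#' `epsilon` evaluates under the epsilon-greedy behavior policy instead.
#' Optionally injects lesion noise into a set of hidden units on every
#' forward pass (see [run_lesion()]).
#'
#' @param agent A `dqn_agent`.
#' @param env A [nav_env()].
#' @param n_trials Number of evaluation episodes.
#' @param seed Optional seed for start/cue draws (and lesion noise).
#' @param lesion_units Optional integer vector of unit indices (1..50).
#' @param noise_scale Lesion noise scale (sd multiplier on the per-pass
#'   maximum activation of the 50-unit layer).
#' @param start_nodes Optional explicit start nodes, one trial each
#'   (overrides `n_trials`).
#' @param epsilon Exploration probability during evaluation.
#' @return List with `success_fraction`, `successes`, `steps` (per
#'   trial), `n_trials`.
#' @export
evaluate_agent <- function(agent, env, n_trials = 25L, seed = NULL,
                           lesion_units = integer(0), noise_scale = 0,
                           start_nodes = NULL, epsilon = 0) {
  run <- function() {
    if (!is.null(start_nodes)) n_trials <- length(start_nodes)
    succ <- logical(n_trials)
    steps <- integer(n_trials)
    lesioned <- noise_scale > 0
    units0 <- as.integer(lesion_units) - 1L
    for (tr in seq_len(n_trials)) {
      env_reset(env)
      if (!is.null(start_nodes)) {
        node <- start_nodes[tr]
        if (node == env$goal_node) node <- env$grid$nodes$id[
          which(env$grid$nodes$id != node)[1L]]
        env$pose <- pose(node, env$pose$heading)
      }
      repeat {
        obs <- matrix(env_observation(env), ncol = 1L)
        q <- if (lesioned) {
          dqn_qvalues_lesioned(agent$ptr, obs, units0, noise_scale)[, 1L]
        } else {
          dqn_qvalues(agent$ptr, obs)[, 1L]
        }
        a <- select_action(q, epsilon)
        st <- env_step(env, a)
        if (st$terminal) break
      }
      succ[tr] <- env$success
      steps[tr] <- env$steps
    }
    list(success_fraction = mean(succ), successes = succ, steps = steps,
         n_trials = n_trials)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
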