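#' Network architecture specification
#'
#' The value network is fixed by design: three convolutional layers with
#' 32, 64 and 64 filters of size 5 x 5 over the 12 x 48 x 3 observation,
#' a fully connected layer with 50 rectified units (the layer whose
#' spatial tuning is analysed), and a dueling output head with one linear
#' unit per action. This helper records the architecture and validates
#' the two knobs that are actually free: the number of actions and the
#' dropout rate applied to the 50-unit layer during training.
#'
#' @param n_actions Number of output actions.
#' @param dropout_rate Dropout rate on the fully connected layer
#'   (default 0.35), active during training only.
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(n_actions, dropout_rate = 0.35) {
  stopifnot(n_actions >= 1, dropout_rate >= 0, dropout_rate < 1)
  structure(list(conv_filters = c(32L, 64L, 64L), kernel = c(5L, 5L),
                 fc_units = 50L, dueling = TRUE,
                 n_actions = as.integer(n_actions),
                 dropout_rate = dropout_rate),
            class = "network_spec")
}

#' Create a dueling double-DQN value network
#'
#' Weights are initialized with zero-mean normal draws scaled by
#' `sqrt(2 / fan_in)` (He initialization for rectifier networks), using
#' the current R RNG state; biases start at zero. The target network
#' starts as a copy of the online network.
#'
#' @param spec A [network_spec()], or an integer number of actions.
#' @param dropout_rate Used when `spec` is given as an action count.
#' @return An object of class `dqn_agent` wrapping the network state.
#' @export
dqn_network <- function(spec, dropout_rate = 0.35) {
  if (is.numeric(spec)) spec <- network_spec(spec, dropout_rate)
  stopifnot(inherits(spec, "network_spec"))
  ptr <- dqn_create(spec$n_actions, spec$dropout_rate)
  structure(list(ptr = ptr, spec = spec), class = "dqn_agent")
}

#' @export
print.dqn_agent <- function(x, ...) {
  g <- dqn_geometry(x$ptr)
  cat(sprintf(
    "<dqn_agent> conv 32/64/64 (5x5) -> %d -> fc 50 -> dueling V+A, %d actions\n",
    g$flat, g$n_actions))
  invisible(x)
}

as_obs_matrix <- function(observation) {
  if (is.matrix(observation)) return(observation)
  matrix(as.numeric(observation), ncol = max(1L, length(observation) %/% 1728L))
}

#' Q-values of observations
#'
#' Evaluation-mode forward pass (dropout disabled).
#'
#' @param agent A `dqn_agent`.
#' @param observation A flat observation vector (length 1728), a
#'   12 x 48 x 3 array, or a 1728 x B matrix of observations in columns.
#' @return Numeric matrix `n_actions x B` of Q-values.
#' @export
q_values <- function(agent, observation) {
  dqn_qvalues(agent$ptr, as_obs_matrix(as.numeric(observation)))
}

#' Hidden-layer activations
#'
#' Activations of the 50-unit analysis layer in evaluation mode.
#'
#' @inheritParams q_values
#' @return Numeric matrix `50 x B`.
#' @export
hidden_activations <- function(agent, observation) {
  dqn_hidden(agent$ptr, as_obs_matrix(as.numeric(observation)))
}

#' Dueling aggregation
#'
#' Combines a state value and per-action advantages into Q-values with
#' mean-advantage centering: `Q(s, a) = V(s) + A(s, a) - mean_a' A(s, a')`.
#' Adding a constant to all advantages therefore leaves Q unchanged.
#'
#' @param v Scalar state value (or length-B vector).
#' @param a Numeric vector of advantages (or `n_actions x B` matrix).
#' @return Q-values with the same shape as `a`.
#' @export
dueling_q <- function(v, a) {
  if (is.matrix(a)) {
    sweep(sweep(a, 2L, colMeans(a), `-`), 2L, v, `+`)
  } else {
    v + a - mean(a)
  }
}

#' Epsilon-greedy action selection
#'
#' With probability `epsilon` a uniformly random action index is
#' returned; otherwise the greedy action, with uniform random
#' tie-breaking among exactly tied maxima.
#'
#' @param q Numeric vector of Q-values.
#' @param epsilon Exploration probability in \[0, 1\].
#' @return An integer action index in `1..length(q)`.
#' @export
select_action <- function(q, epsilon) {
  stopifnot(epsilon >= 0, epsilon <= 1)
  if (epsilon > 0 && stats::runif(1L) < epsilon) {
    return(sample.int(length(q), 1L))
  }
  best <- which(q == max(q))
  if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
}

#' Double-Q temporal-difference target
#'
#' For terminal transitions the target is the reward alone. Otherwise the
#' online network selects the best next action and the target network
#' evaluates it: `y = r + gamma * Q_target(s', argmax_a Q_online(s', a))`.
#' With identical online and target networks this reduces to the
#' standard Q-learning max-target.
#'
#' @param reward Numeric vector of rewards (length B).
#' @param terminal Logical vector (length B).
#' @param q_next_online `n_actions x B` matrix of online Q-values at s'.
#' @param q_next_target `n_actions x B` matrix of target-network Q-values
#'   at s'.
#' @param gamma Discount factor in (0, 1\].
#' @return Numeric vector of TD targets.
#' @export
td_target <- function(reward, terminal, q_next_online, q_next_target, gamma) {
  q_next_online <- as.matrix(q_next_online)
  q_next_target <- as.matrix(q_next_target)
  astar <- max.col(t(q_next_online), ties.method = "first")
  boot <- q_next_target[cbind(astar, seq_along(reward))]
  ifelse(terminal, reward, reward + gamma * boot)
}
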