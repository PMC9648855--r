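#' Noise-injection lesions of analysis-layer units
#'
#' A lesion perturbs the forward pass: on every pass, each targeted unit
#' of the 50-unit layer receives an independent draw from a zero-mean
#' normal distribution whose standard deviation is `noise_scale` times
#' the maximum activation observed in the layer on that pass.
#' Non-targeted units are untouched, and a zero noise scale leaves the
#' network exactly unperturbed. The agent is then evaluated for a fixed
#' number of test trials under its epsilon-greedy behavior policy
#' (`eval_epsilon = 0.3`, the exploration rate used in all simulations;
#' purely greedy evaluation of an epsilon-trained policy can trap the
#' agent in action loops, which lesion noise then paradoxically breaks,
#' confounding the dose-response).
#'
#' @param target_units Integer unit indices in 1..50.
#' @param noise_scale Nonnegative noise multiplier.
#' @param n_test_trials Number of evaluation trials (default 25).
#' @param seed Optional seed for the test trials and noise draws.
#' @param eval_epsilon Exploration rate of the evaluation policy
#'   (default 0.3; set 0 for purely greedy evaluation).
#' @return A list of class `lesion_spec`.
#' @export
lesion_spec <- function(target_units, noise_scale, n_test_trials = 25L,
                        seed = NULL, eval_epsilon = 0.3) {
  target_units <- as.integer(target_units)
  stopifnot(noise_scale >= 0, all(target_units >= 1L))
  if (length(target_units) == 0L && noise_scale > 0)
    stop("empty lesion target with positive noise scale")
  structure(list(target_units = target_units, noise_scale = noise_scale,
                 n_test_trials = as.integer(n_test_trials), seed = seed,
                 eval_epsilon = eval_epsilon),
            class = "lesion_spec")
}

#' Run a single lesion test
#'
#' Evaluates the agent for `n_test_trials` trials under the evaluation
#' policy of the spec with lesion noise injected into the specified
#' units, and for comparison the same trials without any lesion (same
#' seed, so with `noise_scale = 0` the two are identical).
#'
#' @param agent A trained `dqn_agent`.
#' @param env A [nav_env()] (typically in test phase).
#' @param spec A [lesion_spec()].
#' @return List of class `lesion_result`: `success_fraction`, `steps`,
#'   `baseline_success_fraction`, `noise_scale`, `n_trials`.
#' @export
run_lesion <- function(agent, env, spec) {
  stopifnot(inherits(spec, "lesion_spec"))
  base <- evaluate_agent(agent, env, n_trials = spec$n_test_trials,
                         seed = spec$seed, epsilon = spec$eval_epsilon)
  les <- evaluate_agent(agent, env, n_trials = spec$n_test_trials,
                        seed = spec$seed, lesion_units = spec$target_units,
                        noise_scale = spec$noise_scale,
                        epsilon = spec$eval_epsilon)
  structure(list(success_fraction = les$success_fraction,
                 steps = les$steps,
                 baseline_success_fraction = base$success_fraction,
                 noise_scale = spec$noise_scale,
                 n_trials = spec$n_test_trials),
            class = "lesion_result")
}

#' Sweep lesion noise over units or classes
#'
#' `run_noise_sweep` lesions a fixed unit set at each noise level.
#' `run_population_lesions` lesions each representation class (from a
#' [classify_population()] result) at each noise level; classes with no
#' members are reported with `NA` success (absent, not an error).
#'
#' @param agent A trained `dqn_agent`.
#' @param env A [nav_env()].
#' @param units Integer unit indices for `run_noise_sweep`.
#' @param classification A `unit_classification` for
#'   `run_population_lesions`.
#' @param noise_levels Numeric vector of noise scales.
#' @param n_test_trials Trials per level (default 25).
#' @param seed Optional base seed (per-level seeds derived from it).
#' @param eval_epsilon Exploration rate during evaluation (default 0.3).
#' @return A data.frame with one row per (target, noise level):
#'   `target`, `noise_scale`, `success_fraction`, `n_units`, `n_trials`.
#' @export
run_noise_sweep <- function(agent, env, units, noise_levels,
                            n_test_trials = 25L, seed = NULL,
                            eval_epsilon = 0.3) {
  base <- evaluate_agent(agent, env, n_trials = n_test_trials,
                         seed = if (is.null(seed)) NULL else seed,
                         epsilon = eval_epsilon)
  rows <- lapply(seq_along(noise_levels), function(k) {
    les <- evaluate_agent(agent, env, n_trials = n_test_trials,
                          seed = if (is.null(seed)) NULL else seed + k,
                          lesion_units = units,
                          noise_scale = noise_levels[k],
                          epsilon = eval_epsilon)
    data.frame(target = "units", noise_scale = noise_levels[k],
               success_fraction = les$success_fraction,
               baseline = base$success_fraction,
               n_units = length(units), n_trials = n_test_trials)
  })
  do.call(rbind, rows)
}

#' @rdname run_noise_sweep
#' @export
run_population_lesions <- function(agent, env, classification, noise_levels,
                                   n_test_trials = 25L, seed = NULL,
                                   eval_epsilon = 0.3) {
  stopifnot(inherits(classification, "unit_classification"))
  rows <- list()
  for (cls in UNIT_CLASSES) {
    members <- classification$table$unit[classification$table$label == cls]
    for (k in seq_along(noise_levels)) {
      sf <- NA_real_
      base <- NA_real_
      if (length(members) > 0L) {
        sp <- lesion_spec(members, noise_levels[k], n_test_trials,
                          seed = if (is.null(seed)) NULL else seed + k,
                          eval_epsilon = eval_epsilon)
        res <- run_lesion(agent, env, sp)
        sf <- res$success_fraction
        base <- res$baseline_success_fraction
      }
      rows[[length(rows) + 1L]] <- data.frame(
        target = cls, noise_scale = noise_levels[k], success_fraction = sf,
        baseline = base, n_units = length(members), n_trials = n_test_trials)
    }
  }
  do.call(rbind, rows)
}

#' Success rate of a uniformly random policy
#'
#' Monte-Carlo estimate of the chance success level that a fully
#' disrupted agent degrades towards.
#'
#' @param env A [nav_env()].
#' @param n_trials Number of random-walk episodes.
#' @param seed Optional seed.
#' @return Fraction of successful episodes.
#' @export
random_policy_success <- function(env, n_trials = 100L, seed = NULL) {
  run <- function() {
    nA <- n_actions(env$space)
    succ <- logical(n_trials)
    for (tr in seq_len(n_trials)) {
      env_reset(env)
      repeat {
        st <- env_step(env, sample.int(nA, 1L))
        if (st$terminal) break
      }
      succ[tr] <- env$success
    }
    mean(succ)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
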