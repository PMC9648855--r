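# hexnav

Deep reinforcement learning of allocentric and egocentric navigation in
hexagonal-grid arenas, with analysis of the spatial representations that
emerge in the learner.

## The problem

When an animal (or an agent) navigates, it can act in a world-fixed
reference frame — *allocentric*: "move north-east", guided by stable
distal landmarks — or in a body-fixed frame — *egocentric*: "turn left,
go forward". Which strategy wins should depend on the task: reaching a
fixed, unmarked place (guidance) versus approaching a visible cue that
keeps moving (aiming). And whichever strategy is used should shape the
internal spatial code: place-cell-like units (location-tuned, invariant
to head direction) versus egocentric-vector units (tuned to the cue at a
fixed distance and bearing from the agent's facing direction).

`hexnav` is a self-contained test bed for these questions, for
computational neuroscientists and RL researchers. It provides:

* square arenas with a hexagonal movement lattice, colored walls, point
  lights and a red cue cylinder, rendered procedurally into 12 × 48 × 3
  panoramic RGB observations with a 240° field of view;
* guidance and aiming tasks (+1 at the goal, −1 per step, 100-step
  episodes), with train/test splits of start or cue locations,
  arena-size and spatial-information manipulations;
* three action spaces: allocentric (6 lattice moves + 6 absolute
  rotations), egocentric (forward / turn left / turn right), and the
  combined "full" space (12 + 4 × 3 = 24 actions, each egocentric action
  duplicated so the strategies compete at equal width);
* a convolutional dueling double deep Q-network (32/64/64 filters of
  5 × 5; a 50-unit analysis layer with dropout 0.35; ε-greedy ε = 0.3,
  γ = 0.99, Adam with α = 0.001, 3000-transition FIFO replay),
  implemented from scratch in Rcpp/RcppArmadillo and verified against
  independent oracles;
* rate-map analysis of the 50 hidden units on a 25 × 25 grid × 6
  headings (Gaussian smoothing σ = 2 bins), a classifier into
  place / ego-vector / head-direction-modulated / view-selective / other
  units, coverage-entropy statistics, noise-injection lesions of units
  or whole classes, and orchestrated experiments with full
  (config, seed) reproducibility.

The learning rule is Q-learning with function approximation,

    Q(s_t, a_t) <- Q(s_t, a_t) + alpha * [ r_t + gamma * max_a Q(s_{t+1}, a) - Q(s_t, a_t) ]

realized as one Adam step per replay minibatch on the squared TD error,
with double-Q targets (online argmax, target-network evaluation) and the
dueling decomposition `Q(s,a) = V(s) + A(s,a) − mean_a' A(s,a')`.

## Worked example

Train the unconstrained (full action space) model on both tasks at desk
scale (2 m arena, 17 nodes, ~1 minute per run on one CPU) and look at
the strategy that emerges:

```r
library(hexnav)

guid <- run_full_model(experiment_config("guidance", "full", "desk"), seed = 101)
guid
#> <experiment_result> guidance/full seed 101: final success 1.00, allocentric fraction 0.76

aim <- run_full_model(experiment_config("aiming", "full", "desk"), seed = 101)
aim
#> <experiment_result> aiming/full seed 101: final success 0.99, allocentric fraction 0.19
```

The printed `allocentric fraction` is the mean fraction of chosen
actions (over the final 100 trials) that were allocentric: the same
agent, free to mix both strategies, settles on mostly allocentric
actions for guidance (0.76) and mostly egocentric actions for aiming
(0.19 allocentric), while solving both tasks (final-100 success 1.00
and 0.99).

To look at the code underlying the behavior, train a constrained
guidance agent, map its 50 analysis-layer units, classify them, and
probe their causal role with noise lesions:

```r
res <- run_constrained(experiment_config("guidance", "allocentric", "desk"),
                       seed = 101, compute_maps = TRUE)
res$classification$counts
#>          place     ego_vector   hd_modulated view_selective          other
#>              0              0              3              0             47

sweep <- run_noise_sweep(res$training$agent, res$parts$env, units = 1:50,
                         noise_levels = c(0, 0.5, 1, 2, 4), seed = 42)
sweep[, c("noise_scale", "success_fraction", "baseline")]
#>   noise_scale success_fraction baseline
#> 1         0.0             1.00        1
#> 2         0.5             1.00        1
#> 3         1.0             0.96        1
#> 4         2.0             0.72        1
#> 5         4.0             0.60        1
```

Noise injected into all 50 units degrades test success monotonically
from the unlesioned baseline (zero noise leaves the network exactly
untouched). At this desk scale a short training run yields localized,
mostly head-direction-dependent fields but no strictly
direction-invariant place cells (their per-heading field centers move
by more than 5% of the arena side) — that invariance, and the
place-field coverage-entropy analysis built on it
(`coverage_entropy()`), requires the full-scale paper preset; see the
methods vignette. Generalization (`run_generalization()`) trains on 80%
of start or cue nodes and evaluates success on the held-out 20%.

See the methods vignette (`vignettes/hexnav-methods.Rmd`) for the model,
the classifier cascade, all tunable parameters, and the desk/paper scale
presets.

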