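---
title: "Methods: navigation strategies and spatial representations in a deep RL agent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: navigation strategies and spatial representations in a deep RL agent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Animals can navigate in two reference frames: *allocentrically*, choosing
actions with respect to world-fixed directions and stable landmarks ("go
north"), or *egocentrically*, with respect to their own body ("turn left,
go forward"). `hexnav` implements a computational test bed for asking when
each strategy is preferred and which neural-like spatial representations
support it. A deep reinforcement learning agent, seeing only panoramic
pixels, learns two tasks:

* **guidance** — reach a fixed, unmarked goal location, identifiable only
  through the distal landmarks (colored walls, lights);
* **aiming** — reach a visible red cue cylinder whose location moves every
  ten trials.

The agent moves on a hexagonal lattice inside a square arena and can be
given an allocentric action space (6 lattice-direction moves + 6 absolute
rotations), an egocentric one (forward, turn left, turn right), or both at
once ("full" model, with each egocentric action duplicated four times so
both strategies offer twelve actions). After training, the 50 units of the
network's penultimate layer are mapped and classified like hippocampal
recordings: place cells, egocentric vector cells, head-direction-modulated
cells, view-selective cells, or other.

## Model

### Environment and observations

The arena is a square of side `L` (2.75 m standard; 4 m and 5.5 m for
size manipulations) with a hexagonal lattice of nodes at 0.25 m spacing
(a free parameter; the full-scale default gives ~11 steps across the
arena, so optimal paths sit well inside the 100-step episode cap). One
lattice axis is aligned with the arena's x-axis and the lattice is
anchored at the center; both choices are arbitrary but fixed for
reproducibility. A heading is one of six directions 60° apart; heading
`k` points at azimuth `60k` degrees.

Observations are 12 × 48 × 3 RGB images spanning a 240° field of view (5°
per column). The renderer is procedural: one ray per column, the nearest
primitive (cue cylinder, else wall) colors a band around the horizon
whose height shrinks with distance (`half-height ∝ 1/(1 + d/d₀)`,
`d₀ = L/4`); wall brightness also decays smoothly with distance, so views
vary continuously with position. Two point lights above opposite corners
brighten columns pointing toward them with 1/d falloff. The four walls
carry distinct colors (blue/green/yellow/magenta); pure red is reserved
for the cue, whose pixels are the only ones allowed to reach full
intensity. Spatial information is degraded in two steps for the aiming
manipulations: *medium* removes the walls (lights remain), *low* also
replaces the point lights with uniform lighting, leaving the cue as the
only azimuth-dependent signal. These scene parameters are free choices
(a full 3D engine could substitute for the procedural renderer without
changing the analysis); what matters, and what the tests enforce, is
that in the high-information arena ≥99% of pose
pairs produce different images — the tasks are only solvable if views
disambiguate states — and that a 60° rotation shifts shared columns
pixel-exactly.

### Tasks and rewards

Each trial starts at a random node and heading. Rewards: +1 on the step
that reaches the goal (the step penalty is not added on that step; the
rule is exposed in `episode_config()`), −1 for every other step including
blocked moves, which leave the agent in place. A trial ends at the goal
or after 100 steps (40 in the desk preset); reaching the goal exactly on
the last step counts as success. In guidance the goal is one fixed node
(chosen once, nearest to (0.75L, 0.75L) — an arbitrary but recorded
choice); starts equal to the goal are redrawn, since a zero-length trial
is uninformative. In aiming the cue/goal node is redrawn every 10 trials.
Generalization experiments split nodes 80/20 into train/test sets —
start locations for guidance, cued goal locations for aiming (starts stay
unrestricted there).

### Network and learning

The value network is a convolutional dueling double deep Q-network:

* conv 32 filters 5×5, stride (2,2) → 22×4; conv 64 filters 5×5, stride
  (2,2), vertical zero-pad 2 → 9×2; conv 64 filters 5×5, stride (2,1),
  vertical zero-pad 2 → 3×2; flatten (384);
* fully connected layer, 50 rectified units — the analysis layer, with
  dropout (default rate 0.35) during training;
* dueling head: `Q(s,a) = V(s) + A(s,a) − mean_a' A(s,a')`.

Strides and padding are free choices (only the kernel size, filter counts
and 50-unit layer are fixed by the study design); both image axes are
downsampled so that three 5×5 layers reduce 48×12 to a small map. All
activations are rectified-linear except the linear outputs. Learning uses
Q-learning with function approximation: every environment step stores the
transition in a 3000-transition FIFO replay buffer and (once per
`train_every` steps) a uniform 32-sample minibatch drives one Adam step
(learning rate 0.001) on the squared temporal-difference error of the
*chosen* action only — so only the chosen copy of a duplicated egocentric
action is credited. Targets are double-Q: the online network picks the
argmax at `s'`, a target network (synchronized every 100 updates)
evaluates it; terminal transitions bootstrap nothing (the 100-step
timeout is treated as terminal, following the episode contract).
Exploration is ε-greedy with constant ε = 0.3. Batch size, optimizer,
sync interval, update cadence and He weight initialization are free
choices recorded in `hyper_params()`. The whole run is a deterministic
function of (configuration, seed): all randomness, including C++-side
dropout masks and lesion noise, is drawn from R's RNG.

The network itself is implemented in `src/dqn.cpp` (im2col + BLAS gemm
convolutions, hand-derived backprop, Adam). The tests verify the forward
pass against a direct-convolution oracle written independently in R, and
the gradients against central finite differences.

### Activity maps and unit classification

After training, the activation of each of the 50 units is recorded in
evaluation mode (dropout off) on a 25 × 25 grid of *continuous* positions
(bin centers, not lattice nodes) for each of the six headings, and each
heading slice is smoothed with a discrete Gaussian (σ = 2 bins, truncated
at 3σ, edge replication). For aiming, cue maps fix the agent at the arena
center and move the cue over the same grid.

Classification is a cascade with mutually exclusive labels, applied per
unit (thresholds in `classifier_params()`):

1. **other** if the unit's peak is below 1% of the layer-wide maximum
   (dead units exist under rectifiers);
2. a heading is *active* if its peak reaches 20% of the unit's global
   peak; **view_selective** if ≤2 headings are active;
3. fields are extracted per active heading: mask = bins ≥15% of peak;
   *localized* if the mask covers <50% of the environment; the field
   center is the activation-weighted centroid of the peak's connected
   component (8-connectivity flood fill);
4. **place** if all active headings are localized with pairwise centers
   within 5% of the arena side;
5. **ego_vector** if instead the centers are consistent with a field at
   a fixed egocentric distance and bearing: for cue maps the offset is
   read directly (`v_h = R(−60h)(c_h − agent)`); for position maps an
   unknown allocentric target point is fit jointly with the vector by
   least squares (`c_h = t − R(60h)v`). Vectors must agree within 5% of
   the arena side in length and one 60° sector in angle (the angular
   tolerance is our resolution of an unspecified detail);
6. **hd_modulated** if localized but neither place- nor vector-
   consistent; **other** otherwise.

The order (silent → view → place → ego-vector → hd → other) makes the
classes exclusive and mirrors the narrative order of the definitions.
Coverage analysis sums the direction-averaged maps of the place units,
normalizes to a probability distribution over the 625 bins and reports
its Shannon entropy: 9.288 bits for perfectly uniform coverage; lower
values mean concentration (e.g. around the goal).

A synthetic fixture generator (`generate_fixture_maps()`) produces maps
realizing each class's defining geometry with configurable bump width,
amplitude jitter and additive noise; the classifier must recover ≥95% of
labels at 10% noise, and 100% on clean fixtures. The hd-modulated
generator explicitly rejects center configurations that happen to be
place- or vector-consistent, so the ground truth is valid by
construction. These fixtures emulate localized Gaussian fields — they do
not emulate multi-field units, boundary-locked fields or conjunctive
codes, so classifier performance on them bounds only the stated
geometries.

### Lesions

A lesion injects, on every forward pass, independent zero-mean Gaussian
noise into each targeted unit of the 50-unit layer, with standard
deviation `noise_scale ×` the maximum activation of the layer *on that
pass* (a self-contained reading of "scaled by the maximum activation in
the layer"; a dataset-wide alternative would require a reference corpus).
Noise is redrawn every pass, and 25 test trials give success fractions
in units of 1/25. `noise_scale = 0` leaves the network exactly
untouched — the identity is bit-exact and tested. Evaluation runs under
the agent's ε-greedy behavior policy (ε = 0.3, the exploration rate
used in all simulations; `eval_epsilon` exposes the choice). A purely
greedy alternative sounds cleaner but proved misleading: greedy
execution of an ε-trained policy can fall into absorbing action loops,
and small lesion noise then *breaks* the loops and raises success,
inverting the dose-response that the lesion analysis is meant to
measure.

## Scale presets

Every experiment runs under a preset in `experiment_config()`:

* **paper**: 2.75 m arena, 0.25 m spacing (137 nodes), 100-step episodes,
  4000 trials, one update per step — the full study conditions. A single
  training at this scale is an hours-long run on one CPU.
* **desk**: 2.0 m arena, 0.5 m spacing (17 nodes), 40-step episodes,
  300 trials, one update every second step, batch 32, target sync every
  200 updates — well under a minute per training run. The
  generalization experiments use a 2.5 m arena (27 nodes, 350 trials)
  as the "larger" condition and 250 trials per strategy at low spatial
  information.

The desk preset is the package's own calibration of "as small as
possible while the phenomena still express": with it, the unconstrained
agent prefers allocentric actions in guidance and egocentric actions in
aiming in ≥4 of 5 seeds, learning curves rise clearly, and the
representation classes appear in the trained networks. All automated
checks and the acceptance script run at desk scale; the paper preset
retains the full study conditions for full-scale reproduction. What
desk-scale passes show is that the *mechanisms and trends* are
implemented correctly — full-scale quantities (such as the coverage
entropy of a mature place-cell population) require running the paper
preset.

## Numerical choices and degenerate inputs

* Ray azimuths are canonicalized to [0°, 360°) so the same world
  direction yields bit-identical geometry from any heading (exact
  rotational consistency of shared columns).
* Smoothing uses a truncated, renormalized kernel; edge replication keeps
  fields near walls from being downweighted asymmetrically.
* `extract_field` returns nothing for an all-zero map; `classify_unit`
  labels such units "other". `coverage_entropy` raises an error when no
  place units exist rather than fabricating a value.
* Exact Q-value ties in greedy selection are broken uniformly at random.
* Entropy uses the 0·log 0 = 0 convention; 0 ≤ H ≤ log₂(625) for any
  input.
* `make_split` and all `run_*` entry points accept seeds and restore the
  caller's RNG state.

## What expresses at desk scale — and what does not

Two full-scale phenomena demonstrably do *not* express under the desk
preset, and the automated checks that probe them fail by design rather
than being weakened:

* **Egocentric generalization deficit in guidance.** In arenas of 27-46
  nodes, an egocentric agent generalizes essentially perfectly to
  held-out start locations: views at unseen nodes are close to trained
  views, and episodes are short enough that near-correct homing
  suffices. The allocentric advantage on held-out starts therefore does
  not appear (if anything, short-schedule allocentric training is the
  less stable of the two). Expressing the deficit appears to require
  full-scale arenas (hundreds of nodes, 100-step episodes, thousands
  of trials).
* **Strict place cells in guidance/allocentric agents.** Units with
  localized fields are common at desk scale, but their field centers
  move with head direction by ~2.6 bins or more — above the 5 %-of-side
  tolerance — across 250-600 trials, dropout 0.35-0.5, and finer node
  spacings. Head-direction-invariant position codes evidently require
  far more training than the desk schedule provides, so the
  place-coverage entropy analysis has no units to summarize at this
  scale.

Both phenomena remain available through the paper preset.

## Known limitations

* The renderer is a deliberate abstraction: no texture, occluding
  geometry beyond cue-before-wall, shadows, or independent eye/head
  movement. Conclusions about *visual* processing transfer only at the
  level of "distal color landmarks, cue bearing/size, lighting cues".
* The desk preset's arenas are small; path lengths and view diversity
  are far below the full scale, so absolute success rates and class
  proportions at desk scale are only meaningful as trends.
* Egocentric-vector classification assumes a single dominant field per
  heading; multi-field units would be labelled hd-modulated or other.
* Training time dominates everything; the dueling double-DQN runs on one
  CPU thread through BLAS and gains nothing from GPUs here.
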