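arena_hi <- arena_config(side_length = 2.75, node_spacing = 0.25)

test_that("observations have the fixed shape, range, and are deterministic", {
  o1 <- render_observation(c(1.3, 0.8), 2L, arena_hi)
  o2 <- render_observation(c(1.3, 0.8), 2L, arena_hi)
  expect_identical(dim(o1), c(12L, 48L, 3L))
  expect_true(all(o1 >= 0 & o1 <= 1))
  expect_identical(o1, o2)
})

test_that("rotating the agent by 60 degrees shifts shared columns exactly", {
  # a +60-degree heading change shifts the 240-degree window by 12 columns;
  # the overlapping 36 columns must agree pixel-for-pixel
  pos_list <- list(c(1.375, 1.375), c(0.6, 2.0), c(2.1, 0.5))
  for (p in pos_list) {
    for (h in 0:5) {
      a <- render_observation(p, h, arena_hi)
      b <- render_observation(p, (h + 1L) %% 6L, arena_hi)
      expect_identical(a[, 13:48, ], b[, 1:36, ])
    }
  }
})

test_that("a dead-on cue reddens the center columns, matching a single-ray oracle", {
  pos <- c(1.0, 1.375)
  cue <- c(2.2, 1.375)   # straight ahead at heading 0
  obs <- render_observation(pos, 0L, arena_hi, cue_xy = cue)
  az <- column_azimuths(0L)
  hits <- vapply(seq_len(48L), function(cc) {
    oracle_ray_circle(pos, c(cos(az[cc]), sin(az[cc])), cue, 2.75 / 20)
  }, numeric(1L))
  center <- 24:25
  edge <- c(1:2, 47:48)
  expect_true(all(is.finite(hits[center])))
  expect_true(all(is.infinite(hits[edge])))
  # every center column's peak red strictly exceeds every edge column's
  expect_gt(min(apply(obs[, center, 1L], 2L, max)),
            max(apply(obs[, edge, 1L], 2L, max)))
  # red dominance only where the oracle says the cue is hit
  horizon_red <- obs[6L, , 1L] - pmax(obs[6L, , 2L], obs[6L, , 3L])
  expect_true(all(horizon_red[is.finite(hits)] > 0.4))
})

test_that("low-information scenes without a cue are column-invariant", {
  arena_low <- configure_manipulation(arena_hi, info_level = "low")
  obs <- render_observation(c(0.7, 1.9), 3L, arena_low)
  for (ch in 1:3) {
    spread <- apply(obs[, , ch], 1L, function(r) diff(range(r)))
    expect_true(all(spread == 0))
  }
})

test_that("poses are visually distinguishable in the high-information arena", {
  grid <- build_grid(arena_hi)
  set.seed(21)
  n_pairs <- 300L
  differ <- logical(n_pairs)
  for (k in seq_len(n_pairs)) {
    n1 <- sample(grid$nodes$id, 1L); h1 <- sample(0:5, 1L)
    repeat {
      n2 <- sample(grid$nodes$id, 1L); h2 <- sample(0:5, 1L)
      if (n1 != n2 || h1 != h2) break
    }
    o1 <- render_observation(c(grid$nodes$x[n1], grid$nodes$y[n1]), h1, arena_hi)
    o2 <- render_observation(c(grid$nodes$x[n2], grid$nodes$y[n2]), h2, arena_hi)
    differ[k] <- any(o1 != o2)
  }
  expect_gte(mean(differ), 0.99)
})

test_that("approaching the cue head-on never shrinks its red footprint", {
  cue <- c(2.2, 1.375)
  xs <- seq(0.4, 1.9, by = 0.25)   # straight approach along heading 0
  red_count <- vapply(xs, function(x) {
    obs <- render_observation(c(x, 1.375), 0L, arena_hi, cue_xy = cue)
    sum(obs[, , 1L] > 0.5 & obs[, , 1L] - pmax(obs[, , 2L], obs[, , 3L]) > 0.3)
  }, numeric(1L))
  expect_true(all(diff(red_count) >= 0))
  expect_gt(red_count[length(red_count)], red_count[1L])
})

test_that("observation vectors flatten consistently for the network", {
  obs <- render_observation(c(1.0, 1.0), 0L, arena_hi)
  v <- obs_to_vec(obs)
  expect_length(v, 1728L)
  expect_identical(array(v, dim = c(12L, 48L, 3L)), obs)
})
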