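test_that("action spaces have the stated cardinalities and composition", {
  allo <- build_action_space("allocentric")
  ego <- build_action_space("egocentric")
  full <- build_action_space("full", copies = 4L)
  expect_identical(n_actions(allo), 12L)
  expect_identical(n_actions(ego), 3L)
  expect_identical(n_actions(full), 24L)
  expect_identical(sum(grepl("^ego", full$actions$family)), 12L)
  expect_identical(sum(is_allocentric(full)), 12L)
  # allocentric block: 6 moves + 6 rotations, each with parameter 0..5
  expect_setequal(allo$actions$parameter[allo$actions$family == "allo_move"], 0:5)
  expect_setequal(allo$actions$parameter[allo$actions$family == "allo_rotate"], 0:5)
  # copies are distinguished by index but not family
  expect_setequal(full$actions$copy_index[grepl("^ego", full$actions$family)],
                  rep(0:3, each = 3L))
  full2 <- build_action_space("full", copies = 2L)
  expect_identical(n_actions(full2), 18L)
})

grid_small <- build_grid(arena_config(side_length = 2.0, node_spacing = 0.5))
interior <- grid_small$nodes$id[rowSums(!is.na(grid_small$adjacency)) == 6L][1L]
boundary <- grid_small$nodes$id[rowSums(!is.na(grid_small$adjacency)) < 6L][1L]
full_space <- build_action_space("full")

test_that("allocentric moves are heading-invariant, egocentric moves are not", {
  move0 <- full_space$actions[full_space$actions$family == "allo_move" &
                              full_space$actions$parameter == 0L, ][1L, ]
  nodes <- vapply(0:5, function(h) {
    apply_action(pose(interior, h), move0, grid_small)$new_pose$node
  }, integer(1L))
  expect_identical(length(unique(nodes)), 1L)

  fwd <- full_space$actions[full_space$actions$family == "ego_forward", ][1L, ]
  fwd_nodes <- vapply(0:5, function(h) {
    apply_action(pose(interior, h), fwd, grid_small)$new_pose$node
  }, integer(1L))
  expect_gt(length(unique(fwd_nodes)), 1L)
})

test_that("three turns reverse the forward direction", {
  fwd <- full_space$actions[full_space$actions$family == "ego_forward", ][1L, ]
  left <- full_space$actions[full_space$actions$family == "ego_turn_left", ][1L, ]
  p <- pose(interior, 0L)
  ahead <- apply_action(p, fwd, grid_small)$new_pose$node
  for (k in 1:3) p <- apply_action(p, left, grid_small)$new_pose
  expect_identical(p$heading, 3L)
  behind <- apply_action(p, fwd, grid_small)$new_pose$node
  xy <- grid_small$nodes
  d_ahead <- c(xy$x[ahead] - xy$x[interior], xy$y[ahead] - xy$y[interior])
  d_behind <- c(xy$x[behind] - xy$x[interior], xy$y[behind] - xy$y[interior])
  expect_equal(d_behind, -d_ahead, tolerance = 1e-9)
})

test_that("rotations and turns never collide and never change the node", {
  for (h in 0:5) {
    for (fam in c("allo_rotate", "ego_turn_left", "ego_turn_right")) {
      acts <- full_space$actions[full_space$actions$family == fam, ]
      for (r in seq_len(nrow(acts))) {
        out <- apply_action(pose(boundary, h), acts[r, ], grid_small)
        expect_false(out$collided)
        expect_identical(out$new_pose$node, boundary)
      }
    }
  }
  # absolute rotation: heading becomes the action parameter
  rot4 <- full_space$actions[full_space$actions$family == "allo_rotate" &
                             full_space$actions$parameter == 4L, ]
  expect_identical(apply_action(pose(interior, 1L), rot4, grid_small)$new_pose$heading, 4L)
})

test_that("blocked moves collide and leave the pose unchanged", {
  blocked_dir <- which(is.na(grid_small$adjacency[boundary, ]))[1L] - 1L
  mv <- full_space$actions[full_space$actions$family == "allo_move" &
                           full_space$actions$parameter == blocked_dir, ]
  out <- apply_action(pose(boundary, 2L), mv, grid_small)
  expect_true(out$collided)
  expect_identical(out$new_pose$node, boundary)
  expect_identical(out$new_pose$heading, 2L)
})

test_that("all copies of an egocentric action produce identical outcomes", {
  fams <- c("ego_forward", "ego_turn_left", "ego_turn_right")
  for (fam in fams) {
    copies <- full_space$actions[full_space$actions$family == fam, ]
    expect_identical(nrow(copies), 4L)
    for (node in c(interior, boundary)) {
      for (h in 0:5) {
        outs <- lapply(seq_len(nrow(copies)), function(r) {
          apply_action(pose(node, h), copies[r, ], grid_small)
        })
        for (k in 2:4) expect_identical(outs[[k]], outs[[1L]])
      }
    }
  }
})

test_that("the action table exports with stable indices", {
  df <- as.data.frame(full_space)
  expect_named(df, c("index", "family", "parameter", "copy_index"))
  expect_identical(df$index, 1:24)
  expect_identical(df$family[1:6], rep("allo_move", 6L))
})
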