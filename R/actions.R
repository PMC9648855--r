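#' Build an action space
#'
#' Three action spaces realize the two navigation strategies:
#' * `"allocentric"`: 12 actions — move by one lattice edge in one of six
#'   world-fixed directions, or rotate in place to one of six absolute
#'   head directions.
#' * `"egocentric"`: 3 actions — step forward along the current heading,
#'   or turn in place 60 degrees left or right.
#' * `"full"`: both spaces at once. To remove the 12-vs-3 cardinality
#'   bias, each egocentric action appears in `copies` interchangeable
#'   copies (default 4), giving 12 + 4 x 3 = 24 actions. Copies are
#'   physically identical; during learning, credit goes only to the copy
#'   that was chosen.
#'
#' @param name One of `"allocentric"`, `"egocentric"`, `"full"`.
#' @param copies Number of copies of each egocentric action in the full
#'   space (>= 1). Ignored for the constrained spaces, which always use a
#'   single copy.
#' @return An object of class `action_space`: list with `name` and
#'   `actions`, a data.frame with columns `index`, `family`
#'   (`allo_move`, `allo_rotate`, `ego_forward`, `ego_turn_left`,
#'   `ego_turn_right`), `parameter` (direction/heading 0..5 for the
#'   allocentric families, `NA` otherwise) and `copy_index` (0-based).
#' @export
build_action_space <- function(name = c("allocentric", "egocentric", "full"),
                               copies = 4L) {
  name <- match.arg(name)
  copies <- as.integer(copies)
  stopifnot(copies >= 1L)
  allo <- data.frame(
    family = rep(c("allo_move", "allo_rotate"), each = 6L),
    parameter = rep(0:5, times = 2L),
    copy_index = 0L,
    stringsAsFactors = FALSE)
  ego1 <- data.frame(
    family = c("ego_forward", "ego_turn_left", "ego_turn_right"),
    parameter = NA_integer_,
    copy_index = 0L,
    stringsAsFactors = FALSE)
  actions <- switch(name,
    allocentric = allo,
    egocentric = ego1,
    full = {
      ego <- do.call(rbind, lapply(seq_len(copies) - 1L, function(k) {
        e <- ego1; e$copy_index <- k; e
      }))
      rbind(allo, ego)
    })
  actions <- cbind(index = seq_len(nrow(actions)), actions)
  rownames(actions) <- NULL
  structure(list(name = name, actions = actions), class = "action_space")
}

#' @export
print.action_space <- function(x, ...) {
  cat(sprintf("<action_space> %s: %d actions\n", x$name, nrow(x$actions)))
  invisible(x)
}

#' Number of actions in an action space
#' @param space An `action_space`.
#' @return Integer count.
#' @export
n_actions <- function(space) nrow(space$actions)

#' Is each action allocentric?
#'
#' Copies of egocentric actions count as egocentric; used for the
#' strategy-preference curves.
#'
#' @param space An `action_space`.
#' @return Logical vector, one entry per action index.
#' @export
is_allocentric <- function(space) {
  space$actions$family %in% c("allo_move", "allo_rotate")
}

#' Apply an action to a pose
#'
#' Deterministic transition dynamics on the lattice:
#' * `allo_move(d)` attempts a move to the neighbor in world direction
#'   `d`, irrespective of the current heading (the heading is unchanged).
#' * `allo_rotate(h)` sets the heading to the absolute direction `h`.
#' * `ego_forward` attempts a move in the direction of the current
#'   heading.
#' * `ego_turn_left` / `ego_turn_right` change the heading by +60 / -60
#'   degrees.
#' A move whose target neighbor is absent from the grid (blocked by the
#' arena boundary) leaves the agent in place and is flagged as a
#' collision. Rotations and turns never collide.
#'
#' @param p A [pose()].
#' @param action One row of an `action_space`'s `actions` table (or any
#'   list with `family` and `parameter`).
#' @param grid A `hex_grid`.
#' @return List with `new_pose` (a `pose`) and `collided` (logical).
#' @export
apply_action <- function(p, action, grid) {
  node <- p$node
  heading <- p$heading
  family <- as.character(action$family)
  move_dir <- switch(family,
    allo_move = as.integer(action$parameter),
    ego_forward = heading,
    NA_integer_)
  if (!is.na(move_dir)) {
    target <- grid$adjacency[node, move_dir + 1L]
    if (is.na(target)) {
      return(list(new_pose = pose(node, heading), collided = TRUE))
    }
    return(list(new_pose = pose(target, heading), collided = FALSE))
  }
  new_heading <- switch(family,
    allo_rotate = as.integer(action$parameter),
    ego_turn_left = rotate_heading(heading, +1L),
    ego_turn_right = rotate_heading(heading, -1L),
    stop("unknown action family: ", family))
  list(new_pose = pose(node, new_heading), collided = FALSE)
}

#' Export the action table
#'
#' @param x An `action_space`.
#' @param ... Unused.
#' @return The action table as a data.frame (index, family, parameter,
#'   copy_index), suitable for writing to CSV.
#' @export
as.data.frame.action_space <- function(x, ...) x$actions
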