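#' Arena configuration
#'
#' Describes a square arena in which an agent navigates on a hexagonal
#' lattice of nodes. The arena is bounded by four walls carrying distinct
#' colors that act as distal landmarks; a red cylinder can be placed on a
#' node as a salient cue, and point lights provide additional directional
#' information. The spatial-information content of the scene is controlled
#' by `walls_present` and `lighting_mode`.
#'
#' @param side_length Side of the square arena in meters. The standard
#'   arena is 2.75 m; 4 m and 5.5 m are used for size-generalization
#'   experiments. Any positive value is accepted.
#' @param node_spacing Distance between adjacent lattice nodes in meters
#'   (edge length of the hexagonal lattice).
#' @param walls_present Logical; if `FALSE` the walls are removed from the
#'   rendered scene (the arena boundary still blocks movement).
#' @param lighting_mode One of `"high"` (point lights), `"medium"` (point
#'   lights, used together with `walls_present = FALSE`) or `"low"`
#'   (uniform distant light, no point lights).
#' @param wall_colors 4 x 3 numeric matrix of RGB triples in \[0, 1\], one
#'   row per wall in order west (x = 0), east (x = L), south (y = 0),
#'   north (y = L). Must be pairwise distinct; pure red is reserved for
#'   the cue cylinder.
#' @param goal_node Node id of the goal, or `NA` (chosen later).
#' @param cue_node Node id of the cue cylinder, or `NA` (no cue).
#'
#' @return An object of class `arena_config`.
#' @export
arena_config <- function(side_length = 2.75,
                         node_spacing = 0.25,
                         walls_present = TRUE,
                         lighting_mode = c("high", "medium", "low"),
                         wall_colors = default_wall_colors(),
                         goal_node = NA_integer_,
                         cue_node = NA_integer_) {
  lighting_mode <- match.arg(lighting_mode)
  stopifnot(is.numeric(side_length), length(side_length) == 1L, side_length > 0)
  stopifnot(is.numeric(node_spacing), length(node_spacing) == 1L, node_spacing > 0)
  wall_colors <- as.matrix(wall_colors)
  if (!all(dim(wall_colors) == c(4L, 3L)) || any(wall_colors < 0) || any(wall_colors > 1))
    stop("wall_colors must be a 4 x 3 matrix of RGB values in [0, 1]")
  if (anyDuplicated(apply(wall_colors, 1L, paste, collapse = ",")))
    stop("the four wall colors must be distinct")
  structure(
    list(side_length = side_length,
         node_spacing = node_spacing,
         walls_present = isTRUE(walls_present),
         lighting_mode = lighting_mode,
         wall_colors = wall_colors,
         goal_node = as.integer(goal_node),
         cue_node = as.integer(cue_node)),
    class = "arena_config")
}

#' Default wall colors
#'
#' Blue, green, yellow and magenta for the west, east, south and north
#' walls. Pure red is reserved for the cue cylinder so that cue pixels are
#' unambiguous in the rendered observation.
#'
#' @return 4 x 3 numeric matrix.
#' @export
default_wall_colors <- function() {
  rbind(west  = c(0.10, 0.25, 0.95),
        east  = c(0.10, 0.85, 0.20),
        south = c(0.90, 0.85, 0.10),
        north = c(0.85, 0.15, 0.85))
}

#' @export
print.arena_config <- function(x, ...) {
  cat(sprintf("<arena_config> %.3g m square, spacing %.3g m, walls %s, lighting %s\n",
              x$side_length, x$node_spacing,
              if (x$walls_present) "on" else "off", x$lighting_mode))
  cat(sprintf("  goal node: %s, cue node: %s\n",
              ifelse(is.na(x$goal_node), "unset", x$goal_node),
              ifelse(is.na(x$cue_node), "unset", x$cue_node)))
  invisible(x)
}

# Lattice direction table: direction d (0..5) points at azimuth 60*d degrees.
# Axial basis: u = spacing * (1, 0), v = spacing * (cos 60, sin 60).
hex_axial_offsets <- function() {
  # (di, dj) displacement in axial coordinates for directions 0..5
  cbind(di = c(1L, 0L, -1L, -1L, 0L, 1L),
        dj = c(0L, 1L, 1L, 0L, -1L, -1L))
}

#' Unit vector for a lattice heading
#'
#' Heading `h` (0..5) points at azimuth `60 * h` degrees, measured
#' counter-clockwise from the arena's x-axis.
#'
#' @param h Integer heading(s) in 0..5.
#' @return A length-2 vector (or 2-column matrix) of (x, y) components.
#' @export
heading_vector <- function(h) {
  ang <- (h %% 6) * pi / 3
  if (length(h) == 1L) c(cos(ang), sin(ang)) else cbind(cos(ang), sin(ang))
}

#' Rotate a lattice heading
#'
#' Headings form the cyclic group of order six (60-degree increments);
#' `delta` of +3 is a 180-degree turn, achieved by the egocentric agent
#' with three successive single turns.
#'
#' @param h Heading(s) in 0..5.
#' @param delta Signed integer number of 60-degree steps.
#' @return `(h + delta) mod 6`.
#' @export
rotate_heading <- function(h, delta) {
  stopifnot(all(h %in% 0:5))
  (h + as.integer(delta)) %% 6L
}

#' Build the hexagonal movement lattice of an arena
#'
#' Enumerates the maximal hexagonal lattice with the configured spacing
#' whose nodes lie strictly inside the square arena. One lattice axis is
#' aligned with the arena's x-axis and the lattice is anchored at the
#' arena center. Nodes close to a wall are kept; walls act through the
#' collision rule (a missing neighbor), not through the geometry.
#'
#' @param config An [arena_config()].
#' @return An object of class `hex_grid` with elements
#'   `nodes` (data.frame: `id`, `x`, `y`, axial `i`, `j`),
#'   `adjacency` (N x 6 integer matrix, `NA` where the neighbor would fall
#'   outside the arena; column d+1 holds the neighbor in lattice direction
#'   d), `spacing` and `side`.
#' @export
build_grid <- function(config) {
  stopifnot(inherits(config, "arena_config"))
  L <- config$side_length
  s <- config$node_spacing
  if (s >= L) stop("degenerate grid: node_spacing must be smaller than side_length")
  eps <- 1e-9
  rng <- ceiling(L / s) + 2L
  ij <- expand.grid(i = -rng:rng, j = -rng:rng)
  x <- L / 2 + ij$i * s + ij$j * s / 2
  y <- L / 2 + ij$j * s * sqrt(3) / 2
  keep <- x > eps & x < L - eps & y > eps & y < L - eps
  if (!any(keep)) stop("degenerate grid: no node fits inside the arena")
  nodes <- data.frame(id = seq_len(sum(keep)),
                      x = x[keep], y = y[keep],
                      i = ij$i[keep], j = ij$j[keep])
  key <- paste(nodes$i, nodes$j, sep = ",")
  lookup <- stats::setNames(nodes$id, key)
  off <- hex_axial_offsets()
  adjacency <- matrix(NA_integer_, nrow = nrow(nodes), ncol = 6L)
  for (d in 1:6) {
    nk <- paste(nodes$i + off[d, 1L], nodes$j + off[d, 2L], sep = ",")
    hit <- lookup[nk]
    adjacency[, d] <- unname(hit)
  }
  structure(list(nodes = nodes, adjacency = adjacency, spacing = s, side = L),
            class = "hex_grid")
}

#' @export
print.hex_grid <- function(x, ...) {
  cat(sprintf("<hex_grid> %d nodes, spacing %.3g m in a %.3g m square\n",
              nrow(x$nodes), x$spacing, x$side))
  invisible(x)
}

#' Agent pose
#'
#' A pose is a lattice node together with one of six head directions.
#'
#' @param node Node id, valid in the grid the pose is used with.
#' @param heading Integer heading in 0..5 (azimuth `60 * heading` degrees).
#' @return An object of class `pose`.
#' @export
pose <- function(node, heading) {
  heading <- as.integer(heading)
  if (!heading %in% 0:5) stop("heading must be an integer in 0..5")
  structure(list(node = as.integer(node), heading = heading), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> node %d, heading %d (%d deg)\n", x$node, x$heading, 60L * x$heading))
  invisible(x)
}

#' Export a grid as a plain table
#'
#' One row per node: id, position, and the six neighbor ids (-1 where the
#' move is blocked by the arena boundary).
#'
#' @param x A `hex_grid`.
#' @param ... Unused.
#' @return A data.frame with columns `id`, `x`, `y`, `nbr0` .. `nbr5`.
#' @export
as.data.frame.hex_grid <- function(x, ...) {
  adj <- x$adjacency
  adj[is.na(adj)] <- -1L
  colnames(adj) <- paste0("nbr", 0:5)
  cbind(x$nodes[, c("id", "x", "y")], as.data.frame(adj))
}

#' Write / read an arena configuration as YAML
#'
#' @param config An [arena_config()].
#' @param path File path.
#' @return `write_arena_config` returns `path` invisibly;
#'   `read_arena_config` returns an `arena_config`.
#' @export
write_arena_config <- function(config, path) {
  stopifnot(inherits(config, "arena_config"))
  obj <- unclass(config)
  obj$wall_colors <- lapply(seq_len(nrow(config$wall_colors)),
                            function(r) unname(config$wall_colors[r, ]))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_arena_config
#' @export
read_arena_config <- function(path) {
  obj <- yaml::read_yaml(path)
  arena_config(side_length = obj$side_length,
               node_spacing = obj$node_spacing,
               walls_present = obj$walls_present,
               lighting_mode = obj$lighting_mode,
               wall_colors = do.call(rbind, obj$wall_colors),
               goal_node = obj$goal_node %||% NA_integer_,
               cue_node = obj$cue_node %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pick the default guidance goal node
#'
#' The goal is unmarked and fixed in space; its exact position is a free
#' choice of the experiment. We place it on the lattice node nearest to
#' the point (0.75 L, 0.75 L) in the arena's upper-right quadrant, which
#' keeps it away from both the center and the walls.
#'
#' @param grid A `hex_grid`.
#' @return A node id.
#' @export
default_goal_node <- function(grid) {
  tx <- 0.75 * grid$side
  ty <- 0.75 * grid$side
  d2 <- (grid$nodes$x - tx)^2 + (grid$nodes$y - ty)^2
  grid$nodes$id[which.min(d2)]
}
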