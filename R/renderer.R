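#' Procedural panoramic renderer
#'
#' Observations are 12 x 48 x 3 RGB images covering a 240-degree field of
#' view centered on the agent's heading. For each of the 48 columns
#' (5 degrees each) a single ray is cast from the agent's position; the
#' nearest intersected primitive (cue cylinder, else a wall) determines
#' the column's surface color, and the apparent distance of that surface
#' sets the vertical extent of the colored band around the horizon
#' (nearer surfaces fill more of the 12 rows). Wall brightness also falls
#' off smoothly with distance, so that observations vary continuously
#' with position. Two point lights above opposite corners brighten
#' columns whose azimuth points toward them, with intensity decaying with
#' distance; in the low-information lighting mode the scene is lit
#' uniformly and, with walls removed, only the cue produces any
#' azimuth-dependent structure.
#'
#' @name panoramic_renderer
NULL

OBS_ROWS <- 12L
OBS_COLS <- 48L
FOV_DEG <- 240

# scene constants (free choices of the renderer, fixed for reproducibility)
SKY_COLOR <- c(0.55, 0.70, 0.95)
FLOOR_COLOR <- c(0.35, 0.28, 0.22)
CUE_COLOR <- c(1.00, 0.05, 0.05)
NONCUE_CAP <- 0.97  # walls/lights never reach full intensity; reserved for the cue

#' Azimuths of the observation columns
#'
#' Column `c` (1..48) is centered on azimuth
#' `60 * heading - 120 + 5 * (c - 0.5)` degrees, so the field of view
#' spans 240 degrees centered on the heading and a 60-degree rotation
#' shifts scene content by exactly 12 columns.
#'
#' @param heading Heading in 0..5.
#' @return Numeric vector of 48 azimuths in radians.
#' @export
column_azimuths <- function(heading) {
  deg <- 60 * heading - 120 + (FOV_DEG / OBS_COLS) * (seq_len(OBS_COLS) - 0.5)
  # canonicalize to [0, 360) so that the same world direction always maps
  # to bit-identical ray geometry, whatever heading it is seen from
  (deg %% 360) * pi / 180
}

# distance along each ray (unit directions dx, dy) from (x, y) to the square
# boundary [0, L]^2, plus which wall is hit (1 west, 2 east, 3 south, 4 north)
ray_wall_hits <- function(x, y, dx, dy, L) {
  tt <- cbind(ifelse(dx < 0, -x / dx, Inf),
              ifelse(dx > 0, (L - x) / dx, Inf),
              ifelse(dy < 0, -y / dy, Inf),
              ifelse(dy > 0, (L - y) / dy, Inf))
  wall <- max.col(-tt, ties.method = "first")
  list(dist = tt[cbind(seq_along(dx), wall)], wall = wall)
}

# distance along each ray to a cylinder of radius r at (cx, cy); Inf if missed
ray_cue_hits <- function(x, y, dx, dy, cx, cy, r) {
  ox <- cx - x; oy <- cy - y
  proj <- dx * ox + dy * oy
  disc <- proj^2 - (ox^2 + oy^2 - r^2)
  t <- proj - sqrt(pmax(disc, 0))
  ifelse(disc >= 0 & t > 1e-9, t, Inf)
}

#' Render a panoramic observation
#'
#' @param position Length-2 numeric (x, y) in meters, inside the arena.
#' @param heading Integer heading in 0..5.
#' @param arena An [arena_config()].
#' @param cue_xy Optional length-2 numeric: position of the red cue
#'   cylinder; `NULL` for no cue.
#' @return A 12 x 48 x 3 numeric array with values in \[0, 1\]
#'   (rows top to bottom, columns left to right across the field of
#'   view, channels R, G, B). The result is a deterministic function of
#'   its arguments.
#' @export
render_observation <- function(position, heading, arena, cue_xy = NULL) {
  L <- arena$side_length
  x <- position[1L]; y <- position[2L]
  az <- column_azimuths(heading)
  dx <- cos(az); dy <- sin(az)
  d0 <- L / 4

  wall_hit <- ray_wall_hits(x, y, dx, dy, L)
  cue_dist <- if (!is.null(cue_xy)) {
    ray_cue_hits(x, y, dx, dy, cue_xy[1L], cue_xy[2L], L / 20)
  } else rep(Inf, OBS_COLS)

  # per-column surface: 0 none, 1 wall, 2 cue
  wall_vis <- arena$walls_present
  surf <- integer(OBS_COLS)
  if (wall_vis) surf[] <- 1L
  surf[is.finite(cue_dist) & (!wall_vis | cue_dist < wall_hit$dist)] <- 2L
  surf_dist <- ifelse(surf == 2L, cue_dist, wall_hit$dist)

  # surface base colors (3 x 48)
  shade <- 0.35 + 0.65 / (1 + surf_dist / (L / 2))
  col_surface <- matrix(0, nrow = 3L, ncol = OBS_COLS)
  if (wall_vis) {
    col_surface[] <- t(arena$wall_colors[wall_hit$wall, , drop = FALSE]) *
      rep(shade, each = 3L)
  }
  is_cue <- surf == 2L
  if (any(is_cue)) {
    cue_shade <- 0.55 + 0.45 / (1 + surf_dist[is_cue] / (L / 2))
    col_surface[, is_cue] <- CUE_COLOR * rep(cue_shade, each = 3L)
  }

  # point lights above opposite corners brighten nearby-azimuth columns
  light <- rep(1, OBS_COLS)
  if (arena$lighting_mode != "low") {
    for (lp in list(c(0, 0), c(L, L))) {
      lx <- lp[1L] - x; ly <- lp[2L] - y
      laz <- atan2(ly, lx)
      ldist <- sqrt(lx^2 + ly^2)
      dang <- ((az - laz + pi) %% (2 * pi)) - pi
      light <- light + (0.8 / (1 + ldist)) * exp(-0.5 * (dang / (15 * pi / 180))^2)
    }
  }

  # vertical split: band of surface color around the horizon (rows 6/7),
  # half-height shrinking with distance; sky above, floor below
  rowc <- seq_len(OBS_ROWS)  # 1 = top
  hh <- pmax(6 / (1 + surf_dist / d0), 0.55)
  hh[surf == 2L] <- pmax(7 / (1 + surf_dist[surf == 2L] / d0), 0.8)
  hh[surf == 0L] <- 0  # open horizon: no band
  band <- outer(rowc, hh, function(r, h) abs(r - 6.5) <= h)

  sky_grad <- 0.75 + 0.04 * rowc   # vertical-only gradients (column-invariant)
  floor_grad <- 1.15 - 0.03 * rowc

  obs <- array(0, dim = c(OBS_ROWS, OBS_COLS, 3L))
  upper <- outer(rowc, rep(6.5, OBS_COLS), `<`)
  for (ch in 1:3) {
    plane <- ifelse(upper, SKY_COLOR[ch] * sky_grad, FLOOR_COLOR[ch] * floor_grad)
    band_col <- matrix(col_surface[ch, ], nrow = OBS_ROWS, ncol = OBS_COLS,
                       byrow = TRUE)
    plane[band] <- band_col[band]
    plane <- plane * matrix(light, nrow = OBS_ROWS, ncol = OBS_COLS, byrow = TRUE)
    cue_px <- band & matrix(is_cue, OBS_ROWS, OBS_COLS, byrow = TRUE)
    plane[!cue_px] <- pmin(plane[!cue_px], NONCUE_CAP)
    obs[, , ch] <- pmin(pmax(plane, 0), 1)
  }
  obs
}

#' Render the observation for a pose on a grid
#'
#' Convenience wrapper around [render_observation()]: looks up the node
#' position and, when the arena carries a cue node, the cue position.
#'
#' @param p A [pose()].
#' @param arena An [arena_config()].
#' @param grid A `hex_grid`.
#' @return A 12 x 48 x 3 array.
#' @export
render_pose <- function(p, arena, grid) {
  xy <- c(grid$nodes$x[p$node], grid$nodes$y[p$node])
  cue_xy <- if (!is.na(arena$cue_node)) {
    c(grid$nodes$x[arena$cue_node], grid$nodes$y[arena$cue_node])
  } else NULL
  render_observation(xy, p$heading, arena, cue_xy)
}

#' Flatten an observation for the network
#'
#' @param obs A 12 x 48 x 3 array.
#' @return Numeric vector of length 1728 (column-major).
#' @export
obs_to_vec <- function(obs) as.numeric(obs)

#' Write an observation to a PNG file (debugging aid)
#'
#' @param obs A 12 x 48 x 3 array.
#' @param path Output file.
#' @param scale Integer pixel upscaling factor.
#' @return `path`, invisibly.
#' @export
write_observation_png <- function(obs, path, scale = 8L) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG export")
  big <- obs[rep(seq_len(dim(obs)[1L]), each = scale),
             rep(seq_len(dim(obs)[2L]), each = scale), , drop = FALSE]
  png::writePNG(big, path)
  invisible(path)
}

#' Render a six-heading contact sheet at the arena center
#'
#' Stacks the six headings' views vertically into one image; intended as
#' a quick visual fixture when tuning scene parameters.
#'
#' @param arena An [arena_config()].
#' @param grid A `hex_grid`.
#' @param path Optional PNG output path.
#' @return The stacked (72 x 48 x 3) array, invisibly if written.
#' @export
render_contact_sheet <- function(arena, grid, path = NULL) {
  ctr <- c(grid$side / 2, grid$side / 2)
  cue_xy <- if (!is.na(arena$cue_node)) {
    c(grid$nodes$x[arena$cue_node], grid$nodes$y[arena$cue_node])
  } else NULL
  sheets <- lapply(0:5, function(h) render_observation(ctr, h, arena, cue_xy))
  out <- array(0, dim = c(6L * OBS_ROWS, OBS_COLS, 3L))
  for (h in 1:6) out[(h - 1L) * OBS_ROWS + seq_len(OBS_ROWS), , ] <- sheets[[h]]
  if (!is.null(path)) {
    write_observation_png(out, path)
    return(invisible(out))
  }
  out
}
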