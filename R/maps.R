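#' Spatial activity maps of the analysis layer
#'
#' Activity maps sample the activation of each of the 50 hidden units
#' over a 25 x 25 grid of positions (or cue positions) for each of the
#' six head directions, followed by Gaussian smoothing with a standard
#' deviation of 2 bins applied independently to each heading slice.
#'
#' @name representation_analysis
NULL

MAP_BINS <- 25L
MAP_SIGMA <- 2

#' Bin centers of the analysis grid
#'
#' @param side Arena side length in meters.
#' @param n_bins Number of bins per axis (default 25).
#' @return Numeric vector of bin-center coordinates in meters.
#' @export
map_bin_centers <- function(side, n_bins = MAP_BINS) {
  (seq_len(n_bins) - 0.5) * side / n_bins
}

gaussian_kernel_1d <- function(sigma, radius = ceiling(3 * sigma)) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Smooth a 2-D map with a Gaussian filter
#'
#' Separable discrete Gaussian (truncated at 3 sigma, renormalized) with
#' edge-replication boundary handling; sigma is in bin units. Smoothing
#' is linear, so slices can be smoothed in any order. The filter is
#' applied as a pair of precomputed banded operator matrices (one per
#' axis), which is algebraically identical to direct convolution with
#' replicated edges.
#'
#' @param m Numeric matrix.
#' @param sigma Standard deviation in bins (default 2).
#' @return Matrix of the same dimensions.
#' @export
gaussian_smooth <- function(m, sigma = MAP_SIGMA) {
  Kr <- smoothing_operator(nrow(m), sigma)
  Kc <- smoothing_operator(ncol(m), sigma)
  Kr %*% m %*% t(Kc)
}

.smooth_ops <- new.env(parent = emptyenv())

# n x n operator applying the 1-D truncated Gaussian with edge replication
smoothing_operator <- function(n, sigma) {
  key <- paste0(n, "_", sigma)
  hit <- .smooth_ops[[key]]
  if (!is.null(hit)) return(hit)
  k <- gaussian_kernel_1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in -r:r) {
      src <- min(max(i + o, 1L), n)
      K[i, src] <- K[i, src] + k[o + r + 1L]
    }
  }
  .smooth_ops[[key]] <- K
  K
}

new_activity_maps <- function(values, mode, arena, sigma = MAP_SIGMA) {
  stopifnot(length(dim(values)) == 4L, dim(values)[4L] == 6L)
  structure(list(values = values, mode = mode, arena = arena, sigma = sigma),
            class = "activity_maps")
}

#' @export
print.activity_maps <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<activity_maps> %s: %d units x %dx%d bins x 6 headings\n",
              x$mode, d[1L], d[2L], d[3L]))
  invisible(x)
}

smooth_all <- function(values, sigma) {
  d <- dim(values)
  for (u in seq_len(d[1L])) {
    for (h in seq_len(d[4L])) {
      values[u, , , h] <- gaussian_smooth(values[u, , , h], sigma)
    }
  }
  values
}

# render a batch of observations into an obs matrix (1728 x n)
render_batch <- function(positions, heading, arena, cue_list) {
  out <- matrix(0, 1728L, nrow(positions))
  for (i in seq_len(nrow(positions))) {
    out[, i] <- obs_to_vec(render_observation(
      c(positions[i, 1L], positions[i, 2L]), heading, arena, cue_list[[i]]))
  }
  out
}

#' Compute position activity maps
#'
#' The agent is placed at each of 25 x 25 continuous positions (bin
#' centers of the arena square, not snapped to lattice nodes) in each of
#' the six head directions; the 50-unit layer is recorded in evaluation
#' mode (dropout off) and each heading slice is Gaussian-smoothed.
#'
#' @param agent A `dqn_agent`.
#' @param arena An [arena_config()]. If it carries a cue node, the cue
#'   is rendered at that node's position (requires `grid`).
#' @param grid Optional `hex_grid`, needed only to resolve a cue node.
#' @param n_bins Bins per axis (default 25).
#' @param sigma Smoothing width in bins (default 2).
#' @return An `activity_maps` object with `values` of shape
#'   (units, x-bin, y-bin, heading).
#' @export
compute_position_maps <- function(agent, arena, grid = NULL,
                                  n_bins = MAP_BINS, sigma = MAP_SIGMA) {
  ctr <- map_bin_centers(arena$side_length, n_bins)
  pos <- as.matrix(expand.grid(x = ctr, y = ctr))
  cue_xy <- if (!is.na(arena$cue_node)) {
    stopifnot(!is.null(grid))
    c(grid$nodes$x[arena$cue_node], grid$nodes$y[arena$cue_node])
  } else NULL
  cue_list <- rep(list(cue_xy), nrow(pos))
  values <- array(0, dim = c(50L, n_bins, n_bins, 6L))
  for (h in 0:5) {
    obs <- render_batch(pos, h, arena, cue_list)
    act <- dqn_hidden(agent$ptr, obs)  # 50 x 625
    values[, , , h + 1L] <- aperm_units(t(act), n_bins)
  }
  new_activity_maps(smooth_all(values, sigma), "position_maps", arena, sigma)
}

# reorder a (x, y, unit) array into (unit, x, y)
aperm_units <- function(a, n_bins) aperm(array(a, c(n_bins, n_bins, 50L)), c(3L, 1L, 2L))

#' Compute cue activity maps
#'
#' The agent sits at the arena center while the cue is placed at each of
#' 25 x 25 positions, for each of the six head directions; analogous to
#' a receptive-field measurement relative to the cue.
#'
#' @inheritParams compute_position_maps
#' @return An `activity_maps` object (`mode = "cue_maps"`).
#' @export
compute_cue_maps <- function(agent, arena, n_bins = MAP_BINS, sigma = MAP_SIGMA) {
  ctr <- map_bin_centers(arena$side_length, n_bins)
  cue_pos <- expand.grid(x = ctr, y = ctr)
  center <- c(arena$side_length / 2, arena$side_length / 2)
  values <- array(0, dim = c(50L, n_bins, n_bins, 6L))
  for (h in 0:5) {
    obs <- matrix(0, 1728L, nrow(cue_pos))
    for (i in seq_len(nrow(cue_pos))) {
      obs[, i] <- obs_to_vec(render_observation(
        center, h, arena, c(cue_pos$x[i], cue_pos$y[i])))
    }
    act <- dqn_hidden(agent$ptr, obs)
    values[, , , h + 1L] <- aperm_units(t(act), n_bins)
  }
  new_activity_maps(smooth_all(values, sigma), "cue_maps", arena, sigma)
}

#' Export activity maps as a long-format table
#'
#' Flattens a map set to one row per (unit, x-bin, y-bin, heading) for
#' storage as plain CSV.
#'
#' @param maps An `activity_maps` object.
#' @param path Optional CSV path; if given, the table is written there.
#' @return The long data.frame (invisibly when written to `path`).
#' @export
activity_maps_table <- function(maps, path = NULL) {
  stopifnot(inherits(maps, "activity_maps"))
  d <- dim(maps$values)
  df <- expand.grid(unit = seq_len(d[1L]), x_bin = seq_len(d[2L]),
                    y_bin = seq_len(d[3L]), heading = 0:5)
  df$value <- as.numeric(maps$values)
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
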