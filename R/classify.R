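#' Classification of hidden units by spatial tuning
#'
#' Units of the 50-unit analysis layer are assigned to one of five
#' classes from their per-heading activity maps:
#' * `place`: a localized field whose center does not move with head
#'   direction (within 5% of the arena side).
#' * `ego_vector`: a localized field at a fixed distance and direction
#'   relative to where the agent is facing, i.e. the field center
#'   rotates with the heading.
#' * `hd_modulated`: localized fields whose position depends on heading
#'   without a consistent egocentric vector.
#' * `view_selective`: activity confined to one or two head directions.
#' * `other`: near-silent units and units without localized fields.
#'
#' @name unit_classification
NULL

UNIT_CLASSES <- c("place", "ego_vector", "hd_modulated", "view_selective", "other")

#' Classifier thresholds
#'
#' @param field_threshold Field mask cut as a fraction of the map peak
#'   (0.15: bins below 15% of the peak are outside the field).
#' @param localized_fraction A map counts as localized when its
#'   above-threshold area covers less than this fraction of the
#'   environment (0.5).
#' @param center_tolerance Positional tolerance as a fraction of the
#'   arena side (0.05) for both the place and egocentric-vector tests.
#' @param theta_view A heading is "active" when its peak reaches this
#'   fraction of the unit's global peak (0.2).
#' @param n_view Maximum number of active headings for a view-selective
#'   unit (2).
#' @param activity_floor Units whose global peak is below this fraction
#'   of the layer-wide maximum are labelled `other` (0.01).
#' @return A list of class `classifier_params`.
#' @export
classifier_params <- function(field_threshold = 0.15,
                              localized_fraction = 0.5,
                              center_tolerance = 0.05,
                              theta_view = 0.2,
                              n_view = 2L,
                              activity_floor = 0.01) {
  structure(list(field_threshold = field_threshold,
                 localized_fraction = localized_fraction,
                 center_tolerance = center_tolerance,
                 theta_view = theta_view,
                 n_view = as.integer(n_view),
                 activity_floor = activity_floor),
            class = "classifier_params")
}

# flood fill (8-connectivity) of the TRUE region containing (r0, c0)
connected_component <- function(mask, r0, c0) {
  n <- nrow(mask); m <- ncol(mask)
  comp <- matrix(FALSE, n, m)
  stack <- matrix(c(r0, c0), ncol = 2L)
  comp[r0, c0] <- TRUE
  while (nrow(stack) > 0L) {
    r <- stack[1L, 1L]; cc <- stack[1L, 2L]
    stack <- stack[-1L, , drop = FALSE]
    for (dr in -1:1) for (dc in -1:1) {
      rr <- r + dr; ccc <- cc + dc
      if (rr >= 1L && rr <= n && ccc >= 1L && ccc <= m &&
          mask[rr, ccc] && !comp[rr, ccc]) {
        comp[rr, ccc] <- TRUE
        stack <- rbind(stack, c(rr, ccc))
      }
    }
  }
  comp
}

#' Extract the firing field of a 2-D activity map
#'
#' The field is the connected component (8-connectivity) containing the
#' peak within the mask of bins at or above `field_threshold` times the
#' peak. The area fraction is measured on the full above-threshold mask,
#' and the map counts as localized when that fraction is below
#' `localized_fraction` of the environment. The field center is the
#' activation-weighted centroid of the peak's component.
#'
#' @param m Nonnegative numeric matrix (a single heading slice).
#' @param params A [classifier_params()].
#' @return `NULL` for an all-zero map, else a list with `peak_value`,
#'   `peak_bin`, `mask` (logical matrix of the peak's component),
#'   `area_fraction`, `centroid` (x, y in bin coordinates) and
#'   `localized`.
#' @export
extract_field <- function(m, params = classifier_params()) {
  peak <- max(m)
  if (peak <= 0) return(NULL)
  thr_mask <- m >= params$field_threshold * peak
  pk <- which(m == peak, arr.ind = TRUE)[1L, ]
  comp <- connected_component(thr_mask, pk[1L], pk[2L])
  w <- m * comp
  tot <- sum(w)
  centroid <- c(sum(row(m) * w), sum(col(m) * w)) / tot
  area_fraction <- mean(thr_mask)
  list(peak_value = peak,
       peak_bin = c(pk[[1L]], pk[[2L]]),
       mask = comp,
       area_fraction = area_fraction,
       centroid = centroid,
       localized = area_fraction < params$localized_fraction)
}

rot_mat <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2L, 2L)
}

max_pairwise_dist <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  max(stats::dist(pts))
}

# egocentric-vector test. centroids: m x 2 (bin coords), headings: 0..5.
# cue maps ('direct'): field center = agent + R(60h) v  =>  v_h = R(-60h)(c_h - agent)
# position maps ('inverse'): field center = target - R(60h) v for an unknown
# allocentric target point; (t, v) are fit by least squares.
ego_vector_fit <- function(centroids, headings, center, mode, tol_bins) {
  m <- nrow(centroids)
  R <- lapply(headings, function(h) rot_mat(h * pi / 3))
  if (mode == "cue_maps") {
    vh <- t(vapply(seq_len(m), function(k) {
      drop(t(R[[k]]) %*% (centroids[k, ] - center))
    }, numeric(2L)))
  } else {
    # least squares for c_h = t - R_h v
    Rbar <- Reduce(`+`, R) / m
    cbar <- colMeans(centroids)
    M <- matrix(0, 2L, 2L); b <- c(0, 0)
    for (k in seq_len(m)) {
      D <- R[[k]] - Rbar
      M <- M + t(D) %*% D
      b <- b - t(D) %*% (centroids[k, ] - cbar)
    }
    if (abs(det(M)) < 1e-9) return(list(ok = FALSE))
    v <- drop(solve(M, b))
    tt <- cbar + drop(Rbar %*% v)
    vh <- t(vapply(seq_len(m), function(k) {
      drop(t(R[[k]]) %*% (tt - centroids[k, ]))
    }, numeric(2L)))
  }
  radii <- sqrt(rowSums(vh^2))
  if (mean(radii) <= tol_bins) return(list(ok = FALSE))  # degenerate: no offset
  angles <- atan2(vh[, 2L], vh[, 1L])
  ang_spread <- max(vapply(seq_len(m), function(i) {
    max(abs(((angles - angles[i] + pi) %% (2 * pi)) - pi))
  }, numeric(1L)))
  ok <- max(radii) - min(radii) <= tol_bins &&
    max_pairwise_dist(vh) <= 2 * tol_bins &&
    ang_spread <= pi / 3
  list(ok = ok, v = colMeans(vh), radius = mean(radii),
       angle = atan2(mean(vh[, 2L]), mean(vh[, 1L])))
}

#' Classify a single unit from its per-heading activity maps
#'
#' Decision cascade (classes are mutually exclusive, tested in order):
#' near-silent, view-selective, place, egocentric vector,
#' head-direction-modulated, other. See [unit_classification] for the
#' class definitions and [classifier_params()] for the thresholds.
#'
#' @param maps A 25 x 25 x 6 nonnegative array (one unit, smoothed).
#' @param mode `"position_maps"` or `"cue_maps"` — selects the geometry
#'   of the egocentric-vector test.
#' @param params A [classifier_params()].
#' @param layer_max Layer-wide maximum activation used for the activity
#'   floor; defaults to the unit's own peak (floor test then only
#'   removes all-zero units).
#' @return A list of class `unit_class` with `label`, `active_headings`
#'   (0-based), per-heading `fields`, and the egocentric `vector` fit
#'   when applicable.
#' @export
classify_unit <- function(maps, mode = c("position_maps", "cue_maps"),
                          params = classifier_params(), layer_max = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(dim(maps)) == 3L, dim(maps)[3L] == 6L)
  n_bins <- dim(maps)[1L]
  tol_bins <- params$center_tolerance * n_bins
  result <- function(label, active = integer(0), fields = NULL, vec = NULL) {
    structure(list(label = label, active_headings = active, fields = fields,
                   vector = vec), class = "unit_class")
  }
  global_peak <- max(maps)
  if (is.null(layer_max)) layer_max <- global_peak
  if (global_peak < params$activity_floor * layer_max || global_peak <= 0) {
    return(result("other"))
  }
  head_peaks <- apply(maps, 3L, max)
  active <- which(head_peaks >= params$theta_view * global_peak)
  if (length(active) <= params$n_view) {
    return(result("view_selective", active - 1L))
  }
  fields <- lapply(active, function(h) extract_field(maps[, , h], params))
  names(fields) <- as.character(active - 1L)
  all_localized <- all(vapply(fields, function(f)
    !is.null(f) && f$localized, logical(1L)))
  if (all_localized) {
    centroids <- t(vapply(fields, `[[`, numeric(2L), "centroid"))
    if (max_pairwise_dist(centroids) <= tol_bins) {
      return(result("place", active - 1L, fields))
    }
    center <- rep((n_bins + 1) / 2, 2L)
    fit <- ego_vector_fit(centroids, active - 1L, center, mode, tol_bins)
    if (isTRUE(fit$ok)) {
      return(result("ego_vector", active - 1L, fields, fit))
    }
    return(result("hd_modulated", active - 1L, fields))
  }
  result("other", active - 1L, fields)
}

#' @export
print.unit_class <- function(x, ...) {
  cat(sprintf("<unit_class> %s (%d active headings)\n",
              x$label, length(x$active_headings)))
  invisible(x)
}

#' Classify every unit of an activity-map set
#'
#' @param maps An `activity_maps` object (50 units).
#' @param params A [classifier_params()]. The activity floor is applied
#'   relative to the layer-wide maximum activation.
#' @return A list of class `unit_classification` with `table`
#'   (data.frame: unit, label, n_active, ego distance/angle where
#'   applicable), `counts` (named integer vector over the five classes)
#'   and `proportions`.
#' @export
classify_population <- function(maps, params = classifier_params()) {
  stopifnot(inherits(maps, "activity_maps"))
  n_units <- dim(maps$values)[1L]
  layer_max <- max(maps$values)
  rows <- lapply(seq_len(n_units), function(u) {
    cls <- classify_unit(maps$values[u, , , ], maps$mode, params, layer_max)
    data.frame(unit = u, label = cls$label,
               n_active = length(cls$active_headings),
               ego_radius = if (!is.null(cls$vector)) cls$vector$radius else NA_real_,
               ego_angle = if (!is.null(cls$vector)) cls$vector$angle else NA_real_)
  })
  table <- do.call(rbind, rows)
  counts <- vapply(UNIT_CLASSES, function(l) sum(table$label == l), integer(1L))
  structure(list(table = table, counts = counts,
                 proportions = counts / n_units),
            class = "unit_classification")
}

#' @export
print.unit_classification <- function(x, ...) {
  cat("<unit_classification>\n")
  print(x$counts)
  invisible(x)
}

#' Shannon entropy of a probability vector
#'
#' `H = -sum p log2 p`, with the convention `0 log 0 = 0`.
#'
#' @param p Nonnegative numeric vector or matrix summing to 1.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  stopifnot(all(p >= -1e-12), abs(sum(p) - 1) < 1e-8)
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

#' Coverage statistics of place-unit maps
#'
#' Sums the direction-averaged maps of the given place units, normalizes
#' the sum to a probability distribution over the 625 bins, and reports
#' its Shannon entropy (9.288 bits for uniform coverage of a 25 x 25
#' grid), the field centers of the individual units, and their mean
#' distance to the goal.
#'
#' @param maps An `activity_maps` object.
#' @param units Integer indices of the place units (error if empty).
#' @param goal_xy Optional goal position in meters for the
#'   center-to-goal distances.
#' @param params A [classifier_params()] for the field extraction.
#' @return List of class `coverage_stats`: `prob_map` (25 x 25,
#'   sums to 1), `entropy` (bits), `centers` (n x 2 bin coordinates),
#'   `mean_center_goal_dist` (meters, `NA` without `goal_xy`).
#' @export
coverage_entropy <- function(maps, units, goal_xy = NULL,
                             params = classifier_params()) {
  stopifnot(inherits(maps, "activity_maps"))
  if (length(units) == 0L) stop("empty class: no place units to sum")
  n_bins <- dim(maps$values)[2L]
  acc <- matrix(0, n_bins, n_bins)
  centers <- matrix(NA_real_, length(units), 2L)
  for (k in seq_along(units)) {
    avg <- apply(maps$values[units[k], , , ], c(1L, 2L), mean)
    acc <- acc + avg
    f <- extract_field(avg, params)
    if (!is.null(f)) centers[k, ] <- f$centroid
  }
  if (sum(acc) <= 0) stop("summed map is identically zero")
  prob <- acc / sum(acc)
  dist_goal <- NA_real_
  if (!is.null(goal_xy)) {
    side <- maps$arena$side_length
    cx <- (centers[, 1L] - 0.5) * side / n_bins
    cy <- (centers[, 2L] - 0.5) * side / n_bins
    dist_goal <- mean(sqrt((cx - goal_xy[1L])^2 + (cy - goal_xy[2L])^2),
                      na.rm = TRUE)
  }
  structure(list(prob_map = prob, entropy = shannon_entropy(prob),
                 centers = centers, mean_center_goal_dist = dist_goal),
            class = "coverage_stats")
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat(sprintf("<coverage_stats> H = %.3f bits over %d field centers\n",
              x$entropy, nrow(x$centers)))
  invisible(x)
}
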