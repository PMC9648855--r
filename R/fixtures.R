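#' Synthetic activity-map fixtures with known ground truth
#'
#' Generates per-heading activity maps realizing the defining geometry
#' of each unit class, for validating the classifier:
#' * `place`: one Gaussian bump at the same location in all headings.
#' * `ego_vector`: a bump whose center rotates around the reference
#'   point with the heading (fixed egocentric distance and direction).
#' * `hd_modulated`: localized bumps whose centers move with heading
#'   without any consistent egocentric vector (enforced at generation).
#' * `view_selective`: a bump present in only one or two headings.
#' * `other`: either a broad non-localized blob or an almost-silent map.
#'
#' Optional multiplicative-amplitude jitter and additive noise (a
#' fraction of the bump peak) make the fixtures non-trivial; maps are
#' returned unsmoothed so the analysis smoothing step can be applied as
#' in the real pipeline. Randomness comes from the current R RNG state.
#'
#' @param label One of the five class labels.
#' @param n_bins Bins per axis (default 25).
#' @param bump_sigma Bump width in bins (default 2; wide enough that,
#'   after the pipeline's own smoothing, the stated classifier
#'   thresholds separate signal from admissible noise).
#' @param amplitude Bump peak amplitude (default 1).
#' @param noise Additive zero-mean noise amplitude as a fraction of the
#'   bump peak (default 0): each bin receives an independent uniform
#'   draw bounded by `noise * amplitude`. Raw fixtures may then dip
#'   slightly below zero; the analysis smoothing step rectifies.
#' @param radius For `ego_vector`: egocentric distance in bins (default
#'   drawn uniformly in 3..6).
#' @return List of class `fixture_maps`: `values` (n_bins x n_bins x 6),
#'   `label`, and the generating `truth` parameters.
#' @export
generate_fixture_maps <- function(label = UNIT_CLASSES, n_bins = 25L,
                                  bump_sigma = 2, amplitude = 1,
                                  noise = 0, radius = NULL) {
  label <- match.arg(label)
  center0 <- (n_bins + 1) / 2
  grid_r <- row(matrix(0, n_bins, n_bins))
  grid_c <- col(matrix(0, n_bins, n_bins))
  bump <- function(cx, cy, amp = amplitude) {
    amp * exp(-((grid_r - cx)^2 + (grid_c - cy)^2) / (2 * bump_sigma^2))
  }
  rand_center <- function() stats::runif(2L, 6, n_bins - 5)
  values <- array(0, dim = c(n_bins, n_bins, 6L))
  truth <- list()
  amp_jitter <- function() amplitude * stats::runif(1L, 0.9, 1.1)

  if (label == "place") {
    ctr <- rand_center()
    for (h in 1:6) values[, , h] <- bump(ctr[1L], ctr[2L], amp_jitter())
    truth$center <- ctr
  } else if (label == "ego_vector") {
    if (is.null(radius)) radius <- stats::runif(1L, 3, 6)
    phi <- stats::runif(1L, 0, 2 * pi)
    for (h in 1:6) {
      ang <- phi + (h - 1L) * pi / 3
      cx <- center0 + radius * cos(ang)
      cy <- center0 + radius * sin(ang)
      values[, , h] <- bump(cx, cy, amp_jitter())
    }
    truth$radius <- radius
    truth$angle <- phi
  } else if (label == "hd_modulated") {
    repeat {
      centers <- t(vapply(1:6, function(h) rand_center(), numeric(2L)))
      # must be neither place-like (centers coincide) nor ego-vector-like
      # (centers consistent with a rotating fixed offset)
      if (max_pairwise_dist(centers) <= 3) next
      fit_cue <- ego_vector_fit(centers, 0:5, rep(center0, 2L), "cue_maps", 2.5)
      fit_pos <- ego_vector_fit(centers, 0:5, rep(center0, 2L), "position_maps", 2.5)
      if (!isTRUE(fit_cue$ok) && !isTRUE(fit_pos$ok)) break
    }
    for (h in 1:6) values[, , h] <- bump(centers[h, 1L], centers[h, 2L], amp_jitter())
    truth$centers <- centers
  } else if (label == "view_selective") {
    k <- sample(1:2, 1L)
    hs <- sample(1:6, k)
    ctr <- rand_center()
    for (h in hs) values[, , h] <- bump(ctr[1L], ctr[2L], amp_jitter())
    truth$headings <- hs - 1L
    truth$center <- ctr
  } else { # other: a broad blob whose above-threshold area is not localized
    ctr <- rand_center()
    blob_sigma <- stats::runif(1L, 8, 20) * n_bins / 25
    for (h in 1:6) {
      values[, , h] <- amp_jitter() *
        exp(-((grid_r - ctr[1L])^2 + (grid_c - ctr[2L])^2) /
              (2 * blob_sigma^2))
    }
    truth$kind <- "broad"
    truth$blob_sigma <- blob_sigma
  }
  if (noise > 0) {
    # zero-mean bounded noise of the stated amplitude (|eps| <= noise * peak);
    # rectification happens after smoothing in the analysis pipeline, so no
    # clipping bias is introduced here
    values <- values + stats::runif(length(values), -noise * amplitude,
                                    noise * amplitude)
  }
  structure(list(values = values, label = label, truth = truth),
            class = "fixture_maps")
}

#' Smooth and classify a fixture
#'
#' Applies the pipeline's Gaussian smoothing to each heading slice and
#' runs the classifier; convenience wrapper used in validation.
#'
#' @param fixture A `fixture_maps` object.
#' @param mode Map mode for the egocentric-vector geometry.
#' @param params A [classifier_params()].
#' @param sigma Smoothing width in bins.
#' @return The `unit_class` result.
#' @export
classify_fixture <- function(fixture, mode = "cue_maps",
                             params = classifier_params(), sigma = MAP_SIGMA) {
  sm <- fixture$values
  for (h in 1:6) sm[, , h] <- gaussian_smooth(sm[, , h], sigma)
  sm[sm < 0] <- 0   # rate maps are nonnegative; rectify after smoothing
  classify_unit(sm, mode, params)
}
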