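test_that("field extraction recovers a Gaussian bump's center and spread", {
  grid_r <- row(matrix(0, 25L, 25L))
  grid_c <- col(matrix(0, 25L, 25L))
  bump <- exp(-((grid_r - 12)^2 + (grid_c - 12)^2) / (2 * 1.5^2))
  f <- extract_field(bump)
  expect_true(f$localized)
  expect_lt(max(abs(f$centroid - c(12, 12))), 0.5)
  expect_true(bump[f$peak_bin[1L], f$peak_bin[2L]] == max(bump))
  # a constant map is a single full-arena field, not localized
  fc <- extract_field(matrix(1, 25L, 25L))
  expect_identical(fc$area_fraction, 1)
  expect_false(fc$localized)
  # an all-zero map has no field
  expect_null(extract_field(matrix(0, 25L, 25L)))
})

test_that("fixtures of every class are classified correctly without noise", {
  set.seed(51)
  for (label in c("place", "ego_vector", "hd_modulated", "view_selective", "other")) {
    for (rep in 1:25) {
      fx <- generate_fixture_maps(label)
      got <- classify_fixture(fx, mode = "cue_maps")
      expect_identical(got$label, label)
    }
  }
})

test_that("an egocentric-vector fixture's distance is recovered within half a bin", {
  set.seed(52)
  for (rep in 1:20) {
    fx <- generate_fixture_maps("ego_vector", radius = 5)
    got <- classify_fixture(fx, mode = "cue_maps")
    expect_identical(got$label, "ego_vector")
    expect_lt(abs(got$vector$radius - 5), 0.5)
  }
})

test_that("classification is invariant under a global 60-degree rotation", {
  # rotating all fixture geometry by 60 degrees while relabeling headings
  # h -> h + 1 produces the same physical cell, hence the same class
  set.seed(53)
  for (label in c("place", "ego_vector", "view_selective", "hd_modulated")) {
    for (rep in 1:10) {
      fx <- generate_fixture_maps(label)
      rotated <- fx
      rotated$values <- fx$values[, , c(6L, 1:5)]  # slice h now holds old h-1
      a <- classify_fixture(fx, mode = "cue_maps")
      b <- classify_fixture(rotated, mode = "cue_maps")
      expect_identical(b$label, a$label)
    }
  }
})

test_that("the classifier is total and the population counts partition the units", {
  set.seed(54)
  labels <- rep(c("place", "ego_vector", "hd_modulated", "view_selective", "other"),
                each = 10L)
  values <- array(0, dim = c(50L, 25L, 25L, 6L))
  for (u in seq_along(labels)) {
    fx <- generate_fixture_maps(labels[u])
    for (h in 1:6) values[u, , , h] <- gaussian_smooth(fx$values[, , h])
  }
  maps <- hexnav:::new_activity_maps(values, "cue_maps",
                                     arena_config(side_length = 2.75))
  pop <- classify_population(maps)
  expect_identical(sum(pop$counts), 50L)
  expect_equal(sum(pop$proportions), 1)
  expect_identical(unname(pop$counts), rep(10L, 5L))  # exact recovery
  expect_identical(pop$table$label, labels)
})

test_that("coverage entropy hits its analytic values and bounds", {
  uniform <- matrix(1 / 625, 25L, 25L)
  expect_equal(shannon_entropy(uniform), 9.2877, tolerance = 1e-4)
  single <- matrix(0, 25L, 25L); single[3L, 7L] <- 1
  expect_identical(shannon_entropy(single), 0)
  two <- matrix(0, 25L, 25L); two[1L, 1L] <- 0.5; two[20L, 5L] <- 0.5
  expect_identical(shannon_entropy(two), 1)
  # 0 <= H <= log2(625) for arbitrary distributions
  set.seed(55)
  for (rep in 1:50) {
    p <- stats::rgamma(625, shape = stats::runif(1, 0.05, 2))
    H <- shannon_entropy(p / sum(p))
    expect_gte(H, 0)
    expect_lte(H, log2(625))
  }
})

test_that("coverage statistics summarize place-unit maps", {
  set.seed(56)
  values <- array(0, dim = c(50L, 25L, 25L, 6L))
  for (u in 1:5) {
    fx <- generate_fixture_maps("place")
    for (h in 1:6) values[u, , , h] <- gaussian_smooth(fx$values[, , h])
  }
  maps <- hexnav:::new_activity_maps(values, "position_maps",
                                     arena_config(side_length = 2.75))
  cov <- coverage_entropy(maps, units = 1:5, goal_xy = c(2.0, 2.0))
  expect_equal(sum(cov$prob_map), 1)
  expect_gt(cov$entropy, 0)
  expect_lt(cov$entropy, log2(625))  # concentrated mass is below uniform
  expect_identical(nrow(cov$centers), 5L)
  expect_true(is.finite(cov$mean_center_goal_dist))
  expect_error(coverage_entropy(maps, integer(0)), "empty class")
})
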