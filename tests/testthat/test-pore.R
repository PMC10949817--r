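test_that("a uniform cylinder recovers ring radius minus vdW at every slice", {
  cy <- make_cylinder_channel(rep(6.7, 9), spacing = 2)
  pr <- pore_profile(cy$structure, z_range = c(2, 14), step = 2, seed = 1)
  # interior slices sit on rings: analytic inscribed radius 6.7 - 1.7 = 5.0
  expect_true(all(abs(pr$samples$radius - 5.0) < max(0.1, 2 / 2)))
  on_ring <- pr$samples$z %in% cy$manifest$z
  expect_true(all(abs(pr$samples$radius[on_ring] - 5.0) < 0.1))
  expect_false(any(pr$samples$unbounded))
  expect_equal(pr$min_diameter, 10.0, tolerance = 0.2)
})

test_that("a constricted ring sets and localizes the minimum diameter", {
  radii <- c(rep(6.7, 5), 3.7, rep(6.7, 5))
  cy <- make_cylinder_channel(radii, spacing = 2)
  pr <- pore_profile(cy$structure, z_range = c(0, 20), step = 2, seed = 2)
  # minimum radius 3.7 - 1.7 = 2.0 at the constricted ring (z = 10)
  expect_equal(pr$min_diameter, 4.0, tolerance = 0.2)
  expect_equal(pr$z_at_min, 10)
  at_min <- pr$samples[pr$samples$z == 10, ]
  expect_equal(at_min$radius, 2.0, tolerance = 0.1)
})

test_that("slices beyond the channel mouth are flagged and excluded", {
  cy <- make_cylinder_channel(rep(6.7, 5), spacing = 2)
  pr <- pore_profile(cy$structure, z_range = c(0, 40), step = 2, seed = 3)
  expect_true(any(pr$samples$unbounded))
  expect_true(all(pr$samples$radius[pr$samples$unbounded] >= 15 - 1e-9))
  bounded <- pr$samples[!pr$samples$unbounded, ]
  expect_equal(pr$min_diameter, 2 * min(bounded$radius))
})

test_that("the window minimum can only exceed the overall minimum", {
  radii <- c(rep(6.7, 5), 3.7, rep(6.7, 5))
  cy <- make_cylinder_channel(radii, spacing = 2)
  # window that excludes the constriction at z = 10
  pr <- pore_profile(cy$structure, z_range = c(0, 20), step = 2, seed = 4,
                     window = c(0, 4))
  expect_gte(pr$min_diameter_window, pr$min_diameter)
  expect_gt(pr$min_diameter_window, 2 * 2.0 + 0.5)
  # window covering the constriction matches the overall minimum
  pr2 <- pore_profile(cy$structure, z_range = c(0, 20), step = 2, seed = 4,
                      window = c(8, 12))
  expect_equal(pr2$min_diameter_window, pr2$min_diameter)
})

test_that("profiles are seed-reproducible and rotation-invariant", {
  cy <- make_cylinder_channel(c(6.7, 6, 5.5, 6, 6.7), spacing = 2)
  p1 <- pore_profile(cy$structure, z_range = c(0, 8), step = 1, seed = 7)
  p2 <- pore_profile(cy$structure, z_range = c(0, 8), step = 1, seed = 7)
  expect_identical(p1$samples, p2$samples)
  # rotating the frame about the channel axis leaves the profile unchanged
  th <- 33 * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  rot <- set_coords(cy$structure, coords(cy$structure) %*% t(R))
  p3 <- pore_profile(rot, z_range = c(0, 8), step = 1, seed = 7)
  expect_equal(p3$samples$radius, p1$samples$radius, tolerance = 0.05)
})

test_that("an off-z axis is handled by rotating the frame", {
  cy <- make_cylinder_channel(rep(6.7, 5), spacing = 2)
  # tip the cylinder onto the x axis and profile along x
  xyz <- coords(cy$structure)[, c(3, 2, 1)]
  tipped <- set_coords(cy$structure, xyz)
  pr <- pore_profile(tipped, axis = c(1, 0, 0), z_range = c(2, 6), step = 2,
                     seed = 5)
  expect_true(all(abs(pr$samples$radius - 5.0) < 0.1))
})

test_that("per-frame minimum diameters follow a breathing schedule", {
  wide <- make_cylinder_channel(rep(6.7, 5), spacing = 2)$structure
  narrow <- make_cylinder_channel(rep(5.2, 5), spacing = 2)$structure
  xyz <- rbind(as.numeric(t(coords(wide))), as.numeric(t(coords(narrow))),
               as.numeric(t(coords(wide))))
  tr <- gj_trajectory(wide, xyz, 10)
  md <- min_diameter_series(tr, z_range = c(2, 6), step = 2, window = c(2, 6),
                            seed = 11)
  expect_equal(md$min_diameter, 2 * c(5.0, 3.5, 5.0), tolerance = 0.1)
  expect_true(all(md$min_diameter_window >= md$min_diameter - 1e-9))
})
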