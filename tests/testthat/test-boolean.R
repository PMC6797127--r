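test_that("difference with a disjoint solid leaves the volume unchanged", {
  a <- box_mesh(center = c(0, 0, 0), size = 10)
  b <- box_mesh(center = c(30, 0, 0), size = 10)
  d <- boolean_difference(a, b, pitch = 0.4)
  expect_equal(volume(d), volume(a), tolerance = 0.01)
})

test_that("difference with an enclosing solid is empty", {
  a <- icosphere(4, 3)
  b <- box_mesh(size = 20)
  d <- boolean_difference(a, b, pitch = 0.3)
  expect_true(is_empty_mesh(d))
  expect_equal(volume(d), 0)
})

test_that("sphere-sphere difference matches the analytic lens complement", {
  s1 <- icosphere(10, 4)
  s2 <- icosphere(10, 4, center = c(10, 0, 0))
  d <- boolean_difference(s1, s2, pitch = 0.25)
  expected <- 4 / 3 * pi * 1000 - sphere_lens_volume(10, 10, 10)
  expect_equal(volume(d) * 1000, expected, tolerance = 0.01)
})

test_that("intersection semantics: identical, disjoint, half-space clip", {
  a <- icosphere(8, 3)
  expect_equal(volume(boolean_intersection(a, a, pitch = 0.3)), volume(a),
               tolerance = 0.01)
  b <- icosphere(8, 3, center = c(40, 0, 0))
  expect_true(is_empty_mesh(boolean_intersection(a, b, pitch = 0.4)))
  # cube clipped by a large box covering half of it
  cube <- box_mesh(size = 20)
  half <- box_mesh(center = c(20, 0, 0), size = 40)  # covers x > 0
  clipped <- boolean_intersection(cube, half, pitch = 0.2)
  expect_equal(volume(clipped), volume(cube) / 2, tolerance = 0.005)
})

test_that("volume additivity: |a| + |b| = |a union b| + |a intersect b|", {
  set.seed(42)
  for (rep in 1:5) {
    c1 <- runif(3, -5, 5)
    c2 <- runif(3, -5, 5)
    a <- icosphere(runif(1, 6, 10), 3, center = c1)
    b <- icosphere(runif(1, 6, 10), 3, center = c2)
    lhs <- volume(a) + volume(b)
    rhs <- volume(boolean_union(a, b, pitch = 0.5)) +
      volume(boolean_intersection(a, b, pitch = 0.5))
    expect_equal(lhs, rhs, tolerance = 0.01)
  }
})

test_that("voxel difference matches the closed-form box oracle", {
  set.seed(7)
  pitch <- 0.5
  for (rep in 1:50) {
    lo1 <- runif(3, -10, 0)
    hi1 <- lo1 + runif(3, 5, 15)
    lo2 <- runif(3, -10, 0)
    hi2 <- lo2 + runif(3, 5, 15)
    a <- box_mesh((lo1 + hi1) / 2, hi1 - lo1)
    b <- box_mesh((lo2 + hi2) / 2, hi2 - lo2)
    exact <- prod(hi1 - lo1) - box_overlap_volume(lo1, hi1, lo2, hi2)
    d <- boolean_difference(a, b, pitch = pitch)
    # bound: O(pitch x surface area of the operands)
    area <- 2 * sum((hi1 - lo1) * (hi1 - lo1)[c(2, 3, 1)])
    expect_lt(abs(volume(d) * 1000 - exact), 2 * pitch * area)
  }
})

test_that("the exact method falls back to voxels with a warning", {
  a <- box_mesh(size = 10)
  b <- box_mesh(center = c(5, 0, 0), size = 10)
  expect_warning(d <- boolean_difference(a, b, method = "exact",
                                         pitch = 0.25),
                 "falling back")
  expect_equal(volume(d), 0.5, tolerance = 0.01)
})

test_that("voxelization pads the bounding box and reports volume exactly", {
  cb <- box_mesh(size = 9.7)
  g <- voxelize(cb, pitch = 0.25)
  expect_equal(grid_volume(g), volume(mesh_from_grid(g)), tolerance = 1e-12)
  # rasterization of an axis-aligned box quantizes each edge to the voxel
  # lattice: the volume error is bounded by pitch x surface area
  expect_lt(abs(grid_volume(g) - volume(cb)),
            0.25 * 6 * 9.7^2 / 1000)
})
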