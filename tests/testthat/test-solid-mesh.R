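test_that("STL round trip preserves a cube with merged vertices", {
  cb <- box_mesh(size = 10)
  tmp <- tempfile(fileext = ".stl")
  write_solid(cb, tmp)
  m <- load_solid(tmp)
  expect_equal(nrow(m$vertices), 8)
  expect_equal(nrow(m$faces), 12)
  expect_true(is_watertight(m))
  expect_equal(volume(m), 1, tolerance = 1e-12)

  tmp2 <- tempfile(fileext = ".stl")
  write_solid(cb, tmp2, ascii = TRUE)
  m2 <- load_solid(tmp2)
  expect_equal(volume(m2), 1, tolerance = 1e-12)
})

test_that("PLY round trip preserves volume", {
  ic <- icosphere(8, 2)
  tmp <- tempfile(fileext = ".ply")
  write_solid(ic, tmp)
  m <- load_solid(tmp)
  expect_true(is_watertight(m))
  expect_equal(volume(m), volume(ic), tolerance = 1e-9)
})

test_that("inverted winding is fixed to positive signed volume on load", {
  cb <- box_mesh(size = 10)
  cb$faces <- cb$faces[, c(1, 3, 2)]  # invert all faces
  m <- clean_mesh(cb)
  expect_equal(volume(m), 1, tolerance = 1e-12)
})

test_that("icosphere volume converges to the closed form from below", {
  ic4 <- icosphere(10, 4)
  expect_true(is_watertight(ic4))
  v4 <- volume(ic4) * 1000
  expect_lt(v4, 4 / 3 * pi * 1000)
  expect_equal(v4, 4 / 3 * pi * 1000, tolerance = 0.005)
  v5 <- volume(icosphere(20, 5))
  expect_equal(v5, 4 / 3 * pi * 20^3 / 1000, tolerance = 0.003)
})

test_that("volume is additive over disjoint components in one mesh", {
  a <- box_mesh(center = c(0, 0, 0), size = 10)
  b <- box_mesh(center = c(30, 0, 0), size = 10)
  both <- solid_mesh(rbind(a$vertices, b$vertices),
                     rbind(a$faces, b$faces + nrow(a$vertices)))
  expect_equal(volume(both), 2, tolerance = 1e-12)
})

test_that("volume is invariant under rigid transforms", {
  ic <- icosphere(7, 3)
  th <- 0.7
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- transform_mesh(ic, Rz, c(12.3, -4.5, 6.7))
  expect_equal(volume(moved), volume(ic), tolerance = 1e-9)
})

test_that("non-watertight meshes are rejected with an open-edge count", {
  cb <- box_mesh(size = 10)
  cb$faces <- cb$faces[-1, ]  # remove one triangle
  wt <- is_watertight(cb)
  expect_false(wt)
  expect_gt(attr(wt, "open_edges"), 0)
  expect_error(volume(cb), "not watertight")
})

test_that("small holes are filled on load, larger holes error", {
  ic <- icosphere(10, 2)
  holed <- ic
  holed$faces <- holed$faces[-1, ]
  tmp <- tempfile(fileext = ".stl")
  write_solid(holed, tmp)
  # hole from one subdiv-2 face is ~4 mm across: larger than the 1 mm
  # repair limit
  expect_error(load_solid(tmp), "open edge")
})
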