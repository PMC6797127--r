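test_that("symmetric landmarks give the canonical body axes", {
  lm <- list(asis_right = c(120, 0, 0), asis_left = c(-120, 0, 0),
             symphysis = c(0, 0, -90), cor = c(0, -10, 0),
             acet_plane_point = c(0, -10, 0), acet_plane_normal = c(1, 0, 0),
             acet_radius = 26)
  fr <- build_frame(lm, "R")
  expect_equal(fr$x_axis, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(fr$y_axis, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(fr$z_axis, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(fr$app_normal, c(0, 1, 0), tolerance = 1e-12)
  # orthonormal right-handed
  B <- cbind(fr$x_axis, fr$y_axis, fr$z_axis)
  expect_equal(crossprod(B), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(det(B), 1, tolerance = 1e-9)
})

test_that("left and right sides give identical frames after mirroring", {
  lm <- canonical_landmarks()
  frR <- build_frame(lm, "R")
  frL <- build_frame(lm, "L")
  expect_equal(frL$x_axis, frR$x_axis, tolerance = 1e-9)
  expect_equal(frL$y_axis, frR$y_axis, tolerance = 1e-9)
  expect_equal(frL$z_axis, frR$z_axis, tolerance = 1e-9)
  expect_equal(frL$acet_radius, frR$acet_radius, tolerance = 1e-9)
  expect_true(frL$mirrored)
  expect_false(frR$mirrored)
})

test_that("acetabular plane fit recovers the rim plane under noise", {
  set.seed(101)
  angs <- replicate(100, {
    th <- seq(0, 2 * pi, length.out = 61)[-61]
    rim <- cbind(25 * cos(th), 25 * sin(th), 0) +
      matrix(rnorm(180, 0, 0.1), ncol = 3)
    pl <- fit_plane(rim)
    acos(min(abs(sum(pl$normal * c(0, 0, 1))), 1)) * 180 / pi
  })
  expect_lt(max(angs), 0.5)
})

test_that("rim circle fit recovers center and radius", {
  fr <- canonical_frame(rim_r = 25, rim_noise = 0.05, seed = 3)
  expect_equal(fr$acet_radius, 25, tolerance = 0.01)
  expect_equal(fr$acet_plane$point, c(0, 0, 0), tolerance = 0.1)
  expect_gt(sum(fr$acet_plane$normal * c(1, 0, 0)), 0.999)
})

test_that("missing or degenerate landmarks error informatively", {
  lm <- canonical_landmarks()
  expect_error(build_frame(lm[c("asis_left", "symphysis")], "R"),
               "asis_right")
  bad <- lm
  bad$symphysis <- (bad$asis_left + bad$asis_right) / 2
  expect_error(build_frame(bad, "R"), "collinear")
  norim <- lm
  norim$acetabular_rim <- NULL
  expect_error(build_frame(norim, "R"), "acetabular_rim")
})

test_that("missing CoR falls back to the fitted rim-circle center", {
  lm <- canonical_landmarks()
  lm$cor <- NULL
  fr <- build_frame(lm, "R")
  expect_equal(fr$acet_radius, 26, tolerance = 0.01)
  expect_equal(fr$cor, c(0, 0, 0), tolerance = 0.05)
})

test_that("landmark JSON round trip", {
  lm <- canonical_landmarks()
  tmp <- tempfile(fileext = ".json")
  write_landmarks(lm, tmp)
  back <- read_landmarks(tmp)
  expect_equal(back$cor, lm$cor)
  expect_equal(dim(back$acetabular_rim), dim(lm$acetabular_rim))
  expect_equal(unname(as.matrix(back$acetabular_rim)), lm$acetabular_rim,
               tolerance = 1e-12)
})
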