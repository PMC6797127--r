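test_that("ovality of a circular rim is 1", {
  fr <- canonical_frame()
  th <- seq(0, 2 * pi, length.out = 51)[-51]
  rim <- cbind(0, 25 * sin(th), 25 * cos(th))
  ov <- ovality(rim, fr)
  expect_equal(ov$ovality, 1, tolerance = 1e-9)
  expect_equal(ov$length, 50, tolerance = 1e-6)
})

test_that("ovality of a 30/15 ellipse is exactly 2", {
  fr <- canonical_frame()
  th <- seq(0, 2 * pi, length.out = 51)[-51]
  rim <- outer(30 * cos(th), c(0, 0, 1)) + outer(15 * sin(th), c(0, 1, 0))
  ov <- ovality(rim, fr)
  expect_equal(ov$ovality, 2, tolerance = 1e-6)
  expect_equal(ov$length, 60, tolerance = 1e-6)
  expect_equal(ov$width, 30, tolerance = 1e-6)
})

test_that("ovality is recovered within 2% under 0.2 mm rim noise", {
  fr <- canonical_frame()
  th <- seq(0, 2 * pi, length.out = 51)[-51]
  set.seed(31)
  ovs <- replicate(100, {
    rim <- outer(26 * cos(th), c(0, 0, 1)) + outer(20 * sin(th),
                                                   c(0, 1, 0)) +
      matrix(rnorm(150, 0, 0.2), ncol = 3)
    ovality(rim, fr)$ovality
  })
  expect_lt(max(abs(ovs / 1.3 - 1)), 0.02)
})

test_that("ovality is invariant under rigid transforms and scaling", {
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  rim0 <- outer(28 * cos(th), c(0, 0, 1)) + outer(21 * sin(th), c(0, 1, 0))
  fr <- canonical_frame()
  o0 <- ovality(rim0, fr)$ovality
  expect_equal(ovality(rim0 * 2.5, fr)$ovality, o0, tolerance = 1e-9)
  shift <- matrix(c(0, 5, -3), nrow(rim0), 3, byrow = TRUE)
  expect_equal(ovality(rim0 + shift, fr)$ovality, o0, tolerance = 1e-6)
})

test_that("ovality and ellipse fit reject degenerate input", {
  fr <- canonical_frame()
  expect_error(ovality(matrix(0, 5, 3), fr), ">= 6")
  line <- cbind(0, seq_len(10), seq_len(10))
  expect_error(ovality(line, fr))
})

test_that("LCE angle matches simple constructions and the Wiberg bands", {
  fr <- canonical_frame()
  expect_equal(lce_angle(c(0, 3, 30), fr), 0, tolerance = 1e-9)
  expect_equal(lce_angle(c(20, 3, 20), fr), 45, tolerance = 1e-9)
  expect_lt(lce_angle(c(-5, 0, 40), fr), 0)  # medialized edge
  expect_error(lce_angle(c(0, 0, 0), fr), "CoR")
  expect_equal(lce_classify(c(30, 11.6, 63, 25, 39, 24.9, 39.1)),
               c("normal", "reduced", "increased", "normal", "normal",
                 "reduced", "increased"))
})

test_that("LCE angle is invariant under scene translation", {
  lm <- canonical_landmarks()
  shift <- c(7, -12, 4)
  lm2 <- lapply(lm, function(v)
    if (is.matrix(v)) sweep(v, 2, -shift) else v + shift)
  edge <- c(25, 3, 35)
  expect_equal(lce_angle(edge + shift, build_frame(lm2, "R")),
               lce_angle(edge, build_frame(lm, "R")), tolerance = 1e-9)
})

test_that("sphere fit is exact on noiseless data", {
  set.seed(32)
  dirs <- matrix(rnorm(300), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  pts <- sweep(26 * dirs, 2, -c(4, -7, 11))
  fit <- fit_sphere(pts)
  expect_equal(fit$center, c(4, -7, 11), tolerance = 1e-9)
  expect_equal(fit$radius, 26, tolerance = 1e-9)
  expect_lt(fit$rms, 1e-9)
  expect_error(fit_sphere(pts[1:3, ]), ">= 4")
  flat <- cbind(rnorm(20), rnorm(20), 0)
  expect_error(fit_sphere(flat), "coplanar")
})

test_that("implant center is recovered within 0.1 mm from a noisy cap", {
  set.seed(33)
  errs <- replicate(100, {
    dirs <- matrix(rnorm(1800), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    dirs <- dirs[dirs[, 1] < 0, , drop = FALSE]  # half-sphere coverage
    pts <- sweep(26 * dirs, 2, -c(2, -3, 16)) +
      matrix(rnorm(3 * nrow(dirs), 0, 0.1), ncol = 3)
    sqrt(sum((fit_sphere(pts)$center - c(2, -3, 16))^2))
  })
  expect_lt(max(errs), 0.1)
})

test_that("migration components decompose onto body axes in quadrature", {
  fr <- canonical_frame()
  set.seed(34)
  dirs <- matrix(rnorm(450), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  d_true <- c(3, -4, 12)
  mig <- implant_migration(sweep(24 * dirs, 2, -d_true), fr)
  expect_equal(unname(mig$components), d_true, tolerance = 1e-6)
  expect_equal(mig$total, sqrt(sum(mig$components^2)), tolerance = 1e-12)
  expect_equal(mig$predominant, "cranial")
  expect_equal(mig$radius, 24, tolerance = 1e-6)
  # zero migration
  mig0 <- implant_migration(24 * dirs, fr)
  expect_equal(mig0$total, 0, tolerance = 1e-6)
})

test_that("an implausible implant radius warns", {
  fr <- canonical_frame()
  set.seed(35)
  dirs <- matrix(rnorm(300), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  expect_warning(implant_migration(60 * dirs, fr), "implausible")
})

test_that("predominant direction uses the fixed tie-break order", {
  pd <- acetquant:::predominant_direction
  expect_equal(pd(c(lateral = 5, anterior = 0, cranial = 5)), "cranial")
  expect_equal(pd(c(lateral = -6, anterior = -6, cranial = 1)), "posterior")
})

wall_phantom <- function(diameter, seed = 41) {
  generate_phantom(phantom_spec(
    punches = list(list(azimuth = 0, diameter = diameter,
                        side = "lateral")), seed = seed))
}

test_that("identical native and defect have no wall defects", {
  ph <- generate_phantom(phantom_spec(seed = 42))
  fr <- build_frame(ph$landmarks, "R")
  p <- build_partition(fr)
  flags <- suppressWarnings(wall_defects(ph$native, ph$defect, p, fr,
                                         pitch = 0.3))
  expect_false(any(flags))
})

test_that("a 6 mm cranial rim punch flags Cranial and only Cranial", {
  ph <- wall_phantom(6)
  fr <- build_frame(ph$landmarks, "R")
  p <- build_partition(fr)
  flags <- wall_defects(ph$native, ph$defect, p, fr, pitch = 0.25)
  expect_true(flags[["Cranial"]])
  expect_false(any(flags[c("Anterior", "Posterior", "Medial")]))
})

test_that("a 4 mm punch stays below the 5 mm wall-defect threshold", {
  ph <- wall_phantom(4)
  fr <- build_frame(ph$landmarks, "R")
  p <- build_partition(fr)
  flags <- wall_defects(ph$native, ph$defect, p, fr, pitch = 0.25)
  expect_false(any(flags))
})

test_that("enlarging a flagged hole never clears the flag", {
  for (d in c(6, 8, 10)) {
    ph <- wall_phantom(d)
    fr <- build_frame(ph$landmarks, "R")
    p <- build_partition(fr)
    flags <- wall_defects(ph$native, ph$defect, p, fr, pitch = 0.3)
    expect_true(flags[["Cranial"]], label = sprintf("diameter %g", d))
  }
})

test_that("a deep rim erosion is caught by the absent-rim detector", {
  ph <- generate_phantom(phantom_spec(
    erosions = list(list(azimuth = c(-20, 20), depth = 7)), seed = 43))
  fr <- build_frame(ph$landmarks, "R")
  p <- build_partition(fr)
  flags <- wall_defects(ph$native, ph$defect, p, fr, pitch = 0.3)
  expect_true(flags[["Cranial"]])
  det <- attr(flags, "details")
  expect_gt(length(det$arcs), 0)
})
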