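test_that("an empty defect spec reproduces the native bone exactly", {
  ph <- generate_phantom(phantom_spec(seed = 71))
  expect_true(is_watertight(ph$native))
  expect_true(is_watertight(ph$defect))
  expect_identical(ph$native$vertices, ph$defect$vertices)
  expect_equal(volume(ph$native), volume(ph$defect))
  expect_equal(unname(ph$truth$loss_ml), rep(0, 4))
  expect_equal(unname(ph$truth$formation_ml), rep(0, 4))
  expect_equal(ph$truth$group$label, "All intact")
})

test_that("the same seed reproduces identical meshes and truth", {
  sp <- phantom_spec(bites = list(list(center = c(9.3, 0, 28.5),
                                       radius = 5)),
                     implant = list(radius = 24, migration = c(1, 2, 10)),
                     seed = 72)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(p1$native$vertices, p2$native$vertices)
  expect_identical(p1$defect$faces, p2$defect$faces)
  expect_identical(p1$landmarks, p2$landmarks)
  expect_identical(p1$truth$loss_ml, p2$truth$loss_ml)
})

test_that("a 6 mm cranial bite inside bone yields the closed-form loss", {
  sp <- phantom_spec(shell_thickness = 16, lateral_shift = 2,
                     bites = list(list(center = c(10.2, 0, 32.5),
                                       radius = 6)), seed = 73)
  ph <- generate_phantom(sp)
  expect_equal(unname(ph$truth$loss_ml["Cranial"]), 4 / 3 * pi * 216 / 1000,
               tolerance = 0.005)
})

test_that("bites outside the bone are rejected", {
  sp <- phantom_spec(bites = list(list(center = c(100, 0, 0), radius = 5)))
  expect_error(generate_phantom(sp), "outside the native bone")
})

test_that("ground truth is self-consistent", {
  sp <- phantom_spec(bites = list(list(center = c(9.3, 0, 28.5),
                                       radius = 6)), seed = 74)
  ph <- generate_phantom(sp, meshes = FALSE)
  tr <- ph$truth
  expect_equal(unname(tr$loss_pct),
               unname(100 * tr$loss_ml / tr$native_ml), tolerance = 1e-9)
  expect_equal(tr$group$label,
               assign_group(tr$loss_pct, ph$spec$pd_flag)$label)
})

test_that("the truth oracle converges in pitch", {
  # single bite: compare the oracle at 0.1 and 0.05 mm over its box
  sp1 <- phantom_spec(bites = list(list(center = c(9.3, 0, 28.5),
                                        radius = 5)), truth_pitch = 0.1,
                      seed = 75)
  sp2 <- sp1
  sp2$truth_pitch <- 0.05
  v1 <- generate_phantom(sp1, meshes = FALSE)$truth$loss_ml
  v2 <- generate_phantom(sp2, meshes = FALSE)$truth$loss_ml
  expect_equal(unname(v1["Cranial"]), unname(v2["Cranial"]),
               tolerance = 0.005)
})

test_that("left-side phantoms are mirrored consistently", {
  spR <- phantom_spec(bites = list(list(center = c(9.3, 0, 28.5),
                                        radius = 6)), side = "R", seed = 76)
  spL <- spR
  spL$side <- "L"
  phR <- generate_phantom(spR)
  phL <- generate_phantom(spL)
  # same volumes, mirrored coordinates
  expect_equal(volume(phL$native), volume(phR$native), tolerance = 1e-9)
  expect_equal(phL$landmarks$cor, phR$landmarks$cor * c(-1, 1, 1))
  # truth is expressed in anatomical terms and unchanged by side
  expect_identical(phL$truth$loss_ml, phR$truth$loss_ml)
})

test_that("phantom files round trip through disk", {
  ph <- generate_phantom(phantom_spec(seed = 77))
  dir <- tempfile()
  write_phantom(ph, dir, "t")
  m <- load_solid(file.path(dir, "t_native.stl"))
  expect_equal(volume(m), volume(ph$native), tolerance = 1e-6)
  lm <- read_landmarks(file.path(dir, "t_landmarks.json"))
  expect_equal(unlist(lm$cor), ph$landmarks$cor, ignore_attr = TRUE)
  tr <- read.csv(file.path(dir, "t_truth.csv"))
  expect_equal(tr$native_ml, unname(ph$truth$native_ml), tolerance = 1e-9)
})

test_that("a small cohort covers its target groups deterministically", {
  co1 <- generate_cohort(n = 3, seed = 91)
  co2 <- generate_cohort(n = 3, seed = 91)
  expect_identical(co1$truth, co2$truth)
  expect_equal(co1$truth$group, c("All intact", "Cranial", "Anterior"))
  # truth table is in the metrics layout
  expect_true(all(c("loss_pct_Cranial", "formation_ml_Medial",
                    "wall_Posterior", "ovality") %in% names(co1$truth)))
})
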