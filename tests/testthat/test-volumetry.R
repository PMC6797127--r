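# Per-sector volumetry on phantoms with analytic or oracle ground truth.

# fat-shelled phantom whose cranial shell can contain a 6 mm bite entirely
fat_spec <- function(bites = list(), blobs = list(), seed = 2) {
  phantom_spec(shell_thickness = 16, lateral_shift = 2, bites = bites,
               blobs = blobs, seed = seed)
}

fat_bite_phantom <- function(r) {
  cached_fixture(paste0("fat_bite_", r), function()
    generate_phantom(fat_spec(
      bites = list(list(center = c(10.2, 0, 32.5), radius = r)))))
}

test_that("identical native and defect give zero loss and formation", {
  ph <- generate_phantom(phantom_spec(seed = 21))
  p <- build_partition(build_frame(ph$landmarks, "R"))
  lv <- bone_volume_loss(ph$native, ph$defect, p, pitch = 0.4)
  expect_equal(lv$loss_ml, rep(0, 4))
  expect_equal(lv$loss_pct, rep(0, 4))
  nf <- new_bone_formation(ph$native, ph$defect, p, pitch = 0.4)
  expect_equal(nf$formation_ml, rep(0, 4))
})

test_that("an empty defect solid means total resorption (rv = 100%)", {
  ph <- generate_phantom(phantom_spec(seed = 22))
  p <- build_partition(build_frame(ph$landmarks, "R"))
  empty <- solid_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3),
                      clean = FALSE)
  lv <- bone_volume_loss(ph$native, empty, p, pitch = 0.4)
  expect_equal(lv$loss_pct, rep(100, 4), tolerance = 1e-9)
})

test_that("a spherical bite wholly inside cranial bone is recovered", {
  r <- 6
  ph <- fat_bite_phantom(r)
  vtruth <- 4 / 3 * pi * r^3 / 1000  # 0.90478 ml
  expect_equal(unname(ph$truth$loss_ml["Cranial"]), vtruth,
               tolerance = 0.005)
  expect_equal(unname(ph$truth$loss_ml[c("Anterior", "Posterior",
                                         "Medial")]), rep(0, 3))
  p <- build_partition(build_frame(ph$landmarks, "R"))
  lv <- bone_volume_loss(ph$native, ph$defect, p, pitch = 0.25)
  expect_equal(lv$loss_ml[1], vtruth, tolerance = 0.02)
  expect_equal(lv$loss_ml[2:4], rep(0, 3))
})

test_that("an external blob is measured as formation in its sector", {
  # 0.5 ml sphere (r = 4.924 mm) detached from the bone, in the medial gap
  # between the outer cortex and the ROI boundary
  r <- (3 * 500 / (4 * pi))^(1 / 3)
  sp <- fat_spec(blobs = list(list(center = c(-45, -8, -8), radius = r)))
  ph <- generate_phantom(sp)
  expect_equal(unname(ph$truth$formation_ml["Medial"]), 0.5,
               tolerance = 0.005)
  p <- build_partition(build_frame(ph$landmarks, "R"))
  nf <- new_bone_formation(ph$native, ph$defect, p, pitch = 0.25)
  expect_equal(nf$formation_ml[4], 0.5, tolerance = 0.02)
  expect_equal(nf$formation_ml[1:3], rep(0, 3))
})

test_that("simultaneous bite and blob are both recovered", {
  r <- 6
  sp <- fat_spec(bites = list(list(center = c(10.2, 0, 32.5), radius = r)),
                 blobs = list(list(center = c(-45, -8, -8), radius = 4.5)))
  ph <- generate_phantom(sp)
  p <- build_partition(build_frame(ph$landmarks, "R"))
  res <- sector_volumetry(ph$native, ph$defect, p, pitch = 0.25)
  expect_equal(res$table$loss_ml[1], unname(ph$truth$loss_ml["Cranial"]),
               tolerance = 0.02)
  expect_equal(res$table$formation_ml[4],
               unname(ph$truth$formation_ml["Medial"]), tolerance = 0.02)
})

test_that("loss and formation are swap-antisymmetric exactly", {
  ph <- fat_bite_phantom(6)
  p <- build_partition(build_frame(ph$landmarks, "R"))
  lv <- bone_volume_loss(ph$native, ph$defect, p, pitch = 0.3)
  nf <- new_bone_formation(ph$defect, ph$native, p, pitch = 0.3)
  expect_identical(lv$loss_ml, nf$formation_ml)
})

test_that("enlarging a bite never decreases the sector loss", {
  p <- NULL
  losses <- vapply(c(3, 4.5, 6), function(r) {
    ph <- fat_bite_phantom(r)
    if (is.null(p))
      p <<- build_partition(build_frame(ph$landmarks, "R"))
    bone_volume_loss(ph$native, ph$defect, p, pitch = 0.3)$loss_ml[1]
  }, numeric(1))
  expect_true(all(diff(losses) > 0))
})

test_that("relative values use the native sector volume as denominator", {
  ph <- fat_bite_phantom(6)
  p <- build_partition(build_frame(ph$landmarks, "R"))
  lv <- bone_volume_loss(ph$native, ph$defect, p, pitch = 0.3)
  expect_equal(lv$loss_pct, 100 * lv$loss_ml / lv$native_ml,
               tolerance = 1e-9)
})
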