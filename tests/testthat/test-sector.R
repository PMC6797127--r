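part_default <- function() build_partition(canonical_frame())

test_that("partition construction validates its inputs", {
  fr <- canonical_frame()
  expect_error(build_partition(fr, roi_radius_factor = 0.8), "> 1")
  p <- build_partition(fr)
  expect_equal(p$roi_radius, 2 * fr$acet_radius, tolerance = 0.1)
})

test_that("sector regions are disjoint and partition the ROI sphere", {
  p <- part_default()
  set.seed(11)
  # uniform points in the ROI sphere: every one gets exactly one sector
  n <- 20000
  pts <- matrix(rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(n)^(1 / 3) * p$roi_radius * 0.999
  cls <- classify_points(p, pts)
  expect_true(all(cls != "Outside"))
  # outside the ROI: nothing
  dirs <- pts / sqrt(rowSums(pts^2))
  far <- dirs * runif(n, 1.01, 1.5) * p$roi_radius
  expect_true(all(classify_points(p, far) == "Outside"))
})

test_that("a point straight cranial of the CoR is Cranial", {
  p <- part_default()
  expect_equal(as.character(classify_points(p, c(0.5, 0, 30))), "Cranial")
  expect_equal(as.character(classify_points(p, c(-5, 0, 0))), "Medial")
  expect_equal(as.character(classify_points(p, c(2, 30, -10))), "Anterior")
  expect_equal(as.character(classify_points(p, c(2, -30, -10))),
               "Posterior")
})

test_that("a lateral hemisphere splits evenly across the three wedges", {
  p <- part_default()
  # hemisphere solid on the lateral side, centered on the CoR
  set.seed(12)
  n <- 30000
  pts <- matrix(rnorm(3 * n), ncol = 3)
  pts <- pts / sqrt(rowSums(pts^2)) * runif(n)^(1 / 3) * 30
  pts <- pts[pts[, 1] > 0, ]
  cls <- table(classify_points(p, pts))
  counts <- cls[c("Cranial", "Anterior", "Posterior")]
  expect_lt(diff(range(counts)) / mean(counts), 0.05)
  expect_equal(unname(cls["Medial"]), 0)
})

test_that("clipping respects containment and conservation", {
  p <- part_default()
  inside <- icosphere(5, 3, center = c(7, 0, 30))  # within Cranial wedge
  clipped <- clip_to_sector(inside, p, "Cranial", pitch = 0.3)
  expect_equal(volume(clipped), volume(inside), tolerance = 0.01)
  far <- icosphere(5, 3, center = c(0, 0, 200))  # outside the ROI
  expect_true(is_empty_mesh(clip_to_sector(far, p, "Cranial", pitch = 0.4)))
  expect_error(clip_to_sector(inside, p, "Lateral"), "unknown sector")

  # conservation: sector volumes sum to the ROI-clipped volume
  body <- icosphere(20, 3, center = c(5, 3, 8))
  vs <- vapply(c("Cranial", "Anterior", "Posterior", "Medial"), function(s)
    volume(clip_to_sector(body, p, s, pitch = 0.5)), numeric(1))
  vroi <- volume(clip_to_sector(body, p, "ROI", pitch = 0.5))
  expect_equal(sum(vs), vroi, tolerance = 0.01)
})

test_that("sector assignment is invariant under joint rigid transforms", {
  lm <- canonical_landmarks()
  th <- 0.6
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  shift <- c(15, -8, 3)
  move <- function(v) {
    if (is.matrix(v)) sweep(v %*% t(R), 2, -shift) else
      drop(R %*% v) + shift
  }
  lm2 <- lapply(lm, move)
  p1 <- build_partition(build_frame(lm, "R"))
  p2 <- build_partition(build_frame(lm2, "R"))
  set.seed(13)
  pts <- matrix(rnorm(3000, sd = 20), ncol = 3)
  c1 <- classify_points(p1, pts)
  c2 <- classify_points(p2, move(pts))
  expect_gt(mean(as.character(c1) == as.character(c2)), 0.999)
})
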