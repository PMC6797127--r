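test_that("describe reports quantiles with linear interpolation", {
  d <- describe(c(1, 2, 3, 4, 5))
  expect_equal(d$median, 3)
  expect_equal(d$p25, 2)
  expect_equal(d$p75, 4)
  expect_equal(d$min, 1)
  expect_equal(d$max, 5)
  d1 <- describe(7)
  expect_equal(d1$median, 7)
  expect_equal(d1$min, 7)
  expect_true(is.na(d1$sd))
  dm <- describe(c(1, NA, 3))
  expect_equal(dm$n_missing, 1)
  expect_equal(dm$n, 2)
})

test_that("Shapiro-Wilk is calibrated on normal data and powered on
           heavy tails", {
  set.seed(61)
  rej_norm <- mean(replicate(200, shapiro_wilk(rnorm(200))$p < 0.05))
  expect_gte(rej_norm, 0.02)
  expect_lte(rej_norm, 0.08)
  rej_heavy <- mean(replicate(100, shapiro_wilk(rt(200, df = 2))$p < 0.05))
  expect_gte(rej_heavy, 0.95)
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
  expect_error(shapiro_wilk(rep(1, 10)), "constant")
})

test_that("exact Mann-Whitney p matches brute-force enumeration", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)
  expect_equal(mw$method, "exact")
  set.seed(62)
  for (rep in 1:25) {
    na <- sample(2:5, 1)
    nb <- sample(2:5, 1)
    a <- round(runif(na, 0, 100), 3)
    b <- round(runif(nb, 0, 100), 3)
    expect_equal(mann_whitney_u(a, b)$p, brute_force_mwu_p(a, b),
                 tolerance = 1e-12,
                 label = sprintf("rep %d (n=%d, m=%d)", rep, na, nb))
  }
})

test_that("identical samples are not significant", {
  x <- c(3, 1, 4, 1, 5)
  expect_gt(mann_whitney_u(x, x)$p, 0.99)
})

test_that("Mann-Whitney is invariant under monotone transforms", {
  set.seed(63)
  a <- runif(12)
  b <- runif(15) + 0.3
  p1 <- mann_whitney_u(a, b)$p
  expect_equal(mann_whitney_u(exp(a), exp(b))$p, p1, tolerance = 1e-12)
  expect_equal(mann_whitney_u(a^3, b^3)$p, p1, tolerance = 1e-12)
})

test_that("ties route to the corrected normal approximation", {
  a <- c(1, 2, 2, 3)
  b <- c(2, 4, 5, 6)
  mw <- mann_whitney_u(a, b)
  expect_equal(mw$method, "normal")
  expect_true(mw$p > 0 && mw$p <= 1)
  # agreement with the reference implementation of the same approximation
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = TRUE))
  expect_equal(mw$p, ref$p.value, tolerance = 1e-9)
})

test_that("the normal approximation is close to exact for moderate n", {
  set.seed(64)
  a <- rnorm(12)
  b <- rnorm(12, 0.8)
  approx <- mann_whitney_u(a, b)$p
  exact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
  expect_equal(approx, exact, tolerance = 0.05)
})

test_that("correlation bands use inclusive lower edges", {
  expect_equal(correlation_band(c(0.49, 0.5, 0.69, 0.7, 0.89, 0.9, 1.0)),
               c("none", "moderate", "moderate", "high", "high",
                 "very_high", "very_high"))
  expect_equal(correlation_band(c(-0.74, -0.67)), c("high", "moderate"))
})

test_that("correlation matrix reports banded pairwise coefficients", {
  set.seed(65)
  n <- 40
  x <- rnorm(n)
  tab <- data.frame(id = seq_len(n), x = x, y = x + rnorm(n, 0, 0.1),
                    z = rnorm(n))
  cm <- correlation_matrix(tab)
  xy <- cm[cm$var1 == "x" & cm$var2 == "y", ]
  expect_equal(xy$band, "very_high")
  expect_gt(xy$R, 0.9)
  M <- attr(cm, "matrix")
  expect_equal(unname(diag(M)), rep(1, ncol(M)))
  # identical columns correlate at exactly 1
  tab$x2 <- tab$x
  cm2 <- correlation_matrix(tab)
  expect_equal(cm2[cm2$var1 == "x" & cm2$var2 == "x2", "R"], 1)
  expect_error(correlation_matrix(data.frame(a = 1:5)), "two numeric")
})

test_that("trivial absolute-vs-relative pairs are flagged", {
  tab <- data.frame(loss_ml = c(1, 2, 3, 4), loss_pct = c(10, 20, 30, 40),
                    other = c(4, 2, 6, 1))
  cm <- correlation_matrix(tab)
  expect_true(cm[cm$var1 == "loss_ml" & cm$var2 == "loss_pct", "trivial"])
  expect_false(cm[cm$var1 == "loss_ml" & cm$var2 == "other", "trivial"])
})

test_that("cohort_statistics summarizes and tests sector loss columns", {
  set.seed(66)
  n <- 30
  tab <- data.frame(loss_pct_Cranial = runif(n, 20, 80),
                    loss_pct_Anterior = runif(n, 20, 80),
                    loss_pct_Posterior = runif(n, 10, 70),
                    loss_pct_Medial = runif(n, 50, 100))
  st <- cohort_statistics(tab)
  expect_equal(nrow(st$descriptives), 4)
  expect_equal(nrow(st$pairwise), 6)
  expect_true(all(st$pairwise$p >= 0 & st$pairwise$p <= 1))
  mvc <- st$pairwise[st$pairwise$var1 == "loss_pct_Cranial" &
                       st$pairwise$var2 == "loss_pct_Medial", ]
  expect_lt(mvc$p, 0.05)
})
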