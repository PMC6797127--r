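test_that("the group enumeration has 17 unique labels", {
  g <- enumerate_groups()
  expect_length(g, 17)
  expect_false(any(duplicated(g)))
  expect_true(all(c("All intact", "All sectors", "Pelvic discontinuity",
                    "Cranial-Medial") %in% g))
})

test_that("relevance flags apply strict per-sector thresholds", {
  expect_equal(relevance_flags(c(34.0, 12.2, 7.0, 14.6)), "Cranial")
  expect_equal(relevance_flags(c(25.0, 25.0, 15.0, 25.0)), character(0))
  expect_equal(relevance_flags(c(25.001, 25.0, 15.001, 25.0)),
               c("Cranial", "Posterior"))
  expect_equal(relevance_flags(c(23.7, 75.7, 10.5, 62.3)),
               c("Anterior", "Medial"))
})

test_that("worked example quadruples map to their printed groups", {
  cases <- list(
    list(rv = c(34.0, 12.2, 7.0, 14.6), group = "Cranial"),
    list(rv = c(86.4, 23.5, 14.0, 35.5), group = "Cranial-Medial"),
    list(rv = c(23.7, 75.7, 10.5, 62.3), group = "Anterior-Medial"),
    list(rv = c(73.3, 31.1, 13.8, 37.2), group = "Cranial-Anterior-Medial"),
    list(rv = c(67.5, 9.0, 68.3, 95.3), group = "Cranial-Posterior-Medial"),
    list(rv = c(31.8, 65.2, 53.7, 73.5), group = "All sectors"))
  for (cs in cases)
    expect_equal(assign_group(cs$rv)$label, cs$group)
})

test_that("pelvic discontinuity overrides the sector label", {
  g <- assign_group(c(31.8, 65.2, 53.7, 73.5), pd_flag = TRUE)
  expect_equal(g$label, "Pelvic discontinuity")
  # underlying flags are preserved in the record
  expect_equal(g$flagged_sectors,
               c("Cranial", "Anterior", "Posterior", "Medial"))
})

test_that("every assignment lands in the enumerated groups", {
  set.seed(51)
  labels <- replicate(200, assign_group(runif(4, 0, 100),
                                        runif(1) < 0.1)$label)
  expect_true(all(labels %in% enumerate_groups()))
})

test_that("flagging is monotone in relative loss", {
  set.seed(52)
  for (i in 1:50) {
    rv <- runif(4, 0, 80)
    f1 <- relevance_flags(rv)
    bump <- pmin(rv + runif(4, 0, 20), 100)
    f2 <- relevance_flags(bump)
    expect_true(all(f1 %in% f2))
  }
})

test_that("the Paprosky correspondence maps exactly five groups", {
  expect_equal(paprosky_map("All intact"), "1/2A")
  expect_equal(paprosky_map("Cranial"), "2B")
  expect_equal(paprosky_map("Medial"), "2C")
  expect_equal(paprosky_map("Cranial-Medial"), "3A")
  expect_equal(paprosky_map("All sectors"), "3B")
  expect_true(is.na(paprosky_map("Cranial-Posterior")))
  expect_true(is.na(paprosky_map("Pelvic discontinuity")))
  mapped <- !is.na(paprosky_map(enumerate_groups()))
  expect_equal(sum(mapped), 5)
})

test_that("thresholds are validated and configurable", {
  expect_error(assign_group(c(10, 10, 10, 10),
                            thresholds = c(0, 25, 15, 25)), "between")
  g <- assign_group(c(10, 10, 10, 10),
                    thresholds = c(Cranial = 5, Anterior = 5,
                                   Posterior = 5, Medial = 5))
  expect_equal(g$label, "All sectors")
  expect_error(assign_group(c(-1, 10, 10, 10)), "0, 100")
})

test_that("spider plot data uses fixed axis order and group envelope", {
  sp <- spider_plot_data(c(34.0, 12.2, 7.0, 14.6))
  expect_equal(sp$axes, c("Cranial", "Anterior", "Posterior", "Medial"))
  expect_equal(sp$case, c(34.0, 12.2, 7.0, 14.6))
  expect_equal(sp$group_area, c(100, 0, 0, 0))
  expect_equal(sp$label, "Cranial")
  # all-intact case has a zero-area group polygon
  sp0 <- spider_plot_data(c(5, 5, 5, 5))
  expect_equal(sp0$group_area, rep(0, 4))
  p <- plot_spider(sp)
  expect_s3_class(p, "ggplot")
})
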