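test_that("APS severity dichotomizes at 3 and sums", {
  expect_equal(aps_severity(c(0, 0, 0, 0, 0)), 0L)
  expect_equal(aps_severity(c(6, 6, 6, 6, 6)), 5L)
  expect_equal(aps_severity(c(4, 2, 3, 0, 6)), 3L)
  expect_error(aps_severity(c(4, 2, 3, 0)), "5")
  expect_error(aps_severity(c(4, 2, 7, 0, 6)), "position 3")
})

test_that("BS severity treats the special codes correctly", {
  expect_equal(bs_severity(rep(0, 14)), 0L)
  expect_equal(bs_severity(rep(8, 14)), 14L)  # 8 = present, unknown frequency
  expect_equal(bs_severity(c(7, 9, 1, 6, 8, rep(0, 9))), 3L)
  expect_error(bs_severity(rep(0, 5)), "14")
  expect_error(bs_severity(c(rep(0, 13), 10)), "position 14")
})

test_that("severity scoring is monotone and permutation invariant", {
  set.seed(42)
  for (i in 1:50) {
    r <- sample(0:6, 5, replace = TRUE)
    s0 <- aps_severity(r)
    j <- sample(5, 1)
    r2 <- r; r2[j] <- min(r2[j] + sample(0:3, 1), 6)
    expect_gte(aps_severity(r2), s0)
    expect_equal(aps_severity(sample(r)), s0)
    b <- sample(0:9, 14, replace = TRUE)
    expect_equal(bs_severity(sample(b)), bs_severity(b))
  }
})

test_that("composites obey the aggregation identity", {
  cat <- default_item_catalog()
  expect_equal(sum(cat$instrument == "SPI"), 14)
  expect_equal(sum(cat$instrument == "SIPS"), 7)
  c1 <- ema_composites(rep(2, 21), cat)
  expect_equal(unlist(c1), c(mchr = 2, aps = 2, bs = 2, perc = 2, nonp = 2))
  items <- ifelse(cat$instrument == "SPI", 1, 0)
  c2 <- ema_composites(items, cat)
  expect_equal(c2$bs, 1); expect_equal(c2$aps, 0)
  expect_equal(c2$mchr, 14 / 21)
  set.seed(1)
  m <- matrix(runif(21 * 30, 0, 6), 30, 21)
  cc <- ema_composites(m, cat)
  expect_equal((7 * cc$aps + 14 * cc$bs) / 21, cc$mchr, tolerance = 1e-12)
  miss <- rep(2, 21); miss[5] <- NA
  expect_error(ema_composites(miss, cat), "missing")
  expect_equal(ema_composites(miss, cat, allow_partial = TRUE)$mchr,
               2)
})

test_that("RMSSD and individual summaries match hand calculations", {
  expect_equal(rmssd(c(3, 3, 3)), 0)
  expect_equal(rmssd(c(1, 2, 1, 2)), 1)
  expect_equal(rmssd(c(1, NA, 2, NA, 1, 2)), 1) # gaps ignored
  dat <- data.frame(
    person_id = rep(c("a", "b", "c"), each = 4),
    slot = rep(0:3, 3),
    stress = c(1, 1, 1, 1, 3, 3, 3, 3, 2, NA, NA, NA))
  expect_warning(s <- individual_summaries(dat, "stress"), "excluded")
  expect_equal(nrow(s$person), 2) # person c has one observation
  imed <- s$group$mean[s$group$statistic == "imedian"]
  expect_equal(imed, 2) # persons with medians 1 and 3
  expect_equal(s$group$mean[s$group$statistic == "isd"], 0)
  expect_equal(s$group$mean[s$group$statistic == "irmssd"], 0)
})
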