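test_that("usable range has the closed-form bounds", {
  m <- agilentCy3()
  r <- usableRange(m, k = 3, ceiling = 65535)
  expect_equal(r$lower, (3 * 11.90 / 106)^(1 / 0.95), tolerance = 1e-12)
  expect_equal(r$lower, 0.3180436178845768, tolerance = 1e-12)
  expect_equal(predictSignal(r$upper, m), 65535, tolerance = 1e-9)
  expect_false(r$empty)
  expect_identical(usableRange(ScannerModel(106, 0.95, 0), k = 3)$lower, 0)
  expect_error(usableRange(m, k = 1), class = "scancal_domain_error")
})

test_that("the deep dilution series fall below the usable floor", {
  # the k=3 floor for this fit cuts off series 20-27; at the k->1 limit
  # (signal equal to background) the cutoff is x = (g/B)^(1/a) = 0.100,
  # and series 22-27 sit below even that. Either way the deepest third of
  # the dilution series carries no usable dye signal.
  lower <- usableRange(agilentCy3(), k = 3)$lower
  d <- densityForSeries(1:27)
  expect_identical(which(d < lower), 20:27)
  expect_equal((11.90 / 106)^(1 / 0.95), 0.1000584533246445,
               tolerance = 1e-12)
  expect_identical(which(d < 0.1000584533246445), 22:27)
})

test_that("the usable floor moves monotonically with g, k and B", {
  low <- function(B, g, k) usableRange(ScannerModel(B, 0.95, g), k)$lower
  gs <- seq(2, 40, by = 2)
  expect_true(all(diff(vapply(gs, function(g) low(106, g, 3),
                              numeric(1))) > 0))
  ks <- seq(1.5, 20, by = 0.5)
  expect_true(all(diff(vapply(ks, function(k) low(106, 11.9, k),
                              numeric(1))) > 0))
  Bs <- seq(10, 300, by = 10)
  expect_true(all(diff(vapply(Bs, function(B) low(B, 11.9, 3),
                              numeric(1))) < 0))
})

test_that("the range is empty when background reaches the ceiling", {
  m <- ScannerModel(1, 0.95, 500)
  r <- usableRange(m, k = 3, ceiling = 400)
  expect_true(r$empty)
})

test_that("published g values across gains are invariant, B values are not", {
  cy3 <- scannerTable[scannerTable$channel == "Cy3" &
                        scannerTable$scanner == "Agilent", ]
  fits <- lapply(seq_len(3), function(i)
    fitFromParams(cy3$B[i], cy3$a[i], cy3$g[i], "Cy3", cy3$pmt[i]))
  gi <- gainInvariance(fits, "g")
  expect_identical(gi$verdict, "invariant")
  expect_equal(gi$spread, (12.14 - 11.90) / 11.90, tolerance = 1e-12)
  expect_lt(gi$spread, 0.03)
  bi <- gainInvariance(fits, "B")
  expect_identical(bi$verdict, "not invariant")
  expect_gt(bi$spread, 1)
})

test_that("identical fits give zero spread and an invariant verdict", {
  fits <- list(fitFromParams(106, 0.95, 11.9, pmt = 100),
               fitFromParams(106, 0.95, 11.9, pmt = 50))
  gi <- gainInvariance(fits, "g")
  expect_identical(gi$spread, 0)
  expect_identical(gi$verdict, "invariant")
})

test_that("mixing channels without an override is an error", {
  fits <- list(fitFromParams(106, 0.95, 11.9, channel = "Cy3"),
               fitFromParams(54, 0.98, 3.9, channel = "Cy5"))
  expect_error(gainInvariance(fits, "g"),
               class = "scancal_validation_error")
  expect_no_error(gainInvariance(fits, "g", checkChannel = FALSE))
})

test_that("bootstrap intervals drive the verdict when present", {
  ciA <- matrix(c(100, 0.94, 11.0, 112, 0.96, 12.8), ncol = 2,
                dimnames = list(c("B", "a", "g"), c("lower", "upper")))
  ciB <- ciA; ciB["g", ] <- c(12.5, 13.5)       # overlaps A's g interval
  ciC <- ciA; ciC["g", ] <- c(20.0, 22.0)       # disjoint from A's
  fA <- fitFromParams(106, 0.95, 11.9, pmt = 100, ci = ciA)
  fB <- fitFromParams(104, 0.95, 13.0, pmt = 50, ci = ciB)
  fC <- fitFromParams(105, 0.95, 21.0, pmt = 20, ci = ciC)
  ok <- gainInvariance(list(fA, fB), "g")
  expect_true(ok$intervalsUsed)
  expect_identical(ok$verdict, "invariant")
  bad <- gainInvariance(list(fA, fC), "g")
  expect_identical(bad$verdict, "not invariant")
})

test_that("curvature is invariant across published channels and gains", {
  fits <- lapply(1:3, function(i)
    fitFromParams(scannerTable$B[i], scannerTable$a[i], scannerTable$g[i],
                  "Cy3", scannerTable$pmt[i]))
  cc <- curvatureComparison(fits)
  expect_identical(cc$verdict, "invariant")
  expect_equal(cc$values, c(0.95, 0.95, 0.94))
  # cross-channel: Cy5 curvatures 0.98/0.98/0.99 against Cy3 0.95/0.95/0.94
  cross <- curvatureComparison(lapply(1:6, function(i)
    fitFromParams(scannerTable$B[i], scannerTable$a[i], scannerTable$g[i],
                  scannerTable$channel[i], scannerTable$pmt[i])))
  expect_lte(cross$spread, 0.06)
  expect_identical(cross$verdict, "invariant")
  expect_equal(cross$deviationFromUnity,
               abs(c(0.95, 0.95, 0.94, 0.98, 0.98, 0.99) - 1))
  dup <- curvatureComparison(list(fits[[1]], fits[[1]]))
  expect_identical(dup$spread, 0)
})

test_that("equal curvatures make the channel ratio exactly B1/B2", {
  m1 <- ScannerModel(106, 0.95, 11.90, "Cy3", 100)
  m2 <- ScannerModel(54, 0.95, 3.90, "Cy5", 100)
  prof <- channelRatioProfile(m1, m2, densities = 10^seq(-2, 4,
                                                         length.out = 50))
  expect_equal(prof$ratio, rep(106 / 54, 50), tolerance = 1e-12)
  expect_identical(prof$verdict, "constant")
  self <- channelRatioProfile(m1, m1)
  expect_equal(self$ratio, rep(1, length(self$densities)))
  expect_identical(self$verdict, "constant")
})

test_that("different curvatures make the ratio drift as a power of x", {
  m1 <- ScannerModel(106, 0.95, 11.90)
  m2 <- ScannerModel(208, 0.74, 7.45)
  prof <- channelRatioProfile(m1, m2, densities = 10^seq(0, 5,
                                                         length.out = 20))
  expect_identical(prof$verdict, "not constant")
  # ratio scales as x^(0.95 - 0.74)
  expect_equal(prof$ratio[20] / prof$ratio[1], (1e5 / 1)^0.21,
               tolerance = 1e-9)
})

test_that("diagnose aggregates fits and survives permutation", {
  fits <- lapply(1:3, function(i)
    fitFromParams(scannerTable$B[i], scannerTable$a[i], scannerTable$g[i],
                  "Cy3", scannerTable$pmt[i]))
  rpt <- diagnose(fits)
  expect_s4_class(rpt, "DiagnosticsReport")
  expect_identical(nrow(reportTable(rpt)), 3L)
  expect_identical(rpt@gainInvariance[["Cy3"]]$g$verdict, "invariant")
  expect_identical(rpt@gainInvariance[["Cy3"]]$B$verdict, "not invariant")
  perm <- diagnose(fits[c(3, 1, 2)])
  o1 <- order(reportTable(rpt)$pmt_gain)
  o2 <- order(reportTable(perm)$pmt_gain)
  expect_equal(reportTable(rpt)[o1, ], reportTable(perm)[o2, ],
               ignore_attr = TRUE)
  expect_identical(rpt@gainInvariance[["Cy3"]]$g$verdict,
                   perm@gainInvariance[["Cy3"]]$g$verdict)
})

test_that("three-gain simulations sharing one true g reproduce the contrast", {
  # one slide (one g), three PMT gains scaling only B; the fitted g values
  # agree across gains while the fitted B values do not
  fits <- lapply(list(c(106, 100), c(52, 50), c(21, 20)), function(bp) {
    truth <- ScannerModel(bp[1], 0.95, 11.90, "Cy3", bp[2])
    fitResponse(simObs(seed = 500 + bp[2], model = truth))
  })
  expect_identical(gainInvariance(fits, "g")$verdict, "invariant")
  expect_identical(gainInvariance(fits, "B")$verdict, "not invariant")
})
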