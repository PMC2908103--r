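test_that("dilution densities halve each series and match the printed table", {
  d <- densityForSeries(1:27)
  expect_identical(d[1], 1.47e5)
  expect_identical(d[2], 7.35e4)
  expect_equal(d[-1] / d[-27], rep(0.5, 26))
  # agreement with the vendor's printed values to 3 significant figures
  expect_equal(signif(d, 3), printedDensities)
  expect_equal(signif(d[27], 3), 2.19e-3)
})

test_that("series indices outside the dilution range are rejected", {
  expect_error(densityForSeries(0), class = "scancal_domain_error")
  expect_error(densityForSeries(28), class = "scancal_domain_error")
  expect_error(densityForSeries(c(5, 40)), class = "scancal_domain_error")
})

test_that("the standard layout has the documented column roles", {
  layout <- makeSlideLayout(replicatesPerColumn = 20)
  cols <- layoutTable(layout)
  expect_identical(nrow(cols), 32L)
  expect_identical(cols$role[28], "buffer")
  expect_true(is.na(cols$density[28]))
  expect_identical(cols$role[29:31], rep("blank", 3))
  expect_identical(cols$density[29:31], rep(0, 3))
  expect_identical(cols$role[32], "marker")
  expect_identical(cols$role[1:27], rep("dilution", 27))
  expect_identical(nrow(simulateScan(layout,
    SimulationConfig(agilentCy3(), seed = 1))), 640L)
})

test_that("simulation is bit-for-bit reproducible under a fixed seed", {
  layout <- makeSlideLayout(replicatesPerColumn = 5)
  cfg <- SimulationConfig(agilentCy3(), seed = 77)
  expect_identical(simulateScan(layout, cfg), simulateScan(layout, cfg))
  cfg2 <- SimulationConfig(agilentCy3(), seed = 78)
  expect_false(identical(simulateScan(layout, cfg),
                         simulateScan(layout, cfg2)))
})

test_that("the simulator leaves the global RNG stream untouched", {
  layout <- makeSlideLayout(replicatesPerColumn = 2)
  set.seed(123); before <- runif(1)
  set.seed(123)
  invisible(simulateScan(layout, SimulationConfig(agilentCy3(), seed = 9)))
  expect_identical(runif(1), before)
})

test_that("noise-free spots equal the forward model exactly", {
  m <- agilentCy3()
  obs <- simObs(seed = 2, noiseCV = 0, replicates = 3)
  dil <- obs[obs$series <= 27 & !obs$saturated, ]
  expect_identical(dil$signal, predictSignal(dil$x_nominal, m))
  expect_identical(obs$signal[obs$series %in% 29:31], rep(11.90, 9))
})

test_that("buffer spots carry g plus the configured extra autofluorescence", {
  layout <- makeSlideLayout(replicatesPerColumn = 3)
  cfg <- SimulationConfig(agilentCy3(), noiseCV = 0,
                          bufferAutofluorescence = 25, seed = 4)
  obs <- simulateScan(layout, cfg)
  expect_identical(obs$signal[obs$series == 28], rep(11.90 + 25, 3))
  expect_true(all(is.na(obs$x_nominal[obs$series == 28])))
})

test_that("the brightest series saturate a 16-bit detector", {
  # B*x^a alone exceeds 65535 for the top two densities at this truth
  expect_gt(idealSignal(densityForSeries(2), agilentCy3()), 65535)
  obs <- simObs(seed = 3)
  expect_true(all(obs$saturated[obs$series %in% 1:2]))
  expect_true(all(obs$signal[obs$series %in% 1:2] == 65535))
})

test_that("replicate means converge to the model prediction (LLN)", {
  m <- agilentCy3()
  layout <- makeSlideLayout(replicatesPerColumn = 1e4)
  cfg <- SimulationConfig(m, noiseCV = 0.10, seed = 21)
  obs <- simulateScan(layout, cfg)
  for (k in c(10, 14, 20)) {
    s <- obs$signal[obs$series == k]
    mu <- predictSignal(densityForSeries(k), m)
    se <- sd(s) / sqrt(length(s))
    expect_lt(abs(mean(s) - mu), 3 * se)
  }
})

test_that("empirical replicate CV matches the configured noise CV", {
  obs <- simulateScan(makeSlideLayout(replicatesPerColumn = 1e4),
                      SimulationConfig(agilentCy3(), noiseCV = 0.10,
                                       seed = 22))
  s <- obs$signal[obs$series == 10]     # far from both floor and ceiling
  expect_equal(sd(s) / mean(s), 0.10, tolerance = 0.01)
})

test_that("series means decrease along the dilution within the usable part", {
  obs <- simObs(seed = 23)
  unsat <- obs[obs$series <= 27 & !obs$saturated, ]
  means <- tapply(unsat$signal, unsat$series, mean)
  # monotone in expectation until the series sink into the background floor
  keep <- densityForSeries(as.integer(names(means))) >
    usableRange(agilentCy3())$lower
  expect_true(all(diff(means[keep]) < 0))
})

test_that("deep dilutions plateau at the autofluorescence level", {
  m <- agilentCy3()
  obs <- simObs(seed = 24, replicates = 100)
  deep <- which(idealSignal(densityForSeries(1:27), m) < 0.1 * 11.90)
  expect_true(length(deep) >= 3)
  for (k in deep) {
    s <- obs$signal[obs$series == k]
    se <- sd(s) / sqrt(length(s))
    expect_lt(abs(mean(s) - 11.90), 2 * se + 0.1 * 11.90)
  }
})

test_that("fixture bundles round-trip through the readers", {
  dir <- withr::local_tempdir()
  layout <- makeSlideLayout(replicatesPerColumn = 6)
  obs <- simulateScan(layout, SimulationConfig(agilentCy3(), seed = 31))
  paths <- writeFixtureBundle(layout, obs, dir)
  back <- readGal(paths[["gal"]])$layout
  cols <- layoutTable(layout); bcols <- layoutTable(back)
  expect_identical(bcols$role, cols$role)
  expect_identical(bcols$series, cols$series)
  expect_equal(bcols$density, cols$density, tolerance = 1e-9)
  expect_identical(back@replicatesPerColumn, 6L)
  obs2 <- readIntensityTable(paths[["intensities"]])
  expect_equal(obs2[order(obs2$spot_id), ],
               obs[order(obs$spot_id), ], ignore_attr = TRUE,
               tolerance = 0)
})

test_that("a simulated bundle audits cleanly against its own description", {
  dir <- withr::local_tempdir()
  layout <- makeSlideLayout(replicatesPerColumn = 2)
  obs <- simulateScan(layout, SimulationConfig(agilentCy3(), seed = 32))
  paths <- writeFixtureBundle(layout, obs, dir)
  rpt <- checkLayoutConsistency(readSlideDescription(paths[["description"]]),
                                readGal(paths[["gal"]])$layout)
  expect_identical(unname(rpt@counts[c("mismatch", "missing")]), c(0L, 0L))
  expect_identical(unname(rpt@counts["match"]), 32L)
})
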