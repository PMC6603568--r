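test_that("impedance magnitude and capacitance extraction are exact
           inverse pairs", {
  expect_identical(impedanceMagnitude(3, -4), 5)
  expect_identical(impedanceMagnitude(7.3, 0), 7.3)
  expect_equal(capacitanceFromReactance(1 / (2 * pi), -1), 1)
  expect_error(capacitanceFromReactance(31, 0), "singular")
  expect_error(capacitanceFromReactance(0, -1), "frequency")
  # roundtrip Ce -> X -> Ce to machine precision across magnitudes
  for (ce in c(1e-9, 4e-6, 2e-3)) {
    for (f in c(0.5, 31, 999)) {
      x <- -1 / (2 * pi * f * ce)
      expect_equal(capacitanceFromReactance(f, x), ce, tolerance = 1e-14)
    }
  }
  # published wet-frontal example: |X| back-derived from the 31 Hz means
  xAbs <- sqrt(8.2e3^2 - 8.1e3^2)
  expect_equal(impedanceMagnitude(8.1e3, -xAbs), 8.2e3, tolerance = 1e-12)
  expect_equal(capacitanceFromReactance(31, -1278), 1 / (2 * pi * 31 * 1278),
               tolerance = 1e-15)
})

test_that("meter tolerance follows the cable-length correction law", {
  tt <- meterTotalTolerance(meterSpec(TB = 0.3, LC = 4, FM = 31))
  expect_equal(tt, 0.3 + 0.015 * (31 / 1e6)^2 * 16, tolerance = 1e-15)
  expect_lt(tt - 0.3, 1e-9)  # negligible at low frequency
  expect_identical(meterTotalTolerance(meterSpec(TB = 0.3, LC = 0, FM = 31)),
                   0.3)
  expect_equal(meterTotalTolerance(meterSpec(TB = 0, LC = 1, FM = 1e6)),
               0.015)
})

test_that("noiseless sweep fitting recovers parameters exactly", {
  sw <- syntheticSweep(reOhm = 1e4, ceF = 1e-6)
  m <- fitSweep(sw)
  expect_equal(m@ReTable, rep(1e4, 200), tolerance = 1e-14)
  expect_equal(m@CeTable, rep(1e-6, 200), tolerance = 1e-14)
  expect_equal(m@rmEstimate, 1e4, tolerance = 1e-12)
  expect_identical(m@Rm, 0)
})

test_that("noisy sweep fitting recovers medians within 2%", {
  sw <- syntheticSweep(reOhm = 1e4, ceF = 1e-6, noiseSd = 0.01, seed = 42)
  m <- fitSweep(sw)
  expect_lt(abs(stats::median(m@ReTable) - 1e4) / 1e4, 0.02)
  expect_lt(abs(stats::median(m@CeTable) - 1e-6) / 1e-6, 0.02)
})

test_that("positive reactance triggers a warning but |X| is used", {
  expect_warning(
    sw <- impedanceSweep(c(10, 100), c(1e3, 1e3), c(5, -5)),
    "inductive"
  )
  expect_warning(m <- fitSweep(sw), "positive reactance")
  expect_equal(m@CeTable[1], 1 / (2 * pi * 10 * 5), tolerance = 1e-14)
})

test_that("circuit evaluation matches an independent complex-arithmetic
           oracle and its limits", {
  m <- electrodeModel(freqTable = c(10, 31, 100),
                      ReTable = rep(1e4, 3), CeTable = rep(1e-6, 3),
                      Rm = 100)
  z <- modelImpedanceAt(m, 31)
  # oracle: direct complex parallel combination
  zc <- 1 / (1i * 2 * pi * 31 * 1e-6)
  zOracle <- 100 + 1 / (1 / 1e4 + 1 / zc)
  expect_equal(z, zOracle, tolerance = 1e-12)
  # vanishing capacitance: parallel branch opens up to Re
  mOpen <- electrodeModel(freqTable = 31, ReTable = 1e4, CeTable = 1e-30,
                          Rm = 0)
  expect_equal(Mod(modelImpedanceAt(mOpen, 31)), 1e4, tolerance = 1e-6)
  # high-frequency limit with constant tables: impedance collapses onto Rm
  mHf <- electrodeModel(freqTable = c(10, 1000), ReTable = c(1e4, 1e4),
                        CeTable = c(1e-6, 1e-6), Rm = 100)
  expect_equal(Mod(modelImpedanceAt(mHf, 1e8, extrapolate = TRUE)), 100,
               tolerance = 1e-4)
  # low-frequency approximation returns the real resistance
  expect_identical(modelImpedanceAt(m, 31, lowFreqApprox = TRUE), 100 + 1e4)
  # out-of-range frequency requires the extrapolation flag
  expect_error(modelImpedanceAt(m, 5000), "outside")
  expect_equal(modelImpedanceAt(m, 5000, lowFreqApprox = TRUE,
                                extrapolate = TRUE), 100 + 1e4)
})

test_that("|Z| of the parallel RC model is non-increasing in frequency", {
  m <- electrodeModel(freqTable = c(1, 1000), ReTable = c(2e4, 2e4),
                      CeTable = c(5e-7, 5e-7), Rm = 0)
  f <- exp(seq(log(1), log(1000), length.out = 50))
  zmag <- vapply(f, function(fi) Mod(modelImpedanceAt(m, fi)), numeric(1))
  expect_true(all(diff(zmag) <= 1e-9))
})

test_that("replicate summaries use the Student-t 95% interval", {
  mk <- function(r, val) impedanceSweep(c(10, 100), rep(val, 2), c(-1, -1),
                                        "e", "frontal", r)
  sws <- list(mk(1L, 8e3), mk(2L, 12e3))
  s <- summarizeSweeps(sws, atF = 31)
  expect_equal(s$re_mean_ohm, 1e4)
  hw <- stats::qt(0.975, df = 1) * stats::sd(c(8e3, 12e3)) / sqrt(2)
  expect_equal(s$re_ci_ohm, hw, tolerance = 1e-9)
  # identical replicates collapse the interval to zero
  s0 <- summarizeSweeps(list(mk(1L, 8e3), mk(2L, 8e3)), atF = 31)
  expect_equal(s0$re_ci_ohm, 0)
  expect_error(summarizeSweeps(sws, atF = 5000), "outside")
  expect_error(summarizeSweeps(sws[1]), "at least 2")
})

test_that("replicates simulated around the published wet-frontal values
           summarise back to them", {
  set.seed(99)
  sws <- lapply(1:10, function(r) {
    re31 <- 8.1e3 * (1 + stats::rnorm(1, 0, 0.02))
    ce31 <- 4.0e-6 * (1 + stats::rnorm(1, 0, 0.02))
    syntheticSweep(reOhm = re31, ceF = ce31, nPoints = 50,
                   label = "wet", replicate = r)
  })
  s <- summarizeSweeps(sws, atF = 31)
  expect_lt(abs(s$z_mean_ohm - 8.2e3) / 8.2e3, 0.05)
  expect_lt(abs(s$re_mean_ohm - 8.1e3) / 8.1e3, 0.05)
})

test_that("the six published presets recombine to the printed impedance
           means and satisfy |Z| >= Re", {
  pm <- presetModels()
  expect_named(pm, c("wet_frontal", "wet_occipital", "gtec_frontal",
                     "gtec_occipital", "micro_frontal", "micro_occipital"))
  printedZ <- c(8.2, 19.9, 226.5, 77.9, 36.7, 214.9) * 1e3
  printedRe <- c(8.1, 17.6, 198.2, 70.7, 24.0, 135.8) * 1e3
  for (i in seq_along(pm)) {
    m <- pm[[i]]
    expect_equal(m@ReTable, printedRe[i])
    xAbs <- 1 / (2 * pi * 31 * m@CeTable)
    z <- impedanceMagnitude(m@ReTable, -xAbs)
    expect_lt(abs(z - printedZ[i]), 50)  # within printed 0.05 kOhm rounding
    expect_gte(z, m@ReTable)
  }
  expect_equal(electrodePreset("gtec", "frontal")@ReTable, 198.2e3)
})

test_that("sweep CSV and model JSON roundtrips preserve content", {
  sws <- list(syntheticSweep(seed = 1, replicate = 1L),
              syntheticSweep(seed = 2, replicate = 2L))
  csv <- tempfile(fileext = ".csv")
  writeSweeps(sws, csv)
  back <- readSweeps(csv)
  expect_length(back, 2)
  ord <- order(vapply(back, function(s) s@replicateId, integer(1)))
  back <- back[ord]
  expect_equal(back[[1]]@resistance, sws[[1]]@resistance, tolerance = 1e-9)
  expect_equal(back[[2]]@reactance, sws[[2]]@reactance, tolerance = 1e-9)

  json <- tempfile(fileext = ".json")
  writeElectrodeModels(presetModels(), json)
  models <- readElectrodeModels(json)
  expect_length(models, 6)
  expect_equal(models$gtec_frontal@ReTable, 198.2e3)

  bad <- tempfile(fileext = ".csv")
  writeLines("frequency_hz,resistance_ohm", bad)
  expect_error(readSweeps(bad), "missing columns")
})
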