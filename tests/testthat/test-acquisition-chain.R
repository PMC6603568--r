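test_that("input loading law reproduces its worked examples and is linear", {
  # matched low and high impedance cases
  expect_equal(differentialInputVoltage(1, 0, 5e3, 5e3, 1e9), 0.999995,
               tolerance = 1e-12)
  expect_equal(differentialInputVoltage(1, 0, 100e3, 100e3, 1e9), 0.9999,
               tolerance = 1e-12)
  expect_equal(attenuationPercent(5e3, 5e3, 1e9), 5e-4, tolerance = 1e-12)
  expect_equal(attenuationPercent(100e3, 100e3, 1e9), 0.01,
               tolerance = 1e-12)
  expect_identical(attenuationPercent(0, 0, 1e9), 0)
  # ideal source: zero impedances pass the difference through exactly
  v1 <- rnorm(50); v2 <- rnorm(50)
  expect_equal(differentialInputVoltage(v1, v2, 0, 0, 1e9), v1 - v2)
  # pure common mode converts through the mismatch term only
  cm <- differentialInputVoltage(0.3, 0.3, 5e3, 100e3, 1e9)
  expect_equal(cm, 0.3 * (5e3 - 100e3) / 1e9, tolerance = 1e-15)
  # linearity in (v1, v2) for fixed impedances
  a <- differentialInputVoltage(v1, v2, 7e3, 3e3, 1e9)
  b <- differentialInputVoltage(2 * v1 + 1, 2 * v2 + 1, 7e3, 3e3, 1e9)
  ab <- differentialInputVoltage(3 * v1 + 1, 3 * v2 + 1, 7e3, 3e3, 1e9)
  expect_equal(a + b, ab, tolerance = 1e-12)
  expect_error(differentialInputVoltage(1, 0, 1e3, 1e3, 0), "zin")
})

test_that("zero mismatch nulls the common-mode conversion for any zin", {
  for (zin in c(1e6, 1e9, 1e12)) {
    for (z in c(0, 5e3, 1e6)) {
      expect_equal(differentialInputVoltage(0.7, 0.7, z, z, zin), 0,
                   tolerance = 1e-18)
    }
  }
})

test_that("interference injects the mismatch-converted 50 Hz amplitude", {
  zero <- EEGEpoch(numeric(7500) , fs = 250)
  m <- electrodePreset("gtec", "frontal")  # Re(31) = 198.2 kOhm
  cfg <- channelConfig("GTEC_F", m, sourceResistance = 0,
                       referenceImpedance = 5e3)
  amp <- amplifierSpec(cmrrDb = Inf, noiseUvpp = 0)
  intf <- interferenceSpec(cmAmpV = 0.010, cmFreq = 50)
  out <- applyInterference(zero, cfg, amp, intf)
  got <- powerlineAmplitude(out, 50)
  expect_equal(got, 0.010 * (198.2e3 - 5e3) / 1e9, tolerance = 1e-9)
  # finite CMRR adds the intrinsic leakage term
  out2 <- applyInterference(zero, cfg, amplifierSpec(cmrrDb = 120,
                                                     noiseUvpp = 0), intf)
  expect_equal(powerlineAmplitude(out2, 50),
               0.010 * ((198.2e3 - 5e3) / 1e9 + 1e-6), tolerance = 1e-9)
  # balanced stage with ideal CMRR: untouched
  cfgBal <- channelConfig("RESISTOR", NULL, sourceResistance = 5e3,
                          referenceImpedance = 5e3)
  expect_identical(samples(applyInterference(zero, cfgBal, amp, intf)),
                   samples(zero))
  # zero common-mode amplitude: untouched
  expect_identical(
    samples(applyInterference(zero, cfg, amp, interferenceSpec(cmAmpV = 0))),
    samples(zero))
})

test_that("amplifier noise follows the 6.6-sigma peak-to-peak convention
           and is seed-deterministic", {
  zero <- EEGEpoch(numeric(2e5), fs = 250)
  amp <- amplifierSpec(noiseUvpp = 1)
  noisy <- addAmplifierNoise(zero, amp, seed = 31)
  expect_equal(stats::sd(samples(noisy)), 1e-6 / 6.6, tolerance = 0.01)
  noisy2 <- addAmplifierNoise(zero, amp, seed = 31)
  expect_identical(samples(noisy), samples(noisy2))
  quiet <- addAmplifierNoise(zero, amplifierSpec(noiseUvpp = 0), seed = 31)
  expect_identical(samples(quiet), samples(zero))
})

test_that("ADC quantization has the advertised step and bit monotonicity", {
  amp24 <- amplifierSpec(resolutionBits = 24, fullScaleV = 0.187)
  step <- 2 * 0.187 / 2^24
  expect_lt(abs(step - 22.3e-9), 0.1e-9)
  e <- generateEpochs(generatorParams(nEpochs = 1, amplitudeV = 100e-6,
                                      seed = 8))[[1]]
  q <- adcQuantize(e, amp24)
  expect_lte(max(abs(samples(q) - samples(e))), step / 2 + 1e-18)
  # values already on a quantization level are unchanged
  onGrid <- EEGEpoch(round(samples(e) / step) * step, fs = 250)
  expect_identical(samples(adcQuantize(onGrid, amp24)), samples(onGrid))
  # 12-bit quantization is strictly noisier than 24-bit
  amp12 <- amplifierSpec(resolutionBits = 12, fullScaleV = 0.187)
  q12 <- adcQuantize(e, amp12)
  err12 <- sqrt(mean((samples(q12) - samples(e))^2))
  err24 <- sqrt(mean((samples(q) - samples(e))^2))
  expect_gt(err12, err24)
  # clipping warns
  big <- EEGEpoch(rep(1, 100), fs = 250)
  expect_warning(adcQuantize(big, amp24), "clipped")
})

test_that("a transparent chain passes the source through essentially
           unchanged", {
  src <- scaleToMicrovolt(
    generateEpochs(generatorParams(nEpochs = 1, seed = 17))[[1]])
  cfg <- channelConfig("RESISTOR", NULL, sourceResistance = 0,
                       referenceImpedance = 0)
  amp <- amplifierSpec(zin = 1e15, cmrrDb = Inf, noiseUvpp = 0,
                       resolutionBits = 31, fullScaleV = 0.187)
  out <- simulateChannel(src, cfg, amp, interferenceSpec(cmAmpV = 0))
  expect_gt(pearsonR(samples(src), samples(out)), 0.999999)
})

test_that("higher skin-electrode impedance lowers unfiltered SNR
           (paired seeds)", {
  src <- scaleToMicrovolt(
    generateEpochs(generatorParams(nEpochs = 1, seed = 23))[[1]])
  amp <- amplifierSpec()
  intf <- interferenceSpec()
  snrFor <- function(preset) {
    cfg <- channelConfig(toupper(paste0(substr(preset@label, 1, 4), "_F")),
                         preset, 50, 5e3)
    cfg@stage <- switch(preset@label, wet = "WET_F", gtec = "GTEC_F",
                        micro = "MICRO_F")
    out <- simulateChannel(src, cfg, amp, intf, seed = 77)
    y <- zscoreRescale(samples(out), samples(src))
    snrDb(samples(src), y)
  }
  sWet <- snrFor(electrodePreset("wet", "frontal"))
  sGtec <- snrFor(electrodePreset("gtec", "frontal"))
  expect_gt(sWet, sGtec)
})

test_that("unfiltered SNR is non-increasing in total and differential
           source impedance", {
  src <- scaleToMicrovolt(
    generateEpochs(generatorParams(nEpochs = 1, seed = 29))[[1]])
  # high-resolution ADC isolates the loading/interference effect from
  # quantization dither, which is not monotone in the impedances
  amp <- amplifierSpec(resolutionBits = 31)
  intf <- interferenceSpec()
  snrAt <- function(z1, z2) {
    m <- electrodeModel(freqTable = 31, ReTable = max(z1, 1), CeTable = 1e-6)
    cfg <- channelConfig("WET_F", m, sourceResistance = 0,
                         referenceImpedance = z2)
    out <- simulateChannel(src, cfg, amp, intf, seed = 101)
    snrDb(samples(src), zscoreRescale(samples(out), samples(src)))
  }
  # growing z1 + z2 with fixed mismatch
  sumLadder <- c(snrAt(10e3, 5e3), snrAt(100e3, 95e3), snrAt(400e3, 395e3))
  expect_true(all(diff(sumLadder) <= 1e-6))
  # growing |z1 - z2| with fixed z2
  misLadder <- c(snrAt(5e3, 5e3), snrAt(50e3, 5e3), snrAt(200e3, 5e3))
  expect_true(all(diff(misLadder) < 0))
})

test_that("the bench produces nine stages of recordings deterministically", {
  cfg <- testBenchConfig(nEpochs = 2)
  eps <- generateEpochs(cfg@generator)
  out <- runBench(eps, cfg)
  expect_named(out$recordings,
               c("GENERATOR", "RESISTOR", "CLOTH", "WET_F", "WET_O",
                 "GTEC_F", "GTEC_O", "MICRO_F", "MICRO_O"))
  expect_true(all(vapply(out$recordings, length, integer(1)) == 2L))
  expect_length(out$reference, 2)
  out2 <- runBench(eps, cfg)
  expect_identical(samples(out$recordings$GTEC_F[[1]]),
                   samples(out2$recordings$GTEC_F[[1]]))
  expect_error(runBench(list(), cfg), "at least one epoch")
})
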