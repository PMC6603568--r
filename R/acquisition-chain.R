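#' @include AllClasses.R synthetic-eeg.R electrode-models.R
NULL

#' Differential voltage at a loaded amplifier input
#'
#' The loading law of a differential front end fed through source
#' impedances `z1`, `z2` into input impedance `zin`:
#' \deqn{V_A - V_B = \frac{v_1 - v_2}{2}\left(2 - \frac{z_1 + z_2}{z_{in}}\right)
#'   + \frac{v_1 + v_2}{2}\cdot\frac{z_1 - z_2}{z_{in}}}
#' The first term is the (slightly attenuated) differential gain; the
#' second converts common-mode content into a differential error whenever
#' the source impedances are mismatched. Applied sample-wise to series.
#'
#' @param v1,v2 input voltages (V), scalars or equal-length vectors.
#' @param z1,z2 source impedances (ohm), >= 0.
#' @param zin amplifier input impedance (ohm), > 0.
#' @return The differential input voltage(s) (V).
#' @examples
#' differentialInputVoltage(1, 0, 5e3, 5e3, 1e9)    # 0.9999975
#' @export
differentialInputVoltage <- function(v1, v2, z1, z2, zin) {
  if (zin <= 0) stop("zin must be > 0")
  if (z1 < 0 || z2 < 0) stop("source impedances must be >= 0")
  ((v1 - v2) / 2) * (2 - (z1 + z2) / zin) +
    ((v1 + v2) / 2) * ((z1 - z2) / zin)
}

#' Differential-gain attenuation in percent
#'
#' The fractional loss of the differential gain under input loading,
#' `100 * (z1 + z2) / (2 * zin)`.
#'
#' @inheritParams differentialInputVoltage
#' @return Attenuation (percent).
#' @examples
#' attenuationPercent(5e3, 5e3, 1e9)     # 0.0005
#' attenuationPercent(100e3, 100e3, 1e9) # 0.01
#' @export
attenuationPercent <- function(z1, z2, zin) {
  if (zin <= 0) stop("zin must be > 0")
  if (z1 < 0 || z2 < 0) stop("source impedances must be >= 0")
  100 * (z1 + z2) / (2 * zin)
}

# effective source impedances (z1 signal path, z2 reference path) of a stage
# at frequency f; electrode stages use the resistive in-band approximation
stageImpedances <- function(cfg, f, clothResistance = 0) {
  if (is.null(cfg@electrode)) {
    z1 <- cfg@sourceResistance
    z2 <- cfg@sourceResistance
  } else {
    re <- Re(modelImpedanceAt(cfg@electrode, f, lowFreqApprox = TRUE,
                              extrapolate = TRUE))
    z1 <- re + cfg@sourceResistance + clothResistance
    z2 <- cfg@referenceImpedance
  }
  c(z1 = z1, z2 = z2)
}

#' Add mismatch-converted and CMRR-leaked power-line interference
#'
#' A common-mode sinusoid of amplitude `intf@cmAmpV` reaches the
#' differential output with amplitude
#' `cmAmpV * (|z1 - z2| / zin + 10^(-CMRR/20))`: the first term is
#' common-mode to differential conversion by source-impedance mismatch, the
#' second the amplifier's intrinsic common-mode leakage. With matched
#' impedances and infinite CMRR the epoch passes through untouched.
#'
#' @param epoch an [EEGEpoch-class].
#' @param cfg a [ChannelConfig-class] carrying the stage's impedances.
#' @param amp an [AmplifierSpec-class].
#' @param intf an [InterferenceSpec-class].
#' @param clothResistance extra series source resistance (ohm) from the
#'   cloth stage.
#' @return The epoch with the interference added.
#' @export
applyInterference <- function(epoch, cfg, amp, intf, clothResistance = 0) {
  if (intf@cmAmpV == 0) return(epoch)
  zs <- stageImpedances(cfg, intf@cmFreq, clothResistance)
  leak <- if (is.finite(amp@cmrrDb)) 10^(-amp@cmrrDb / 20) else 0
  ampl <- intf@cmAmpV * (abs(zs["z1"] - zs["z2"]) / amp@zin + leak)
  if (ampl == 0) return(epoch)
  t <- (0:(nSamples(epoch) - 1)) / samplingRate(epoch)
  samples(epoch) <- samples(epoch) +
    ampl * sin(2 * pi * intf@cmFreq * t + intf@cmPhase)
  epoch
}

#' Add input-referred amplifier noise
#'
#' Zero-mean Gaussian noise with `6.6 * sigma = noiseUvpp` (the 99.9%
#' peak-to-peak coverage convention). Deterministic given `seed`.
#'
#' @param epoch an [EEGEpoch-class].
#' @param amp an [AmplifierSpec-class].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return The noisy epoch.
#' @export
addAmplifierNoise <- function(epoch, amp, seed = NULL) {
  if (amp@noiseUvpp == 0) return(epoch)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sigma <- amp@noiseUvpp * 1e-6 / 6.6
  samples(epoch) <- samples(epoch) +
    stats::rnorm(nSamples(epoch), 0, sigma)
  epoch
}

#' Mid-tread ADC quantization (with resampling to the ADC rate)
#'
#' Uniform mid-tread quantization to `resolutionBits` over
#' `+/- fullScaleV`; samples beyond full scale are clipped with a warning.
#' If the epoch's rate differs from `amp@fs` it is resampled first.
#'
#' @param epoch an [EEGEpoch-class].
#' @param amp an [AmplifierSpec-class].
#' @return The quantized epoch at `amp@fs`.
#' @export
adcQuantize <- function(epoch, amp) {
  if (samplingRate(epoch) != amp@fs) {
    y <- signal::resample(samples(epoch), p = amp@fs,
                          q = samplingRate(epoch))
    epoch <- EEGEpoch(y, fs = amp@fs, label = epochLabel(epoch),
                      epochIndex = epoch@epochIndex, seed = epoch@seed,
                      meta = epoch@meta)
  }
  x <- samples(epoch)
  if (any(abs(x) > amp@fullScaleV)) {
    warning("samples beyond ADC full scale were clipped")
    x <- pmin(amp@fullScaleV, pmax(-amp@fullScaleV, x))
  }
  step <- 2 * amp@fullScaleV / 2^amp@resolutionBits
  samples(epoch) <- round(x / step) * step
  epoch
}

#' Simulate one recording channel of the bench
#'
#' Composition of the chain: input loading at the stage's in-band source
#' impedances (evaluated at `loadingFreq`, 31 Hz by default, the in-band
#' impedance-check frequency) -> common-mode interference -> amplifier
#' noise -> ADC quantization.
#'
#' @param source an [EEGEpoch-class] feeding the stage (microvolt-scale for
#'   electrode stages).
#' @param cfg a [ChannelConfig-class].
#' @param amp an [AmplifierSpec-class].
#' @param intf an [InterferenceSpec-class].
#' @param seed integer seed for the noise draw.
#' @param loadingFreq frequency (Hz) at which the stage impedances are
#'   evaluated for the loading law.
#' @param clothResistance extra series source resistance (ohm).
#' @return The recorded [EEGEpoch-class], labelled with the stage name.
#' @export
simulateChannel <- function(source, cfg, amp, intf, seed = NULL,
                            loadingFreq = 31, clothResistance = 0) {
  zs <- stageImpedances(cfg, loadingFreq, clothResistance)
  out <- source
  samples(out) <- differentialInputVoltage(samples(source), 0,
                                           zs["z1"], zs["z2"], amp@zin)
  out@label <- cfg@stage
  out <- applyInterference(out, cfg, amp, intf, clothResistance)
  out <- addAmplifierNoise(out, amp, seed)
  adcQuantize(out, amp)
}

#' Default nine-stage bench layout
#'
#' Three framework stages (generator output, resistor divider output,
#' conductive cloth) plus the six published electrode presets at frontal
#' and occipital locations.
#'
#' @param presets named list of electrode models as from [presetModels()].
#' @param sourceResistance series source resistance of the framework (ohm).
#' @param referenceImpedance reference-path impedance at the second
#'   amplifier input (ohm).
#' @return List of nine [ChannelConfig-class] objects.
#' @export
defaultStages <- function(presets = presetModels(), sourceResistance = 50,
                          referenceImpedance = 5000) {
  mk <- function(stage, electrode = NULL)
    channelConfig(stage, electrode, sourceResistance, referenceImpedance)
  list(
    mk("GENERATOR"), mk("RESISTOR"), mk("CLOTH"),
    mk("WET_F", presets$wet_frontal), mk("WET_O", presets$wet_occipital),
    mk("GTEC_F", presets$gtec_frontal), mk("GTEC_O", presets$gtec_occipital),
    mk("MICRO_F", presets$micro_frontal),
    mk("MICRO_O", presets$micro_occipital)
  )
}

#' Construct a BenchConfig
#'
#' @param generator a [GeneratorParams-class].
#' @param amplifier an [AmplifierSpec-class].
#' @param interference an [InterferenceSpec-class].
#' @param stages list of [ChannelConfig-class]; defaults to the nine-stage
#'   layout of [defaultStages()].
#' @param dividerRatio voltage divider ratio (> 1).
#' @param clothResistance cloth series resistance (ohm).
#' @param masterSeed master seed for the run.
#' @return A [BenchConfig-class].
#' @export
benchConfig <- function(generator = generatorParams(),
                        amplifier = amplifierSpec(),
                        interference = interferenceSpec(),
                        stages = defaultStages(),
                        dividerRatio = 5000, clothResistance = 2,
                        masterSeed = 1L) {
  new("BenchConfig",
    generator = generator, amplifier = amplifier,
    interference = interference, stages = stages,
    dividerRatio = dividerRatio, clothResistance = clothResistance,
    masterSeed = as.integer(masterSeed)
  )
}

#' Run the full simulated bench
#'
#' For every input epoch and every configured stage, simulates the
#' electrode-to-digital path. The GENERATOR stage records the playback-range
#' epoch directly; RESISTOR and CLOTH record the microvolt-scaled epoch
#' (the CLOTH stage adding its series resistance); the electrode stages
#' record the scaled epoch through their skin-electrode impedance against
#' the reference path. Per-(stage, epoch) noise seeds are derived from
#' `config@masterSeed` by counter, so a rerun with the same config is
#' bitwise identical.
#'
#' @param epochs list of playback-range (+/-0.5 V) [EEGEpoch-class] epochs.
#' @param config a [BenchConfig-class].
#' @return List with elements `recordings` (named list stage -> list of
#'   epochs) and `reference` (the microvolt-scaled source epochs the
#'   recordings should be scored against).
#' @export
runBench <- function(epochs, config) {
  stopifnot(is(config, "BenchConfig"))
  if (!length(epochs)) stop("need at least one epoch")
  scaled <- lapply(epochs, scaleToMicrovolt, dividerRatio = config@dividerRatio)
  scaled <- lapply(scaled, clothStage,
                   seriesResistanceOhm = config@clothResistance)
  recordings <- list()
  for (si in seq_along(config@stages)) {
    cfg <- config@stages[[si]]
    cloth <- switch(cfg@stage, GENERATOR = 0, RESISTOR = 0,
                    config@clothResistance)
    # the playback-range stage is recorded by a wide-range digitizer
    # (bench oscilloscope), not the EEG ADC, so widen its full scale
    amp <- config@amplifier
    if (cfg@stage == "GENERATOR" && amp@fullScaleV < 1)
      amp@fullScaleV <- 1
    recs <- lapply(seq_along(epochs), function(i) {
      src <- if (cfg@stage == "GENERATOR") epochs[[i]] else scaled[[i]]
      seed <- deriveSeed(config@masterSeed, si * 1000L + i)
      simulateChannel(src, cfg, amp, config@interference,
                      seed = seed, clothResistance = cloth)
    })
    recordings[[cfg@stage]] <- recs
  }
  list(recordings = recordings, reference = scaled)
}
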