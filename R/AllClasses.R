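#' @import methods
NULL

setClassUnion("ElectrodeModelOrNULL", "NULL")

#' EEGEpoch: a uniformly sampled voltage time series
#'
#' The atomic signal container of the bench. Samples are stored in volts at a
#' fixed sampling rate; the label records which acquisition stage or channel
#' produced the epoch. Arbitrary stage metadata (e.g. the conductive-cloth
#' series resistance) travels in `meta`.
#'
#' @slot samples numeric vector of voltages (V).
#' @slot fs sampling rate in Hz (> 0).
#' @slot label stage/channel identifier.
#' @slot epochIndex integer index of the epoch within its set.
#' @slot seed RNG seed used to generate the epoch, or `NA` if not generated.
#' @slot meta list of additional metadata.
#'
#' @exportClass EEGEpoch
setClass("EEGEpoch",
  representation(
    samples = "numeric",
    fs = "numeric",
    label = "character",
    epochIndex = "integer",
    seed = "integer",
    meta = "list"
  ),
  prototype(
    label = "", epochIndex = 1L, seed = NA_integer_, meta = list()
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "fs must be a single positive finite number")
    if (length(object@samples) && any(!is.finite(object@samples)))
      msg <- c(msg, "all samples must be finite")
    if (length(object@label) != 1L)
      msg <- c(msg, "label must be a single string")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an EEGEpoch
#'
#' @param samples numeric vector of voltages (V).
#' @param fs sampling rate (Hz).
#' @param label stage/channel identifier.
#' @param epochIndex integer epoch index.
#' @param seed integer seed or `NA`.
#' @param meta metadata list.
#' @return An [EEGEpoch-class] object.
#' @examples
#' e <- EEGEpoch(sin(2 * pi * 10 * seq(0, 1, by = 1 / 250)), fs = 250)
#' nSamples(e)
#' @export
EEGEpoch <- function(samples, fs, label = "", epochIndex = 1L,
                     seed = NA_integer_, meta = list()) {
  new("EEGEpoch",
    samples = as.numeric(samples), fs = as.numeric(fs),
    label = as.character(label), epochIndex = as.integer(epochIndex),
    seed = as.integer(seed), meta = meta
  )
}

#' GeneratorParams: synthetic neonatal EEG generator settings
#'
#' Defaults emulate the bench's source material: 15 epochs of 30 s at
#' 250 Hz, band-limited 0.5--100 Hz, peak-scaled to +/-0.5 V, with a 45--55 Hz
#' spectral gap mirroring the 50 Hz notch applied to the clinical recordings
#' before playback.
#'
#' @slot nEpochs number of epochs to generate.
#' @slot durationS epoch duration (s).
#' @slot fs sampling rate (Hz).
#' @slot band length-2 numeric, passband (Hz).
#' @slot amplitudeV peak amplitude (V).
#' @slot spectralProfile one of `"pink"`, `"white"`, `"mixed"`.
#' @slot seizureFraction fraction of epochs carrying a rhythmic 0.5--3 Hz
#'   discharge component.
#' @slot powerlineAmpV residual 50 Hz amplitude added after scaling (V).
#' @slot notchGap length-2 numeric band (Hz) zeroed in the synthesis spectrum
#'   (the emulated preprocessing notch); `NA` disables it.
#' @slot seed master seed.
#' @exportClass GeneratorParams
setClass("GeneratorParams",
  representation(
    nEpochs = "integer", durationS = "numeric", fs = "numeric",
    band = "numeric", amplitudeV = "numeric", spectralProfile = "character",
    seizureFraction = "numeric", powerlineAmpV = "numeric",
    notchGap = "numeric", seed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (object@nEpochs < 1L) msg <- c(msg, "nEpochs must be >= 1")
    if (object@durationS <= 0) msg <- c(msg, "durationS must be > 0")
    if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
    if (length(object@band) != 2L ||
        !(0 < object@band[1] && object@band[1] < object@band[2] &&
          object@band[2] < object@fs / 2))
      msg <- c(msg, "band must satisfy 0 < low < high < fs/2")
    if (object@amplitudeV <= 0) msg <- c(msg, "amplitudeV must be > 0")
    if (!object@spectralProfile %in% c("pink", "white", "mixed"))
      msg <- c(msg, "spectralProfile must be 'pink', 'white' or 'mixed'")
    if (object@seizureFraction < 0 || object@seizureFraction > 1)
      msg <- c(msg, "seizureFraction must be in [0, 1]")
    if (object@powerlineAmpV < 0) msg <- c(msg, "powerlineAmpV must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct GeneratorParams
#'
#' @param nEpochs,durationS,fs,band,amplitudeV,spectralProfile see slots.
#' @param seizureFraction,powerlineAmpV,notchGap,seed see slots.
#' @return A [GeneratorParams-class] object.
#' @examples
#' generatorParams(nEpochs = 3, seed = 1)
#' @export
generatorParams <- function(nEpochs = 15L, durationS = 30, fs = 250,
                            band = c(0.5, 100), amplitudeV = 0.5,
                            spectralProfile = "pink", seizureFraction = 0.25,
                            powerlineAmpV = 0, notchGap = c(45, 55),
                            seed = 1L) {
  new("GeneratorParams",
    nEpochs = as.integer(nEpochs), durationS = durationS, fs = fs,
    band = band, amplitudeV = amplitudeV, spectralProfile = spectralProfile,
    seizureFraction = seizureFraction, powerlineAmpV = powerlineAmpV,
    notchGap = notchGap, seed = as.integer(seed)
  )
}

#' ImpedanceSweep: one skin-electrode impedance frequency sweep
#'
#' Per-frequency resistance and (signed) reactance measured between one
#' electrode pair at one scalp location, as produced by an LCR meter sweep.
#' Reactance is expected to be capacitive (negative); a positive value
#' triggers a warning at construction, and downstream extraction uses |X|.
#'
#' @slot frequencies Hz, strictly ascending, positive.
#' @slot resistance ohms at each frequency.
#' @slot reactance ohms (signed) at each frequency.
#' @slot electrodeLabel electrode identifier (e.g. "wet").
#' @slot location `"frontal"` or `"occipital"`.
#' @slot replicateId replicate number.
#' @exportClass ImpedanceSweep
setClass("ImpedanceSweep",
  representation(
    frequencies = "numeric", resistance = "numeric", reactance = "numeric",
    electrodeLabel = "character", location = "character",
    replicateId = "integer"
  ),
  validity = function(object) {
    msg <- character()
    n <- length(object@frequencies)
    if (n < 2L) msg <- c(msg, "need at least 2 sweep points")
    if (length(object@resistance) != n || length(object@reactance) != n)
      msg <- c(msg, "frequencies, resistance, reactance lengths must match")
    if (any(object@frequencies <= 0))
      msg <- c(msg, "frequencies must be positive")
    if (n >= 2L && any(diff(object@frequencies) <= 0))
      msg <- c(msg, "frequencies must be strictly ascending")
    if (!object@location %in% c("frontal", "occipital"))
      msg <- c(msg, "location must be 'frontal' or 'occipital'")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an ImpedanceSweep
#'
#' @param frequencies,resistance,reactance,electrodeLabel,location,replicateId
#'   see slots.
#' @return An [ImpedanceSweep-class] object. Warns if any reactance is
#'   positive (inductive), which the capacitive interface model does not
#'   expect.
#' @export
impedanceSweep <- function(frequencies, resistance, reactance,
                           electrodeLabel = "electrode",
                           location = "frontal", replicateId = 1L) {
  if (any(reactance > 0))
    warning("positive (inductive) reactance in sweep; |X| will be used")
  new("ImpedanceSweep",
    frequencies = as.numeric(frequencies),
    resistance = as.numeric(resistance),
    reactance = as.numeric(reactance),
    electrodeLabel = as.character(electrodeLabel),
    location = as.character(location),
    replicateId = as.integer(replicateId)
  )
}

#' ElectrodeModel: skin-electrode equivalent circuit
#'
#' The interface is modelled as a half-cell DC source Ehc in series with the
#' electrode material resistance Rm and a parallel RC block (Re || Ce) whose
#' elements are tabulated against frequency, because the interface is
#' dispersive: Re falls with frequency as the stratum corneum's capacitance
#' shunts it. Evaluation interpolates the tables log-linearly in frequency.
#'
#' @slot Rm electrode material resistance (ohm).
#' @slot freqTable frequencies (Hz) at which Re/Ce are tabulated.
#' @slot ReTable interface resistance (ohm) per tabulated frequency.
#' @slot CeTable interface capacitance (F) per tabulated frequency.
#' @slot Ehc half-cell DC offset (V).
#' @slot rmEstimate high-frequency resistance asymptote recovered by
#'   [fitSweep()] (ohm), `NA` when not fitted. Kept as diagnostics, not added
#'   into evaluation: the tabulated resistance already contains the series
#'   Rm of the measurement path.
#' @slot label electrode identifier.
#' @slot location `"frontal"` or `"occipital"`.
#' @exportClass ElectrodeModel
setClass("ElectrodeModel",
  representation(
    Rm = "numeric", freqTable = "numeric", ReTable = "numeric",
    CeTable = "numeric", Ehc = "numeric", rmEstimate = "numeric",
    label = "character", location = "character"
  ),
  prototype(Rm = 0, Ehc = 0, rmEstimate = NA_real_,
            label = "", location = "frontal"),
  validity = function(object) {
    msg <- character()
    n <- length(object@freqTable)
    if (n < 1L) msg <- c(msg, "need at least one tabulated frequency")
    if (length(object@ReTable) != n || length(object@CeTable) != n)
      msg <- c(msg, "freqTable, ReTable, CeTable lengths must match")
    if (any(object@freqTable <= 0)) msg <- c(msg, "frequencies must be > 0")
    if (any(object@ReTable <= 0)) msg <- c(msg, "Re must be > 0 everywhere")
    if (any(object@CeTable <= 0)) msg <- c(msg, "Ce must be > 0 everywhere")
    if (object@Rm < 0) msg <- c(msg, "Rm must be >= 0")
    if (length(msg)) msg else TRUE
  }
)
setIs("ElectrodeModel", "ElectrodeModelOrNULL")

#' Construct an ElectrodeModel
#'
#' @param freqTable,ReTable,CeTable,Rm,Ehc,rmEstimate,label,location see
#'   slots of [ElectrodeModel-class].
#' @return An [ElectrodeModel-class] object.
#' @export
electrodeModel <- function(freqTable, ReTable, CeTable, Rm = 0, Ehc = 0,
                           rmEstimate = NA_real_, label = "",
                           location = "frontal") {
  new("ElectrodeModel",
    Rm = Rm, freqTable = as.numeric(freqTable),
    ReTable = as.numeric(ReTable), CeTable = as.numeric(CeTable),
    Ehc = Ehc, rmEstimate = rmEstimate, label = label, location = location
  )
}

#' MeterSpec: LCR meter tolerance inputs
#'
#' @slot TB basic tolerance (percent).
#' @slot LC test cable length (m).
#' @slot FM measurement frequency (Hz).
#' @exportClass MeterSpec
setClass("MeterSpec",
  representation(TB = "numeric", LC = "numeric", FM = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@TB < 0) msg <- c(msg, "TB must be >= 0")
    if (object@LC < 0) msg <- c(msg, "LC must be >= 0")
    if (object@FM <= 0) msg <- c(msg, "FM must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a MeterSpec
#'
#' Defaults follow the impedance-check protocol: 0.3% basic tolerance, 4 m
#' cable, 31 Hz in-band test frequency.
#'
#' @param TB basic tolerance (percent).
#' @param LC cable length (m).
#' @param FM measurement frequency (Hz).
#' @return A [MeterSpec-class] object.
#' @export
meterSpec <- function(TB = 0.3, LC = 4, FM = 31) {
  new("MeterSpec", TB = TB, LC = LC, FM = FM)
}

#' AmplifierSpec: acquisition front-end contract
#'
#' Defaults match a low-cost 24-bit biosignal front end: 1 GOhm input
#' impedance, 120 dB CMRR, 1 uVpp input-referred noise, 250 Hz sampling.
#'
#' @slot zin input impedance (ohm).
#' @slot cmrrDb common-mode rejection ratio (dB); `Inf` for an ideal
#'   amplifier.
#' @slot noiseUvpp input-referred noise, microvolt peak-to-peak (6.6 sigma
#'   convention).
#' @slot fs output sampling rate (Hz).
#' @slot resolutionBits ADC resolution (bits).
#' @slot fullScaleV ADC full scale (+/- V).
#' @exportClass AmplifierSpec
setClass("AmplifierSpec",
  representation(
    zin = "numeric", cmrrDb = "numeric", noiseUvpp = "numeric",
    fs = "numeric", resolutionBits = "integer", fullScaleV = "numeric"
  ),
  validity = function(object) {
    msg <- character()
    if (object@zin <= 0) msg <- c(msg, "zin must be > 0")
    if (object@fs <= 0) msg <- c(msg, "fs must be > 0")
    if (object@resolutionBits < 12L)
      msg <- c(msg, "resolutionBits must be >= 12")
    if (object@fullScaleV <= 0) msg <- c(msg, "fullScaleV must be > 0")
    if (object@noiseUvpp < 0) msg <- c(msg, "noiseUvpp must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an AmplifierSpec
#'
#' @param zin,cmrrDb,noiseUvpp,fs,resolutionBits,fullScaleV see slots.
#' @return An [AmplifierSpec-class] object.
#' @examples
#' amplifierSpec()                      # low-cost 24-bit board defaults
#' amplifierSpec(cmrrDb = Inf, noiseUvpp = 0)  # ideal front end
#' @export
amplifierSpec <- function(zin = 1e9, cmrrDb = 120, noiseUvpp = 1,
                          fs = 250, resolutionBits = 24L,
                          fullScaleV = 0.187) {
  new("AmplifierSpec",
    zin = zin, cmrrDb = cmrrDb, noiseUvpp = noiseUvpp, fs = fs,
    resolutionBits = as.integer(resolutionBits), fullScaleV = fullScaleV
  )
}

#' InterferenceSpec: common-mode power-line pickup
#'
#' A sinusoid of amplitude `cmAmpV` present identically on both amplifier
#' inputs; it reaches the differential output only through source-impedance
#' mismatch and finite CMRR.
#'
#' @slot cmAmpV common-mode amplitude (V).
#' @slot cmFreq frequency (Hz), 50 by default.
#' @slot cmPhase phase (rad).
#' @slot seed integer seed for any stochastic extension.
#' @exportClass InterferenceSpec
setClass("InterferenceSpec",
  representation(cmAmpV = "numeric", cmFreq = "numeric",
                 cmPhase = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@cmAmpV < 0) msg <- c(msg, "cmAmpV must be >= 0")
    if (object@cmFreq <= 0) msg <- c(msg, "cmFreq must be > 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an InterferenceSpec
#'
#' @param cmAmpV,cmFreq,cmPhase,seed see slots.
#' @return An [InterferenceSpec-class] object.
#' @export
interferenceSpec <- function(cmAmpV = 0.010, cmFreq = 50, cmPhase = 0,
                             seed = 1L) {
  new("InterferenceSpec",
    cmAmpV = cmAmpV, cmFreq = cmFreq, cmPhase = cmPhase,
    seed = as.integer(seed)
  )
}

.STAGES <- c("GENERATOR", "RESISTOR", "CLOTH",
             "WET_F", "WET_O", "GTEC_F", "GTEC_O", "MICRO_F", "MICRO_O")
.ELECTRODE_STAGES <- .STAGES[4:9]

#' ChannelConfig: one recording stage of the bench
#'
#' @slot stage one of GENERATOR, RESISTOR, CLOTH, WET_F, WET_O, GTEC_F,
#'   GTEC_O, MICRO_F, MICRO_O.
#' @slot electrode an [ElectrodeModel-class] for the six electrode stages,
#'   otherwise `NULL`.
#' @slot sourceResistance series source resistance feeding the stage (ohm).
#' @slot referenceImpedance impedance of the shared reference path at the
#'   second amplifier input (ohm).
#' @exportClass ChannelConfig
setClass("ChannelConfig",
  representation(stage = "character", electrode = "ElectrodeModelOrNULL",
                 sourceResistance = "numeric",
                 referenceImpedance = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@stage %in% .STAGES)
      msg <- c(msg, paste("stage must be one of:",
                          paste(.STAGES, collapse = ", ")))
    isElec <- object@stage %in% .ELECTRODE_STAGES
    if (isElec && is.null(object@electrode))
      msg <- c(msg, "electrode stages require an electrode model")
    if (!isElec && !is.null(object@electrode))
      msg <- c(msg, "non-electrode stages must not carry an electrode model")
    if (object@sourceResistance < 0)
      msg <- c(msg, "sourceResistance must be >= 0")
    if (object@referenceImpedance < 0)
      msg <- c(msg, "referenceImpedance must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a ChannelConfig
#'
#' @param stage,electrode,sourceResistance,referenceImpedance see slots.
#' @return A [ChannelConfig-class] object.
#' @export
channelConfig <- function(stage, electrode = NULL, sourceResistance = 50,
                          referenceImpedance = 5000) {
  new("ChannelConfig",
    stage = stage, electrode = electrode,
    sourceResistance = sourceResistance,
    referenceImpedance = referenceImpedance
  )
}

#' QualityReport: per-stage signal-quality summary
#'
#' One row per stage with mean and 95% CI half-width (Student t,
#' `nEpochs - 1` df) across epochs for unfiltered/filtered correlation,
#' unfiltered/filtered SNR (dB), and pre-filtering 50 Hz bin amplitude (uV).
#'
#' @slot table data.frame of summaries (see [scoreBench()]).
#' @slot nEpochs number of epochs the summary averages over.
#' @exportClass QualityReport
setClass("QualityReport",
  representation(table = "data.frame", nEpochs = "integer"),
  validity = function(object) {
    msg <- character()
    need <- c("stage",
              "correlation_unfiltered_mean", "correlation_unfiltered_ci",
              "correlation_filtered_mean", "correlation_filtered_ci",
              "snr_db_unfiltered_mean", "snr_db_unfiltered_ci",
              "snr_db_filtered_mean", "snr_db_filtered_ci",
              "noise_50hz_uv_mean", "noise_50hz_uv_ci")
    if (!all(need %in% names(object@table)))
      msg <- c(msg, "report table is missing required columns")
    cors <- unlist(object@table[grep("^correlation.*mean$",
                                     names(object@table))])
    if (length(cors) && any(cors < -1 - 1e-12 | cors > 1 + 1e-12))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    cis <- unlist(object@table[grep("_ci$", names(object@table))])
    if (length(cis) && any(!is.na(cis) & cis < 0))
      msg <- c(msg, "CI half-widths must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' BenchConfig: a full bench run configuration
#'
#' @slot generator a [GeneratorParams-class].
#' @slot amplifier an [AmplifierSpec-class].
#' @slot interference an [InterferenceSpec-class].
#' @slot stages list of [ChannelConfig-class] with unique stage labels.
#' @slot dividerRatio voltage-divider ratio mapping generator volts to
#'   microvolt-scale EEG (default 5000: +/-0.5 V to +/-100 uV).
#' @slot clothResistance conductive-cloth series resistance (ohm).
#' @slot masterSeed master seed for the run.
#' @exportClass BenchConfig
setClass("BenchConfig",
  representation(
    generator = "GeneratorParams", amplifier = "AmplifierSpec",
    interference = "InterferenceSpec", stages = "list",
    dividerRatio = "numeric", clothResistance = "numeric",
    masterSeed = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (!all(vapply(object@stages, is, logical(1), "ChannelConfig")))
      msg <- c(msg, "stages must all be ChannelConfig objects")
    labs <- vapply(object@stages, function(s) s@stage, character(1))
    if (anyDuplicated(labs)) msg <- c(msg, "stage labels must be unique")
    if (object@dividerRatio <= 1) msg <- c(msg, "dividerRatio must be > 1")
    if (object@clothResistance < 0)
      msg <- c(msg, "clothResistance must be >= 0")
    if (length(msg)) msg else TRUE
  }
)
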