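#' @include AllClasses.R
NULL

#' Accessors for EEGEpoch
#'
#' @param object an [EEGEpoch-class].
#' @return `samples()` the voltage vector (V); `samplingRate()` the rate in
#'   Hz; `epochLabel()` the stage/channel label; `nSamples()` the sample
#'   count; `durationS()` the duration in seconds; `peakAmplitude()`
#'   `max(abs(samples))`.
#' @name EEGEpoch-accessors
#' @aliases samples samplingRate epochLabel nSamples durationS peakAmplitude
NULL

#' @rdname EEGEpoch-accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname EEGEpoch-accessors
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname EEGEpoch-accessors
#' @export
setGeneric("epochLabel", function(object) standardGeneric("epochLabel"))

#' @rdname EEGEpoch-accessors
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' @rdname EEGEpoch-accessors
#' @export
setGeneric("durationS", function(object) standardGeneric("durationS"))

#' @rdname EEGEpoch-accessors
#' @export
setGeneric("peakAmplitude", function(object) standardGeneric("peakAmplitude"))

#' @rdname EEGEpoch-accessors
setMethod("samples", "EEGEpoch", function(object) object@samples)

#' @rdname EEGEpoch-accessors
setMethod("samplingRate", "EEGEpoch", function(object) object@fs)

#' @rdname EEGEpoch-accessors
setMethod("epochLabel", "EEGEpoch", function(object) object@label)

#' @rdname EEGEpoch-accessors
setMethod("nSamples", "EEGEpoch", function(object) length(object@samples))

#' @rdname EEGEpoch-accessors
setMethod("durationS", "EEGEpoch",
          function(object) length(object@samples) / object@fs)

#' @rdname EEGEpoch-accessors
setMethod("peakAmplitude", "EEGEpoch",
          function(object) max(abs(object@samples)))

#' Replace the samples of an epoch, keeping its metadata
#'
#' @param object an [EEGEpoch-class].
#' @param value numeric replacement vector.
#' @return The updated epoch.
#' @export
setGeneric("samples<-", function(object, value) standardGeneric("samples<-"))

#' @rdname samples-set
#' @name samples<-
setReplaceMethod("samples", "EEGEpoch", function(object, value) {
  object@samples <- as.numeric(value)
  validObject(object)
  object
})

#' Report table accessor
#'
#' @param object a [QualityReport-class].
#' @return The per-stage summary `data.frame`.
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))

#' @rdname reportTable
setMethod("reportTable", "QualityReport", function(object) object@table)

setMethod("show", "EEGEpoch", function(object) {
  cat(sprintf(
    "EEGEpoch '%s' #%d: %d samples @ %g Hz (%.3g s), peak %.4g V\n",
    object@label, object@epochIndex, length(object@samples), object@fs,
    durationS(object), if (length(object@samples)) peakAmplitude(object)
    else NA_real_
  ))
})

setMethod("show", "ImpedanceSweep", function(object) {
  cat(sprintf(
    "ImpedanceSweep '%s' (%s, replicate %d): %d points, %.4g-%.4g Hz\n",
    object@electrodeLabel, object@location, object@replicateId,
    length(object@frequencies), min(object@frequencies),
    max(object@frequencies)
  ))
})

setMethod("show", "ElectrodeModel", function(object) {
  cat(sprintf(
    "ElectrodeModel '%s' (%s): %d tabulated frequencies (%.4g-%.4g Hz), Rm = %g ohm, Ehc = %g V\n",
    object@label, object@location, length(object@freqTable),
    min(object@freqTable), max(object@freqTable), object@Rm, object@Ehc
  ))
})

setMethod("show", "AmplifierSpec", function(object) {
  cat(sprintf(
    "AmplifierSpec: ZIN = %.3g ohm, CMRR = %g dB, noise = %g uVpp, fs = %g Hz, %d bits, FS +/- %g V\n",
    object@zin, object@cmrrDb, object@noiseUvpp, object@fs,
    object@resolutionBits, object@fullScaleV
  ))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport over %d epochs:\n", object@nEpochs))
  tbl <- object@table
  fmt <- function(m, ci) {
    ifelse(is.na(ci), sprintf("%.3f (CI n/a)", m),
           sprintf("%.3f ± %.3f", m, ci))
  }
  out <- data.frame(
    stage = tbl$stage,
    corr_unf = fmt(tbl$correlation_unfiltered_mean,
                   tbl$correlation_unfiltered_ci),
    corr_filt = fmt(tbl$correlation_filtered_mean,
                    tbl$correlation_filtered_ci),
    snr_unf_db = fmt(tbl$snr_db_unfiltered_mean, tbl$snr_db_unfiltered_ci),
    snr_filt_db = fmt(tbl$snr_db_filtered_mean, tbl$snr_db_filtered_ci),
    noise50_uV = fmt(tbl$noise_50hz_uv_mean, tbl$noise_50hz_uv_ci)
  )
  print(out, row.names = FALSE)
})

setMethod("show", "BenchConfig", function(object) {
  labs <- vapply(object@stages, function(s) s@stage, character(1))
  cat(sprintf(
    "BenchConfig: %d epochs x %d stages [%s], divider 1:%g, master seed %d\n",
    object@generator@nEpochs, length(labs), paste(labs, collapse = ", "),
    object@dividerRatio, object@masterSeed
  ))
})
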