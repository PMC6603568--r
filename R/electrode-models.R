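#' @include AllClasses.R
NULL

#' Impedance magnitude from resistance and reactance
#'
#' `|Z| = sqrt(Re^2 + X^2)`, the magnitude of `Re + iX`.
#'
#' @param re resistance (ohm).
#' @param x reactance (ohm, signed).
#' @return Impedance magnitude (ohm). Vectorised.
#' @examples
#' impedanceMagnitude(3, -4)  # 5
#' @export
impedanceMagnitude <- function(re, x) {
  if (any(!is.finite(re)) || any(!is.finite(x)))
    stop("inputs must be finite")
  sqrt(re^2 + x^2)
}

#' Interface capacitance from capacitive reactance
#'
#' `Ce = 1 / (2 * pi * f * |X|)`; the sign of X is discarded because the
#' interface is modelled as capacitive.
#'
#' @param f frequency (Hz), > 0.
#' @param x reactance (ohm), nonzero.
#' @return Capacitance (F). Vectorised.
#' @export
capacitanceFromReactance <- function(f, x) {
  if (any(f <= 0)) stop("frequency must be > 0")
  if (any(x == 0)) stop("singular input: zero reactance")
  1 / (2 * pi * f * abs(x))
}

#' Total LCR-meter measurement tolerance
#'
#' `TT = TB + 0.015% * (FM / 1e6)^2 * LC^2`; the cable-length correction is
#' negligible at EEG-band measurement frequencies.
#'
#' @param spec a [MeterSpec-class].
#' @return Total tolerance (percent).
#' @examples
#' meterTotalTolerance(meterSpec(TB = 0.3, LC = 4, FM = 31))
#' @export
meterTotalTolerance <- function(spec) {
  stopifnot(is(spec, "MeterSpec"))
  spec@TB + 0.015 * (spec@FM / 1e6)^2 * spec@LC^2
}

#' Extract an equivalent-circuit model from an impedance sweep
#'
#' Per-frequency extraction: the tabulated interface resistance is the
#' measured resistance itself, and the capacitance at each point follows
#' from the measured reactance via [capacitanceFromReactance()]. The
#' high-frequency resistance asymptote (mean over the top decile of sweep
#' frequencies) is recorded as `rmEstimate` for diagnostics; the circuit
#' `Rm` slot is left at 0 because the measured series resistance already
#' contains it.
#'
#' @param sweep an [ImpedanceSweep-class].
#' @return An [ElectrodeModel-class] tabulated at the sweep frequencies.
#' @export
fitSweep <- function(sweep) {
  stopifnot(is(sweep, "ImpedanceSweep"))
  f <- sweep@frequencies
  if (any(f <= 0)) stop("nonpositive frequency in sweep")
  if (any(sweep@reactance > 0))
    warning("positive reactance in sweep; using |X| for capacitance")
  ce <- capacitanceFromReactance(f, sweep@reactance)
  nTop <- max(1L, ceiling(length(f) / 10))
  rmEst <- mean(utils::tail(sweep@resistance, nTop))
  electrodeModel(
    freqTable = f, ReTable = sweep@resistance, CeTable = ce,
    Rm = 0, Ehc = 0, rmEstimate = rmEst,
    label = sweep@electrodeLabel, location = sweep@location
  )
}

interpLogF <- function(freqTable, values, f, extrapolate = FALSE) {
  if (length(freqTable) == 1L) {
    if (!extrapolate && abs(f - freqTable) > 1e-9 * freqTable)
      stop(sprintf(
        "f = %g Hz outside tabulated range (single point at %g Hz); set extrapolate = TRUE",
        f, freqTable))
    return(values)
  }
  lo <- min(freqTable); hi <- max(freqTable)
  if (f < lo || f > hi) {
    if (!extrapolate)
      stop(sprintf("f = %g Hz outside tabulated range [%g, %g] Hz", f, lo, hi))
    return(values[if (f < lo) which.min(freqTable) else which.max(freqTable)])
  }
  stats::approx(log(freqTable), values, xout = log(f), ties = "ordered")$y
}

#' Evaluate the skin-electrode circuit impedance at a frequency
#'
#' Full circuit: `Rm + (Re(f) || 1 / (i 2 pi f Ce(f)))` with Re/Ce read off
#' the model's tables by log-linear interpolation in frequency. With
#' `lowFreqApprox = TRUE` the in-band EEG approximation is used and the
#' (real) interface resistance `Re(f)` alone is returned, plus `Rm`.
#'
#' @param m an [ElectrodeModel-class].
#' @param f frequency (Hz), > 0.
#' @param lowFreqApprox return the resistive approximation instead of the
#'   parallel RC combination.
#' @param extrapolate allow constant extension outside the tabulated range.
#' @return Complex impedance (ohm); real-valued under `lowFreqApprox`.
#' @export
modelImpedanceAt <- function(m, f, lowFreqApprox = FALSE,
                             extrapolate = FALSE) {
  stopifnot(is(m, "ElectrodeModel"))
  if (f <= 0) stop("f must be > 0")
  re <- interpLogF(m@freqTable, m@ReTable, f, extrapolate)
  if (lowFreqApprox) return(m@Rm + re)
  ce <- interpLogF(m@freqTable, m@CeTable, f, extrapolate)
  zc <- 1 / (1i * 2 * pi * f * ce)
  m@Rm + (re * zc) / (re + zc)
}

#' Summarise replicate sweeps at one frequency
#'
#' Interpolates `|Z|` and `Re` at `atF` in every replicate sweep, then
#' reports mean and two-sided 95% Student-t confidence half-width (n - 1 df)
#' per electrode/location group.
#'
#' @param sweeps list of [ImpedanceSweep-class] replicates.
#' @param atF evaluation frequency (Hz), inside every sweep's range.
#' @return data.frame with columns electrode, location, n, z_mean_ohm,
#'   z_ci_ohm, re_mean_ohm, re_ci_ohm.
#' @export
summarizeSweeps <- function(sweeps, atF = 31) {
  if (length(sweeps) < 2L) stop("need at least 2 replicate sweeps")
  per <- lapply(sweeps, function(s) {
    lo <- min(s@frequencies); hi <- max(s@frequencies)
    if (atF < lo || atF > hi)
      stop(sprintf("atF = %g Hz outside sweep range [%g, %g] Hz",
                   atF, lo, hi))
    re <- interpLogF(s@frequencies, s@resistance, atF)
    x <- interpLogF(s@frequencies, s@reactance, atF)
    data.frame(
      electrode = s@electrodeLabel, location = s@location,
      z = impedanceMagnitude(re, x), re = re, stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, per)
  out <- lapply(split(df, list(df$electrode, df$location), drop = TRUE),
    function(g) {
      if (nrow(g) < 2L)
        stop(sprintf("group %s/%s has fewer than 2 replicates",
                     g$electrode[1], g$location[1]))
      zi <- meanCi95(g$z); ri <- meanCi95(g$re)
      data.frame(
        electrode = g$electrode[1], location = g$location[1], n = nrow(g),
        z_mean_ohm = zi[["mean"]], z_ci_ohm = zi[["ci"]],
        re_mean_ohm = ri[["mean"]], re_ci_ohm = ri[["ci"]],
        stringsAsFactors = FALSE
      )
    })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Published 31 Hz means (kOhm): |Z| and Re per electrode/location.
.PRESET31 <- data.frame(
  key = c("wet_frontal", "wet_occipital", "gtec_frontal", "gtec_occipital",
          "micro_frontal", "micro_occipital"),
  electrode = rep(c("wet", "gtec", "micro"), each = 2),
  location = rep(c("frontal", "occipital"), 3),
  z_kohm = c(8.2, 19.9, 226.5, 77.9, 36.7, 214.9),
  re_kohm = c(8.1, 17.6, 198.2, 70.7, 24.0, 135.8),
  stringsAsFactors = FALSE
)

#' Published single-frequency electrode presets
#'
#' Six skin-electrode models (wet, dry pin, dry microneedle; frontal and
#' occipital) tabulated at the 31 Hz impedance-check frequency. The
#' resistance is the published 31 Hz mean; the capacitance is recovered from
#' the published impedance magnitude via `|X| = sqrt(|Z|^2 - Re^2)` and
#' [capacitanceFromReactance()]. `Rm` and `Ehc` default to 0.
#'
#' @return Named list of six [ElectrodeModel-class] objects with keys
#'   `wet_frontal`, `wet_occipital`, `gtec_frontal`, `gtec_occipital`,
#'   `micro_frontal`, `micro_occipital`.
#' @examples
#' presetModels()$gtec_frontal
#' @export
presetModels <- function() {
  out <- lapply(seq_len(nrow(.PRESET31)), function(i) {
    row <- .PRESET31[i, ]
    re <- row$re_kohm * 1e3
    z <- row$z_kohm * 1e3
    xAbs <- sqrt(z^2 - re^2)
    electrodeModel(
      freqTable = 31, ReTable = re,
      CeTable = capacitanceFromReactance(31, -xAbs),
      Rm = 0, Ehc = 0, label = row$electrode, location = row$location
    )
  })
  names(out) <- .PRESET31$key
  out
}

#' Fetch one preset model
#'
#' @param electrode `"wet"`, `"gtec"` or `"micro"`.
#' @param location `"frontal"` or `"occipital"`.
#' @return An [ElectrodeModel-class].
#' @export
electrodePreset <- function(electrode = c("wet", "gtec", "micro"),
                            location = c("frontal", "occipital")) {
  electrode <- match.arg(electrode)
  location <- match.arg(location)
  presetModels()[[paste(electrode, location, sep = "_")]]
}

#' Read impedance sweeps from CSV
#'
#' Expected columns: `frequency_hz`, `resistance_ohm`, `reactance_ohm`,
#' `electrode`, `location`, `replicate`. Rows are grouped into one sweep per
#' (electrode, location, replicate).
#'
#' @param path CSV file path.
#' @return List of [ImpedanceSweep-class] objects.
#' @export
readSweeps <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frequency_hz", "resistance_ohm", "reactance_ohm",
            "electrode", "location", "replicate")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("sweep CSV is missing columns: ", paste(missing, collapse = ", "))
  if (!nrow(df)) stop("sweep CSV contains no data rows")
  groups <- split(df, list(df$electrode, df$location, df$replicate),
                  drop = TRUE)
  out <- lapply(groups, function(g) {
    g <- g[order(g$frequency_hz), ]
    impedanceSweep(
      frequencies = g$frequency_hz, resistance = g$resistance_ohm,
      reactance = g$reactance_ohm, electrodeLabel = g$electrode[1],
      location = g$location[1], replicateId = as.integer(g$replicate[1])
    )
  })
  unname(out)
}

#' Write impedance sweeps to CSV
#'
#' @param sweeps list of [ImpedanceSweep-class] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSweeps <- function(sweeps, path) {
  rows <- lapply(sweeps, function(s) {
    data.frame(
      frequency_hz = s@frequencies, resistance_ohm = s@resistance,
      reactance_ohm = s@reactance, electrode = s@electrodeLabel,
      location = s@location, replicate = s@replicateId,
      stringsAsFactors = FALSE
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

modelToList <- function(m) {
  list(
    label = m@label, location = m@location, Rm = m@Rm, Ehc = m@Ehc,
    rmEstimate = if (is.na(m@rmEstimate)) NULL else m@rmEstimate,
    frequency_hz = m@freqTable, re_ohm = m@ReTable, ce_f = m@CeTable
  )
}

#' Write electrode models to JSON
#'
#' @param models a single [ElectrodeModel-class] or a (possibly named) list
#'   of them.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeElectrodeModels <- function(models, path) {
  if (is(models, "ElectrodeModel")) models <- list(models)
  jsonlite::write_json(lapply(models, modelToList), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read electrode models from JSON written by [writeElectrodeModels()]
#'
#' @param path JSON file path.
#' @return Named list of [ElectrodeModel-class] objects.
#' @export
readElectrodeModels <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(m) {
    electrodeModel(
      freqTable = unlist(m$frequency_hz), ReTable = unlist(m$re_ohm),
      CeTable = unlist(m$ce_f), Rm = unlist(m$Rm) %||% 0,
      Ehc = unlist(m$Ehc) %||% 0,
      rmEstimate = unlist(m$rmEstimate) %||% NA_real_,
      label = unlist(m$label) %||% "",
      location = unlist(m$location) %||% "frontal"
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
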