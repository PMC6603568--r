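#' @include AllClasses.R
NULL

rmsValue <- function(x) sqrt(mean(x^2))

#' Rescale a signal onto a reference signal's mean and scale
#'
#' Z-score normalisation followed by re-expression on the reference scale:
#' `((y - mean(y)) / sd(y)) * sd(x) + mean(x)`. Any positive affine
#' transform of the reference maps back to the reference exactly, which is
#' what lets the bench compare recordings regardless of channel gain.
#'
#' @param y numeric series to rescale.
#' @param xRef numeric reference series of the same length.
#' @return Numeric series on the reference's mean/scale.
#' @examples
#' zscoreRescale(c(1, 2, 3), c(10, 20, 30))
#' @export
zscoreRescale <- function(y, xRef) {
  if (length(y) != length(xRef))
    stop("y and xRef must have the same length")
  sy <- stats::sd(y)
  if (!is.finite(sy) || sy == 0)
    stop("degenerate signal: y has zero standard deviation")
  (y - mean(y)) / sy * stats::sd(xRef) + mean(xRef)
}

#' Pearson correlation coefficient
#'
#' Computed from the definitional sum of standardised products with the
#' 1/(N-1) sample convention:
#' `r = sum(((x - mx)/sx) * ((y - my)/sy)) / (N - 1)`.
#'
#' @param x,y numeric series of equal length >= 2.
#' @return Correlation in `[-1, 1]`.
#' @export
pearsonR <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 2L) stop("x and y must have equal length >= 2")
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) stop("zero-variance input")
  r <- sum(((x - mean(x)) / sx) * ((y - mean(y)) / sy)) / (n - 1)
  min(1, max(-1, r))
}

#' RMS signal-to-noise ratio in dB
#'
#' `20 * log10(rms(xRef) / rms(xRef - y))` where `y` should already be
#' aligned to the reference (see [zscoreRescale()]). A residual of exactly
#' zero returns the cap (default 200 dB) rather than infinity.
#'
#' @param xRef reference series.
#' @param y received series, same length.
#' @param capDb ceiling returned for a zero residual.
#' @return SNR in dB.
#' @examples
#' x <- sin(seq(0, 10, by = 0.01))
#' snrDb(x, x)            # zero residual: capped
#' snrDb(x, 1.1 * x)      # residual is a tenth of the reference: 20 dB
#' @export
snrDb <- function(xRef, y, capDb = 200) {
  if (length(xRef) == 0L) stop("zero-length input")
  if (length(xRef) != length(y)) stop("xRef and y must have equal length")
  resid <- rmsValue(xRef - y)
  if (resid == 0) return(capDb)
  min(capDb, 20 * log10(rmsValue(xRef) / resid))
}

#' Single-sided amplitude at the power-line FFT bin
#'
#' Rectangular-window FFT of the full epoch; returns `2 * |X[k]| / N` at the
#' bin nearest `f0`. With a 30 s epoch at 250 Hz the bin spacing is 1/30 Hz
#' and 50 Hz falls exactly on bin 1500, so an on-bin sinusoid is read out at
#' its exact amplitude.
#'
#' @param epoch an [EEGEpoch-class].
#' @param f0 target frequency (Hz), below Nyquist.
#' @return Amplitude in the epoch's units (volts).
#' @export
powerlineAmplitude <- function(epoch, f0 = 50) {
  fs <- samplingRate(epoch)
  if (f0 >= fs / 2) stop("f0 must be below the Nyquist frequency")
  x <- samples(epoch)
  n <- length(x)
  kExact <- f0 * n / fs
  k <- round(kExact)
  if (abs(kExact - k) > 1e-9)
    warning(sprintf(
      "epoch duration is not an integer number of 1/%g s periods; using nearest bin",
      f0))
  2 * Mod(stats::fft(x)[k + 1L]) / n
}

# FIR designs are cached per (fs, band, type) because the long low-cut-on
# band-pass is the expensive design in a 9-stage x 15-epoch run.
.firCache <- new.env(parent = emptyenv())

# Blackman-windowed design: ~74 dB stopband and a passband deviation small
# enough (~2e-4) that the forward-backward pass does not itself become the
# SNR floor of a clean channel.
firCoefs <- function(fs, w, type, transitionHz) {
  key <- paste(fs, paste(w, collapse = "-"), type, sep = "|")
  if (!is.null(.firCache[[key]])) return(.firCache[[key]])
  ntaps <- ceiling(5.5 * fs / transitionHz)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1L  # odd length: type-I linear phase
  b <- signal::fir1(ntaps - 1L, w / (fs / 2), type = type,
                    window = signal::blackman(ntaps))
  .firCache[[key]] <- b
  b
}

# Zero-phase (forward-backward) application of a linear-phase FIR. The
# "circular" method applies the filter's squared magnitude by circular
# convolution: for the bench's epochs, which are synthesised on exact FFT
# bins and therefore periodic over their own length, this is transient-free.
# "reflect" is the conventional odd-reflection-padded filtfilt for imported
# recordings that do not wrap; its edge error is confined to about one
# filter length at each end.
applyFir <- function(epoch, b, method = c("circular", "reflect")) {
  method <- match.arg(method)
  x <- samples(epoch)
  n <- length(x)
  if (n <= length(b))
    stop("epoch too short for the requested filter order")
  if (method == "circular") {
    h <- stats::fft(c(b, numeric(n - length(b))))
    y <- Re(stats::fft(stats::fft(x) * Mod(h)^2, inverse = TRUE)) / n
  } else {
    np <- min(3L * length(b), n - 1L)
    pre <- 2 * x[1] - x[(np + 1):2]
    post <- 2 * x[n] - x[(n - 1):(n - np)]
    y <- signal::filtfilt(signal::Ma(b), c(pre, x, post))[(np + 1):(np + n)]
  }
  samples(epoch) <- y
  epoch
}

#' Zero-phase FIR band-pass filter
#'
#' Blackman-window linear-phase FIR applied forward-backward
#' (zero net phase; stopband attenuation and passband flatness are the
#' single-pass figures squared). The filter order scales with the lower
#' cut-on so that the transition band stays inside the cut-on frequency.
#'
#' @param epoch an [EEGEpoch-class].
#' @param low,high band edges (Hz), `0 < low < high < fs/2`.
#' @param method `"circular"` (transient-free for periodic/synthesised
#'   epochs) or `"reflect"` (odd-reflection padding for imported data).
#' @return The filtered epoch.
#' @export
bandpassFir <- function(epoch, low, high,
                        method = c("circular", "reflect")) {
  fs <- samplingRate(epoch)
  if (!(0 < low && low < high && high < fs / 2))
    stop("band must satisfy 0 < low < high < fs/2")
  b <- firCoefs(fs, c(low, high), "pass", transitionHz = low)
  applyFir(epoch, b, method)
}

#' Zero-phase FIR notch (band-stop) filter
#'
#' Removes a narrow band centred on `f0` (default width 4 Hz), the
#' power-line cleanup step of the bench. Same design family as
#' [bandpassFir()].
#'
#' @param epoch an [EEGEpoch-class].
#' @param f0 notch centre (Hz).
#' @param width full stop-band width (Hz).
#' @inheritParams bandpassFir
#' @return The filtered epoch.
#' @export
notchFir <- function(epoch, f0 = 50, width = 4,
                     method = c("circular", "reflect")) {
  fs <- samplingRate(epoch)
  if (!(0 < f0 - width / 2 && f0 + width / 2 < fs / 2))
    stop("notch band must lie inside (0, fs/2)")
  b <- firCoefs(fs, c(f0 - width / 2, f0 + width / 2), "stop",
                transitionHz = width / 2)
  applyFir(epoch, b, method)
}

meanCi95 <- function(v) {
  n <- length(v)
  m <- mean(v)
  if (n < 2L) return(c(mean = m, ci = NA_real_))
  hw <- stats::qt(0.975, df = n - 1L) * stats::sd(v) / sqrt(n)
  c(mean = m, ci = hw)
}

#' Score a bench run against its reference epochs
#'
#' For every stage and epoch the recording is aligned to its reference by
#' [zscoreRescale()], then five metrics are computed: Pearson correlation
#' and RMS SNR on the unfiltered signal, the same pair after a 50 Hz notch
#' ([notchFir()]), and the 50 Hz FFT-bin amplitude taken *before* filtering
#' (reported in microvolts, assuming volt-scale inputs). Each metric is
#' summarised as mean with a two-sided 95% Student-t confidence half-width
#' across epochs; with a single epoch the CI is `NA`.
#'
#' @param recordings named list (stage -> list of [EEGEpoch-class]) as
#'   produced by [runBench()].
#' @param reference list of reference epochs, one per epoch index (normally
#'   the microvolt-scaled source epochs).
#' @param notchHz notch centre for the filtered variants (Hz).
#' @return A [QualityReport-class].
#' @export
scoreBench <- function(recordings, reference, notchHz = 50) {
  if (!length(recordings)) stop("no recordings to score")
  nRef <- length(reference)
  rows <- lapply(names(recordings), function(stage) {
    recs <- recordings[[stage]]
    if (length(recs) != nRef)
      stop(sprintf("stage '%s' has %d epochs but reference has %d",
                   stage, length(recs), nRef))
    per <- vapply(seq_len(nRef), function(i) {
      x <- samples(reference[[i]])
      rec <- recs[[i]]
      if (nSamples(rec) != length(x))
        stop("recording/reference length mismatch")
      yAligned <- zscoreRescale(samples(rec), x)
      alignedEpoch <- rec
      samples(alignedEpoch) <- yAligned
      filt <- notchFir(alignedEpoch, f0 = notchHz)
      yFilt <- zscoreRescale(samples(filt), x)
      c(
        corrU = pearsonR(x, yAligned),
        corrF = pearsonR(x, yFilt),
        snrU = snrDb(x, yAligned),
        snrF = snrDb(x, yFilt),
        noise50 = powerlineAmplitude(alignedEpoch, notchHz) * 1e6
      )
    }, numeric(5))
    s <- apply(per, 1L, meanCi95)
    data.frame(
      stage = stage,
      correlation_unfiltered_mean = s["mean", "corrU"],
      correlation_unfiltered_ci = s["ci", "corrU"],
      correlation_filtered_mean = s["mean", "corrF"],
      correlation_filtered_ci = s["ci", "corrF"],
      snr_db_unfiltered_mean = s["mean", "snrU"],
      snr_db_unfiltered_ci = s["ci", "snrU"],
      snr_db_filtered_mean = s["mean", "snrF"],
      snr_db_filtered_ci = s["ci", "snrF"],
      noise_50hz_uv_mean = s["mean", "noise50"],
      noise_50hz_uv_ci = s["ci", "noise50"],
      stringsAsFactors = FALSE
    )
  })
  tbl <- do.call(rbind, rows)
  rownames(tbl) <- NULL
  new("QualityReport", table = tbl, nEpochs = as.integer(nRef))
}

#' Export a quality report
#'
#' @param report a [QualityReport-class].
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
writeQualityReport <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  tbl <- reportTable(report)
  if (format == "csv") {
    utils::write.csv(tbl, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(n_epochs = report@nEpochs, table = tbl),
      path, dataframe = "rows", auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  invisible(path)
}

#' Read a JSON quality report written by [writeQualityReport()]
#'
#' @param path JSON file path.
#' @return A [QualityReport-class].
#' @export
readQualityReport <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  tbl <- as.data.frame(obj$table, stringsAsFactors = FALSE)
  ciCols <- grep("_ci$", names(tbl))
  for (j in ciCols) tbl[[j]] <- as.numeric(tbl[[j]])
  new("QualityReport", table = tbl, nEpochs = as.integer(obj$n_epochs))
}
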