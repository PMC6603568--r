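#' @include AllClasses.R quality-metrics.R
NULL

# Per-epoch seeds are derived from the master seed by counter so that any
# epoch can be regenerated independently. Kept below 2^31 - 1.
deriveSeed <- function(masterSeed, counter) {
  as.integer((as.numeric(masterSeed) * 7919 + 101 * as.numeric(counter)) %%
               2147483647)
}

# Synthesise a band-limited real signal directly in the frequency domain:
# amplitudes per rFFT bin with uniform random phases, hermitian assembly,
# inverse FFT. Band limiting is exact (bins outside the band are zero).
spectralSynth <- function(n, fs, binAmp) {
  nBins <- floor(n / 2)
  phases <- stats::runif(nBins, 0, 2 * pi)
  spec <- complex(real = rep(0, n))
  spec[2:(nBins + 1)] <- binAmp * exp(1i * phases)
  # mirror for a real signal; bin n/2+1 (Nyquist, even n) must be real
  if (n %% 2 == 0) spec[nBins + 1] <- Mod(spec[nBins + 1])
  spec[seq(n, by = -1, length.out = nBins)] <- Conj(spec[2:(nBins + 1)])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

#' Generate synthetic neonatal-EEG-like epochs
#'
#' Each epoch is a band-limited random process synthesised in the frequency
#' domain: a 1/f ("pink") amplitude profile by default, confined exactly to
#' `params@band`, with a 45--55 Hz gap zeroed to emulate the 50 Hz notch
#' applied to the source recordings before playback. A configurable fraction
#' of epochs ("non-healthy") additionally carries a rhythmic 0.5--3 Hz
#' discharge: a slow fundamental with decaying harmonics under a smooth
#' amplitude envelope, the spectral signature of neonatal seizure activity.
#' Every epoch is peak-normalised to `params@amplitudeV` exactly. Output is
#' a pure function of `params` (including its seed).
#'
#' @param params a [GeneratorParams-class].
#' @return List of `params@nEpochs` [EEGEpoch-class] objects labelled
#'   `"database"`. The first `round(seizureFraction * nEpochs)` epochs carry
#'   the discharge component (flagged in `meta$seizure`).
#' @examples
#' ep <- generateEpochs(generatorParams(nEpochs = 2, durationS = 4, seed = 3))
#' peakAmplitude(ep[[1]])
#' @export
generateEpochs <- function(params) {
  stopifnot(is(params, "GeneratorParams"))
  validObject(params)
  n <- round(params@durationS * params@fs)
  nBins <- floor(n / 2)
  f <- (1:nBins) / params@durationS
  inBand <- f >= params@band[1] & f <= params@band[2]
  if (length(params@notchGap) == 2L && all(is.finite(params@notchGap)))
    inBand <- inBand & !(f >= params@notchGap[1] & f <= params@notchGap[2])
  profile <- switch(params@spectralProfile,
    pink = 1 / sqrt(f),
    white = rep(1, nBins),
    mixed = 1 / sqrt(f) +
      2 * exp(-((f - 1)^2) / 0.5) + 1 * exp(-((f - 8)^2) / 2)
  )
  profile[!inBand] <- 0
  nSeiz <- round(params@seizureFraction * params@nEpochs)
  lapply(seq_len(params@nEpochs), function(i) {
    epSeed <- deriveSeed(params@seed, i)
    set.seed(epSeed)
    x <- spectralSynth(n, params@fs, profile)
    isSeiz <- i <= nSeiz
    if (isSeiz) {
      # rhythmic discharge: on-bin fundamental in [0.8, 2.5] Hz + harmonics,
      # raised-cosine envelope, ~2x the background RMS
      f0 <- round(stats::runif(1, 0.8, 2.5) * params@durationS) /
        params@durationS
      t <- (0:(n - 1)) / params@fs
      burst <- 0
      for (h in 1:3) {
        hf <- h * f0
        if (hf >= params@band[1] && hf <= params@band[2])
          burst <- burst +
            (1 / h) * sin(2 * pi * hf * t + stats::runif(1, 0, 2 * pi))
      }
      env <- 0.5 * (1 - cos(2 * pi * t / params@durationS))
      burst <- burst * env
      x <- x + burst * 2 * stats::sd(x) / stats::sd(burst)
    }
    x <- x / max(abs(x)) * params@amplitudeV
    if (params@powerlineAmpV > 0) {
      t <- (0:(n - 1)) / params@fs
      x <- x + params@powerlineAmpV * sin(2 * pi * 50 * t)
    }
    EEGEpoch(x, fs = params@fs, label = "database", epochIndex = i,
             seed = epSeed, meta = list(seizure = isSeiz))
  })
}

#' Preprocess an arbitrary epoch into database form
#'
#' Emulates the preprocessing applied to the source recordings: resample to
#' `targetFs` (250 Hz), band-pass 0.5--100 Hz, notch at `notchHz`, and scale
#' *down* to at most `amplitudeV` peak. Epochs already below the peak target
#' are not scaled up, so out-of-band content genuinely disappears instead of
#' being renormalised back.
#'
#' @param e an [EEGEpoch-class] with `fs >= 2 * notchHz`.
#' @param notchHz notch frequency (Hz), below Nyquist.
#' @param targetFs output sampling rate (Hz).
#' @param band output passband (Hz).
#' @param amplitudeV peak ceiling (V).
#' @return The preprocessed [EEGEpoch-class] at `targetFs`.
#' @export
preprocessDatabaseEpoch <- function(e, notchHz = 50, targetFs = 250,
                                    band = c(0.5, 100), amplitudeV = 0.5) {
  stopifnot(is(e, "EEGEpoch"))
  if (samplingRate(e) < 2 * notchHz)
    stop("notchHz must be below the epoch's Nyquist frequency")
  if (samplingRate(e) != targetFs) {
    y <- signal::resample(samples(e), p = targetFs, q = samplingRate(e))
    e <- EEGEpoch(y, fs = targetFs, label = epochLabel(e),
                  epochIndex = e@epochIndex, seed = e@seed, meta = e@meta)
  }
  e <- bandpassFir(e, band[1], band[2])
  e <- notchFir(e, f0 = notchHz)
  pk <- peakAmplitude(e)
  if (pk > amplitudeV) samples(e) <- samples(e) * (amplitudeV / pk)
  e
}

#' Scale an epoch through the voltage divider
#'
#' Divides every sample by `dividerRatio`; the default 5000 maps the
#' +/-0.5 V playback range to the +/-100 uV scalp-EEG range.
#'
#' @param e an [EEGEpoch-class].
#' @param dividerRatio divider ratio, > 1.
#' @return The scaled epoch, labelled `"<label>/scaled"`.
#' @export
scaleToMicrovolt <- function(e, dividerRatio = 5000) {
  stopifnot(is(e, "EEGEpoch"))
  if (dividerRatio <= 1) stop("dividerRatio must be > 1")
  EEGEpoch(samples(e) / dividerRatio, fs = samplingRate(e),
           label = paste0(epochLabel(e), "/scaled"),
           epochIndex = e@epochIndex, seed = e@seed, meta = e@meta)
}

#' Record the conductive-cloth series resistance on an epoch
#'
#' The cloth strip contributes a small series source resistance to every
#' downstream electrode; the samples themselves are untouched and the
#' resistance is carried in `meta$clothResistanceOhm` for the chain model.
#'
#' @param e an [EEGEpoch-class].
#' @param seriesResistanceOhm cloth series resistance (ohm), >= 0.
#' @return The epoch with cloth metadata set.
#' @export
clothStage <- function(e, seriesResistanceOhm = 2) {
  stopifnot(is(e, "EEGEpoch"))
  if (seriesResistanceOhm < 0) stop("seriesResistanceOhm must be >= 0")
  e@meta$clothResistanceOhm <- seriesResistanceOhm
  e
}

# ---------------------------------------------------------------------------
# Signal I/O: CSV (time_s + one column per channel label) and 16-bit EDF.

#' Write epochs to CSV or EDF
#'
#' CSV layout: a `time_s` column followed by one column per epoch, headed by
#' `<label>#<epochIndex>`. EDF stores each epoch as one 16-bit signal with
#' physical min/max set to its peak range (so roundtrip error is at most one
#' quantization step of that range). Both formats require all epochs to
#' share sampling rate and length.
#'
#' @param epochs list of [EEGEpoch-class] objects.
#' @param path output file path.
#' @param format `"csv"` or `"edf"`.
#' @return `path`, invisibly.
#' @export
writeSignals <- function(epochs, path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (!length(epochs)) stop("no epochs to write")
  fs <- unique(vapply(epochs, samplingRate, numeric(1)))
  ns <- unique(vapply(epochs, nSamples, numeric(1)))
  if (length(fs) != 1L || length(ns) != 1L)
    stop("all epochs must share sampling rate and length")
  if (format == "csv") {
    cols <- lapply(epochs, samples)
    names(cols) <- vapply(epochs, function(e)
      sprintf("%s#%d", epochLabel(e), e@epochIndex), character(1))
    df <- data.frame(time_s = (0:(ns - 1)) / fs, cols, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    writeEdf(epochs, path)
  }
  invisible(path)
}

#' Read epochs from CSV or EDF written by [writeSignals()]
#'
#' @param path input file path.
#' @param format `"csv"` or `"edf"`.
#' @return List of [EEGEpoch-class] objects.
#' @export
readSignals <- function(path, format = c("csv", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(readEdf(path))
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"time_s" %in% names(df) || ncol(df) < 2L)
    stop("malformed signal CSV: need a time_s column plus channel columns")
  dt <- diff(df$time_s)
  if (any(abs(dt - dt[1]) > 1e-9 * abs(dt[1])) || dt[1] <= 0)
    stop("malformed signal CSV: time_s is not uniformly sampled")
  fs <- 1 / dt[1]
  chans <- setdiff(names(df), "time_s")
  lapply(seq_along(chans), function(j) {
    nm <- chans[j]
    parts <- strsplit(nm, "#", fixed = TRUE)[[1]]
    idx <- suppressWarnings(as.integer(parts[length(parts)]))
    lab <- if (!is.na(idx) && length(parts) > 1L)
      paste(parts[-length(parts)], collapse = "#") else nm
    EEGEpoch(df[[nm]], fs = fs, label = lab,
             epochIndex = if (is.na(idx)) j else idx)
  })
}

padAscii <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = width, flag = "-")
}

edfNum <- function(x) {
  # 8-char ascii numeric field; parse-back of this string is what the codec
  # uses, so header rounding never breaks the digital<->physical mapping
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > 8) s <- formatC(x, format = "g", digits = 4)
  s
}

writeEdf <- function(epochs, path) {
  nSig <- length(epochs)
  fs <- samplingRate(epochs[[1]])
  ns <- nSamples(epochs[[1]])
  dur <- ns / fs
  physMaxS <- vapply(epochs, function(e) {
    pk <- max(peakAmplitude(e), 1e-12)
    edfNum(pk * 1.0001)  # headroom so the peak itself is representable
  }, character(1))
  physMax <- as.numeric(physMaxS)
  physMin <- -physMax
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(padAscii(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256L * (nSig + 1L)), 8); wr("", 44)
  wr("1", 8)                      # one data record holding the whole epoch
  wr(edfNum(dur), 8); wr(as.character(nSig), 4)
  labs <- vapply(epochs, function(e)
    sprintf("%s#%d", epochLabel(e), e@epochIndex), character(1))
  for (l in labs) wr(l, 16)
  for (i in seq_len(nSig)) wr("simulated", 80)
  for (i in seq_len(nSig)) wr("V", 8)
  for (i in seq_len(nSig)) wr(edfNum(physMin[i]), 8)
  for (i in seq_len(nSig)) wr(physMaxS[i], 8)
  for (i in seq_len(nSig)) wr("-32768", 8)
  for (i in seq_len(nSig)) wr("32767", 8)
  for (i in seq_len(nSig)) wr("", 80)
  for (i in seq_len(nSig)) wr(as.character(ns), 8)
  for (i in seq_len(nSig)) wr("", 32)
  for (i in seq_len(nSig)) {
    x <- samples(epochs[[i]])
    dig <- round((x - physMin[i]) / (physMax[i] - physMin[i]) * 65535 - 32768)
    dig <- pmin(32767, pmax(-32768, dig))
    writeBin(as.integer(dig), con, size = 2L, endian = "little")
  }
  invisible(path)
}

readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  ver <- rd(8)
  if (ver != "0") stop("malformed EDF: bad version field '", ver, "'")
  rd(80); rd(80); rd(8); rd(8)
  rd(8)  # header bytes
  rd(44)
  nRec <- as.integer(rd(8))
  durRec <- as.numeric(rd(8))
  nSig <- as.integer(rd(4))
  if (is.na(nRec) || is.na(durRec) || is.na(nSig))
    stop("malformed EDF header")
  labs <- vapply(seq_len(nSig), function(i) rd(16), character(1))
  for (i in seq_len(nSig)) rd(80)
  for (i in seq_len(nSig)) rd(8)
  physMin <- vapply(seq_len(nSig), function(i) as.numeric(rd(8)), numeric(1))
  physMax <- vapply(seq_len(nSig), function(i) as.numeric(rd(8)), numeric(1))
  digMin <- vapply(seq_len(nSig), function(i) as.numeric(rd(8)), numeric(1))
  digMax <- vapply(seq_len(nSig), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nSig)) rd(80)
  spr <- vapply(seq_len(nSig), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nSig)) rd(32)
  data <- lapply(seq_len(nSig), function(i) numeric(0))
  for (r in seq_len(nRec)) {
    for (i in seq_len(nSig)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) != spr[i]) stop("malformed EDF: truncated record ", r)
      phys <- physMin[i] +
        (dig - digMin[i]) * (physMax[i] - physMin[i]) / (digMax[i] - digMin[i])
      data[[i]] <- c(data[[i]], phys)
    }
  }
  lapply(seq_len(nSig), function(i) {
    parts <- strsplit(labs[i], "#", fixed = TRUE)[[1]]
    idx <- suppressWarnings(as.integer(parts[length(parts)]))
    lab <- if (!is.na(idx) && length(parts) > 1L)
      paste(parts[-length(parts)], collapse = "#") else labs[i]
    EEGEpoch(data[[i]], fs = spr[i] / durRec, label = lab,
             epochIndex = if (is.na(idx)) i else idx)
  })
}
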