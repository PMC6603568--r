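---
title: "Simulating an EEG acquisition bench: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating an EEG acquisition bench: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegbench)
```

## Why simulate the bench

Assessing EEG electrodes and low-cost acquisition boards on neonates is
ethically and practically constrained; a hardware playback bench (waveform
generator, voltage divider, conductive cloth, electrode impedance models,
acquisition board) sidesteps human participants but still needs the physical
instruments. `eegbench` reproduces that bench entirely in software: synthetic
neonatal-EEG-like epochs are pushed through skin-electrode equivalent-circuit
models and a non-ideal differential acquisition chain, and the received
signals are scored exactly as a bench operator would score them —
Pearson correlation and RMS SNR against the source signal, and the amplitude
of the 50 Hz power-line FFT bin — as means with 95% confidence intervals
across epochs.

The simulator's purpose is comparative: which electrode, at which site,
degrades the signal how much, and how much of that degradation a 50 Hz notch
repairs. Absolute SNR values depend on physical hardware (the waveform
generator's DAC, the ambient interference level, board firmware) that a
software bench cannot know; the package therefore treats orderings and
paired contrasts as its reproducible outputs, and absolute dB values as
configuration-dependent.

## The signal model

### Synthetic neonatal EEG

Real neonatal recordings behind the bench are not redistributable, so the
generator emulates their stated envelope: 30 s epochs at 250 Hz, peak
amplitude ±0.5 V (the playback range), band-limited 0.5–100 Hz. Each epoch is
synthesised directly in the frequency domain: per-FFT-bin amplitudes follow a
1/f ("pink") profile by default — neonatal background EEG is strongly
low-frequency dominant — with uniform random phases, then an inverse FFT.
Band limiting is exact because out-of-band bins are identically zero, which
the spectral-compliance tests exploit.

Two deliberate features:

* **A 45–55 Hz spectral gap.** The source recordings had a 50 Hz notch
  applied before playback; the generator zeroes 45–55 Hz so that the scoring
  notch (48–52 Hz stop band plus 2 Hz transitions) never removes genuine
  signal content. Without the gap, notch-filtering a recording necessarily
  costs reference-band energy and the "filtering helps" comparison becomes
  ambiguous.
* **Rhythmic discharges.** A configurable fraction of epochs
  (`seizureFraction`, default 0.25 so that a 15-epoch run holds roughly four
  "non-healthy" epochs — the balance in the original epoch selection is not
  documented, so the fraction is exposed rather than fixed) carries a
  0.5–3 Hz discharge: an on-bin fundamental drawn from 0.8–2.5 Hz with three
  decaying harmonics under a raised-cosine envelope, scaled to twice the
  background RMS. This emulates neonatal seizure rhythms at the level of
  band power, which is all the bench's metrics are sensitive to; no attempt
  is made to mimic individual patients' morphology.

Each epoch is peak-normalised to `amplitudeV` exactly (the stated ±0.5 V is
a peak range, so peak rather than RMS scaling is used). Generation is a pure
function of the parameter object: per-epoch seeds are derived from the
master seed by counter, so any epoch can be regenerated independently and
two runs with equal parameters are bitwise identical.

### Skin-electrode interface

The interface is the classic equivalent circuit: a half-cell potential
`Ehc` (DC), the electrode material resistance `Rm`, and a parallel RC block
(`Re`, `Ce`) for the skin-electrode junction. Because the interface is
dispersive, `Re` and `Ce` are stored as tables against frequency and
interpolated log-linearly; the package never forces a single-pole fit. Sweep
fitting is per-point: `Re` is the measured series resistance itself and
`Ce = 1/(2πf|X|)` from the measured reactance. The high-frequency resistance
asymptote (mean over the top decile of sweep frequencies) is recorded as a
diagnostic `rmEstimate`, but the circuit `Rm` slot stays 0 for fitted
models: the measured series resistance already contains the material
resistance, and adding the asymptote again would double-count it.

Six presets tabulate published 31 Hz means (the in-band impedance-check
frequency) for wet, dry-pin and dry-microneedle electrodes at frontal and
occipital sites; the preset capacitance is recovered from
`|X| = sqrt(|Z|² − Re²)` so that the series recombination reproduces the
published impedance magnitudes to their printed rounding. For in-band EEG
(< 50 Hz) the resistive approximation `Z ≈ Re` is available as a flag and is
what the acquisition chain uses.

### Acquisition chain

Four stages compose `simulateChannel()`:

1. **Input loading.** The differential voltage at the amplifier inputs is
   `((v1−v2)/2)(2−(z1+z2)/zin) + ((v1+v2)/2)((z1−z2)/zin)`. The first term
   attenuates the differential gain by `(z1+z2)/(2 zin)`; the second
   converts common-mode content into a differential error proportional to
   the impedance mismatch. Impedances are evaluated at 31 Hz (resistive
   in-band approximation); a per-frequency spectral mode was considered and
   rejected because the interface model the bench uses is itself the
   in-band approximation, and a one-point table cannot support a
   frequency-resolved convolution.
2. **Interference.** A common-mode 50 Hz sinusoid of amplitude `cmAmpV`
   reaches the output with amplitude
   `cmAmpV · (|z1−z2|/zin + 10^(−CMRR/20))`. The ambient common-mode level
   is not a published quantity; the default 10 mV was chosen once so that
   the wet-frontal preset's converted noise lands in the sub-microvolt
   range typical of a well-behaved bench, and it is documented as a
   calibration knob — orderings across electrodes are independent of it.
3. **Amplifier noise.** Zero-mean Gaussian with `6.6σ` equal to the
   peak-to-peak rating (99.9% coverage convention), seed-deterministic.
4. **ADC.** Mid-tread uniform quantization over ±`fullScaleV` (default
   ±0.187 V, a 24-bit front end at a typical gain; configurable), clipping
   with a warning, with resampling when the epoch rate differs from the
   ADC rate. The playback-range stage is recorded through a widened full
   scale, standing in for the bench oscilloscope that records the
   generator output in hardware.

The nine default stages mirror the hardware bench: generator output,
resistor-divider output (±0.5 V mapped to ±100 µV by the 1:5000 divider that
the two stated amplitudes imply), conductive cloth (a ≤ 2 Ω/square silver
cloth modelled as a worst-case 2 Ω series source resistance recorded in
epoch metadata), and the six electrode presets against a 5 kΩ wet reference
path. The reference-path impedance is not published; 5 kΩ makes the
mismatch scale with electrode resistance, which is the mechanism the bench
exists to demonstrate.

## Scoring

Each recording is aligned to its reference by z-score rescaling
(`(y−μy)/σy · σx + μx`), which undoes any positive affine gain — exactly
what differs between recording chains. Correlation uses the 1/(N−1) sample
convention; SNR is `20·log10(rms(x)/rms(x−y))` with a 200 dB cap for a zero
residual (a per-sample ratio reading of the same formula is undefined at
zero crossings and yields no finite summary). The 50 Hz noise is the
single-sided rectangular-window FFT-bin amplitude, taken **before**
filtering, reported in µV; with 30 s epochs at 250 Hz the 50 Hz bin is
exact (bin width 1/30 Hz). "Filtered" variants re-score after a 50 Hz
notch only, mirroring the simulation protocol's published table; the
1–100 Hz band-pass belongs to the separate in-vivo protocol and is provided
as `bandpassFir()` for imported recordings. Summaries are means with
two-sided 95% Student-t intervals on n−1 degrees of freedom (the CI method
is not named in the source material; t is the standard small-n choice, and
replicate counts here are 5–15). Single-epoch summaries flag the CI as
unavailable rather than fabricating one.

### Filtering

Filters are linear-phase FIR (Blackman window), applied forward-backward so
the net phase is zero — phase distortion would corrupt the correlation
metric. The Blackman design was chosen over shorter windows because the
*passband deviation* of the squared response, not the stopband, is what
limits the filtered SNR of a clean channel; Blackman keeps that floor near
−70 dB, well below the amplifier-noise-limited SNRs the bench produces.
Orders scale with the transition width (5.5·fs/transition): ≈ 690 taps for
the 4 Hz-wide notch at 250 Hz.

Zero-phase application offers two methods. `"circular"` (the default)
applies the squared magnitude by circular convolution, which is
transient-free for the bench's own epochs — they are synthesised on exact
FFT bins and therefore periodic over their length. `"reflect"` is the
conventional odd-reflection-padded filtfilt for imported recordings that do
not wrap; its residual edge error is confined to about one filter length at
each end and sits near −50 dB relative, which is why it is not the default
for simulator-generated data.

## What the defaults pin down

| Parameter | Default | Unit | Why |
|---|---|---|---|
| epochs × duration × rate | 15 × 30 s × 250 Hz | — | the bench's stated epoch design |
| band / amplitude | 0.5–100 Hz / ±0.5 V peak | — | stated preprocessing envelope |
| spectral gap | 45–55 | Hz | emulated database notch incl. transitions |
| seizureFraction | 0.25 | — | balance unstated; exposed, ~4/15 epochs |
| divider ratio | 5000 | — | ±0.5 V → ±100 µV, the two stated amplitudes |
| cloth resistance | 2 | Ω | worst case of the stated ≤ 2 Ω/square |
| amplifier | 1 GΩ, 120 dB, 1 µVpp, 24 bit, 250 Hz | — | the low-cost board's published spec |
| ADC full scale | ±0.187 | V | 24-bit front end at typical gain; configurable |
| common-mode 50 Hz | 10 | mV | calibration knob, sub-µV wet-channel noise |
| reference path | 5 | kΩ | unpublished; wet-grade reference wiring |
| notch | 48–52 stop, 2 Hz transitions | Hz | ≥ 40 dB depth, ≤ 0.5 dB ripple met with margin |

## Numerical and degenerate-input choices

* Peak normalisation is exact (division by the sample maximum), so the
  amplitude contract holds to machine precision.
* `zscoreRescale` refuses zero-variance inputs rather than returning NaN;
  `snrDb` returns its cap for a zero residual; `powerlineAmplitude` warns
  and uses the nearest bin for off-bin targets.
* Positive (inductive) sweep reactance warns and proceeds on |X|: the
  interface model is capacitive and an isolated inductive reading is
  treated as a measurement artefact, not a model change.
* Frequencies outside a model's tabulated range error unless constant
  extrapolation is requested explicitly; single-point (preset) tables only
  evaluate at their own frequency without that flag.
* Seeds: one master seed; per-(stage, epoch) seeds derived by counter and
  kept below 2³¹−1. Reruns are byte-identical including written reports.

## What the tests do and do not show

The suite verifies the bench's *mechanisms* on synthetic data: loading-law
worked examples to printed precision, preset recombination within printed
rounding, exact parameter recovery from noiseless sweeps and 2% medians
under 1% noise, metric equivalence against brute-force definitional oracles
at 1e-12, and the ordering properties of a full 15-epoch, 9-stage run —
50 Hz noise ranked exactly by impedance mismatch, notch gains positive for
every electrode stage and increasing with mismatch, SNR monotone in source
impedance under paired seeds. The default problem size throughout (15 × 30 s
× 250 Hz, nine stages) is the bench's own design and runs in seconds.

Passing these tests does not certify behaviour on real recordings: the
generator has no motion or electrode-pop artefacts, no half-cell drift
beyond an optional DC term, no multi-channel spatial structure, stationary
interference of known frequency, and adult-derived impedance presets that
overstate neonatal impedances (a conservative direction for the
comparisons the bench makes). Absolute SNR/correlation levels from the
simulator reflect the configured noise and interference, not any physical
board's measured performance.

## Known limitations

* The one-point presets cannot drive a frequency-resolved loading model;
  full sweeps fitted with `fitSweep()` can, but the chain still applies the
  in-band resistive approximation by design.
* EDF output is 16-bit integer-scaled per signal; roundtrip error is
  bounded by one quantization step of each epoch's peak range.
* The CLI is a thin wrapper (`inst/cli/bench.R`) over the exported
  functions; it validates configs by construction rather than by schema.
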