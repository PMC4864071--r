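# DTW-spectrum: sweep a bank of standardized sinusoidal templates across a
# frequency band and record, per frequency, the banded DTW dissimilarity of
# the (standardized) pre-trial segment against that template. Low values mean
# close match, so the curve is roughly a vertical mirror of a power spectrum.
# A matched direct-DFT spectrum on the same grid makes the two comparable
# bin by bin. Each spectrum is condensed to its standard deviation for the
# trial-wise GLMs.

#' Build a bank of standardized oscillatory templates
#'
#' Generates progressively higher-frequency waveforms on a linear grid from
#' `fLo` to `fHi` (inclusive when reachable by `step`), each standardized to
#' zero mean and unit sample variance. Sine templates have phase 0 at the
#' first sample; warping is what absorbs phase offsets in the data.
#'
#' @param fLo,fHi band edges in Hz (`0 < fLo <= fHi < rate/2`).
#' @param step frequency step in Hz (default 0.1).
#' @param nSamples template length in samples (e.g. 50 for a 1 s pre-trial
#'   window at 50 Hz).
#' @param rate sampling rate in Hz.
#' @param shape `"sine"` (default) or `"sawtooth"`.
#' @return a [TemplateBank-class].
#' @examples
#' makeTemplates(8, 13, 0.5, nSamples = 50, rate = 50)
#' @export
makeTemplates <- function(fLo = 8, fHi = 13, step = 0.1, nSamples, rate,
                          shape = c("sine", "sawtooth")) {
  shape <- match.arg(shape)
  if (step <= 0) stop("step must be positive")
  if (fLo <= 0 || fLo > fHi) stop("need 0 < fLo <= fHi")
  if (fHi >= rate / 2)
    stop("fHi = ", fHi, " Hz reaches the Nyquist frequency (", rate / 2, " Hz)")
  if (nSamples < 2L) stop("templates need at least 2 samples")
  k <- floor((fHi - fLo) / step + 1e-9)
  freqs <- fLo + step * (0:k)
  t <- (0:(nSamples - 1L)) / rate
  wave <- function(f) {
    if (shape == "sine") sin(2 * pi * f * t)
    else 2 * ((f * t) %% 1) - 1  # rising sawtooth in [-1, 1), period 1/f
  }
  tpl <- t(vapply(freqs, function(f) .zstd(wave(f)), numeric(nSamples)))
  new("TemplateBank", shape = shape, frequencies = freqs,
      templates = tpl, rate = as.numeric(rate))
}

#' DTW-spectrum of one segment against a template bank
#'
#' For every template frequency, the banded DTW distance between the
#' standardized segment and the standardized template. Standardization makes
#' the dissimilarity amplitude-invariant so that frequency content, not
#' power, drives the minimum; pass `standardize = FALSE` to compare raw
#' amplitudes instead.
#'
#' @param segment numeric pre-trial segment, same length as the templates.
#' @param bank a [TemplateBank-class].
#' @param window Sakoe-Chiba band half-width (default 20).
#' @param cost local cost for the DTW ("abs" or "squared").
#' @param standardize z-standardize the segment first (default `TRUE`).
#' @return a [SpectrumResult-class] of kind `"dtw"`.
#' @export
dtwSpectrum <- function(segment, bank, window = 20L, cost = c("abs", "squared"),
                        standardize = TRUE) {
  cost <- match.arg(cost)
  stopifnot(is(bank, "TemplateBank"))
  if (length(segment) != nSamples(bank))
    stop("segment length ", length(segment), " does not match template length ",
         nSamples(bank))
  if (stats::sd(segment) == 0)
    stop("degenerate input: segment has zero variance")
  seg <- if (standardize) .zstd(segment) else as.numeric(segment)
  vals <- dtw_sweep(seg, templateMatrix(bank), as.integer(window),
                    cost == "squared")
  new("SpectrumResult", kind = "dtw", frequencies = frequencies(bank),
      values = as.numeric(vals))
}

#' Direct DFT power spectrum on an arbitrary frequency grid
#'
#' Squared magnitude of the discrete Fourier projection of the mean-removed
#' segment onto each grid frequency, evaluated by direct summation so the
#' grid can match a DTW template bank bin for bin (no padding, no FFT grid).
#'
#' @param segment numeric segment (length >= 2).
#' @param rate sampling rate in Hz.
#' @param freqs frequency grid in Hz, all below the Nyquist frequency.
#' @return a [SpectrumResult-class] of kind `"dft"`.
#' @export
dftSpectrum <- function(segment, rate, freqs) {
  if (length(segment) < 2L) stop("segment needs at least 2 samples")
  if (any(freqs >= rate / 2)) stop("grid reaches the Nyquist frequency")
  seg <- as.numeric(segment) - mean(segment)
  t <- (0:(length(seg) - 1L)) / rate
  vals <- vapply(freqs, function(f) {
    sum(seg * cos(2 * pi * f * t))^2 + sum(seg * sin(2 * pi * f * t))^2
  }, numeric(1))
  new("SpectrumResult", kind = "dft", frequencies = as.numeric(freqs),
      values = vals)
}

#' Rank correlation between two spectra on the same grid
#'
#' Spearman correlation of the per-bin values; for a DTW-spectrum against a
#' DFT spectrum of the same segment this is typically strongly negative
#' (good template match = low dissimilarity = high power).
#'
#' @param a,b [SpectrumResult-class] objects on identical frequency grids.
#' @return Spearman correlation in `[-1, 1]`.
#' @export
spectraCorrelation <- function(a, b) {
  stopifnot(is(a, "SpectrumResult"), is(b, "SpectrumResult"))
  if (length(frequencies(a)) != length(frequencies(b)) ||
      any(frequencies(a) != frequencies(b)))
    stop("spectra are on different frequency grids")
  va <- spectrumValues(a); vb <- spectrumValues(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("correlation undefined: constant spectrum values")
  stats::cor(va, vb, method = "spearman")
}

#' Per-trial DTW- and DFT-spectrum standard deviations
#'
#' For one channel, extracts each trial's 1 s pre-trial segment (the
#' half-open window `[t - rate, t)`), computes both spectra on the shared
#' 8-13 Hz grid, and reduces each to its standard deviation. The SD is
#' invariant to adding a constant to all bins, so it measures how peaked,
#' not how large, a spectrum is.
#'
#' @param eeg an [EEGRecording-class].
#' @param trials a [TrialTable-class].
#' @param channel channel index or label (default first channel).
#' @param fLo,fHi,step frequency grid (defaults 8, 13, 0.1 Hz).
#' @param window Sakoe-Chiba half-width (default 20).
#' @param shape template shape.
#' @param cost DTW local cost.
#' @param standardize standardize segments before DTW (default `TRUE`).
#' @return data.frame with columns `trial`, `dtw_sd`, `dft_sd`.
#' @export
trialSpectra <- function(eeg, trials, channel = 1L, fLo = 8, fHi = 13,
                         step = 0.1, window = 20L,
                         shape = c("sine", "sawtooth"),
                         cost = c("abs", "squared"), standardize = TRUE) {
  shape <- match.arg(shape); cost <- match.arg(cost)
  stopifnot(is(eeg, "EEGRecording"), is(trials, "TrialTable"))
  if (is.character(channel)) channel <- match(channel, channelLabels(eeg))
  if (is.na(channel) || channel < 1L || channel > nChannels(eeg))
    stop("unknown channel")
  rate <- samplingRate(eeg)
  w <- as.integer(round(rate))  # 1 s pre-trial window
  sig <- eegData(eeg)[channel, ]
  bank <- makeTemplates(fLo, fHi, step, nSamples = w, rate = rate, shape = shape)
  at <- trialSamples(trials)
  res <- vapply(at, function(t0) {
    seg <- sig[.pretrialIdx(t0, w)]
    c(spectrumSD(dtwSpectrum(seg, bank, window = window, cost = cost,
                             standardize = standardize)),
      spectrumSD(dftSpectrum(seg, rate, frequencies(bank))))
  }, numeric(2))
  data.frame(trial = seq_along(at), dtw_sd = res[1L, ], dft_sd = res[2L, ])
}
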