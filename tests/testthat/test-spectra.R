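# Template bank construction, DTW- and DFT-spectrum behaviour, and the
# rank correlation between the two.

test_that("makeTemplates spans the band inclusively and standardizes", {
  b <- makeTemplates(8, 13, 0.5, nSamples = 50, rate = 50)
  expect_equal(frequencies(b), seq(8, 13, by = 0.5))
  tpl <- templateMatrix(b)
  expect_equal(rowMeans(tpl), rep(0, nrow(tpl)), tolerance = 1e-12)
  expect_equal(apply(tpl, 1, sd), rep(1, nrow(tpl)), tolerance = 1e-12)
  # step exceeding the band leaves a single frequency
  b1 <- makeTemplates(8, 13, 10, nSamples = 50, rate = 50)
  expect_equal(frequencies(b1), 8)
  # closed-form waveform: standardized sin(2 pi f t / rate)
  f <- 9.5
  i <- which(frequencies(b) == f)
  w <- sin(2 * pi * f * (0:49) / 50)
  expect_equal(tpl[i, ], (w - mean(w)) / sd(w), tolerance = 1e-12)
})

test_that("makeTemplates rejects aliasing and bad steps", {
  expect_error(makeTemplates(8, 25, 0.5, 50, 50), "Nyquist")
  expect_error(makeTemplates(8, 13, 0, 50, 50), "step")
  expect_error(makeTemplates(8, 13, -1, 50, 50), "step")
  expect_error(makeTemplates(0, 13, 0.5, 50, 50), "fLo")
})

test_that("sawtooth templates have the requested period", {
  b <- makeTemplates(5, 5, 1, nSamples = 50, rate = 50, shape = "sawtooth")
  tpl <- templateMatrix(b)[1, ]
  expect_equal(tpl[1:10], tpl[11:20], tolerance = 1e-12)  # period 10 samples
})

test_that("dtwSpectrum of a pure sine dips at its own frequency", {
  b <- makeTemplates(8, 13, 0.5, nSamples = 50, rate = 50)
  for (f in c(8, 10, 11.5, 13)) {
    seg <- sin(2 * pi * f * (0:49) / 50)
    s <- dtwSpectrum(seg, b)
    expect_s4_class(s, "SpectrumResult")
    expect_length(spectrumValues(s), length(frequencies(b)))
    expect_true(all(spectrumValues(s) >= 0))
    expect_equal(frequencies(b)[which.min(spectrumValues(s))], f)
  }
})

test_that("dtwSpectrum rejects degenerate and mismatched segments", {
  b <- makeTemplates(8, 13, 0.5, nSamples = 50, rate = 50)
  expect_error(dtwSpectrum(rep(1, 50), b), "zero variance")
  expect_error(dtwSpectrum(rnorm(40), b), "length")
})

test_that("spectrum bins are independent: each equals a standalone DTW call", {
  b <- makeTemplates(8, 13, 1, nSamples = 50, rate = 50)
  set.seed(1); seg <- rnorm(50)
  z <- (seg - mean(seg)) / sd(seg)
  v <- spectrumValues(dtwSpectrum(seg, b))
  solo <- apply(templateMatrix(b), 1, function(tp)
    dtwDistance(z, tp, window = 20L))
  expect_equal(v, solo, tolerance = 1e-12)
})

test_that("dftSpectrum matches the naive direct-summation oracle", {
  set.seed(3)
  freqs <- seq(8, 13, by = 0.5)
  for (i in 1:10) {
    seg <- rnorm(50)
    v <- spectrumValues(dftSpectrum(seg, 50, freqs))
    expect_equal(v, sapply(freqs, function(f) naiveDFTPower(seg, 50, f)),
                 tolerance = 1e-10)
  }
  # pure on-grid sine peaks at itself; zero segment gives zero power
  s10 <- spectrumValues(dftSpectrum(sin(2 * pi * 10 * (0:49) / 50), 50, freqs))
  expect_equal(freqs[which.max(s10)], 10)
  expect_equal(spectrumValues(dftSpectrum(rep(0, 50), 50, freqs)),
               rep(0, length(freqs)))
})

test_that("spectrum SD reduction is shift-invariant", {
  b <- makeTemplates(8, 13, 0.5, nSamples = 50, rate = 50)
  set.seed(4); seg <- rnorm(50)
  s <- dtwSpectrum(seg, b)
  shifted <- new("SpectrumResult", kind = "dtw", frequencies = frequencies(s),
                 values = spectrumValues(s) + 7)
  expect_equal(spectrumSD(shifted), spectrumSD(s))
})

test_that("spectraCorrelation handles extremes and errors", {
  f <- seq(8, 13, 0.5)
  a <- new("SpectrumResult", kind = "dtw", frequencies = f,
           values = seq_along(f) + 0)
  b <- new("SpectrumResult", kind = "dft", frequencies = f,
           values = rev(seq_along(f)) + 0)
  expect_equal(spectraCorrelation(a, a), 1)
  expect_equal(spectraCorrelation(a, b), -1)
  cst <- new("SpectrumResult", kind = "dft", frequencies = f,
             values = rep(1, length(f)))
  expect_error(spectraCorrelation(a, cst), "constant")
  short <- new("SpectrumResult", kind = "dft", frequencies = f[-1],
               values = seq_along(f[-1]) + 0)
  expect_error(spectraCorrelation(a, short), "grids")
})

test_that("trialSpectra returns one row per trial with positive SDs", {
  sub <- simulateSubject(synthConfig(nSubjects = 1, blockLenSec = 12,
                                     nTrials = 10), seed = 2)
  ts <- trialSpectra(sub$eeg, sub$trials, channel = 1)
  expect_equal(nrow(ts), 10)
  expect_true(all(ts$dtw_sd > 0) && all(ts$dft_sd > 0))
})
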