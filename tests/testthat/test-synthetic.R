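# Generators: layout, determinism, and the planted structure each measure
# is meant to detect.

test_that("default layout: 5 alternating blocks, 112 trials, seeded determinism", {
  cfg <- synthConfig()
  expect_equal(cfg$nTrials, 112L)
  expect_equal(cfg$nBlocks, 5L)
  sub <- simulateSubject(cfg, seed = 3)
  expect_equal(nTrials(sub$trials), 112L)
  expect_equal(unique(blockTypes(sub$trials)[order(blockIDs(sub$trials))]),
               c("task", "rest"))
  expect_equal(as.vector(table(blockIDs(sub$trials))), c(23L, 23L, 22L, 22L, 22L))
  expect_equal(nSamples(sub$eeg), 5L * 60L * 50L)
  expect_true(validObject(sub$eeg) && validObject(sub$trials))
  sub2 <- simulateSubject(cfg, seed = 3)
  expect_identical(eegData(sub$eeg), eegData(sub2$eeg))
  expect_identical(sub$truth$stateLabels, sub2$truth$stateLabels)
  # the generator leaves the caller's RNG stream untouched
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(simulateSubject(cfg, seed = 4)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("config validation rejects impossible settings", {
  expect_error(synthConfig(nSubjects = 0), "positive")
  expect_error(synthConfig(alphaFreq = 20), "8, 13")
  expect_error(synthConfig(stateDwellMean = 0.2), "stateDwellMean")
})

test_that("block-dependent alpha amplitude shows up as band power", {
  cfg <- synthConfig(nSubjects = 1, alphaAmpTask = 0, alphaAmpRest = 1,
                     noiseSdTask = 0.4, noiseSdRest = 0.4, eventRate = 0)
  sub <- simulateSubject(cfg, seed = 7)
  sig <- eegData(sub$eeg)[1, ]
  bandPower <- function(t0) {
    seg <- sig[(t0 - 49):t0 + 1]
    mean(spectrumValues(dftSpectrum(seg, 50, seq(8, 13, 0.5))))
  }
  at <- trialSamples(sub$trials)
  bp <- sapply(at, bandPower)
  rest <- blockTypes(sub$trials) == "rest"
  expect_gt(mean(bp[rest]), 2 * mean(bp[!rest]))
})

test_that("planted dwell times are geometric with the configured mean", {
  cfg <- synthConfig(nSubjects = 1, stateDwellMean = 4)
  sub <- simulateSubject(cfg, seed = 11)
  runs <- rle(sub$truth$stateLabels)$lengths
  expect_gt(length(runs), 1000)
  expect_equal(mean(runs), 4, tolerance = 0.1)   # within 10%
})

test_that("null measures are independent unit-variance columns", {
  ms <- generateNullMeasures(2, 5000, seed = 13)
  expect_length(ms, 2)
  df <- measuresTable(ms[[1]])
  M <- as.matrix(df[, measureNames()])
  expect_equal(apply(M, 2, sd), rep(1, 6), tolerance = 0.05,
               ignore_attr = TRUE)
  cors <- cor(M)[upper.tri(diag(6))]
  expect_true(all(abs(cors) < 0.1))
  expect_identical(measuresTable(generateNullMeasures(2, 100, seed = 5)[[1]]),
                   measuresTable(generateNullMeasures(2, 100, seed = 5)[[1]]))
})

test_that("generateBOLD builds couplings exactly when noiseless", {
  ms <- generateNullMeasures(1, 40, seed = 15)[[1]]
  df <- measuresTable(ms)
  trials <- TrialTable(df$trial_sample, df$block_id, df$block_type)
  b0 <- generateBOLD(ms, trials, coupling = list(), noiseSd = 0, seed = 1)
  expect_true(all(b0 == 0))
  b1 <- generateBOLD(ms, trials,
                     coupling = list(list(network = 2, measure = "sse",
                                          beta = 2)),
                     noiseSd = 0, seed = 1)
  expect_true(all(b1[, c(1, 3)] == 0))
  expect_equal(sd(b1[, 2]), 2, tolerance = 1e-10)
  expect_error(generateBOLD(ms, trials,
                            coupling = list(list(network = 1,
                                                 measure = "nope", beta = 1))),
               "unknown measure")
})

test_that("alpha-burst segments carry their stated frequency", {
  ab <- alphaBurstSegments(n = 30, seed = 17)
  expect_equal(dim(ab$segments), c(30L, 50L))
  grid <- seq(8, 13, 0.5)
  hit <- sapply(1:30, function(i) {
    pw <- spectrumValues(dftSpectrum(ab$segments[i, ], 50, grid))
    abs(grid[which.max(pw)] - ab$freq[i]) <= 0.75
  })
  expect_gte(mean(hit), 0.8)
})

test_that("study-level measures assemble completely for every subject", {
  cfg <- synthConfig(nSubjects = 2, blockLenSec = 12, nTrials = 15,
                     nBlocks = 3)
  study <- simulateStudy(cfg, seed = 19)
  expect_length(study, 2)
  ms <- computeStudyMeasures(study, k = 4, seed = 19)
  expect_length(ms, 2)
  for (m in ms) {
    expect_s4_class(m, "TrialMeasures")
    expect_equal(nTrials(m), 15L)
    expect_true(all(is.finite(as.matrix(measuresTable(m)[, measureNames()]))))
  }
})
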