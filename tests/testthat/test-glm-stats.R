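# OLS betas, group t, BH-FDR, permutation null, HRF convolution and the
# full cross-prediction matrix.

nullSubjects <- function(n = 6, trials = 40, seed = 1)
  generateNullMeasures(n, trials, seed)

test_that("fitTrialGLM recovers exact linear structure and matches normal equations", {
  m <- nullSubjects(1, 60, seed = 2)[[1]]
  df <- measuresTable(m)
  # target equal to one z-scored predictor: that beta 1, others 0
  z <- (df$dft_sd - mean(df$dft_sd)) / sd(df$dft_sd)
  df$sse <- z + 5
  b <- fitTrialGLM(df, "sse")
  expect_equal(unname(b["dft_sd"]), 1, tolerance = 1e-10)
  expect_equal(unname(b[setdiff(names(b), "dft_sd")]), rep(0, 4),
               tolerance = 1e-10)
  # random design matches the closed-form normal-equations oracle
  df2 <- measuresTable(nullSubjects(1, 50, seed = 3)[[1]])
  preds <- setdiff(measureNames(), "dtw_sd")
  Z <- sapply(preds, function(p) (df2[[p]] - mean(df2[[p]])) / sd(df2[[p]]))
  oracle <- normalEqBetas(cbind(1, Z), df2$dtw_sd)[-1]
  expect_equal(unname(fitTrialGLM(df2, "dtw_sd")), oracle, tolerance = 1e-8)
})

test_that("fitTrialGLM rejects singular designs and short tables", {
  df <- measuresTable(nullSubjects(1, 50, seed = 4)[[1]])
  df$dft_sd <- df$dtw_sd              # duplicated predictor column
  expect_error(fitTrialGLM(df, "sse"), "singular")
  expect_error(fitTrialGLM(df[1:4, ], "sse"), "at least")
  # a constant predictor is singular next to the intercept...
  df2 <- measuresTable(nullSubjects(1, 50, seed = 4)[[1]])
  df2$ava_length <- 1
  expect_error(fitTrialGLM(df2, "sse"), "constant")
  # ...unless explicitly tolerated, in which case its beta is 0
  b <- fitTrialGLM(df2, "sse", allowConstant = TRUE)
  expect_equal(unname(b["ava_length"]), 0)
  expect_equal(names(b), setdiff(measureNames(), "sse"))
})

test_that("runComparison tolerates a measure constant within a condition", {
  ms <- nullSubjects(4, 40, seed = 55)
  ms <- lapply(ms, function(m) {
    df <- measuresTable(m)
    df$ava_length <- ifelse(df$block_type == "task", 1, df$ava_length)
    TrialMeasures(subjectID(m), df)
  })
  r <- runComparison(ms, nPerm = 9, seed = 6)
  tb <- comparisonTable(r)
  expect_equal(nrow(tb), 2 * 30)
  # cells with the degenerate predictor in the degenerate condition are null
  cell <- tb[tb$condition == "task" & tb$predictor == "ava_length", ]
  expect_true(all(cell$beta == 0) && all(cell$p == 1))
  # the same predictor still carries information in the intact condition
  rest <- tb[tb$condition == "rest" & tb$predictor == "ava_length", ]
  expect_true(any(rest$beta != 0))
})

test_that("groupTTest matches the textbook statistic", {
  b <- c(1, 2, 3, 4, 5)
  r <- groupTTest(b)
  expect_equal(r$t, mean(b) / (sd(b) / sqrt(5)))
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-abs(r$t), 4))
  expect_error(groupTTest(3), "2 subjects")
  expect_error(groupTTest(rep(1, 5)), "zero variance")
})

test_that("fdrBH reproduces the hand step-up and bounds Bonferroni", {
  p <- c(0.01, 0.02, 0.03, 0.5)
  r <- fdrBH(p, 0.05)
  # hand BH: adjusted = min_k>=i (p_k * n / k), cumulative from the top
  expect_equal(r$adjusted, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(r$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(fdrBH(rep(1, 6), 0.05)$reject))
  expect_true(fdrBH(0.01, 0.05)$reject)
  expect_error(fdrBH(c(0.5, 1.2)), "0, 1")
  # BH rejections are a superset of Bonferroni at the same alpha
  set.seed(5)
  for (i in 1:20) {
    pv <- runif(15)^2
    bh <- fdrBH(pv, 0.05)$reject
    bonf <- pv <= 0.05 / length(pv)
    expect_true(all(bh[bonf]))
  }
})

test_that("permutationTest is exact-bounded and flags a perfect effect", {
  ms <- nullSubjects(5, 40, seed = 6)
  ms <- lapply(ms, function(m) {
    df <- measuresTable(m)
    df$sse <- df$dtw_sd              # target identical to the predictor
    TrialMeasures(subjectID(m), df)
  })
  r <- permutationTest(ms, "sse", "dtw_sd", nPerm = 99, seed = 1)
  expect_equal(r$p, 1 / 100)         # no permutation can beat the observed t
  expect_true(all(abs(r$tPerm) <= abs(r$tObs)))
  expect_error(permutationTest(ms, "sse", "dtw_sd", nPerm = 0), "nPerm")
})

test_that("permutation betas agree with refitting the GLM explicitly", {
  ms <- nullSubjects(3, 30, seed = 7)
  r <- permutationTest(ms, "ms_length", "mean_gfp", nPerm = 5, seed = 2)
  obs <- sapply(ms, function(m) fitTrialGLM(m, "ms_length")[["mean_gfp"]])
  expect_equal(r$tObs, mean(obs) / (sd(obs) / sqrt(3)), tolerance = 1e-10)
})

test_that("hrfConvolve: kernel shape, zero input, impulse and linearity", {
  rate <- 2
  expect_equal(hrfConvolve(rep(0, 100), rate), rep(0, 100))
  k <- hrfKernel(rate)
  expect_equal(max(k), 1)
  peakT <- (which.max(k) - 1) / rate
  expect_true(peakT >= 4 && peakT <= 8)         # response peak near 5-6 s
  expect_lt(min(k), 0)                          # undershoot exists
  # unit impulse reproduces the kernel
  x <- c(1, rep(0, 99))
  expect_equal(hrfConvolve(x, rate)[seq_along(k)], k, tolerance = 1e-8)
  # linearity
  set.seed(8)
  a <- rnorm(80); b <- rnorm(80)
  expect_equal(hrfConvolve(a + b, rate),
               hrfConvolve(a, rate) + hrfConvolve(b, rate), tolerance = 1e-8)
})

test_that("runComparison produces the full off-diagonal matrix per condition", {
  ms <- nullSubjects(5, 40, seed = 9)
  r <- runComparison(ms, nPerm = 19, seed = 3)
  tb <- comparisonTable(r)
  for (cond in c("task", "rest")) {
    sub <- tb[tb$condition == cond, ]
    expect_equal(nrow(sub), 6 * 5)
    expect_true(all(sub$target != sub$predictor))
    expect_true(all(sub$p >= 0 & sub$p <= 1))
    expect_true(all(sub$p_perm >= 1 / 20))
  }
  # n_reps = 1 equals passing the same measures as a single repetition list
  r2 <- runComparison(list(ms), nPerm = 19, seed = 3)
  expect_equal(comparisonTable(r2)$beta, tb$beta)
  expect_equal(comparisonTable(r2)$p_perm, tb$p_perm)
})

test_that("planted coupling is detected and repetition averaging shrinks variance", {
  set.seed(11)
  plant <- function(seed) {
    ms <- nullSubjects(6, 60, seed = seed)
    lapply(ms, function(m) {
      df <- measuresTable(m)
      df$sse <- 0.8 * df$dtw_sd + rnorm(nrow(df), sd = 0.5) + 5
      TrialMeasures(subjectID(m), df)
    })
  }
  r <- runComparison(plant(20), nPerm = 19, seed = 4)
  tb <- comparisonTable(r)
  cell <- tb[tb$condition == "task" & tb$target == "sse" &
             tb$predictor == "dtw_sd", ]
  expect_lt(cell$p_fdr, 0.05)
  expect_gt(cell$beta, 0)
  # repetition averaging: variance of the 10-rep mean < single-rep variance
  base <- nullSubjects(1, 60, seed = 30)[[1]]
  noisyRep <- function(seed) {
    df <- measuresTable(base)
    set.seed(seed)
    df$sse <- df$sse + rnorm(nrow(df))
    list(TrialMeasures("s01", df))
  }
  singles <- sapply(1:30, function(s)
    fitTrialGLM(noisyRep(s)[[1]], "sse")[["dtw_sd"]])
  reps10 <- sapply(seq(1, 300, by = 10), function(s0)
    mean(sapply(s0:(s0 + 9), function(s)
      fitTrialGLM(noisyRep(1000 + s)[[1]], "sse")[["dtw_sd"]])))
  expect_lt(var(reps10), var(singles))
})

test_that("BOLD targets regress on convolved measure regressors", {
  ms <- nullSubjects(4, 40, seed = 40)
  trialsList <- lapply(ms, function(m) {
    df <- measuresTable(m)
    TrialTable(df$trial_sample, df$block_id, df$block_type)
  })
  # noiseless coupling: net01 driven by dtw_sd
  bold <- lapply(seq_along(ms), function(s)
    generateBOLD(ms[[s]], trialsList[[s]], rate = 50, tr = 2,
                 coupling = list(list(network = "net01", measure = "dtw_sd",
                                      beta = 1)),
                 nNetworks = 2, noiseSd = 0.05, seed = 50 + s))
  r <- runComparison(ms, trialsList = trialsList, bold = bold,
                     nPerm = 9, seed = 5)
  tb <- comparisonTable(r)
  bl <- tb[tb$condition == "bold", ]
  expect_equal(nrow(bl), 2 * 6)
  expect_true(all(is.na(bl$p_perm)))
  cell <- bl[bl$target == "net01" & bl$predictor == "dtw_sd", ]
  expect_lt(cell$p_fdr, 0.05)
})
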