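# One-step MLP prediction of a single EEG channel from lagged inputs.
# A single hidden layer of the same size as the input (tanh activations,
# linear output) is trained by batch-partitioned gradient descent on squared
# error; if the final training SSE exceeds a (relative) threshold the model
# is re-initialized from the next seed. Per-trial SSE over the 1 s pre-trial
# window is the predictability measure.

.mlpForward <- function(W1, b1, W2, b2, X) {
  H <- tanh(X %*% t(W1) + rep(b1, each = nrow(X)))
  list(H = H, out = as.vector(H %*% t(W2)) + b2)
}

#' Build the lagged one-step training set for the pre-trial windows
#'
#' For each trial at 0-based sample `t`, slides over the half-open window
#' `[t - rate, t)`: every target sample inside the window that has
#' `nLags + 1` preceding in-window samples yields one example (input = the
#' `nLags + 1` samples immediately before it, output = the sample itself).
#' With a 50-sample window and 40 lags that is `50 - 41 = 9` examples per
#' trial.
#'
#' @param signal numeric single-channel series (standardize it with
#'   training-block statistics before calling; this function is
#'   deterministic plumbing).
#' @param trialAt 0-based trial sample indices.
#' @param rate sampling rate in Hz (window length = `rate` samples).
#' @param nLags number of extra lagged inputs (default 40, so 41 inputs).
#' @return list with matrix `X` (examples x inputs), vector `y`, and
#'   `trial`, the trial index of each example.
#' @export
buildTrainingSet <- function(signal, trialAt, rate, nLags = 40L) {
  nLags <- as.integer(nLags)
  w <- as.integer(round(rate))
  if (w <= nLags + 1L)
    stop("window of ", w, " samples cannot hold ", nLags + 1L,
         " inputs plus a target")
  bad <- trialAt < w
  if (any(bad))
    stop("trial at sample ", trialAt[which(bad)[1L]],
         " is too close to the start for a ", w, "-sample window")
  d <- nLags + 1L
  perTrial <- w - d                       # targets per trial
  X <- matrix(0, length(trialAt) * perTrial, d)
  y <- numeric(nrow(X))
  row <- 1L
  for (t0 in trialAt) {
    for (tgt in (t0 - w + d):(t0 - 1L)) { # 0-based target samples
      X[row, ] <- signal[(tgt - d):(tgt - 1L) + 1L]
      y[row] <- signal[tgt + 1L]
      row <- row + 1L
    }
  }
  list(X = X, y = y, trial = rep(seq_along(trialAt), each = perTrial))
}

#' Train the one-step MLP by batch gradient descent
#'
#' Parameters are initialized uniformly on `(-1/sqrt(fan_in), 1/sqrt(fan_in))`
#' from `seed`; training partitions the data into consecutive batches of
#' `batchSize` and applies plain gradient descent on the mean squared error
#' of each batch, for `epochs` passes. If the final training SSE exceeds
#' `sseThreshold` times the SSE of the constant-mean predictor, the model is
#' re-initialized from the next seed, up to `maxRetrains` times, and the
#' first sub-threshold model is returned.
#'
#' @param X,y training examples (e.g. from [buildTrainingSet()]).
#' @param hidden hidden-layer size (default: same as the input layer).
#' @param learningRate gradient-descent step size (default 0.05).
#' @param epochs passes over the data (default 200); `epochs = 0` returns
#'   the initialization.
#' @param batchSize batch size (default 50).
#' @param sseThreshold training-error threshold as a fraction of the
#'   constant-mean predictor's SSE (default 0.5); scale-free.
#' @param maxRetrains re-initialization budget (default 10).
#' @param seed RNG seed for the initialization.
#' @return an [MLPModel-class].
#' @export
trainMLP <- function(X, y, hidden = ncol(X), learningRate = 0.05,
                     epochs = 200L, batchSize = 50L, sseThreshold = 0.5,
                     maxRetrains = 10L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 1L) stop("empty training set")
  stopifnot(hidden >= 1L, batchSize >= 1L)
  sse0 <- sum((y - mean(y))^2)
  limit <- sseThreshold * sse0
  batches <- split(seq_len(n), ceiling(seq_len(n) / batchSize))
  for (attempt in 0:maxRetrains) {
    s <- as.integer(seed) + attempt
    par <- .withSeed(s, {
      r1 <- 1 / sqrt(d); r2 <- 1 / sqrt(hidden)
      list(W1 = matrix(stats::runif(hidden * d, -r1, r1), hidden, d),
           b1 = stats::runif(hidden, -r1, r1),
           W2 = matrix(stats::runif(hidden, -r2, r2), 1L, hidden),
           b2 = stats::runif(1L, -r2, r2))
    })
    W1 <- par$W1; b1 <- par$b1; W2 <- par$W2; b2 <- par$b2
    if (epochs > 0L) for (e in seq_len(epochs)) {
      for (idx in batches) {
        Xb <- X[idx, , drop = FALSE]; yb <- y[idx]; nb <- length(idx)
        fw <- .mlpForward(W1, b1, W2, b2, Xb)
        err <- fw$out - yb
        gW2 <- (2 / nb) * matrix(err, 1L) %*% fw$H
        gb2 <- (2 / nb) * sum(err)
        dH <- (2 / nb) * outer(err, as.vector(W2)) * (1 - fw$H^2)
        gW1 <- crossprod(dH, Xb)
        gb1 <- colSums(dH)
        W1 <- W1 - learningRate * gW1; b1 <- b1 - learningRate * gb1
        W2 <- W2 - learningRate * gW2; b2 <- b2 - learningRate * gb2
      }
    }
    sse <- sum((.mlpForward(W1, b1, W2, b2, X)$out - y)^2)
    if (sse <= limit || epochs == 0L)
      return(new("MLPModel", W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 trainSSE = sse, nLags = d - 1L,
                 seedUsed = s, retrains = attempt))
  }
  stop("training did not reach the SSE threshold (", signif(limit, 4),
       ") within ", maxRetrains, " retrains")
}

#' Predict with a trained MLP
#' @param model an [MLPModel-class].
#' @param X input matrix (columns = `nLags + 1` lagged samples).
#' @return numeric predictions.
#' @export
predictMLP <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(model@W1))
    stop("input size ", ncol(X), " does not match model (", ncol(model@W1), ")")
  .mlpForward(model@W1, model@b1, model@W2, model@b2, X)$out
}

#' Per-trial one-step prediction error (SSE)
#'
#' Sums the squared one-step prediction errors over each trial's pre-trial
#' window.
#'
#' @param model an [MLPModel-class].
#' @param signal standardized single-channel series.
#' @param trialAt 0-based trial sample indices.
#' @param rate sampling rate in Hz.
#' @return numeric vector, one nonnegative SSE per trial.
#' @export
predictSSE <- function(model, signal, trialAt, rate) {
  te <- buildTrainingSet(signal, trialAt, rate, nLags = model@nLags)
  pe <- (predictMLP(model, te$X) - te$y)^2
  as.numeric(tapply(pe, te$trial, sum))
}

#' Trial-wise MLP predictability for one recording
#'
#' Trains one model per condition (task and rest) on that condition's
#' designated training block — the first task block and the second rest
#' block (or the only one, if a single rest block exists) — and scores every
#' trial of the condition with its model. The signal is z-scored with
#' statistics of the training trials' pre-trial windows only, so test data
#' never leaks into scaling or training.
#'
#' @param eeg an [EEGRecording-class].
#' @param trials a [TrialTable-class].
#' @param channel channel index or label (default 1).
#' @param nLags,hidden,learningRate,epochs,batchSize,sseThreshold,maxRetrains,seed
#'   passed to [trainMLP()] / [buildTrainingSet()]; `hidden = NULL` means
#'   input-sized.
#' @return data.frame with `trial`, `sse`; attribute `"models"` carries the
#'   two fitted [MLPModel-class] objects.
#' @export
trialSSE <- function(eeg, trials, channel = 1L, nLags = 40L, hidden = NULL,
                     learningRate = 0.05, epochs = 200L, batchSize = 50L,
                     sseThreshold = 0.5, maxRetrains = 10L, seed = 1L) {
  stopifnot(is(eeg, "EEGRecording"), is(trials, "TrialTable"))
  if (is.character(channel)) channel <- match(channel, channelLabels(eeg))
  rate <- samplingRate(eeg)
  w <- as.integer(round(rate))
  sig <- eegData(eeg)[channel, ]
  at <- trialSamples(trials); bid <- blockIDs(trials); bty <- blockTypes(trials)
  out <- numeric(length(at))
  models <- list()
  for (cond in c("task", "rest")) {
    sel <- bty == cond
    if (!any(sel)) next
    blocks <- unique(bid[sel])
    trainBlock <- if (cond == "rest" && length(blocks) >= 2L) blocks[2L]
                  else blocks[1L]
    trainAt <- at[sel & bid == trainBlock]
    # standardize with training-window statistics only
    winIdx <- unique(unlist(lapply(trainAt, .pretrialIdx, width = w)))
    mu <- mean(sig[winIdx]); sdv <- stats::sd(sig[winIdx])
    if (sdv == 0) stop("training windows have zero variance")
    z <- (sig - mu) / sdv
    tr <- buildTrainingSet(z, trainAt, rate, nLags)
    model <- trainMLP(tr$X, tr$y,
                      hidden = if (is.null(hidden)) ncol(tr$X) else hidden,
                      learningRate = learningRate, epochs = epochs,
                      batchSize = batchSize, sseThreshold = sseThreshold,
                      maxRetrains = maxRetrains, seed = seed)
    out[sel] <- predictSSE(model, z, at[sel], rate)
    models[[cond]] <- model
  }
  res <- data.frame(trial = seq_along(at), sse = out)
  attr(res, "models") <- models
  res
}
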