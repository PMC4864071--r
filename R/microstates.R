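# EEG microstate pipeline: global field power, GFP-peak detection, pooled
# polarity-invariant k-means over peak topographies, back-fitting of the
# centroid maps to every sample, and the two pre-trial measures (length of
# the microstate at trial time, mean GFP over that microstate).

#' Global field power
#'
#' The spatial (population) standard deviation of the scalp potentials
#' across channels at each sample: `gfp[t] = sqrt(mean((v - mean(v))^2))`
#' for the column `v` of potentials at time `t`.
#'
#' @param eeg an [EEGRecording-class] with at least 2 channels.
#' @return nonnegative numeric vector, one value per sample.
#' @export
globalFieldPower <- function(eeg) {
  stopifnot(is(eeg, "EEGRecording"))
  if (nChannels(eeg) < 2L)
    stop("global field power needs at least 2 channels")
  X <- eegData(eeg)
  mu <- colMeans(X)
  sqrt(colMeans(X^2) - mu^2)
}

#' Strict interior local maxima of a GFP series
#'
#' Returns 0-based sample indices `t` with `gfp[t-1] < gfp[t] > gfp[t+1]`,
#' in ascending order. Topographies at GFP peaks carry the highest
#' signal-to-noise ratio and are what gets clustered.
#'
#' @param gfp numeric series of length >= 3.
#' @return integer vector of 0-based peak indices.
#' @export
detectGFPPeaks <- function(gfp) {
  n <- length(gfp)
  if (n < 3L) stop("series too short for peak detection (need >= 3 samples)")
  mid <- gfp[-c(1L, n)]
  idx <- which(gfp[-c(n - 1L, n)] < mid & mid > gfp[-c(1L, 2L)])
  as.integer(idx)  # interior position i (1-based i+1) -> 0-based index i
}

# average-reference rows and scale to unit norm; rows with zero norm error out
.normalizeMaps <- function(M) {
  M <- M - rowMeans(M)
  nrm <- sqrt(rowSums(M^2))
  if (any(nrm == 0)) stop("degenerate (flat) topography encountered")
  M / nrm
}

#' Polarity-invariant k-means over GFP-peak topographies
#'
#' Clusters average-referenced, unit-norm scalp maps with the dissimilarity
#' `1 - |spatial correlation|` (polarity-invariant, the microstate
#' convention) or `1 - correlation` when `polarityInvariant = FALSE`.
#' Cluster centroids are the dominant polarity-aligned direction of their
#' members, re-normalized; empty clusters are re-seeded from the point
#' worst-explained by the current centroids. The best of `restarts` seeded
#' restarts (by total within-cluster dissimilarity) is returned.
#'
#' @param peakMaps matrix, n_peaks x channels (rows = topographies).
#' @param k number of microstate maps (default 12).
#' @param restarts number of k-means restarts (default 10).
#' @param maxIter iteration cap per restart (default 100).
#' @param seed RNG seed for reproducible restarts.
#' @param polarityInvariant use `1 - |corr|` (default `TRUE`).
#' @param trace if `TRUE`, attach attribute `"objective"` with the
#'   per-iteration objective of the winning restart.
#' @return k x channels matrix of unit-norm centroid maps.
#' @export
clusterMaps <- function(peakMaps, k = 12L, restarts = 10L, maxIter = 100L,
                        seed = 1L, polarityInvariant = TRUE, trace = FALSE) {
  P <- .normalizeMaps(as.matrix(peakMaps))
  n <- nrow(P)
  if (n < k) stop("fewer peak maps (", n, ") than clusters (", k, ")")
  simFun <- if (polarityInvariant) function(S) abs(S) else function(S) S
  .withSeed(seed, {
    best <- NULL; bestObj <- Inf; bestTrace <- NULL
    for (r in seq_len(restarts)) {
      C <- P[sample.int(n, k), , drop = FALSE]
      objTrace <- numeric(0)
      for (it in seq_len(maxIter)) {
        S <- simFun(tcrossprod(P, C))          # n x k similarity
        z <- max.col(S, ties.method = "first")
        objTrace <- c(objTrace, sum(1 - S[cbind(seq_len(n), z)]))
        Cn <- C
        for (j in seq_len(k)) {
          idx <- which(z == j)
          if (!length(idx)) {                  # re-seed from farthest point
            far <- which.min(apply(S, 1L, max))
            Cn[j, ] <- P[far, ]
            next
          }
          Pj <- P[idx, , drop = FALSE]
          v <- if (polarityInvariant) {
            sgn <- sign(Pj %*% C[j, ]); sgn[sgn == 0] <- 1
            colSums(Pj * as.vector(sgn))
          } else colSums(Pj)
          nv <- sqrt(sum(v^2))
          Cn[j, ] <- if (nv > 0) v / nv else P[sample.int(n, 1L), ]
        }
        Cn <- .normalizeMaps(Cn)
        if (max(abs(Cn - C)) < 1e-10) { C <- Cn; break }
        C <- Cn
      }
      S <- simFun(tcrossprod(P, C))
      obj <- sum(1 - S[cbind(seq_len(n), max.col(S, ties.method = "first"))])
      if (obj < bestObj) { bestObj <- obj; best <- C; bestTrace <- objTrace }
    }
    if (trace) attr(best, "objective") <- bestTrace
    best
  })
}

#' Back-fit centroid maps to every EEG sample
#'
#' Assigns each time point the map with the highest (absolute, when
#' polarity-invariant) spatial correlation with the instantaneous
#' topography; ties go to the lowest map index.
#'
#' @param eeg an [EEGRecording-class].
#' @param maps k x channels centroid matrix (e.g. from [clusterMaps()]).
#' @param polarityInvariant match on `|corr|` (default `TRUE`).
#' @return integer vector of map labels (1..k), one per sample.
#' @export
backfit <- function(eeg, maps, polarityInvariant = TRUE) {
  stopifnot(is(eeg, "EEGRecording"))
  maps <- as.matrix(maps)
  if (ncol(maps) != nChannels(eeg))
    stop("map channel count (", ncol(maps), ") does not match recording (",
         nChannels(eeg), ")")
  X <- eegData(eeg)
  X <- X - rep(colMeans(X), each = nrow(X))   # average-reference each sample
  nrm <- sqrt(colSums(X^2)); nrm[nrm == 0] <- 1
  X <- X / rep(nrm, each = nrow(X))
  C <- .normalizeMaps(maps)
  S <- C %*% X                                # k x samples correlations
  if (polarityInvariant) S <- abs(S)
  max.col(t(S), ties.method = "first")
}

#' Pre-trial microstate measures
#'
#' For each trial at 0-based sample `t`, finds the maximal run of identical
#' labels containing `t`; `ms_length` is that run's length in samples and
#' `mean_gfp` the mean GFP over the run.
#'
#' @param labels per-sample map labels (from [backfit()]).
#' @param gfp per-sample global field power.
#' @param trials a [TrialTable-class].
#' @return data.frame with `trial`, `ms_length`, `mean_gfp`.
#' @export
pretrialMicrostates <- function(labels, gfp, trials) {
  stopifnot(is(trials, "TrialTable"))
  if (length(labels) != length(gfp)) stop("labels and gfp lengths differ")
  at <- trialSamples(trials)
  if (length(at) && (max(at) >= length(labels)))
    stop("trial sample out of range of the label series")
  r <- rle(labels)
  ends <- cumsum(r$lengths)                    # 1-based run end positions
  starts <- ends - r$lengths + 1L
  runOf <- rep.int(seq_along(r$lengths), r$lengths)
  res <- t(vapply(at, function(t0) {
    k <- runOf[t0 + 1L]
    c(r$lengths[k], mean(gfp[starts[k]:ends[k]]))
  }, numeric(2)))
  data.frame(trial = seq_along(at), ms_length = as.integer(res[, 1L]),
             mean_gfp = res[, 2L])
}

#' Group-level microstate pipeline
#'
#' Runs GFP -> peak detection per subject, pools all subjects' peak
#' topographies, clusters them once at the group level, then back-fits the
#' group maps to every subject and extracts the pre-trial measures.
#'
#' @param recordings list of [EEGRecording-class] objects.
#' @param trialsList list of matching [TrialTable-class] objects.
#' @param k,restarts,maxIter,seed,polarityInvariant passed to [clusterMaps()].
#' @param gfpPower if `TRUE`, average squared GFP instead of GFP over the
#'   pre-trial microstate.
#' @return list with `maps` (group centroids) and `perSubject`, a list of
#'   lists holding each subject's `model` ([MicrostateModel-class]) and
#'   `measures` (the [pretrialMicrostates()] data.frame).
#' @export
microstatePipeline <- function(recordings, trialsList, k = 12L, restarts = 10L,
                               maxIter = 100L, seed = 1L,
                               polarityInvariant = TRUE, gfpPower = FALSE) {
  stopifnot(length(recordings) == length(trialsList))
  gfps <- lapply(recordings, globalFieldPower)
  peakMaps <- do.call(rbind, lapply(seq_along(recordings), function(s) {
    pk <- detectGFPPeaks(gfps[[s]])
    t(eegData(recordings[[s]])[, pk + 1L, drop = FALSE])
  }))
  maps <- clusterMaps(peakMaps, k = k, restarts = restarts, maxIter = maxIter,
                      seed = seed, polarityInvariant = polarityInvariant)
  perSubject <- lapply(seq_along(recordings), function(s) {
    lab <- backfit(recordings[[s]], maps, polarityInvariant)
    g <- if (gfpPower) gfps[[s]]^2 else gfps[[s]]
    list(model = new("MicrostateModel", maps = maps, labels = lab,
                     gfp = gfps[[s]]),
         measures = pretrialMicrostates(lab, g, trialsList[[s]]))
  })
  list(maps = maps, perSubject = perSubject)
}
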