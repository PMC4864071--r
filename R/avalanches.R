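# Neuronal avalanche/cascade detection: z-score each channel, mark one
# point-process event at the onset of every suprathreshold excursion, bin
# the timeline, and call a cascade any maximal run of consecutive bins that
# each contain at least one event on any channel. The threshold is chosen
# from a small candidate set so the cascade count roughly matches the
# number of trials.

#' Detect suprathreshold point-process events
#'
#' Each channel is z-scored independently; an event is recorded at the
#' first sample of every maximal excursion where the (absolute, by default)
#' z value exceeds the threshold — one point per excursion per channel.
#'
#' @param eeg an [EEGRecording-class]; every channel must have nonzero
#'   variance.
#' @param threshold threshold in SD multiples (e.g. 3.5).
#' @param side `"both"` (|z|, default), `"pos"` or `"neg"`.
#' @param perSample if `TRUE`, mark every suprathreshold sample instead of
#'   excursion onsets.
#' @return data.frame with columns `channel`, `sample` (0-based), ordered
#'   by sample.
#' @export
detectEvents <- function(eeg, threshold,
                         side = c("both", "pos", "neg"), perSample = FALSE) {
  side <- match.arg(side)
  stopifnot(is(eeg, "EEGRecording"), threshold > 0)
  X <- eegData(eeg)
  sds <- apply(X, 1L, stats::sd)
  if (any(sds == 0))
    stop("degenerate input: zero-variance channel(s) ",
         paste(which(sds == 0), collapse = ", "))
  Z <- (X - rowMeans(X)) / sds
  M <- switch(side,
              both = abs(Z) > threshold,
              pos  = Z > threshold,
              neg  = Z < -threshold)
  ev <- lapply(seq_len(nrow(M)), function(ch) {
    m <- M[ch, ]
    s <- if (perSample) which(m) else which(m & !c(FALSE, m[-length(m)]))
    if (length(s)) data.frame(channel = ch, sample = s - 1L) else NULL
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev)) ev <- data.frame(channel = integer(0), sample = integer(0))
  ev[order(ev$sample, ev$channel), , drop = FALSE]
}

#' Bin events and extract cascades
#'
#' Partitions samples into consecutive bins of `binWidth` samples; a
#' cascade is a maximal run of consecutive bins each containing at least
#' one event from any channel.
#'
#' @param events data.frame from [detectEvents()] (needs a 0-based `sample`
#'   column).
#' @param nSamples total number of samples in the recording.
#' @param binWidth bin width in samples (default 2).
#' @param threshold the detection threshold, carried into the result.
#' @return an [AvalancheSet-class].
#' @export
binCascades <- function(events, nSamples, binWidth = 2L, threshold = NA_real_) {
  binWidth <- as.integer(binWidth)
  if (binWidth < 1L) stop("binWidth must be >= 1")
  s <- events$sample
  if (length(s) && (min(s) < 0L || max(s) >= nSamples))
    stop("event sample outside [0, nSamples)")
  nBins <- as.integer(ceiling(nSamples / binWidth))
  if (!length(s)) {
    cc <- data.frame(start_bin = integer(0), length_bins = integer(0),
                     n_events = integer(0))
  } else {
    counts <- tabulate(s %/% binWidth + 1L, nbins = nBins)
    occ <- counts > 0L
    r <- rle(occ)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    cc <- data.frame(
      start_bin = starts[keep] - 1L,
      length_bins = r$lengths[keep],
      n_events = vapply(keep, function(k)
        sum(counts[starts[k]:ends[k]]), integer(1))
    )
  }
  new("AvalancheSet", cascades = cc, threshold = as.numeric(threshold),
      binWidth = binWidth, nBins = nBins)
}

#' Choose the z threshold whose cascade count best matches the trial count
#'
#' Runs detection and binning for each candidate threshold and returns the
#' candidate minimizing `|cascade count - targetCount|`; ties break toward
#' the larger (stricter) threshold.
#'
#' @param eeg an [EEGRecording-class].
#' @param thresholds candidate SD multiples (default `c(3.2, 3.5, 3.7)`).
#' @param binWidth bin width in samples (default 2).
#' @param targetCount desired cascade count (the number of trials).
#' @param side passed to [detectEvents()].
#' @return the winning [AvalancheSet-class] (its `threshold` slot records
#'   the selected candidate).
#' @export
selectThreshold <- function(eeg, thresholds = c(3.2, 3.5, 3.7), binWidth = 2L,
                            targetCount, side = "both") {
  if (!length(thresholds)) stop("need at least one candidate threshold")
  sets <- lapply(thresholds, function(th)
    binCascades(detectEvents(eeg, th, side = side), nSamples(eeg),
                binWidth, threshold = th))
  gaps <- abs(vapply(sets, length, integer(1)) - targetCount)
  ord <- order(gaps, -thresholds)   # ties -> larger threshold
  sets[[ord[1L]]]
}

#' Pre-trial cascade length per trial
#'
#' For each trial, the length (in bins) of the cascade containing the
#' trial's bin; failing that, of the most recent cascade ending before it;
#' 0 if none. The event count of that cascade is reported alongside.
#'
#' @param avas an [AvalancheSet-class] from the same recording.
#' @param trials a [TrialTable-class].
#' @return data.frame with `trial`, `ava_length` (bins), `ava_events`.
#' @export
pretrialCascadeLength <- function(avas, trials) {
  stopifnot(is(avas, "AvalancheSet"), is(trials, "TrialTable"))
  cc <- cascadeTable(avas)
  bw <- avas@binWidth
  at <- trialSamples(trials)
  res <- t(vapply(at, function(t0) {
    b <- t0 %/% bw
    if (!nrow(cc)) return(c(0, 0))
    # cascades are ordered and non-overlapping: the last cascade starting at
    # or before b either contains b or is the most recent one ending before it
    k <- findInterval(b, cc$start_bin)
    if (k == 0L) return(c(0, 0))
    c(cc$length_bins[k], cc$n_events[k])
  }, numeric(2)))
  data.frame(trial = seq_along(at), ava_length = as.integer(res[, 1L]),
             ava_events = as.integer(res[, 2L]))
}
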