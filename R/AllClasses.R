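#' @include AllGenerics.R
NULL

# Central S4 containers. Sample indices are 0-based everywhere a trial or
# event position is stored, matching the on-disk table convention; R code
# converts at the point of matrix indexing.

#' Multichannel EEG recording
#'
#' A channels-by-samples matrix of scalp potentials with its sampling rate,
#' channel labels and subject identifier. This is the raw substrate every
#' trial-wise measure in the package is computed from.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot rate sampling rate in Hz (positive).
#' @slot channelLabels character vector, one label per channel.
#' @slot subjectID subject identifier.
#'
#' @examples
#' rec <- EEGRecording(matrix(rnorm(200), 2), rate = 50)
#' nChannels(rec); nSamples(rec)
#' @export
setClass("EEGRecording", representation(
  data = "matrix", rate = "numeric",
  channelLabels = "character", subjectID = "character"
))

setValidity("EEGRecording", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("data must be a numeric matrix")
  if (nrow(d) < 1L) return("need at least one channel")
  if (ncol(d) < 2L) return("need at least two samples")
  if (!all(is.finite(d))) return("all potentials must be finite")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    return("rate must be a single positive number")
  if (length(object@channelLabels) != nrow(d))
    return("channelLabels length must equal channel count")
  TRUE
})

#' @param data numeric matrix, channels x samples.
#' @param rate sampling rate in Hz.
#' @param channelLabels channel labels; defaults to ch01, ch02, ...
#' @param subjectID subject identifier.
#' @rdname EEGRecording-class
#' @export
EEGRecording <- function(data, rate,
                         channelLabels = sprintf("ch%02d", seq_len(nrow(data))),
                         subjectID = "s01") {
  new("EEGRecording", data = as.matrix(data), rate = as.numeric(rate),
      channelLabels = as.character(channelLabels),
      subjectID = as.character(subjectID))
}

#' @rdname EEGRecording-class
#' @aliases eegData,EEGRecording-method
#' @param x an `EEGRecording`.
#' @export
setMethod("eegData", "EEGRecording", function(x) x@data)

#' @rdname EEGRecording-class
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@rate)

#' @rdname EEGRecording-class
#' @export
setMethod("channelLabels", "EEGRecording", function(x) x@channelLabels)

#' @rdname EEGRecording-class
#' @export
setMethod("subjectID", "EEGRecording", function(x) x@subjectID)

#' @rdname EEGRecording-class
#' @export
setMethod("nChannels", "EEGRecording", function(x) nrow(x@data))

#' @rdname EEGRecording-class
#' @export
setMethod("nSamples", "EEGRecording", function(x) ncol(x@data))

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s': %d channels x %d samples @ %g Hz (%.1f s)\n",
              object@subjectID, nrow(object@data), ncol(object@data),
              object@rate, ncol(object@data) / object@rate))
})

#' Ordered trial markers with block membership
#'
#' Trial onsets as 0-based sample indices, each assigned to a block and a
#' block type (`"task"` or `"rest"`). The 1 s pre-trial analysis window of
#' every measure is the half-open interval `[t - rate, t)` ending at the
#' trial sample.
#'
#' @slot trialSample integer vector of 0-based sample indices, strictly increasing.
#' @slot blockID integer block id per trial.
#' @slot blockType `"task"` or `"rest"` per trial, constant within a block.
#' @export
setClass("TrialTable", representation(
  trialSample = "integer", blockID = "integer", blockType = "character"
))

setValidity("TrialTable", function(object) {
  n <- length(object@trialSample)
  if (length(object@blockID) != n || length(object@blockType) != n)
    return("slot lengths differ")
  if (n > 1L && any(diff(object@trialSample) <= 0L))
    return("trialSample must be strictly increasing")
  if (n > 0L && any(object@trialSample < 0L))
    return("trialSample indices are 0-based and must be nonnegative")
  if (!all(object@blockType %in% c("task", "rest")))
    return("blockType must be 'task' or 'rest'")
  for (b in unique(object@blockID))
    if (length(unique(object@blockType[object@blockID == b])) > 1L)
      return("blockType must be constant within a block")
  TRUE
})

#' @param trialSample 0-based trial sample indices.
#' @param blockID block id per trial.
#' @param blockType "task"/"rest" per trial.
#' @rdname TrialTable-class
#' @export
TrialTable <- function(trialSample, blockID, blockType) {
  new("TrialTable", trialSample = as.integer(trialSample),
      blockID = as.integer(blockID), blockType = as.character(blockType))
}

#' @rdname TrialTable-class
#' @param x a `TrialTable`.
#' @export
setMethod("trialSamples", "TrialTable", function(x) x@trialSample)

#' @rdname TrialTable-class
#' @export
setMethod("blockIDs", "TrialTable", function(x) x@blockID)

#' @rdname TrialTable-class
#' @export
setMethod("blockTypes", "TrialTable", function(x) x@blockType)

#' @rdname TrialTable-class
#' @export
setMethod("nTrials", "TrialTable", function(x) length(x@trialSample))

setMethod("length", "TrialTable", function(x) length(x@trialSample))

setMethod("show", "TrialTable", function(object) {
  tb <- table(object@blockType)
  cat(sprintf("TrialTable: %d trials in %d blocks (%s)\n",
              length(object@trialSample), length(unique(object@blockID)),
              paste(sprintf("%s=%d", names(tb), tb), collapse = ", ")))
})

#' Bank of standardized oscillatory templates
#'
#' One row per frequency on an increasing grid; every template is
#' standardized to zero mean and unit (sample) variance so that DTW
#' dissimilarity reflects waveform shape, not amplitude. Sine templates have
#' phase zero at the first sample.
#'
#' @slot shape `"sine"` or `"sawtooth"`.
#' @slot frequencies increasing grid in Hz.
#' @slot templates matrix, `length(frequencies)` x `nSamples`.
#' @slot rate sampling rate in Hz.
#' @export
setClass("TemplateBank", representation(
  shape = "character", frequencies = "numeric",
  templates = "matrix", rate = "numeric"
))

setValidity("TemplateBank", function(object) {
  if (!object@shape %in% c("sine", "sawtooth")) return("unknown template shape")
  if (nrow(object@templates) != length(object@frequencies))
    return("one template row per frequency required")
  if (ncol(object@templates) < 2L) return("templates need >= 2 samples")
  if (is.unsorted(object@frequencies, strictly = TRUE))
    return("frequencies must be strictly increasing")
  TRUE
})

#' @rdname TemplateBank-class
#' @param x a `TemplateBank`.
#' @export
setMethod("frequencies", "TemplateBank", function(x) x@frequencies)

#' @rdname TemplateBank-class
#' @export
setMethod("templateMatrix", "TemplateBank", function(x) x@templates)

#' @rdname TemplateBank-class
#' @export
setMethod("samplingRate", "TemplateBank", function(x) x@rate)

#' @rdname TemplateBank-class
#' @export
setMethod("nSamples", "TemplateBank", function(x) ncol(x@templates))

setMethod("show", "TemplateBank", function(object) {
  f <- object@frequencies
  cat(sprintf("TemplateBank: %d %s templates, %g-%g Hz, %d samples @ %g Hz\n",
              length(f), object@shape, min(f), max(f),
              ncol(object@templates), object@rate))
})

#' Per-frequency spectrum of one pre-trial segment
#'
#' Holds either a DTW-spectrum (per-frequency dissimilarity; low = good
#' match, so the curve is inverted relative to a power spectrum) or a direct
#' DFT power spectrum on the same frequency grid.
#'
#' @slot kind `"dtw"` or `"dft"`.
#' @slot frequencies grid in Hz.
#' @slot values nonnegative dissimilarities (dtw) or powers (dft).
#' @export
setClass("SpectrumResult", representation(
  kind = "character", frequencies = "numeric", values = "numeric"
))

setValidity("SpectrumResult", function(object) {
  if (!object@kind %in% c("dtw", "dft")) return("kind must be 'dtw' or 'dft'")
  if (length(object@values) != length(object@frequencies))
    return("values and frequencies lengths differ")
  if (any(object@values < 0)) return("spectrum values must be nonnegative")
  TRUE
})

#' @rdname SpectrumResult-class
#' @param x a `SpectrumResult`.
#' @export
setMethod("frequencies", "SpectrumResult", function(x) x@frequencies)

#' @rdname SpectrumResult-class
#' @export
setMethod("spectrumValues", "SpectrumResult", function(x) x@values)

#' @rdname SpectrumResult-class
#' @export
setMethod("spectrumSD", "SpectrumResult", function(x) stats::sd(x@values))

setMethod("show", "SpectrumResult", function(object) {
  cat(sprintf("SpectrumResult (%s): %d bins %g-%g Hz, sd = %.4g\n",
              object@kind, length(object@frequencies),
              min(object@frequencies), max(object@frequencies),
              stats::sd(object@values)))
})

#' Warp path realizing a banded DTW alignment
#'
#' Matched index pairs (0-based) from `(0, 0)` to `(n-1, m-1)`; every step
#' increments one or both indices by one and respects the Sakoe-Chiba band.
#'
#' @slot pairs integer matrix with columns `i`, `j` (0-based).
#' @slot totalCost cumulative local cost along the path.
#' @slot window the band half-width the path was computed under.
#' @export
setClass("WarpPath", representation(
  pairs = "matrix", totalCost = "numeric", window = "integer"
))

setValidity("WarpPath", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must have two columns")
  if (nrow(p) < 1L) return("empty path")
  if (any(p[1L, ] != 0L)) return("path must start at (0, 0)")
  if (nrow(p) > 1L) {
    st <- diff(p)
    if (any(st < 0L) || any(st > 1L) || any(rowSums(st) < 1L))
      return("each step must increment i, j, or both by 1")
  }
  if (any(abs(p[, 1L] - p[, 2L]) > object@window))
    return("path leaves the Sakoe-Chiba band")
  if (object@totalCost < 0) return("totalCost must be nonnegative")
  TRUE
})

#' @rdname WarpPath-class
#' @param x a `WarpPath`.
#' @export
setMethod("warpPairs", "WarpPath", function(x) x@pairs)

#' @rdname WarpPath-class
#' @export
setMethod("totalCost", "WarpPath", function(x) x@totalCost)

setMethod("show", "WarpPath", function(object) {
  n <- nrow(object@pairs)
  cat(sprintf("WarpPath: %d steps (0,0)->(%d,%d), cost %.4g, window %d\n",
              n, object@pairs[n, 1L], object@pairs[n, 2L],
              object@totalCost, object@window))
})

#' Fitted microstate model
#'
#' `k` unit-norm, average-referenced centroid topographies, the back-fitted
#' per-sample label sequence, and the global field power series.
#'
#' @slot maps matrix, k x channels, rows unit-norm.
#' @slot labels integer map index (1..k) per sample.
#' @slot gfp nonnegative global field power per sample.
#' @export
setClass("MicrostateModel", representation(
  maps = "matrix", labels = "integer", gfp = "numeric"
))

setValidity("MicrostateModel", function(object) {
  nrm <- sqrt(rowSums(object@maps^2))
  if (any(abs(nrm - 1) > 1e-6)) return("map rows must be unit-norm")
  if (length(object@labels) != length(object@gfp))
    return("labels and gfp lengths differ")
  if (length(object@labels) &&
      (min(object@labels) < 1L || max(object@labels) > nrow(object@maps)))
    return("labels out of map range")
  if (any(object@gfp < 0)) return("gfp must be nonnegative")
  TRUE
})

#' @rdname MicrostateModel-class
#' @param x a `MicrostateModel`.
#' @export
setMethod("stateMaps", "MicrostateModel", function(x) x@maps)

#' @rdname MicrostateModel-class
#' @export
setMethod("stateLabels", "MicrostateModel", function(x) x@labels)

#' @rdname MicrostateModel-class
#' @export
setMethod("gfpValues", "MicrostateModel", function(x) x@gfp)

setMethod("show", "MicrostateModel", function(object) {
  cat(sprintf("MicrostateModel: %d maps x %d channels, %d labeled samples\n",
              nrow(object@maps), ncol(object@maps), length(object@labels)))
})

#' Detected avalanche/cascade set
#'
#' Non-overlapping maximal runs of consecutive occupied time bins, each bin
#' containing at least one suprathreshold point-process event on any channel.
#'
#' @slot cascades data.frame with columns `start_bin` (0-based),
#'   `length_bins`, `n_events`.
#' @slot threshold the z threshold (in SDs) the events were detected at.
#' @slot binWidth bin width in samples.
#' @slot nBins total number of bins spanned by the recording.
#' @export
setClass("AvalancheSet", representation(
  cascades = "data.frame", threshold = "numeric",
  binWidth = "integer", nBins = "integer"
))

setValidity("AvalancheSet", function(object) {
  cc <- object@cascades
  need <- c("start_bin", "length_bins", "n_events")
  if (!all(need %in% names(cc))) return("cascades needs start_bin/length_bins/n_events")
  if (nrow(cc)) {
    if (any(cc$length_bins < 1L) || any(cc$n_events < 1L))
      return("cascades must span >= 1 bin and contain >= 1 event")
    if (nrow(cc) > 1L) {
      ends <- cc$start_bin + cc$length_bins
      if (any(cc$start_bin[-1L] <= ends[-nrow(cc)]))
        return("cascades must be ordered and separated by >= 1 empty bin")
    }
  }
  if (object@binWidth < 1L) return("binWidth must be >= 1")
  TRUE
})

#' @rdname AvalancheSet-class
#' @param x an `AvalancheSet`.
#' @export
setMethod("cascadeTable", "AvalancheSet", function(x) x@cascades)

#' @rdname AvalancheSet-class
#' @export
setMethod("thresholdUsed", "AvalancheSet", function(x) x@threshold)

setMethod("length", "AvalancheSet", function(x) nrow(x@cascades))

setMethod("show", "AvalancheSet", function(object) {
  cat(sprintf("AvalancheSet: %d cascades (threshold %g SD, bin %d, %d bins)\n",
              nrow(object@cascades), object@threshold,
              object@binWidth, object@nBins))
})

.MEASURE_NAMES <- c("dtw_sd", "dft_sd", "sse", "ms_length", "mean_gfp", "ava_length")

#' Per-trial table of the six scalar measures
#'
#' One row per trial holding the six trial-wise measures: the SD of the
#' DTW-spectrum (`dtw_sd`), the SD of the DFT spectrum (`dft_sd`), the MLP
#' one-step prediction error (`sse`), the pre-trial microstate length in
#' samples (`ms_length`), the mean GFP over that microstate (`mean_gfp`),
#' and the pre-trial avalanche length in bins (`ava_length`), together with
#' the trial position and block membership needed to split by condition.
#'
#' @slot subjectID subject identifier.
#' @slot measures data.frame with columns `trial`, `trial_sample`,
#'   `block_id`, `block_type`, then the six measures.
#' @export
setClass("TrialMeasures", representation(
  subjectID = "character", measures = "data.frame"
))

setValidity("TrialMeasures", function(object) {
  m <- object@measures
  need <- c("trial", "trial_sample", "block_id", "block_type", .MEASURE_NAMES)
  if (!all(need %in% names(m)))
    return(paste("measures must contain columns:", paste(need, collapse = ", ")))
  num <- m[, .MEASURE_NAMES]
  if (nrow(m) && any(!is.finite(as.matrix(num))))
    return("all measure values must be finite (no missing values)")
  if (nrow(m) && any(as.matrix(num) < 0))
    return("measures are nonnegative")
  TRUE
})

#' @param subjectID subject identifier.
#' @param measures the per-trial data.frame (see slots).
#' @rdname TrialMeasures-class
#' @export
TrialMeasures <- function(subjectID, measures) {
  new("TrialMeasures", subjectID = as.character(subjectID),
      measures = as.data.frame(measures))
}

#' @rdname TrialMeasures-class
#' @param x a `TrialMeasures`.
#' @export
setMethod("measuresTable", "TrialMeasures", function(x) x@measures)

#' @rdname TrialMeasures-class
#' @export
setMethod("subjectID", "TrialMeasures", function(x) x@subjectID)

#' @rdname TrialMeasures-class
#' @export
setMethod("nTrials", "TrialMeasures", function(x) nrow(x@measures))

setMethod("show", "TrialMeasures", function(object) {
  cat(sprintf("TrialMeasures '%s': %d trials x %d measures\n",
              object@subjectID, nrow(object@measures), length(.MEASURE_NAMES)))
})

#' Names of the six trial-wise measures
#' @return character vector of measure column names.
#' @export
measureNames <- function() .MEASURE_NAMES

#' Group-level cross-prediction result
#'
#' Long-format table with one row per (condition, target, predictor) cell:
#' the rep-averaged group mean beta, one-sample t statistic, raw two-sided
#' p, BH-FDR adjusted p (family = all off-diagonal cells of the condition),
#' and the within-subject trial-permutation p.
#'
#' @slot table data.frame with columns `condition`, `target`, `predictor`,
#'   `beta`, `t`, `p`, `p_fdr`, `p_perm`.
#' @slot alpha FDR level used.
#' @slot nPerm number of permutations used.
#' @export
setClass("ComparisonResult", representation(
  table = "data.frame", alpha = "numeric", nPerm = "integer"
))

setValidity("ComparisonResult", function(object) {
  tb <- object@table
  need <- c("condition", "target", "predictor", "beta", "t", "p", "p_fdr", "p_perm")
  if (!all(need %in% names(tb))) return("missing result columns")
  if (any(tb$target == tb$predictor)) return("diagonal cells must be excluded")
  pv <- c(tb$p, tb$p_fdr, tb$p_perm)
  pv <- pv[!is.na(pv)]
  if (length(pv) && (any(pv < 0) || any(pv > 1))) return("p values out of [0, 1]")
  TRUE
})

#' @rdname ComparisonResult-class
#' @param x a `ComparisonResult`.
#' @export
setMethod("comparisonTable", "ComparisonResult", function(x) x@table)

setMethod("show", "ComparisonResult", function(object) {
  tb <- object@table
  cat(sprintf("ComparisonResult: %d cells, conditions: %s; FDR alpha %g, %d permutations\n",
              nrow(tb), paste(unique(tb$condition), collapse = "/"),
              object@alpha, object@nPerm))
  sig <- tb[!is.na(tb$p_fdr) & tb$p_fdr <= object@alpha, ]
  if (nrow(sig)) {
    cat("significant (FDR):\n")
    print(sig[, c("condition", "target", "predictor", "beta", "t", "p_fdr")],
          row.names = FALSE)
  } else cat("no cells significant at FDR alpha\n")
})

#' Trained one-step MLP predictor
#'
#' Single hidden layer with tanh activations and a linear output, trained by
#' full-batch-partitioned gradient descent on squared error.
#'
#' @slot W1,b1 input-to-hidden weights and biases.
#' @slot W2,b2 hidden-to-output weights and bias.
#' @slot trainSSE final training sum of squared errors.
#' @slot nLags number of extra lagged inputs (input size is `nLags + 1`).
#' @slot seedUsed the seed the returned (sub-threshold) model was initialized from.
#' @slot retrains how many re-initializations were needed.
#' @export
setClass("MLPModel", representation(
  W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
  trainSSE = "numeric", nLags = "integer",
  seedUsed = "integer", retrains = "integer"
))

setValidity("MLPModel", function(object) {
  if (!all(is.finite(object@W1)) || !all(is.finite(object@W2)) ||
      !all(is.finite(object@b1)) || !all(is.finite(object@b2)))
    return("model parameters must be finite")
  if (object@trainSSE < 0) return("trainSSE must be nonnegative")
  TRUE
})

setMethod("show", "MLPModel", function(object) {
  cat(sprintf("MLPModel: %d -> %d -> 1 (tanh/linear), train SSE %.4g, %d retrain(s)\n",
              ncol(object@W1), nrow(object@W1), object@trainSSE, object@retrains))
})
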