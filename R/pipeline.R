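# End-to-end per-subject and study-level measure extraction: runs the
# spectrum sweep, the MLP predictor, the microstate pipeline and the
# avalanche detector over the same trial table and assembles the six
# trial-wise measures into one TrialMeasures object per subject.

#' Compute all six trial-wise measures for one recording
#'
#' @param eeg an [EEGRecording-class].
#' @param trials a [TrialTable-class].
#' @param channel single channel used for the spectra and the MLP
#'   (index or label; default 1).
#' @param msLabels,gfp optional precomputed microstate labels and GFP
#'   series (e.g. back-fitted group maps); when `NULL` a per-subject
#'   microstate model is fitted with [clusterMaps()].
#' @param k microstate count for the per-subject fallback (default 12).
#' @param fLo,fHi,step,window spectrum parameters (defaults 8, 13, 0.1 Hz,
#'   band 20).
#' @param thresholds,binWidth avalanche parameters.
#' @param seed RNG seed (k-means restarts, MLP init).
#' @param ... further arguments to [trialSSE()].
#' @return a [TrialMeasures-class].
#' @export
computeTrialMeasures <- function(eeg, trials, channel = 1L,
                                 msLabels = NULL, gfp = NULL, k = 12L,
                                 fLo = 8, fHi = 13, step = 0.1, window = 20L,
                                 thresholds = c(3.2, 3.5, 3.7), binWidth = 2L,
                                 seed = 1L, ...) {
  stopifnot(is(eeg, "EEGRecording"), is(trials, "TrialTable"))
  sp <- trialSpectra(eeg, trials, channel, fLo = fLo, fHi = fHi, step = step,
                     window = window)
  ss <- trialSSE(eeg, trials, channel, seed = seed, ...)
  if (is.null(gfp)) gfp <- globalFieldPower(eeg)
  if (is.null(msLabels)) {
    pk <- detectGFPPeaks(gfp)
    maps <- clusterMaps(t(eegData(eeg)[, pk + 1L, drop = FALSE]),
                        k = k, seed = seed)
    msLabels <- backfit(eeg, maps)
  }
  ms <- pretrialMicrostates(msLabels, gfp, trials)
  avas <- selectThreshold(eeg, thresholds, binWidth,
                          targetCount = nTrials(trials))
  av <- pretrialCascadeLength(avas, trials)
  df <- data.frame(trial = seq_len(nTrials(trials)),
                   trial_sample = trialSamples(trials),
                   block_id = blockIDs(trials),
                   block_type = blockTypes(trials),
                   dtw_sd = sp$dtw_sd, dft_sd = sp$dft_sd, sse = ss$sse,
                   ms_length = ms$ms_length, mean_gfp = ms$mean_gfp,
                   ava_length = av$ava_length)
  TrialMeasures(subjectID(eeg), df)
}

#' Compute the six measures for every subject of a study
#'
#' Microstate maps are clustered once at the group level (pooled GFP-peak
#' topographies) and back-fitted per subject; everything else is
#' per subject.
#'
#' @param study list of per-subject lists with elements `eeg` and `trials`
#'   (e.g. from [simulateStudy()]).
#' @param channel,k,seed,... as in [computeTrialMeasures()].
#' @return list of [TrialMeasures-class], one per subject.
#' @export
computeStudyMeasures <- function(study, channel = 1L, k = 12L, seed = 1L, ...) {
  ms <- microstatePipeline(lapply(study, `[[`, "eeg"),
                           lapply(study, `[[`, "trials"),
                           k = k, seed = seed)
  lapply(seq_along(study), function(s)
    computeTrialMeasures(study[[s]]$eeg, study[[s]]$trials, channel = channel,
                         msLabels = stateLabels(ms$perSubject[[s]]$model),
                         gfp = gfpValues(ms$perSubject[[s]]$model),
                         seed = seed, ...))
}
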