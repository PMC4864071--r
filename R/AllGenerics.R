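#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @export
setGeneric("subjectID", function(x) standardGeneric("subjectID"))

#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("eegData", function(x) standardGeneric("eegData"))

#' @export
setGeneric("trialSamples", function(x) standardGeneric("trialSamples"))

#' @export
setGeneric("blockIDs", function(x) standardGeneric("blockIDs"))

#' @export
setGeneric("blockTypes", function(x) standardGeneric("blockTypes"))

#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @export
setGeneric("spectrumValues", function(x) standardGeneric("spectrumValues"))

#' @export
setGeneric("spectrumSD", function(x) standardGeneric("spectrumSD"))

#' @export
setGeneric("templateMatrix", function(x) standardGeneric("templateMatrix"))

#' @export
setGeneric("stateMaps", function(x) standardGeneric("stateMaps"))

#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @export
setGeneric("gfpValues", function(x) standardGeneric("gfpValues"))

#' @export
setGeneric("cascadeTable", function(x) standardGeneric("cascadeTable"))

#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))

#' @export
setGeneric("measuresTable", function(x) standardGeneric("measuresTable"))

#' @export
setGeneric("comparisonTable", function(x) standardGeneric("comparisonTable"))

#' @export
setGeneric("warpPairs", function(x) standardGeneric("warpPairs"))

#' @export
setGeneric("totalCost", function(x) standardGeneric("totalCost"))
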