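# Plain-text readers/writers. Matrices are delimited text (comma or tab,
# auto-detected); tables are TSV; the EEG sidecar is JSON. All writes are
# atomic (temp file in the target directory + rename).

.detectSep <- function(path) {
  l1 <- readLines(path, n = 1L)
  if (grepl("\t", l1)) "\t" else ","
}

#' Read an EEG recording from a delimited matrix plus JSON sidecar
#'
#' The matrix file holds one channel per row (comma- or tab-separated,
#' auto-detected, no header). The sidecar is a JSON object with fields
#' `rate`, `channel_labels` and `subject_id`.
#'
#' @param path matrix file.
#' @param metaPath JSON sidecar; defaults to `<path>.json`.
#' @return an [EEGRecording-class].
#' @seealso [writeEEG()]
#' @export
readEEG <- function(path, metaPath = paste0(path, ".json")) {
  if (!file.exists(path)) stop("no such EEG matrix file: ", path)
  if (!file.exists(metaPath)) stop("missing sidecar metadata file: ", metaPath)
  meta <- jsonlite::fromJSON(metaPath)
  if (is.null(meta$rate)) stop("sidecar is missing the sampling rate")
  sep <- .detectSep(path)
  rows <- strsplit(readLines(path), sep, fixed = TRUE)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("ragged matrix: row lengths ", paste(unique(lens), collapse = "/"))
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  if (anyNA(vals) || !all(is.finite(vals)))
    stop("non-numeric or non-finite cell in EEG matrix ", path)
  dat <- matrix(vals, nrow = length(rows), byrow = TRUE)
  labs <- if (!is.null(meta$channel_labels)) as.character(meta$channel_labels)
          else sprintf("ch%02d", seq_len(nrow(dat)))
  EEGRecording(dat, rate = meta$rate, channelLabels = labs,
               subjectID = if (!is.null(meta$subject_id)) meta$subject_id else "s01")
}

#' Write an EEG recording to a delimited matrix plus JSON sidecar
#'
#' @param rec an [EEGRecording-class].
#' @param path output matrix file (tab-separated).
#' @param metaPath sidecar path; defaults to `<path>.json`.
#' @return the matrix path, invisibly.
#' @export
writeEEG <- function(rec, path, metaPath = paste0(path, ".json")) {
  stopifnot(is(rec, "EEGRecording"))
  .writeAtomic(function(tmp) {
    utils::write.table(eegData(rec), tmp, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }, path)
  .writeAtomic(function(tmp) {
    jsonlite::write_json(list(rate = samplingRate(rec),
                              channel_labels = channelLabels(rec),
                              subject_id = subjectID(rec)),
                         tmp, auto_unbox = TRUE, digits = NA)
  }, metaPath)
  invisible(path)
}

#' Read a trial table (TSV)
#'
#' Expects columns `trial_sample` (0-based), `block_id`, `block_type`
#' (task/rest).
#'
#' @param path TSV file.
#' @return a [TrialTable-class].
#' @export
readTrials <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("trial_sample", "block_id", "block_type")
  if (!all(need %in% names(tb)))
    stop("trial table needs columns: ", paste(need, collapse = ", "))
  if (is.unsorted(tb$trial_sample, strictly = TRUE))
    stop("trial_sample must be strictly increasing")
  if (!all(tb$block_type %in% c("task", "rest")))
    stop("unknown block_type token: ",
         paste(setdiff(unique(tb$block_type), c("task", "rest")), collapse = ", "))
  TrialTable(tb$trial_sample, tb$block_id, tb$block_type)
}

#' Write a trial table (TSV)
#' @param trials a [TrialTable-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTrials <- function(trials, path) {
  stopifnot(is(trials, "TrialTable"))
  df <- data.frame(trial_sample = trialSamples(trials),
                   block_id = blockIDs(trials),
                   block_type = blockTypes(trials))
  .writeAtomic(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  }, path)
}

#' Write per-trial measures (TSV)
#'
#' Emits `trial`, `trial_sample`, `block_id`, `block_type` plus the six
#' measure columns in the fixed order of [measureNames()].
#'
#' @param measures a [TrialMeasures-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMeasures <- function(measures, path) {
  stopifnot(is(measures, "TrialMeasures"))
  m <- measuresTable(measures)
  cols <- c("trial", "trial_sample", "block_id", "block_type", measureNames())
  if (nrow(m) && any(!is.finite(as.matrix(m[, measureNames()]))))
    stop("measures table contains missing values")
  df <- m[, cols]
  attr(df, "subject") <- NULL
  .writeAtomic(function(tmp) {
    con <- file(tmp, "w")
    on.exit(close(con))
    writeLines(paste0("# subject: ", subjectID(measures)), con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  }, path)
}

#' Read per-trial measures written by [writeMeasures()]
#' @param path TSV path.
#' @return a [TrialMeasures-class].
#' @export
readMeasures <- function(path) {
  first <- readLines(path, n = 1L)
  subj <- if (startsWith(first, "# subject: ")) sub("^# subject: ", "", first) else "s01"
  tb <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  TrialMeasures(subj, tb)
}
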