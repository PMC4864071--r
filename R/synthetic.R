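# Seeded generators for the block-design study the measures are defined on:
# multichannel EEG with planted microstate topographies, band-limited alpha
# whose amplitude depends on block type, 1/f background noise with
# block-dependent SD (rest noisier, hence less predictable, by
# construction), rare high-amplitude multi-channel transients, evenly
# spaced trials, plus null-measure tables and BOLD-style network courses
# for statistical calibration.

#' Synthetic-study configuration
#'
#' Defaults emulate the working layout every measure expects: 15 subjects,
#' 5 alternating 60 s task/rest blocks at 50 Hz, 112 trials total
#' (23/23/22/22/22 per block), 32 channels, 4 planted microstate maps with
#' a geometric dwell of mean 80 ms, 10 Hz alpha (weaker in task), 1/f
#' background (quieter in task), and multi-channel transients at 0.1/s.
#'
#' @param nSubjects,nChannels,rate,nBlocks,nTrials study layout.
#' @param blockLenSec block length in seconds (default 60).
#' @param kStates,stateDwellMean,stateAmp planted microstate sequence:
#'   number of maps, mean geometric dwell in samples, amplitude scale.
#' @param alphaFreq alpha frequency in Hz (within 8-13).
#' @param alphaAmpTask,alphaAmpRest alpha amplitude per block type.
#' @param alphaDriftSd SD of the per-sample random phase-drift increments.
#' @param noiseSdTask,noiseSdRest 1/f background SD per block type.
#' @param noiseColor `"pink"` (1/f, default) or `"white"`.
#' @param eventRate transient rate per second.
#' @param eventAmp transient amplitude in multiples of the block noise SD.
#' @param coupling optional list of `list(target=, predictor=, beta=)`
#'   entries used by [generateBOLD()].
#' @return a validated configuration list of class `SynthConfig`.
#' @export
synthConfig <- function(nSubjects = 15L, nChannels = 32L, rate = 50,
                        nBlocks = 5L, nTrials = 112L, blockLenSec = 60,
                        kStates = 4L, stateDwellMean = 4, stateAmp = 0.5,
                        alphaFreq = 10, alphaAmpTask = 0.8, alphaAmpRest = 1.0,
                        alphaDriftSd = 0.03, noiseSdTask = 0.3,
                        noiseSdRest = 1.2, noiseColor = c("pink", "white"),
                        eventRate = 0.1, eventAmp = 6, coupling = list()) {
  noiseColor <- match.arg(noiseColor)
  cfg <- list(nSubjects = as.integer(nSubjects), nChannels = as.integer(nChannels),
              rate = rate, nBlocks = as.integer(nBlocks),
              nTrials = as.integer(nTrials), blockLenSec = blockLenSec,
              kStates = as.integer(kStates), stateDwellMean = stateDwellMean,
              stateAmp = stateAmp, alphaFreq = alphaFreq,
              alphaAmpTask = alphaAmpTask, alphaAmpRest = alphaAmpRest,
              alphaDriftSd = alphaDriftSd, noiseSdTask = noiseSdTask,
              noiseSdRest = noiseSdRest, noiseColor = noiseColor,
              eventRate = eventRate, eventAmp = eventAmp, coupling = coupling)
  with(cfg, {
    if (any(c(nSubjects, nChannels, nBlocks, nTrials, kStates) < 1L))
      stop("all counts must be positive")
    if (rate <= 0 || blockLenSec <= 0) stop("rate and block length must be positive")
    if (alphaFreq < 8 || alphaFreq > 13) stop("alphaFreq must lie in [8, 13] Hz")
    if (stateDwellMean < 1) stop("stateDwellMean must be >= 1 sample")
    if (min(alphaAmpTask, alphaAmpRest, noiseSdTask, noiseSdRest,
            eventRate) < 0) stop("amplitudes and rates must be nonnegative")
  })
  structure(cfg, class = "SynthConfig")
}

# split nTrials across nBlocks as evenly as possible, extras to early blocks
.trialsPerBlock <- function(nTrials, nBlocks) {
  base <- nTrials %/% nBlocks
  extra <- nTrials %% nBlocks
  base + as.integer(seq_len(nBlocks) <= extra)
}

#' Generate one subject's recording, trial table and ground truth
#'
#' The signal is the sum of (i) a planted microstate topography sequence —
#' geometric dwell times over `kStates` orthonormal average-referenced maps,
#' amplitude-modulated by a smooth positive envelope, (ii) a band-limited
#' alpha sinusoid with slow random phase drift and block-dependent
#' amplitude, (iii) 1/f-shaped (or white) background noise with
#' block-dependent SD, and (iv) rare high-amplitude multi-channel transients
#' (shared latent spike times a per-channel loading). Trials are evenly
#' spaced within blocks. Fully reproducible from the seed.
#'
#' @param cfg a [synthConfig()].
#' @param seed RNG seed.
#' @param subjectID subject identifier.
#' @return list with `eeg` ([EEGRecording-class]), `trials`
#'   ([TrialTable-class]) and `truth` (list: `stateLabels`, `maps`,
#'   `eventSamples`, `alphaFreq`, per-block parameters).
#' @export
simulateSubject <- function(cfg = synthConfig(), seed = 1L, subjectID = "s01") {
  stopifnot(inherits(cfg, "SynthConfig"))
  .withSeed(seed, {
    blockLen <- as.integer(round(cfg$blockLenSec * cfg$rate))
    nSamp <- blockLen * cfg$nBlocks
    nCh <- cfg$nChannels
    btype <- rep(c("task", "rest"), length.out = cfg$nBlocks)
    typeOf <- rep(btype, each = blockLen)

    # planted microstate sequence
    M <- qr.Q(qr(matrix(stats::rnorm(nCh * cfg$kStates), nCh)))
    M <- M - rep(colMeans(M), each = nCh)
    M <- M / rep(sqrt(colSums(M^2)), each = nCh)
    lab <- integer(nSamp)
    pos <- 1L; cur <- sample.int(cfg$kStates, 1L)
    while (pos <= nSamp) {
      dwell <- stats::rgeom(1L, 1 / cfg$stateDwellMean) + 1L
      lab[pos:min(nSamp, pos + dwell - 1L)] <- cur
      pos <- pos + dwell
      cur <- if (cfg$kStates > 1L)
        sample(setdiff(seq_len(cfg$kStates), cur), 1L) else cur
    }
    env <- abs(stats::filter(stats::rnorm(nSamp), rep(1, 5) / 5,
                             circular = TRUE)) + 0.2
    env <- as.numeric(env) / stats::sd(env)
    X <- M[, lab] * rep(env, each = nCh) * cfg$stateAmp

    # alpha with slow phase drift, block-dependent amplitude
    drift <- cumsum(stats::rnorm(nSamp, sd = cfg$alphaDriftSd))
    phase <- 2 * pi * cfg$alphaFreq * (0:(nSamp - 1L)) / cfg$rate + drift
    amp <- ifelse(typeOf == "task", cfg$alphaAmpTask, cfg$alphaAmpRest)
    # alpha is treated as a near-uniform (common-mode) field: per-channel
    # loadings stay close to 1 so average-referencing removes most of it
    # from the instantaneous topography, leaving the planted maps to carry
    # the microstate structure
    loading <- abs(stats::rnorm(nCh, 1, 0.05))
    X <- X + outer(loading, amp * sin(phase))

    # background noise, block-dependent SD
    nsd <- ifelse(typeOf == "task", cfg$noiseSdTask, cfg$noiseSdRest)
    for (ch in seq_len(nCh)) {
      bg <- if (cfg$noiseColor == "pink") .pinkNoise(nSamp)
            else stats::rnorm(nSamp)
      X[ch, ] <- X[ch, ] + bg * nsd
    }

    # rare multi-channel transients
    nEv <- stats::rpois(1L, cfg$eventRate * nSamp / cfg$rate)
    evAt <- sort(sample.int(nSamp, min(nEv, nSamp)))
    if (length(evAt)) {
      w <- abs(stats::rnorm(nCh, 1, 0.5))
      for (t in evAt)
        X[, t] <- X[, t] + w * cfg$eventAmp * nsd[t] * sample(c(-1, 1), 1L)
    }

    # evenly spaced trials, first one clear of the pre-trial + lag window
    perBlock <- .trialsPerBlock(cfg$nTrials, cfg$nBlocks)
    margin <- as.integer(round(cfg$rate)) + 45L
    at <- unlist(lapply(seq_len(cfg$nBlocks), function(b) {
      (b - 1L) * blockLen +
        as.integer(round(seq(margin, blockLen - 10L,
                             length.out = perBlock[b])))
    }))
    trials <- TrialTable(at, rep(seq_len(cfg$nBlocks), perBlock),
                         rep(btype, perBlock))
    list(eeg = EEGRecording(X, cfg$rate, subjectID = subjectID),
         trials = trials,
         truth = list(stateLabels = lab, maps = t(M),
                      eventSamples = evAt - 1L, alphaFreq = cfg$alphaFreq,
                      blockType = btype, envelope = env))
  })
}

#' Generate the full multi-subject study
#'
#' @param cfg a [synthConfig()].
#' @param seed master seed; per-subject seeds are derived from it.
#' @return list of per-subject lists as returned by [simulateSubject()].
#' @export
simulateStudy <- function(cfg = synthConfig(), seed = 1L) {
  seeds <- .withSeed(seed, sample.int(.Machine$integer.max %/% 2L,
                                      cfg$nSubjects))
  lapply(seq_len(cfg$nSubjects), function(s)
    simulateSubject(cfg, seed = seeds[s], subjectID = sprintf("s%02d", s)))
}

#' Microstate-recovery fixture
#'
#' A generator preset that isolates the planted topographic dynamics:
#' 4 orthonormal maps, geometric dwell of mean 80 ms (4 samples at 50 Hz),
#' state-amplitude-to-noise ratio 3 with white sensor noise, alpha and
#' transients off. One subject, 120 s.
#'
#' @param seed RNG seed.
#' @param snr state-amplitude-to-noise ratio (default 3).
#' @return as [simulateSubject()].
#' @export
microstateFixture <- function(seed = 1L, snr = 3) {
  cfg <- synthConfig(nSubjects = 1L, blockLenSec = 24, nTrials = 20L,
                     stateAmp = snr, alphaAmpTask = 0, alphaAmpRest = 0,
                     noiseSdTask = 1, noiseSdRest = 1, noiseColor = "white",
                     eventRate = 0)
  simulateSubject(cfg, seed = seed, subjectID = "msfix")
}

#' Independent standard-normal null measures
#'
#' Six mutually independent N(0, 1) measure columns per subject over the
#' default block layout — an exchangeable null for permutation and FDR
#' calibration. `ms_length`/`ava_length` are shifted to be nonnegative
#' (adding a constant changes no test statistic).
#'
#' @param nSubjects,nTrials counts (defaults 15 and 112).
#' @param seed RNG seed.
#' @return list of [TrialMeasures-class].
#' @export
generateNullMeasures <- function(nSubjects = 15L, nTrials = 112L, seed = 1L) {
  nBlocks <- 5L
  perBlock <- .trialsPerBlock(nTrials, nBlocks)
  blockLen <- 3000L
  at <- unlist(lapply(seq_len(nBlocks), function(b)
    (b - 1L) * blockLen + as.integer(round(seq(95, blockLen - 10,
                                               length.out = perBlock[b])))))
  btype <- rep(c("task", "rest"), length.out = nBlocks)
  .withSeed(seed, lapply(seq_len(nSubjects), function(s) {
    m <- matrix(stats::rnorm(nTrials * 6L), nTrials)
    colnames(m) <- measureNames()
    df <- data.frame(trial = seq_len(nTrials), trial_sample = at,
                     block_id = rep(seq_len(nBlocks), perBlock),
                     block_type = rep(btype, perBlock), m + 10)
    TrialMeasures(sprintf("s%02d", s), df)
  }))
}

#' BOLD-style network time courses coupled to trial measures
#'
#' Each network course is a sum of beta-weighted, HRF-convolved,
#' TR-resampled trial-measure regressors plus white noise — a stand-in for
#' network time courses obtained by spatial regression of resting-state
#' network maps against fMRI data (synthetic; no haemodynamic model beyond
#' the canonical double-gamma kernel).
#'
#' @param measures a [TrialMeasures-class] for one subject.
#' @param trials the matching [TrialTable-class].
#' @param rate EEG sampling rate in Hz.
#' @param tr repetition time in seconds (default 2).
#' @param coupling list of `list(network=, measure=, beta=)` entries.
#' @param nNetworks number of network courses (default 3).
#' @param noiseSd white-noise SD added to each course (default 1).
#' @param seed RNG seed.
#' @return matrix, scans x networks.
#' @export
generateBOLD <- function(measures, trials, rate = 50, tr = 2,
                         coupling = list(), nNetworks = 3L, noiseSd = 1,
                         seed = 1L) {
  stopifnot(is(measures, "TrialMeasures"), is(trials, "TrialTable"))
  df <- measuresTable(measures)
  nSamp <- max(trialSamples(trials)) + as.integer(round(rate))
  nScans <- as.integer(floor(nSamp / (tr * rate)))
  out <- matrix(0, nScans, nNetworks)
  colnames(out) <- sprintf("net%02d", seq_len(nNetworks))
  for (cp in coupling) {
    if (!cp$measure %in% measureNames())
      stop("unknown measure in coupling: ", cp$measure)
    j <- if (is.character(cp$network)) match(cp$network, colnames(out))
         else cp$network
    reg <- .measureRegressor(df[[cp$measure]], trialSamples(trials), nSamp,
                             rate, tr, nScans)
    out[, j] <- out[, j] + cp$beta * .zstd(reg)
  }
  .withSeed(seed, out + matrix(stats::rnorm(length(out), sd = noiseSd),
                               nrow(out)))
}

#' Synthetic alpha-burst pre-trial segments
#'
#' One-second segments in which a random-frequency alpha oscillation
#' (random phase, slow phase drift) clearly dominates a 1/f background —
#' the regime in which DTW- and DFT-spectra are strongly inversely
#' rank-correlated.
#'
#' @param n number of segments (default 200).
#' @param nSamples segment length (default 50).
#' @param rate sampling rate (default 50 Hz).
#' @param fLo,fHi alpha frequency range the burst is drawn from.
#' @param alphaAmp oscillation amplitude (default 1).
#' @param noiseSd 1/f background SD (default 0.3).
#' @param driftSd phase-drift increment SD (default 0.05).
#' @param seed RNG seed.
#' @return list with `segments` (n x nSamples matrix) and `freq` (the true
#'   burst frequency per segment).
#' @export
alphaBurstSegments <- function(n = 200L, nSamples = 50L, rate = 50,
                               fLo = 8, fHi = 13, alphaAmp = 1,
                               noiseSd = 0.3, driftSd = 0.05, seed = 1L) {
  .withSeed(seed, {
    freq <- stats::runif(n, fLo, fHi)
    seg <- t(vapply(seq_len(n), function(i) {
      ph <- stats::runif(1, 0, 2 * pi)
      drift <- cumsum(stats::rnorm(nSamples, sd = driftSd))
      s <- alphaAmp * sin(2 * pi * freq[i] * (0:(nSamples - 1L)) / rate +
                          ph + drift)
      s + .pinkNoise(nSamples) * noiseSd
    }, numeric(nSamples)))
    list(segments = seg, freq = freq)
  })
}
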