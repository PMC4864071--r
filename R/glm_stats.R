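# Cross-prediction statistics: per-subject OLS GLMs among the six trial-wise
# measures, one-sample group t-tests on the betas, BH-FDR over each
# condition's off-diagonal family, a within-subject trial-permutation null,
# double-gamma HRF convolution for BOLD-style regressors, and averaging over
# seeded pipeline repetitions.

# Build the z-scored design for one subject. A constant predictor column is
# rank-deficient next to the intercept: strict callers error; the comparison
# layer drops it (it carries no trial-wise information, so its beta is 0).
.designFor <- function(df, target, predictors, allowConstant = FALSE) {
  sds <- vapply(predictors, function(p) stats::sd(df[[p]]), numeric(1))
  if (any(sds == 0) && !allowConstant)
    stop("singular design: constant predictor(s) ",
         paste(predictors[sds == 0], collapse = ", "))
  keep <- predictors[sds > 0]
  Z <- vapply(keep, function(p) .zstd(df[[p]]), numeric(nrow(df)))
  X <- cbind(`(Intercept)` = 1, Z)
  qr <- qr(X)
  if (qr$rank < ncol(X))
    stop("singular design: predictors are linearly dependent")
  list(X = X, y = df[[target]], qr = qr, keep = keep)
}

#' Per-subject GLM of one measure on the other five
#'
#' Ordinary least squares of the target measure on the z-scored (within
#' subject) remaining measures plus an intercept.
#'
#' @param measures a [TrialMeasures-class] or its data.frame; only the
#'   supplied rows are used, so subset by condition before calling.
#' @param target one of [measureNames()].
#' @param predictors predictor measures (default: all others).
#' @param allowConstant if `TRUE`, a constant predictor column is dropped
#'   from the design and reported with coefficient 0 instead of raising a
#'   singular-design error (used by [runComparison()], where a degenerate
#'   measure in one condition must not abort the whole matrix).
#' @return named numeric vector of predictor coefficients (intercept
#'   dropped).
#' @export
fitTrialGLM <- function(measures, target,
                        predictors = setdiff(measureNames(), target),
                        allowConstant = FALSE) {
  df <- if (is(measures, "TrialMeasures")) measuresTable(measures) else measures
  if (!target %in% names(df)) stop("unknown target measure: ", target)
  if (nrow(df) < length(predictors) + 2L)
    stop("need at least ", length(predictors) + 2L, " trials")
  d <- .designFor(df, target, predictors, allowConstant)
  beta <- stats::setNames(numeric(length(predictors)), predictors)
  # a constant target has slope exactly 0 everywhere; computing it through
  # the QR would leave signed rounding noise (~1e-13) that a group t-test
  # across subjects could mistake for a consistent effect
  if (stats::sd(d$y) > 0)
    beta[d$keep] <- qr.coef(d$qr, d$y)[-1L]
  beta
}

#' One-sample group t-test on per-subject betas
#'
#' @param betas one coefficient per subject (length >= 2, nonzero variance).
#' @return list with `t`, `p` (two-sided), `df`, `mean`.
#' @export
groupTTest <- function(betas) {
  betas <- as.numeric(betas)
  if (length(betas) < 2L) stop("need at least 2 subjects")
  if (stats::sd(betas) == 0)
    stop("degenerate: zero variance across subjects (all betas ",
         betas[1L], ")")
  ht <- stats::t.test(betas, mu = 0)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean = mean(betas))
}

#' Benjamini-Hochberg FDR over a p-value family
#'
#' @param pvals p values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `adjusted` (BH-adjusted p, monotone in rank) and
#'   `reject` (step-up decisions at `alpha`).
#' @export
fdrBH <- function(pvals, alpha = 0.05) {
  pvals <- as.numeric(pvals)
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p values must lie in [0, 1]")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = adj <= alpha)
}

#' Within-subject trial-permutation test for one GLM cell
#'
#' Builds the null for the group t statistic of `predictor`'s beta in the
#' GLM for `target` by independently shuffling the target's trial order
#' within each subject, refitting every subject's GLM, and recomputing the
#' group t. The p value is `(1 + #{|t_perm| >= |t_obs|}) / (nPerm + 1)`.
#'
#' @param measuresList list of per-subject [TrialMeasures-class] (or
#'   data.frames), already restricted to one condition.
#' @param target,predictor measure names.
#' @param nPerm number of permutations (default 5000).
#' @param seed RNG seed.
#' @return list with `p`, `tObs`, `tPerm` (the null draws).
#' @export
permutationTest <- function(measuresList, target, predictor, nPerm = 5000L,
                            seed = 1L) {
  nPerm <- as.integer(nPerm)
  if (nPerm < 1L) stop("nPerm must be >= 1")
  predictors <- setdiff(measureNames(), target)
  dfs <- lapply(measuresList, function(m)
    if (is(m, "TrialMeasures")) measuresTable(m) else m)
  prep <- lapply(dfs, function(df) .permPrep(df, target, predictors, predictor))
  tFor <- .permT
  obs <- vapply(prep, function(p) sum(p$m * p$y), numeric(1))
  tObs <- tFor(obs)
  tPerm <- .withSeed(seed, {
    B <- vapply(prep, function(p) {
      n <- length(p$y)
      Yp <- vapply(seq_len(nPerm), function(b) p$y[sample.int(n)],
                   numeric(n))
      as.numeric(p$m %*% Yp)
    }, numeric(nPerm))                       # nPerm x nSubjects
    apply(B, 1L, tFor)
  })
  list(p = (1 + sum(abs(tPerm) >= abs(tObs))) / (nPerm + 1),
       tObs = tObs, tPerm = tPerm)
}

#' Canonical double-gamma HRF convolution
#'
#' Convolves a regressor sampled at `rate` Hz with the canonical
#' double-gamma hemodynamic response (response gamma with mean lag 6 s,
#' undershoot gamma with mean lag 16 s, undershoot ratio 1/6, kernel
#' truncated at 32 s, scaled to unit peak) and truncates to the input
#' length.
#'
#' @param x numeric series (finite).
#' @param rate sampling rate of `x` in Hz.
#' @return convolved series, same length as `x`.
#' @export
hrfConvolve <- function(x, rate) {
  if (any(!is.finite(x))) stop("regressor must be finite")
  k <- hrfKernel(rate)
  n <- length(x)
  full <- stats::convolve(c(x, numeric(length(k))), rev(k), type = "open")
  full[seq_len(n)]
}

#' @rdname hrfConvolve
#' @export
hrfKernel <- function(rate) {
  t <- seq(0, 32, by = 1 / rate)
  k <- stats::dgamma(t, shape = 6, rate = 1) -
       stats::dgamma(t, shape = 16, rate = 1) / 6
  k / max(k)
}

# trial-level measure values -> an impulse-train regressor at EEG rate,
# HRF-convolved, then averaged within TR frames ("TR-resampled")
.measureRegressor <- function(values, trialAt, nSamples, rate, tr, nScans) {
  stick <- numeric(nSamples)
  stick[trialAt + 1L] <- values
  conv <- hrfConvolve(stick, rate)
  spt <- tr * rate
  reg <- vapply(seq_len(nScans), function(s) {
    idx <- floor((s - 1L) * spt + 1):min(nSamples, floor(s * spt))
    mean(conv[idx])
  }, numeric(1))
  reg
}

.condCells <- function(targets, predictors = NULL) {
  cells <- expand.grid(target = targets,
                       predictor = if (is.null(predictors)) targets else predictors,
                       stringsAsFactors = FALSE)
  cells[cells$target != cells$predictor, ]
}

#' Group-level cross-prediction of the trial-wise measures
#'
#' For each condition (task, rest) and each target measure, fits per-subject
#' GLMs of the target on the other five measures (z-scored within subject),
#' averages each subject's betas across pipeline repetitions, then runs a
#' one-sample group t-test per (target, predictor) cell, BH-FDR over the
#' condition's 30 off-diagonal cells, and a within-subject trial-permutation
#' test per cell (rep-averaged t against rep-averaged permuted t). When a
#' BOLD table is supplied, each network time course becomes an extra target
#' regressed on the HRF-convolved, TR-resampled trial measures (condition
#' `"bold"`; permutation p is not defined for these cells and is `NA`).
#'
#' @param measuresReps either a list of per-subject [TrialMeasures-class]
#'   objects (a single repetition) or a list of such lists (one per
#'   repetition, differing only in seeded pipeline randomness).
#' @param trialsList list of per-subject [TrialTable-class]; required for
#'   BOLD regressor construction, otherwise taken from the measures.
#' @param bold optional list of per-subject matrices (scans x networks).
#' @param rate EEG sampling rate (needed for BOLD; default 50).
#' @param tr BOLD repetition time in seconds (default 2).
#' @param alpha FDR level (default 0.05).
#' @param nPerm permutations per cell (default 5000).
#' @param seed RNG seed for the permutation draws.
#' @return a [ComparisonResult-class].
#' @export
runComparison <- function(measuresReps, trialsList = NULL, bold = NULL,
                          rate = 50, tr = 2, alpha = 0.05, nPerm = 5000L,
                          seed = 1L) {
  if (length(measuresReps) && is(measuresReps[[1L]], "TrialMeasures"))
    measuresReps <- list(measuresReps)
  nReps <- length(measuresReps)
  nSubj <- length(measuresReps[[1L]])
  dfsRep <- lapply(measuresReps, function(rep)
    lapply(rep, function(m)
      if (is(m, "TrialMeasures")) measuresTable(m) else m))
  meas <- measureNames()
  rows <- list()
  permSeed <- as.integer(seed)
  for (cond in c("task", "rest")) {
    sub <- lapply(dfsRep, function(rep)
      lapply(rep, function(df) df[df$block_type == cond, , drop = FALSE]))
    if (!nrow(sub[[1L]][[1L]])) next
    cells <- .condCells(meas)
    res <- lapply(seq_len(nrow(cells)), function(ci) {
      tg <- cells$target[ci]; pr <- cells$predictor[ci]
      # per-subject betas averaged over reps
      betas <- vapply(seq_len(nSubj), function(s) {
        mean(vapply(seq_len(nReps), function(r)
          fitTrialGLM(sub[[r]][[s]], tg, allowConstant = TRUE)[[pr]],
          numeric(1)))
      }, numeric(1))
      tt <- if (stats::sd(betas) == 0 && all(betas == 0))
        list(t = 0, p = 1, mean = 0)   # fully degenerate cell
      else groupTTest(betas)
      pp <- .permAveraged(sub, tg, pr, nPerm, permSeed + ci)
      data.frame(condition = cond, target = tg, predictor = pr,
                 beta = tt$mean, t = tt$t, p = tt$p, p_fdr = NA_real_,
                 p_perm = pp, stringsAsFactors = FALSE)
    })
    tb <- do.call(rbind, res)
    tb$p_fdr <- fdrBH(tb$p, alpha)$adjusted
    rows[[cond]] <- tb
  }
  if (!is.null(bold)) {
    if (is.null(trialsList))
      stop("BOLD analysis needs trialsList for regressor construction")
    rows[["bold"]] <- .boldComparison(dfsRep, trialsList, bold, rate, tr, alpha)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  new("ComparisonResult", table = tab, alpha = alpha, nPerm = as.integer(nPerm))
}

# row of the coefficient operator (X'X)^-1 X' for one predictor; a zero row
# when the predictor is constant in this subject's data (its beta is 0 under
# every permutation)
.permPrep <- function(df, target, predictors, predictor) {
  d <- .designFor(df, target, predictors, allowConstant = TRUE)
  col <- match(predictor, d$keep)
  if (is.na(col))
    return(list(m = numeric(nrow(df)), y = d$y))
  R <- qr.R(d$qr); Q <- qr.Q(d$qr)
  M <- backsolve(R, t(Q))
  list(m = M[col + 1L, ], y = d$y)
}

# group t that degrades to 0 when every subject's beta is exactly 0 (a fully
# degenerate cell); nonzero-mean zero-variance vectors still error upstream
.permT <- function(betas) {
  s <- stats::sd(betas)
  if (s == 0) return(0)
  mean(betas) / (s / sqrt(length(betas)))
}

# rep-averaged permutation p for one cell: each permutation shuffles the
# target's trial order independently within every subject and repetition;
# subject betas are rep-averaged before the group t
.permAveraged <- function(sub, target, predictor, nPerm, seed) {
  nReps <- length(sub); nSubj <- length(sub[[1L]])
  if (nReps == 1L)
    return(permutationTest(sub[[1L]], target, predictor, nPerm, seed)$p)
  predictors <- setdiff(measureNames(), target)
  prep <- lapply(sub, function(rep) lapply(rep, function(df)
    .permPrep(df, target, predictors, predictor)))
  tFor <- .permT
  obs <- vapply(seq_len(nSubj), function(s)
    mean(vapply(prep, function(rep) sum(rep[[s]]$m * rep[[s]]$y), numeric(1))),
    numeric(1))
  tObs <- tFor(obs)
  tPerm <- .withSeed(seed, {
    B <- vapply(seq_len(nSubj), function(s) {
      acc <- matrix(0, nPerm, nReps)
      for (r in seq_len(nReps)) {
        p <- prep[[r]][[s]]; n <- length(p$y)
        Yp <- vapply(seq_len(nPerm), function(b) p$y[sample.int(n)], numeric(n))
        acc[, r] <- as.numeric(p$m %*% Yp)
      }
      rowMeans(acc)
    }, numeric(nPerm))
    apply(B, 1L, tFor)
  })
  (1 + sum(abs(tPerm) >= abs(tObs))) / (nPerm + 1)
}

.boldComparison <- function(dfsRep, trialsList, bold, rate, tr, alpha) {
  nReps <- length(dfsRep); nSubj <- length(dfsRep[[1L]])
  meas <- measureNames()
  nets <- colnames(bold[[1L]])
  if (is.null(nets)) nets <- sprintf("net%02d", seq_len(ncol(bold[[1L]])))
  cells <- expand.grid(target = nets, predictor = meas,
                       stringsAsFactors = FALSE)
  betas <- array(NA_real_, c(nSubj, nrow(cells), nReps))
  for (r in seq_len(nReps)) for (s in seq_len(nSubj)) {
    df <- dfsRep[[r]][[s]]
    trials <- trialsList[[s]]
    nScans <- nrow(bold[[s]])
    nSamp <- max(trialSamples(trials)) + 1L
    nSamp <- max(nSamp, ceiling(nScans * tr * rate))
    X <- vapply(meas, function(mn)
      .zstd(.measureRegressor(df[[mn]], trialSamples(trials), nSamp, rate,
                              tr, nScans)), numeric(nScans))
    X <- cbind(1, X)
    for (j in seq_along(nets)) {
      b <- qr.coef(qr(X), bold[[s]][, j])[-1L]
      idx <- which(cells$target == nets[j])
      betas[s, idx, r] <- b[match(cells$predictor[idx], meas)]
    }
  }
  res <- lapply(seq_len(nrow(cells)), function(ci) {
    bb <- rowMeans(betas[, ci, , drop = FALSE], dims = 1L)
    tt <- groupTTest(bb)
    data.frame(condition = "bold", target = cells$target[ci],
               predictor = cells$predictor[ci], beta = tt$mean, t = tt$t,
               p = tt$p, p_fdr = NA_real_, p_perm = NA_real_,
               stringsAsFactors = FALSE)
  })
  tb <- do.call(rbind, res)
  tb$p_fdr <- fdrBH(tb$p, alpha)$adjusted
  tb
}
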