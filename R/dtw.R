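# Exact banded DTW: dynamic programming over the Sakoe-Chiba band with
# deterministic backtracking. The band both speeds up the alignment and
# bounds how much temporal distortion the warp may introduce.

.dtwCheck <- function(x, y, window) {
  if (length(x) < 1L || length(y) < 1L) stop("sequences must be nonempty")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("sequences must contain only finite values")
  if (window < 0L) stop("window must be nonnegative")
  if (abs(length(x) - length(y)) > window)
    stop("infeasible Sakoe-Chiba band: |", length(x), " - ", length(y),
         "| > window ", window)
}

#' Banded dynamic-time-warping distance
#'
#' Minimum cumulative local cost over all monotone warp paths from
#' `(0, 0)` to `(n-1, m-1)` whose index pairs satisfy `|i - j| <= window`
#' (Sakoe-Chiba band). The step pattern is the symmetric unweighted
#' three-move (diagonal, i-step, j-step); cells outside the band are
#' unreachable.
#'
#' @param x,y numeric sequences.
#' @param window band half-width in samples (default 20).
#' @param cost local cost, `"abs"` (default) or `"squared"`.
#' @param normalize if `TRUE`, divide the cumulative cost by `n + m`.
#'   The default reports the raw cumulative cost: across a fixed-length
#'   template bank all alignments share the same lengths, so normalization
#'   does not change which frequency minimizes the spectrum.
#' @return a nonnegative scalar distance.
#' @examples
#' dtwDistance(c(1, 2, 3), c(1, 2, 3))            # 0
#' dtwDistance(c(0, 0), c(1, 1), window = 1)      # 2
#' @export
dtwDistance <- function(x, y, window = 20L, cost = c("abs", "squared"),
                        normalize = FALSE) {
  cost <- match.arg(cost)
  window <- as.integer(window)
  .dtwCheck(x, y, window)
  D <- dtw_cost_matrix(as.numeric(x), as.numeric(y), window, cost == "squared")
  d <- D[length(x) + 1L, length(y) + 1L]
  if (normalize) d <- d / (length(x) + length(y))
  d
}

#' Optimal warp path for a banded DTW alignment
#'
#' Backtracks the dynamic-programming matrix from `(n-1, m-1)` to `(0, 0)`.
#' Ties are broken deterministically: prefer the diagonal move, then the
#' i-decrement, then the j-decrement.
#'
#' @inheritParams dtwDistance
#' @return a [WarpPath-class]; its `totalCost` equals [dtwDistance()].
#' @export
dtwPath <- function(x, y, window = 20L, cost = c("abs", "squared")) {
  cost <- match.arg(cost)
  window <- as.integer(window)
  .dtwCheck(x, y, window)
  x <- as.numeric(x); y <- as.numeric(y)
  D <- dtw_cost_matrix(x, y, window, cost == "squared")
  # i, j are 1-based sequence positions; the DP cell for (i, j) is D[i+1, j+1]
  i <- length(x); j <- length(y)
  pairs <- matrix(0L, i + j, 2L)
  k <- nrow(pairs)
  while (i > 1L || j > 1L) {
    pairs[k, ] <- c(i - 1L, j - 1L); k <- k - 1L
    if (i == 1L) { j <- j - 1L; next }
    if (j == 1L) { i <- i - 1L; next }
    pred <- c(D[i, j], D[i, j + 1L], D[i + 1L, j])
    mv <- which.min(pred)  # first minimum: diagonal, then i-dec, then j-dec
    if (mv == 1L) { i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) i <- i - 1L
    else j <- j - 1L
  }
  pairs[k, ] <- c(0L, 0L)
  pairs <- pairs[k:nrow(pairs), , drop = FALSE]
  colnames(pairs) <- c("i", "j")
  new("WarpPath", pairs = pairs,
      totalCost = D[length(x) + 1L, length(y) + 1L], window = window)
}
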