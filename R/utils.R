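# internal helpers

# z-standardize to zero mean, unit sample variance
.zstd <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) stop("cannot standardize a constant sequence")
  (v - mean(v)) / s
}

# run expr under a temporary RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# atomic text write: write to a temp file in the target directory, then rename
.writeAtomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  ok <- FALSE
  on.exit(if (!ok && file.exists(tmp)) unlink(tmp))
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  ok <- TRUE
  invisible(path)
}

# 0-based pre-trial window [t - width, t) as 1-based R column indices
.pretrialIdx <- function(trialSample0, width) {
  if (trialSample0 - width < 0)
    stop("trial at sample ", trialSample0,
         " is too close to the start for a ", width, "-sample pre-trial window")
  seq.int(trialSample0 - width + 1L, trialSample0)
}

# 1/f-amplitude-shaped Gaussian background noise, zero mean, unit variance.
# The DC bin is zeroed: a per-channel constant offset is not noise, and any
# leak here becomes a fixed spatial direction that dominates topography.
.pinkNoise <- function(n) {
  m <- 2L * n
  f <- stats::fft(stats::rnorm(m))
  k <- pmin(seq_len(m) - 1L, m - (seq_len(m) - 1L))
  w <- c(0, 1 / sqrt(k[-1L]))
  x <- Re(stats::fft(f * w, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  x / stats::sd(x)
}
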