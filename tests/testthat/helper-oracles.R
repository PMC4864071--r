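# Independent oracles used across the suite. These deliberately share no
# code with the package internals.

# Exhaustive DTW: recursive minimum over every monotone warp path from
# (1, 1) to (n, m) restricted to the Sakoe-Chiba band. Exponential-time
# enumeration; only usable for short sequences.
bruteDTW <- function(x, y, window, cost = "abs") {
  lc <- function(a, b) if (cost == "abs") abs(a - b) else (a - b)^2
  rec <- function(i, j) {
    if (abs(i - j) > window) return(Inf)
    c0 <- lc(x[i], y[j])
    if (i == 1L && j == 1L) return(c0)
    if (i == 1L) return(c0 + rec(i, j - 1L))
    if (j == 1L) return(c0 + rec(i - 1L, j))
    c0 + min(rec(i - 1L, j - 1L), rec(i - 1L, j), rec(i, j - 1L))
  }
  rec(length(x), length(y))
}

# Direct-summation DFT power at one frequency (naive O(n) per bin)
naiveDFTPower <- function(seg, rate, f) {
  seg <- seg - mean(seg)
  t <- (0:(length(seg) - 1)) / rate
  sum(seg * cos(2 * pi * f * t))^2 + sum(seg * sin(2 * pi * f * t))^2
}

# two-pass population SD across channels at each sample
naiveGFP <- function(X) {
  apply(X, 2, function(v) sqrt(mean((v - mean(v))^2)))
}

# closed-form OLS via normal equations
normalEqBetas <- function(X, y) as.vector(solve(t(X) %*% X, t(X) %*% y))

# small helper: recording filled with given matrix at 50 Hz
rec50 <- function(X, ...) EEGRecording(as.matrix(X), rate = 50, ...)

# a minimal valid trial table at given 0-based samples
tt <- function(at, type = "task") {
  TrialTable(at, rep(1L, length(at)), rep(type, length(at)))
}
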