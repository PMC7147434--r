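# Independent oracles used to validate package computations. These
# deliberately share no code with the implementation.

# Brute-force grid integration of the occupancy posterior: uniform priors on
# the unit cube truncated to p10 < p11, marginal binomial likelihood, grid of
# cell midpoints.
gridOccupancyOracle <- function(y, K, n = 51) {
  g <- seq(1 / (2 * n), 1 - 1 / (2 * n), length.out = n)
  grid <- expand.grid(psi = g, p11 = g, p10 = g)
  grid <- grid[grid$p10 < grid$p11, ]
  ll <- numeric(nrow(grid))
  for (i in seq_along(y)) {
    f11 <- dbinom(y[i], K[i], grid$p11)
    f10 <- dbinom(y[i], K[i], grid$p10)
    ll <- ll + log(grid$psi * f11 + (1 - grid$psi) * f10)
  }
  wgt <- exp(ll - max(ll))
  wgt <- wgt / sum(wgt)
  c(psi = sum(grid$psi * wgt), p11 = sum(grid$p11 * wgt),
    p10 = sum(grid$p10 * wgt))
}

# Exhaustive optimal 2-partition of 1-D values by within-cluster SS: tries
# every assignment of points to two non-empty clusters.
bruteForceSplit <- function(values) {
  n <- length(values)
  best <- Inf
  best_assign <- NULL
  for (code in 1:(2^n - 2)) {
    a <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    wss <- sum((values[a] - mean(values[a]))^2) +
      sum((values[!a] - mean(values[!a]))^2)
    if (wss < best) { best <- wss; best_assign <- a }
  }
  list(wss = best, assign = best_assign)
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign assignments.
enumSignedRankP <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  stats <- vapply(0:(2^n - 1), function(code) {
    s <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    sum(r[s])
  }, 0)
  mu <- n * (n + 1) / 4
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}

# Exact two-sided rank-sum p by enumeration of all group-A index choices.
enumRankSumP <- function(a, b) {
  v <- c(a, b)
  r <- rank(v)
  nA <- length(a)
  obs <- sum(r[seq_len(nA)])
  combs <- combn(length(v), nA)
  stats <- apply(combs, 2, function(j) sum(r[j]))
  mu <- nA * (length(v) + 1) / 2
  mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
}
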