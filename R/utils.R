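# Internal numeric helpers shared across modules.

# Linear-interpolated time (seconds, 0-based) at which series `x` crosses
# `thr` between adjacent samples i and i+1. `dir` +1 = upward, -1 = downward.
# Returns times for all crossings inside index window [from, to].
crossing_times <- function(x, thr, rate, dir = 1L, from = 1L, to = length(x)) {
  if (to <= from) return(numeric(0))
  xi <- x[from:to]
  d <- if (dir > 0) (xi < thr)[-length(xi)] & (xi[-1] >= thr)
       else         (xi > thr)[-length(xi)] & (xi[-1] <= thr)
  idx <- which(d)
  if (!length(idx)) return(numeric(0))
  i <- from + idx - 1L
  frac <- (thr - x[i]) / (x[i + 1L] - x[i])
  frac[!is.finite(frac)] <- 0
  (i - 1L + frac) / rate
}

# Centered moving average with odd window; endpoints padded by replication.
moving_average <- function(x, k) {
  if (k <= 1L) return(x)
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  if (n < k) return(x)
  half <- (k - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[n], half))
  as.numeric(stats::filter(xp, rep(1 / k, k), sides = 2L)[(half + 1L):(half + n)])
}

# Fast simple linear regression returning slope, intercept and r^2 without
# the model-frame overhead of lm(); used inside per-breath loops.
fast_lsq <- function(t, y) {
  n <- length(t)
  mt <- mean(t); my <- mean(y)
  dt <- t - mt; dy <- y - my
  sxx <- sum(dt * dt)
  if (sxx <= 0) return(list(slope = NA_real_, intercept = my, r2 = 0))
  sxy <- sum(dt * dy)
  syy <- sum(dy * dy)
  slope <- sxy / sxx
  r2 <- if (syy <= 0) 1 else (sxy * sxy) / (sxx * syy)
  list(slope = slope, intercept = my - slope * mt, r2 = r2)
}

# Trapezoidal cumulative integral (same length as x, starts at 0).
cumtrapz <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((x[-n] + x[-1L]) / 2) * dt)
}

# Counter-based seed splitting: derived streams are stable under changes in
# how many other streams are drawn. Keeps results < 2^31 (R integer seeds).
derive_seed <- function(root_seed, ...) {
  idx <- c(...)
  s <- as.numeric(root_seed) %% 2147483587
  for (k in seq_along(idx)) {
    s <- (s * 48271 + as.numeric(idx[k]) * 16807 + 11) %% 2147483587
  }
  as.integer(s + 1)
}

# Run lengths of TRUE in a logical vector -> matrix of [start, end] indices.
true_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Estimate PEEP and PS from the airway-pressure trace (robust quantiles).
estimate_paw_levels <- function(paw) {
  q <- stats::quantile(paw, c(0.1, 0.95), names = FALSE, na.rm = TRUE)
  list(peep = q[1L], ps = max(q[2L] - q[1L], 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
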