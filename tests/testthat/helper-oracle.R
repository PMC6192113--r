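# Independent brute-force oracle: exhaustive least-squares grid search over
# combinations of inter-time midpoints. Deliberately built from scratch
# (plain design matrices + .lm.fit), not from the package's fitting path.

oracle_grid_fit <- function(y, times, k) {
  ut <- unique(sort(times))
  if (k == 0) {
    ft <- .lm.fit(cbind(1, times), y)
    return(list(rss = sum(ft$residuals^2), b = numeric(0)))
  }
  mids <- (ut[-1] + ut[-length(ut)]) / 2
  combos <- utils::combn(mids, k, simplify = FALSE)
  best_rss <- Inf
  best_b <- NULL
  for (b in combos) {
    X <- cbind(1, times, pmax(outer(times, b, "-"), 0))
    ft <- .lm.fit(X, y)
    if (ft$rank < ncol(X)) next
    rss <- sum(ft$residuals^2)
    if (rss < best_rss) {
      best_rss <- rss
      best_b <- b
    }
  }
  list(rss = best_rss, b = best_b)
}

# Piecewise-linear mean built directly from segment slopes and breakpoints
# (independent of the package's prediction code).
oracle_piecewise_mean <- function(times, slopes, breaks, intercept = 0) {
  mu <- intercept + slopes[1] * times
  for (i in seq_along(breaks)) {
    mu <- mu + (slopes[i + 1] - slopes[i]) * pmax(times - breaks[i], 0)
  }
  mu
}
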