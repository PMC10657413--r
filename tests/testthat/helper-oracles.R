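# independent brute-force oracles, deliberately naive

# product-limit estimate by direct risk-set enumeration
brute_km <- function(time, event) {
  ts <- sort(unique(time))
  s <- 1
  rows <- lapply(ts, function(t) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <<- s * (1 - d / n_risk)
    data.frame(time = t, n_risk = n_risk, n_event = d, survival = s)
  })
  do.call(rbind, rows)
}

# two-arm log-rank chi-square by per-event-time 2x2 hypergeometric tables
brute_logrank_chisq <- function(time, event, group) {
  gs <- sort(unique(group))
  stopifnot(length(gs) == 2)
  o <- 0; e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & group == gs[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == gs[1])
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o - e)^2 / v
}

# OLS slope/intercept through explicit normal equations
brute_ols <- function(x, y) {
  X <- cbind(1, x)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  c(intercept = beta[1], slope = beta[2])
}
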