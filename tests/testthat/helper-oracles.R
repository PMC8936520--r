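# Independent oracles used to validate the analysis implementations.
# These deliberately re-derive each quantity from its definition by
# enumeration or direct formula, not by calling the code under test.

# Step-up FDR: literal q_(i) = min over j >= i of p_(j) * m / j
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Step-down Sidak from its definition, computed longhand
holm_sidak_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    a <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, a)
    adj[i] <- min(1, running)
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Product-limit estimator computed by hand at each event time
km_bruteforce <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# Two-group log-rank from the hypergeometric expectation/variance sums
logrank_bruteforce <- function(time, event, group) {
  g <- as.integer(factor(group))
  ts <- sort(unique(time[event == 1]))
  o1 <- e1 <- v <- 0
  for (t in ts) {
    risk <- time >= t
    n1 <- sum(risk & g == 1); n <- sum(risk)
    d1 <- sum(risk & g == 1 & time == t & event == 1)
    d <- sum(risk & time == t & event == 1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n - d) / (n - 1) * n1 * (n - n1) / n^2
  }
  (o1 - e1)^2 / v
}

# Cox log partial likelihood (no ties in the data used with this oracle)
cox_logpl <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Two-stage exhaustive grid maximizer of the partial likelihood
cox_grid_mle <- function(time, event, x, lo = -5, hi = 5) {
  grid <- seq(lo, hi, length.out = 2001)
  ll <- vapply(grid, cox_logpl, numeric(1), time, event, x)
  b <- grid[which.max(ll)]
  fine <- seq(b - 0.01, b + 0.01, by = 1e-6)
  llf <- vapply(fine, cox_logpl, numeric(1), time, event, x)
  fine[which.max(llf)]
}

# Hypergeometric upper tail by complete enumeration of all draws
hyper_tail_enum <- function(k, set_size, list_size, background_size) {
  universe <- seq_len(background_size)
  gene_set <- seq_len(set_size)
  draws <- utils::combn(background_size, list_size)
  overlaps <- apply(draws, 2, function(d) length(intersect(d, gene_set)))
  mean(overlaps >= k)
}
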