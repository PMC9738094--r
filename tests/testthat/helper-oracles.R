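# Independent oracles, kept deliberately naive: enumeration, brute-force
# definitions and hand product-limit arithmetic, never the code paths they
# check.

# exact two-sided Wilcoxon rank-sum p by full enumeration of rank subsets
oracle_wilcoxon_null <- function(n1, n2) {
  n <- n1 + n2
  subsets <- utils::combn(n, n1)
  u <- colSums(matrix(seq_len(n)[subsets], nrow = n1)) - n1 * (n1 + 1) / 2
  u
}

oracle_wilcoxon_p <- function(u_obs, u_null) {
  lower <- mean(u_null <= u_obs)
  upper <- mean(u_null >= u_obs)
  min(1, 2 * min(lower, upper))
}

# brute-force Benjamini-Hochberg from its definition:
# adj(i) = min_{j : p(j) >= p(i) in sorted order} p(j) * m / rank(j)
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(sorted[i:m] * m / (i:m)))
  }, numeric(1))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# hand product-limit estimator over event times
oracle_km <- function(times, events) {
  ord <- order(times)
  times <- times[ord]
  events <- events[ord]
  utimes <- sort(unique(times[events == 1]))
  s <- 1
  out <- data.frame(time = utimes, surv = NA_real_)
  for (k in seq_along(utimes)) {
    t <- utimes[k]
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
    out$surv[k] <- s
  }
  out
}

# hand log-rank: O-E and hypergeometric variance summed over event times
oracle_logrank <- function(times, events, group) {
  group <- factor(group)
  lev <- levels(group)
  utimes <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in utimes) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == lev[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & group == lev[1])
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (o1 - e1)^2 / v
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE),
       o1 = o1, e1 = e1)
}

# closed-form Pearson r and its two-sided t-transform p
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- x - mean(x)
  sy <- y - mean(y)
  r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2))
}

# central binomial interval bounds on the frequency scale
binom_envelope <- function(p, n, level = 0.99) {
  a <- (1 - level) / 2
  c(qbinom(a, n, p), qbinom(1 - a, n, p)) / n
}
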