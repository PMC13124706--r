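# Independent brute-force oracles, written from first principles (choose()
# and full enumeration) so they share no code path with the package.

# all hypergeometric tables with the observed margins; returns p-values
# for greater / less / min-likelihood two-sided
enum_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; n <- r1 + r2
  ks <- max(0, c1 - r2):min(r1, c1)
  pk <- choose(r1, ks) * choose(r2, c1 - ks) / choose(n, c1)
  p_obs <- pk[ks == a]
  list(greater = sum(pk[ks >= a]),
       less = sum(pk[ks <= a]),
       two_sided = sum(pk[pk <= p_obs * (1 + 1e-7)]))
}

enum_binom <- function(k, n, p0) {
  pk <- choose(n, 0:n) * p0^(0:n) * (1 - p0)^(n - (0:n))
  p_obs <- pk[k + 1]
  list(greater = sum(pk[(0:n) >= k]),
       less = sum(pk[(0:n) <= k]),
       two_sided = min(1, sum(pk[pk <= p_obs * (1 + 1e-7)])))
}

enum_hyper_upper <- function(k, set_size, special, universe) {
  ks <- max(0, set_size - (universe - special)):min(set_size, special)
  pk <- choose(special, ks) * choose(universe - special, set_size - ks) /
    choose(universe, set_size)
  sum(pk[ks >= k])
}

# brute-force GSEA enrichment score: full running sum over every position
brute_es <- function(scores, hit, weight = 1) {
  N <- length(scores)
  w <- abs(scores)^weight
  w[!hit] <- 0
  if (sum(w) == 0) w[hit] <- 1
  inc <- ifelse(hit, w / sum(w), -1 / (N - sum(hit)))
  rs <- cumsum(inc)
  i <- which.max(abs(rs))
  # resolve ties toward the earliest extremum, matching max/min semantics
  hi <- max(rs); lo <- min(c(rs, 0))
  if (hi >= abs(lo)) hi else lo
}

# naive per-pair Pearson correlation table via the textbook formula
naive_corr_table <- function(m, lnc_ids, coding_ids) {
  out <- list()
  for (l in lnc_ids) for (g in coding_ids) {
    x <- m[l, ]; y <- m[g, ]
    n <- length(x)
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tt <- r * sqrt((n - 2) / (1 - r^2))
    out[[paste(l, g)]] <- data.frame(
      lnc_id = l, coding_id = g, r = r,
      p = 2 * pt(-abs(tt), df = n - 2), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
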