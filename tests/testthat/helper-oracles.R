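# Independent oracles: exhaustive lm-based two-segment fit and a
# log-factorial Fisher enumeration.

# moving average with symmetric shrinking window, written independently
ma_ref <- function(x, w = 5) {
  n <- length(x)
  h <- (w - 1) / 2
  sapply(seq_len(n), function(i) {
    hh <- min(h, i - 1, n - i)
    mean(x[(i - hh):(i + hh)])
  })
}

# exhaustive two-segment least squares: lines fitted by lm() on the smoothed
# trace, scored by squared error against the raw trace
onset_oracle <- function(trace, min_segment = 5, window = 5) {
  t <- trace$time_min
  yr <- trace$value
  ys <- ma_ref(yr, window)
  n <- length(t)
  cand <- seq(min_segment, n - min_segment + 1)
  sse <- sapply(cand, function(k) {
    tl <- t[1:k]; tr <- t[k:n]
    fl <- lm(ys[1:k] ~ tl)
    fr <- lm(ys[k:n] ~ tr)
    sum((yr[1:k] - (coef(fl)[1] + coef(fl)[2] * tl))^2) +
      sum((yr[k:n] - (coef(fr)[1] + coef(fr)[2] * tr))^2)
  })
  cand[which.min(sse)]
}

# two-sided Fisher p by direct enumeration with log-factorial table
# probabilities (no dhyper)
fisher_oracle <- function(a, b, c, d) {
  lfac <- function(x) lgamma(x + 1)
  N <- a + b + c + d
  logp <- function(aa) {
    bb <- a + b - aa; cc <- a + c - aa; dd <- d - a + aa
    if (bb < 0 || cc < 0 || dd < 0) return(-Inf)
    lfac(a + b) + lfac(c + d) + lfac(a + c) + lfac(b + d) -
      lfac(N) - lfac(aa) - lfac(bb) - lfac(cc) - lfac(dd)
  }
  as_ <- 0:min(a + b, a + c)
  lp <- vapply(as_, logp, 0)
  p_obs <- logp(a)
  sum(exp(lp[lp <= p_obs + 1e-7]))
}
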