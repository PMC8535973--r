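# Independent oracles used across the suite. Deliberately naive, loop-based
# implementations kept separate from the package's vectorized code paths.

# ssGSEA running sum, literal position-by-position walk
ssgsea_brute <- function(x, set_genes, alpha) {
  genes <- names(x)
  n <- length(x)
  rk <- rank(x, ties.method = "average")
  ord <- order(-x, seq_along(x))
  hits <- genes[ord] %in% set_genes
  denom_in <- 0
  for (j in seq_len(n)) if (hits[j]) denom_in <- denom_in + rk[ord[j]]^alpha
  n_miss <- n - sum(hits)
  score <- 0
  acc_in <- 0
  acc_out <- 0
  for (j in seq_len(n)) {
    if (hits[j]) acc_in <- acc_in + rk[ord[j]]^alpha else acc_out <- acc_out + 1
    score <- score + acc_in / denom_in - acc_out / n_miss
  }
  unname(score)
}

# BH step-up by explicit sort-and-cummin
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o]
  running <- 1
  for (i in m:1) {
    running <- min(running, m * sorted[i] / i)
    adj[i] <- running
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# naive Breslow log partial likelihood (single covariate), O(n^2)
cox_loglik_naive <- function(beta, x, times, events) {
  ll <- 0
  for (i in seq_along(times)) {
    if (events[i] == 1) {
      risk <- which(times >= times[i])
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
  }
  ll
}

# naive average-linkage agglomeration returning a k-cut labeling
average_linkage_cut <- function(d, k) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  dd <- d
  diag(dd) <- Inf
  while (length(clusters) > k) {
    m <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      dij <- mean(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d) { best_d <- dij; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(clusters)) lab[clusters[[g]]] <- g
  lab
}

# hypergeometric upper-tail P(X >= q) by point-mass enumeration
hyper_upper_enum <- function(q, white, black, draws) {
  kk <- q:min(white, draws)
  sum(choose(white, kk) * choose(black, draws - kk) / choose(white + black, draws))
}

# two-sided Fisher p by enumerating all tables with the observed margins
fisher_enum <- function(a, b, cc, d) {
  m1 <- a + b; m2 <- cc + d; n1 <- a + cc
  lo <- max(0, n1 - m2); hi <- min(m1, n1)
  probs <- vapply(lo:hi, function(aa) {
    choose(m1, aa) * choose(m2, n1 - aa) / choose(m1 + m2, n1)
  }, 0)
  p_obs <- probs[a - lo + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random clinical table helper
rand_surv <- function(n, rate = 0.01, cens_frac = 0.2, beta = 0, x = NULL) {
  if (is.null(x)) x <- rnorm(n)
  t_event <- rexp(n, rate * exp(beta * x))
  cens <- if (cens_frac > 0) {
    cmax <- uniroot(function(cm) mean(pmin(t_event / cm, 1)) - cens_frac,
                    lower = 1e-9, upper = max(t_event) * 1e6)$root
    runif(n, 0, cmax)
  } else rep(Inf, n)
  list(time = pmax(pmin(t_event, cens), 1e-4),
       event = as.numeric(t_event <= cens), x = x)
}
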