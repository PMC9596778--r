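# Independent brute-force oracles. These are literal transcriptions of the
# published definitions (explicit running sums / walks / likelihood scans),
# deliberately kept separate from the package's vectorized implementations.

## ssGSEA: explicit running sum over the ranked list.
oracle_ssgsea <- function(expr, sets, alpha = 0.25) {
  genes <- rownames(expr)
  N <- nrow(expr)
  out <- matrix(NA_real_, length(sets), ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    ord <- order(-x, genes)
    rv <- rank(x, ties.method = "average")
    for (s in seq_along(sets)) {
      hit <- genes[ord] %in% sets[[s]]
      w <- abs(rv[ord])^alpha
      p_hit <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
      p_miss <- cumsum(!hit) / sum(!hit)
      out[s, j] <- sum(p_hit - p_miss)
    }
  }
  out
}

## GSVA: per-gene Gaussian kernel CDF, symmetric rank statistic, weighted KS
## walk, mx.diff score — all as explicit loops.
oracle_gsva <- function(expr, sets, tau = 1) {
  genes <- rownames(expr)
  N <- nrow(expr); n <- ncol(expr)
  z <- matrix(0, N, n)
  for (g in seq_len(N)) {
    h <- sd(expr[g, ]) / 4
    for (j in seq_len(n)) {
      z[g, j] <- if (h == 0) 0.5 else mean(pnorm((expr[g, j] - expr[g, ]) / h))
    }
  }
  out <- matrix(NA_real_, length(sets), n,
                dimnames = list(names(sets), colnames(expr)))
  for (j in seq_len(n)) {
    ord <- order(-z[, j], genes)
    for (s in seq_along(sets)) {
      hit <- genes[ord] %in% sets[[s]]
      r_sym <- abs(N / 2 - seq_len(N))^tau
      num <- 0; den_hit <- sum(r_sym[hit]); miss <- 0
      walk <- numeric(N)
      for (i in seq_len(N)) {
        if (hit[i]) num <- num + r_sym[i] else miss <- miss + 1
        walk[i] <- num / den_hit - miss / sum(!hit)
      }
      out[s, j] <- max(0, max(walk)) + min(0, min(walk))
    }
  }
  out
}

## Cox partial log-likelihood for a binary covariate, direct definition.
oracle_cox_loglik <- function(beta, time, event, x, ties = "efron") {
  r <- exp(beta * x)
  ll <- 0
  for (u in unique(time[event == 1])) {
    at_risk <- time >= u
    dead <- event == 1 & time == u
    d <- sum(dead)
    ll <- ll + beta * sum(x[dead])
    if (ties == "breslow") {
      ll <- ll - d * log(sum(r[at_risk]))
    } else {
      for (jj in seq_len(d) - 1) {
        ll <- ll - log(sum(r[at_risk]) - (jj / d) * sum(r[dead]))
      }
    }
  }
  ll
}

## Dense grid maximizer of the partial likelihood, refined to < 1e-7.
oracle_grid_cox <- function(time, event, x, lo = -5, hi = 5, ties = "efron") {
  for (pass in 1:4) {
    grid <- seq(lo, hi, length.out = 2001L)
    ll <- vapply(grid, oracle_cox_loglik, numeric(1L),
                 time = time, event = event, x = x, ties = ties)
    best <- grid[which.max(ll)]
    step <- grid[2L] - grid[1L]
    lo <- best - 2 * step; hi <- best + 2 * step
  }
  best
}

## DerSimonian-Laird pooling, textbook sequence.
oracle_dl <- function(y, se) {
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  k <- length(y)
  tau2 <- max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (se^2 + tau2)
  b <- sum(ws * y) / sum(ws)
  sep <- sqrt(1 / sum(ws))
  list(b = b, se = sep, Q = Q, tau2 = tau2,
       p = 2 * pnorm(-abs(b / sep)))
}

## Fisher two-sided p by direct hypergeometric enumeration with choose().
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  xs <- max(0, k - n):min(k, m)
  prob <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, c_) / choose(m + n, k)
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

## Spearman rho and t-approximation p from average ranks, by formula.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * pt(-abs(tstat), n - 2))
}

## Small random expression fixture.
random_expr <- function(n_genes, n_samples, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
         dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                         sprintf("S%02d", seq_len(n_samples))))
}

random_sets <- function(genes, sizes, seed = 2) {
  set.seed(seed)
  sets <- lapply(sizes, function(k) sample(genes, k))
  names(sets) <- sprintf("SET%d", seq_along(sets))
  signature_collection(sets)
}
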