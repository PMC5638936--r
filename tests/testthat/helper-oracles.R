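# Independent oracles and fixture builders. Every oracle here is a direct,
# naive implementation (grid search, double loops, term-by-term sums) kept
# deliberately separate from the package's code paths.

# dense scalar grid search for the proximal operator: coarse 1e-3 pass over
# the bracketing interval, then a 1e-5 grid around the coarse minimizer
grid_threshold_oracle <- function(z, s, spec) {
  obj <- function(b) 0.5 * s * (b - z)^2 + penalty_value(b, spec)
  lo <- -abs(z) - 1; hi <- abs(z) + 1
  g1 <- seq(lo, hi, by = 1e-3)
  b1 <- g1[which.min(obj(g1))]
  g2 <- seq(b1 - 2e-3, b1 + 2e-3, by = 1e-5)
  g2[which.min(obj(g2))]
}

# central finite differences
fd_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(j) {
    xp <- x; xp[j] <- xp[j] + eps
    xm <- x; xm[j] <- xm[j] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# term-by-term Breslow negative partial log-likelihood (risk set t_j >= t_i)
npll_bruteforce <- function(beta, X, time, status) {
  eta <- drop(X %*% beta)
  s <- 0
  for (i in seq_along(time)) {
    if (status[i] == 1) {
      R <- which(time >= time[i])
      s <- s - (eta[i] - log(sum(exp(eta[R]))))
    }
  }
  s
}

# O(n^2) concordance double loop, ties get 1/2
ci_bruteforce <- function(pred, time, status) {
  num <- 0; den <- 0
  n <- length(pred)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && status[i] == 1) {
      den <- den + 1
      if (pred[i] < pred[j]) num <- num + 1
      else if (pred[i] == pred[j]) num <- num + 0.5
    }
  }
  num / den
}

# conditional mean E[T | T > c] of a step survival curve by fine quadrature
km_cond_mean_quadrature <- function(knots, surv, cc, dt = 1e-5) {
  s_at <- function(tt) {
    k <- findInterval(tt, knots)
    ifelse(k == 0, 1, surv[pmax(k, 1)])
  }
  tmax <- max(knots)
  grid <- seq(cc, tmax, by = dt)
  integral <- sum(s_at(grid)) * dt
  cc + integral / s_at(cc)
}

# small random survival dataset with controllable censoring
make_toy_surv <- function(n = 20, p = 4, seed = 1, cens_frac = 0.3,
                          beta = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("S", 1:n), paste0("g", 1:p)))
  beta <- beta %||% numeric(p)
  tt <- rexp(n, rate = exp(drop(X %*% beta)))
  status <- rep(1L, n)
  ncen <- round(cens_frac * n)
  if (ncen > 0) {
    cen <- sample.int(n, ncen)
    status[cen] <- 0L
    tt[cen] <- tt[cen] * runif(ncen)
  }
  survival_dataset(X, tt, status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
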