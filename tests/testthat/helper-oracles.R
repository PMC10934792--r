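# independent oracles shared by unit and acceptance tests; each is a
# deliberately literal implementation, kept separate from the package's path

# double-loop sample Pearson correlation, 1/(n-1) convention
oracle_pearson <- function(trial) {
  n <- ncol(trial); nch <- nrow(trial)
  r <- matrix(0, nch, nch)
  for (a in seq_len(nch)) for (b in seq_len(nch)) {
    x <- trial[a, ]; y <- trial[b, ]
    r[a, b] <- sum((x - mean(x)) / sd(x) * (y - mean(y)) / sd(y)) / (n - 1)
  }
  r
}

# classic CSP via whitening of the composite covariance
csp_whitening_oracle <- function(q1, q2) {
  ec <- eigen(q1 + q2, symmetric = TRUE)
  wh <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  s <- wh %*% q1 %*% t(wh)
  es <- eigen((s + t(s)) / 2, symmetric = TRUE)
  t(wh) %*% es$vectors     # columns ordered by descending eigenvalue
}

principal_angle <- function(a, b) {
  acos(pmin(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))))
}

# random two-class epoch set with per-channel variance contrast
random_two_class <- function(seed, nch, n_per = 12L, ns = 80L) {
  set.seed(seed)
  scale0 <- runif(nch, 0.5, 2)
  scale1 <- runif(nch, 0.5, 2)
  d <- array(0, c(2L * n_per, nch, ns))
  for (i in seq_len(n_per)) {
    d[i, , ] <- matrix(rnorm(nch * ns), nch, ns) * scale0
    d[n_per + i, , ] <- matrix(rnorm(nch * ns), nch, ns) * scale1
  }
  epoch_set(d, labels = rep(0:1, each = n_per), sfreq = 100)
}

# --- literal transcriptions of the three sparrow update rules --------------

oracle_producers <- function(X, np, itermax, st) {
  r2 <- runif(1)
  for (i in seq_len(np)) {
    if (r2 < st) {
      a <- runif(1)
      for (j in seq_len(ncol(X))) X[i, j] <- X[i, j] * exp(-i / (a * itermax))
    } else {
      q <- rnorm(1)
      for (j in seq_len(ncol(X))) X[i, j] <- X[i, j] + q * 1
    }
    X[i, ] <- pmin(pmax(X[i, ], 0), 1)
  }
  X
}

oracle_scroungers <- function(X, np, xworst) {
  n <- nrow(X); d <- ncol(X); n2 <- n - np
  xbest <- X[1, ]
  for (i in seq_len(n2)) {
    r <- np + i
    if (i > n2 / 2) {
      q <- rnorm(1)
      for (j in seq_len(d)) X[r, j] <- q * exp((xworst[j] - X[r, j]) / i^2)
    } else {
      rr <- runif(d, -1, 1)
      step <- sum(rr * abs(X[r, ] - xbest)) / d
      for (j in seq_len(d)) X[r, j] <- xbest[j] + step
    }
    X[r, ] <- pmin(pmax(X[r, ], 0), 1)
  }
  X
}

oracle_scouts <- function(X, F, scout_idx, xbest, xworst, fg, fw, eps = 1e-10) {
  for (s in scout_idx) {
    if (F[s] != fg) {
      b <- rnorm(1)
      X[s, ] <- xbest + b * (X[s, ] - xbest)
    } else {
      k <- runif(1, -1, 1)
      X[s, ] <- X[s, ] + k * (X[s, ] - xworst) / ((F[s] - fw) + eps)
    }
    X[s, ] <- pmin(pmax(X[s, ], 0), 1)
  }
  X
}

evaluated_pop <- function(seed, n = 10L, d = 4L,
                          cfg = ssa_config(n = 10L, itermax = 20L)) {
  set.seed(seed)
  pop <- ssa_init_population(cfg, d)
  pop$F <- apply(pop$X, 1, function(x) sum((x - 0.3)^2))
  list(pop = pop, cfg = cfg)
}
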