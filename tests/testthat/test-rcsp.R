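test_that("per-trial covariance estimators match their definitions", {
  # hand-computed: E = [[1,0,1],[0,1,0]] -> EE' = diag(2,1), trace 3
  e <- rbind(c(1, 0, 1), c(0, 1, 0))
  expect_equal(normalized_covariance(e), diag(c(2, 1)) / 3)
  expect_lt(abs(sum(diag(normalized_covariance(e))) - 1), 1e-12)
  # scale invariance of the trace-normalized form
  set.seed(1)
  tr <- matrix(rnorm(4 * 60), 4, 60)
  expect_equal(normalized_covariance(tr * 5), normalized_covariance(tr),
               tolerance = 1e-12)
  # pairwise covariance: double-loop oracle, 1/(n-1), mean removal
  oracle <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4)
    oracle[a, b] <- sum((tr[a, ] - mean(tr[a, ])) *
                        (tr[b, ] - mean(tr[b, ]))) / (ncol(tr) - 1)
  expect_lt(max(abs(pairwise_covariance(tr) - oracle)), 1e-12)
  # shift invariance
  tr2 <- tr + c(1, 2, 3, 4)
  expect_equal(pairwise_covariance(tr2), pairwise_covariance(tr),
               tolerance = 1e-12)
  # mean-zero trial: equals EE'/(n-1)
  trc <- tr - rowMeans(tr)
  expect_equal(pairwise_covariance(trc), tcrossprod(trc) / (ncol(trc) - 1),
               tolerance = 1e-12)
  expect_error(normalized_covariance(matrix(0, 2, 3)), "zero-energy")
  expect_error(pairwise_covariance(matrix(1, 2, 1)), "2 samples")
})

test_that("class covariance averaging interpolates its two estimators", {
  set.seed(2)
  trials <- lapply(1:3, function(i) matrix(rnorm(3 * 40), 3, 40))
  a0 <- average_covariance(trials, alpha = 0)
  expect_equal(a0, Reduce(`+`, lapply(trials, normalized_covariance)) / 3,
               tolerance = 1e-12)
  a1 <- average_covariance(trials, alpha = 1)
  expect_equal(a1, Reduce(`+`, lapply(trials, pairwise_covariance)) / 3,
               tolerance = 1e-12)
  # alpha = 0.4 equals the hand-combined mixture
  a4 <- average_covariance(trials, alpha = 0.4)
  hand <- (0.6 * Reduce(`+`, lapply(trials, normalized_covariance)) +
           0.4 * Reduce(`+`, lapply(trials, pairwise_covariance))) / 3
  expect_lt(max(abs(a4 - hand)), 1e-12)
  expect_error(average_covariance(list(), 0.4), "empty class")
})

test_that("shrinkage preserves the trace and hits both limits", {
  set.seed(3)
  p <- crossprod(matrix(rnorm(25), 5, 5))
  expect_equal(regularize_covariance(p, 0), p)
  expect_equal(regularize_covariance(p, 1), (sum(diag(p)) / 5) * diag(5))
  for (beta in c(0, 0.01, 0.3, 0.7, 1))
    expect_lt(abs(sum(diag(regularize_covariance(p, beta))) - sum(diag(p))),
              1e-10)
})

test_that("unregularized fit reproduces classic CSP across random instances", {
  for (nch in c(4L, 8L, 16L)) {
    for (s in 1:5) {
      e <- random_two_class(1000L * nch + s, nch)
      m <- rcsp_fit(e, m = 2L, alpha = 0, beta = 0)
      wo <- csp_whitening_oracle(m$Q1, m$Q2)
      cols <- c(1:2, nch - 1L, nch)
      for (j in 1:4)
        expect_lt(principal_angle(m$omega2m[, j], wo[, cols[j]]), 1e-6)
    }
  }
})

test_that("generalized eigenpairs satisfy residual and Rayleigh identities", {
  e <- random_two_class(77L, 8L)
  m <- rcsp_fit(e, m = 2L, alpha = 0.4, beta = 0.01)
  for (j in seq_len(ncol(m$omega2m))) {
    w <- m$omega2m[, j]; l <- m$eigenvalues[j]
    resid <- sqrt(sum((m$Q1 %*% w - l * m$Q2 %*% w)^2))
    expect_lte(resid, 1e-8 * sqrt(sum((m$Q1 %*% w)^2)))
    rayleigh <- c(t(w) %*% m$Q1 %*% w) / c(t(w) %*% m$Q2 %*% w)
    expect_lt(abs(rayleigh - l), 1e-10)
    expect_lt(abs(c(t(w) %*% m$Q2 %*% w) - 1), 1e-10)  # scale convention
  }
  expect_error(rcsp_fit(e, m = 5L), "2m")
})

test_that("equal class covariances give unit eigenvalues and no separation", {
  set.seed(4)
  d <- array(rnorm(20 * 4 * 80), c(20, 4, 80))
  e <- epoch_set(d, labels = rep(0:1, 10), sfreq = 100)
  # same trials in both classes -> Q1 == Q2 by construction
  e$data[e$labels == 1L, , ] <- e$data[e$labels == 0L, , ]
  m <- rcsp_fit(e, m = 2L, alpha = 0.4, beta = 0.01)
  expect_lt(max(abs(m$eigenvalues - 1)), 1e-8)
})

test_that("log-variance features obey the scaling identity", {
  e <- random_two_class(5L, 6L)
  m <- rcsp_fit(e, m = 2L)
  f <- rcsp_transform(m, e)
  for (cc in c(0.1, 5)) {
    e2 <- e; e2$data <- e$data * cc
    f2 <- rcsp_transform(m, e2)
    expect_lt(max(abs(f2 - f - 2 * log(cc))), 1e-9)
  }
  expect_error(rcsp_transform(m, subset_epochs(e, channels = 1:3)),
               "channel count mismatch")
})

test_that("features separate classes with the sign pattern of the eigenvalues", {
  e <- random_two_class(6L, 6L, n_per = 30L)
  m <- rcsp_fit(e, m = 2L, alpha = 0.4, beta = 0.01)
  f <- rcsp_transform(m, e)
  mean0 <- colMeans(f[e$labels == 0L, ])
  mean1 <- colMeans(f[e$labels == 1L, ])
  # first m filters maximize class-0 (Q1) variance relative to class-1:
  # class-0 means exceed class-1 means there, and conversely for the last m
  expect_true(all(mean0[1:2] > mean1[1:2]))
  expect_true(all(mean0[3:4] < mean1[3:4]))
  # invariance to consistent channel relabeling
  perm <- sample(6L)
  ep <- subset_epochs(e, channels = perm)
  mp <- rcsp_fit(ep, m = 2L, alpha = 0.4, beta = 0.01)
  fp <- rcsp_transform(mp, ep)
  expect_equal(abs(fp), abs(rcsp_transform(m, e)), tolerance = 1e-6)
})
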