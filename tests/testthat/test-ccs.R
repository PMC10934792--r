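test_that("z-scoring normalizes every trial/channel to mean 0, sd 1", {
  e <- random_epochs(n_trials = 3L, n_channels = 4L, n_samples = 200L)
  z <- zscore_epochs(e)
  for (i in 1:3) for (j in 1:4) {
    expect_lt(abs(mean(z$data[i, j, ])), 1e-10)
    expect_lt(abs(sd(z$data[i, j, ]) - 1), 1e-10)
  }
  # affine invariance (positive slope)
  e2 <- e; e2$data <- 3.7 * e$data + 42
  expect_equal(zscore_epochs(e2)$data, z$data, tolerance = 1e-10)
  e3 <- e; e3$data[2, 3, ] <- 5
  expect_error(zscore_epochs(e3), "trial 2, channel 3")
})

test_that("pearson_matrix matches the double-loop transcription", {
  set.seed(8)
  for (rep in 1:20) {
    trial <- matrix(rnorm(5 * 50), 5, 50)
    r <- pearson_matrix(trial)
    expect_lt(max(abs(r - oracle_pearson(trial))), 1e-12)
    expect_lt(max(abs(r - t(r))), 1e-14)
    expect_equal(diag(r), rep(1, 5))
    expect_true(all(r >= -1 - 1e-12 & r <= 1 + 1e-12))
  }
  # duplicated channel -> 1; negated channel -> -1
  x <- rnorm(50)
  r2 <- pearson_matrix(rbind(x, x, -x))
  expect_equal(r2[1, 2], 1)
  expect_equal(r2[1, 3], -1)
  # affine rescaling of a channel leaves the matrix unchanged
  trial <- matrix(rnorm(4 * 60), 4, 60)
  trial2 <- trial; trial2[2, ] <- 2.5 * trial[2, ] + 3
  expect_equal(pearson_matrix(trial2), pearson_matrix(trial),
               tolerance = 1e-12)
  expect_error(pearson_matrix(matrix(1:3, 3, 1)), "2 samples")
  expect_error(pearson_matrix(rbind(x, rep(1, 50))), "zero-variance")
})

test_that("rank_channels orders by decreasing row mean with index ties", {
  expect_identical(rank_channels(diag(4)), 1:4)
  # one channel correlated 0.9 with all others -> ranked first
  r <- diag(5) * 0.1 + 0.0
  diag(r) <- 1
  r[5, 1:4] <- r[1:4, 5] <- 0.9
  expect_identical(rank_channels(r)[1], 5L)
  # permutation equivariance
  set.seed(9)
  m <- stats::cor(matrix(rnorm(200 * 4), 200, 4))
  p <- c(3L, 1L, 4L, 2L)
  rk <- rank_channels(m)
  rk_p <- rank_channels(m[p, p])
  expect_identical(p[rk_p], rk)
})

test_that("select_channels votes across trials and recovers a planted group", {
  e <- random_epochs(n_trials = 6L, n_channels = 5L, n_samples = 80L)
  all_sel <- select_channels(e, ns = 5L)
  expect_identical(sort(all_sel$selected), 1:5)
  expect_true(all(all_sel$votes == 6L))
  expect_identical(sum(all_sel$votes), 6L * 5L)   # votes sum = Nt * Ns
  # Nt = 1 equals that single trial's top-Ns
  one <- select_channels(e, ns = 2L, nt = 1L)
  z <- zscore_epochs(e)
  expect_identical(one$selected,
                   rank_channels(pearson_matrix(z$data[1, , ]))[1:2])
  expect_error(select_channels(e, ns = 9L), "exceeds channel count")
  # recovery of a correlated group (common oscillation on channels 1-4)
  hits <- 0L
  for (s in 1:10) {
    p <- synth_params(n_trials_per_class = 20L, n_channels = 16L,
                      informative_channels = list(class0 = integer(0),
                                                  class1 = integer(0)),
                      erd_depth = 0, osc_scale = 6,
                      common_mode_channels = 1:4, common_mode_scale = 10,
                      seed = 100L + s)
    sel <- select_channels(generate_epochs(p), ns = 4L, nt = 40L)
    if (setequal(sel$selected, 1:4)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("selection is invariant to trial order when votes are untied", {
  p <- synth_params(n_trials_per_class = 15L, n_channels = 8L,
                    informative_channels = list(class0 = integer(0),
                                                class1 = integer(0)),
                    erd_depth = 0, common_mode_channels = 1:3,
                    common_mode_scale = 10, seed = 55L)
  e <- generate_epochs(p)
  sel1 <- select_channels(e, ns = 3L)
  perm <- sample(n_trials(e))
  sel2 <- select_channels(subset_epochs(e, trials = perm), ns = 3L)
  expect_identical(sort(sel1$selected), sort(sel2$selected))
})
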