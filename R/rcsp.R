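#' @name rcsp
#' @title Regularized common spatial pattern (RCSP)
#'
#' @description
#' CSP finds spatial filters maximizing the variance of one class while
#' minimizing the other's, via the generalized eigenproblem
#' `Q1 w = lambda Q2 w` on the two class covariance matrices. The
#' regularized variant forms each class covariance as a convex combination
#' (weight `alpha`) of two per-trial estimators - the trace-normalized outer
#' product `E E' / trace(E E')` and the sample pairwise covariance - averaged
#' over trials, then shrinks it toward a scaled identity with weight `beta`:
#' `Q = (1 - beta) P + beta (trace(P)/Nch) I`. Shrinkage (`beta > 0`)
#' guarantees positive definiteness; the trace is preserved for every
#' `beta`. Features are the log-variances of the trial projected through
#' the `2m` filters belonging to the `m` largest and `m` smallest
#' generalized eigenvalues.
NULL

#' Trace-normalized covariance of one trial
#'
#' `C = E E' / trace(E E')` with no mean removal; `trace(C) = 1` and `C` is
#' invariant to rescaling of the trial.
#'
#' @param trial numeric matrix, channels x samples, nonzero energy.
#' @return `Nch x Nch` matrix.
#' @export
normalized_covariance <- function(trial) {
  ee <- tcrossprod(trial)
  tr <- sum(diag(ee))
  if (tr <= 0) stop("normalized_covariance: zero-energy trial", call. = FALSE)
  ee / tr
}

#' Pairwise sample covariance of one trial
#'
#' Sample covariance across channels with per-channel mean removal,
#' `1/(n-1)` convention.
#'
#' @param trial numeric matrix, channels x samples, >= 2 samples.
#' @return `Nch x Nch` matrix.
#' @export
pairwise_covariance <- function(trial) {
  if (ncol(trial) < 2L)
    stop("pairwise_covariance: need >= 2 samples", call. = FALSE)
  stats::cov(t(trial))
}

#' Average regularized-mixture covariance of one class
#'
#' `P = [(1 - alpha) * sum_i C_i + alpha * sum_i Chat_i] / Ntr` over the
#' class's trials, where `C_i` is the trace-normalized covariance and
#' `Chat_i` the pairwise covariance.
#'
#' @param trials list of channels x samples matrices (one class, >= 1).
#' @param alpha mixing weight in `[0, 1]`.
#' @return `Nch x Nch` matrix.
#' @export
average_covariance <- function(trials, alpha) {
  if (length(trials) == 0L)
    stop("average_covariance: empty class", call. = FALSE)
  acc <- 0
  for (e in trials)
    acc <- acc + (1 - alpha) * normalized_covariance(e) +
      alpha * pairwise_covariance(e)
  acc / length(trials)
}

#' Shrink a covariance toward scaled identity
#'
#' `Q = (1 - beta) P + beta (trace(P)/Nch) I`; trace-preserving, and
#' positive definite whenever `P` is positive semidefinite with positive
#' trace and `beta > 0`.
#'
#' @param p symmetric matrix.
#' @param beta shrinkage weight in `[0, 1]`.
#' @param nch dimension (defaults to `nrow(p)`).
#' @return `Nch x Nch` matrix.
#' @export
regularize_covariance <- function(p, beta, nch = nrow(p)) {
  (1 - beta) * p + beta * (sum(diag(p)) / nch) * diag(nch)
}

#' Fit an RCSP spatial filter bank
#'
#' Builds the regularized class covariances `Q1` (smaller label) and `Q2`
#' (larger label), solves the generalized eigenproblem
#' `Q1 w = lambda Q2 w` via Cholesky whitening of `Q2` and a symmetric
#' eigendecomposition, and keeps the eigenvectors of the `m` largest and
#' `m` smallest eigenvalues (in that column order). Eigenvectors are scaled
#' to `w' Q2 w = 1` with the first nonzero component positive, so fitted
#' models are byte-reproducible.
#'
#' @param epochs an `epoch_set` with exactly two classes.
#' @param m filter pairs (requires `2m <=` channel count).
#' @param alpha covariance mixing weight (default 0.4).
#' @param beta shrinkage weight (default 0.01).
#' @return an `rcsp_model`: list with `omega2m` (Nch x 2m), `eigenvalues`
#'   (length 2m, descending-then-ascending block order), `Q1`, `Q2`,
#'   `classes`, and the parameters.
#' @export
rcsp_fit <- function(epochs, m = 2L, alpha = 0.4, beta = 0.01) {
  validate_epoch_set(epochs, require_two_classes = TRUE)
  nch <- n_channels(epochs)
  if (2L * m > nch)
    stop("rcsp_fit: 2m (", 2L * m, ") exceeds channel count (", nch, ")",
         call. = FALSE)
  classes <- sort(unique(epochs$labels))
  # fast equivalent of average_covariance over a class: one crossproduct per
  # trial serves both estimators, since cov = (EE' - n mu mu') / (n - 1)
  class_cov <- function(cl) {
    idx <- which(epochs$labels == cl)
    ns_t <- dim(epochs$data)[3L]
    acc <- matrix(0, nch, nch)
    for (i in idx) {
      e <- epochs$data[i, , ]
      ee <- tcrossprod(e)
      mu <- rowMeans(e)
      acc <- acc + (1 - alpha) * (ee / sum(diag(ee))) +
        alpha * ((ee - ns_t * tcrossprod(mu)) / (ns_t - 1L))
    }
    acc / length(idx)
  }
  q1 <- regularize_covariance(class_cov(classes[1L]), beta, nch)
  q2 <- regularize_covariance(class_cov(classes[2L]), beta, nch)
  ch <- tryCatch(chol(q2), error = function(e)
    stop("rcsp_fit: class-2 covariance is numerically singular; ",
         "use beta > 0 to shrink toward identity", call. = FALSE))
  # whiten: with q2 = U'U, solve symmetric S = U^-T q1 U^-1, w = U^-1 y
  ui <- backsolve(ch, diag(nch))
  s <- crossprod(ui, q1 %*% ui)
  s <- (s + t(s)) / 2
  es <- eigen(s, symmetric = TRUE)           # eigenvalues descending
  keep <- c(seq_len(m), (nch - m + 1L):nch)
  w <- ui %*% es$vectors[, keep, drop = FALSE]
  # sign convention: first component of magnitude > tol positive
  for (j in seq_len(ncol(w))) {
    nz <- which(abs(w[, j]) > 1e-12)[1L]
    if (!is.na(nz) && w[nz, j] < 0) w[, j] <- -w[, j]
  }
  structure(list(omega2m = w, eigenvalues = es$values[keep],
                 Q1 = q1, Q2 = q2, classes = classes,
                 channel_names = epochs$channel_names,
                 m = m, alpha = alpha, beta = beta),
            class = "rcsp_model")
}

#' @export
print.rcsp_model <- function(x, ...) {
  cat(sprintf("<rcsp_model> %d channels, m = %d (alpha = %g, beta = %g)\n",
              nrow(x$omega2m), x$m, x$alpha, x$beta))
  cat("  eigenvalues:", format(x$eigenvalues, digits = 4), "\n")
  invisible(x)
}

#' Extract log-variance features
#'
#' Per trial, the signal is projected through the `2m` spatial filters and
#' each projection's sample variance over time (mean-removed, `1/(n-1)`) is
#' log-transformed: `f = ln var(w' E)`, with no normalization across
#' filters.
#'
#' @param model an `rcsp_model`.
#' @param epochs an `epoch_set` on the same channels.
#' @return numeric matrix, trials x 2m, column order matching `omega2m`.
#' @export
rcsp_transform <- function(model, epochs) {
  if (n_channels(epochs) != nrow(model$omega2m))
    stop("rcsp_transform: channel count mismatch (", n_channels(epochs),
         " vs ", nrow(model$omega2m), ")", call. = FALSE)
  nt <- n_trials(epochs)
  ns <- n_samples(epochs)
  feats <- matrix(0, nt, ncol(model$omega2m))
  for (i in seq_len(nt)) {
    proj <- crossprod(model$omega2m, epochs$data[i, , ])
    v <- (rowSums(proj^2) - ns * rowMeans(proj)^2) / (ns - 1L)
    if (any(v <= 0))
      stop("rcsp_transform: zero-variance projection in trial ", i,
           call. = FALSE)
    feats[i, ] <- log(v)
  }
  feats
}
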