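#' @name ccs
#' @title Correlation-based channel selection (CCS)
#'
#' @description
#' Channels engaged by the same motor-imagery task carry shared information
#' and therefore correlate; channels that correlate weakly with the rest are
#' mostly noise. CCS z-scores each trial, computes the Pearson correlation
#' matrix of the channels within each trial, ranks channels by the mean of
#' their correlation-matrix row, takes the top `Ns` per trial, and selects
#' the `Ns` channels appearing most frequently over `Nt` trials.
NULL

#' Z-score every trial/channel signal
#'
#' Per trial and channel, center to mean 0 and scale to standard deviation
#' 1 (sample convention, `1/(n-1)`) over the sample axis.
#'
#' @param epochs an `epoch_set`.
#' @return a z-scored `epoch_set`.
#' @export
zscore_epochs <- function(epochs) {
  d <- dim(epochs$data)
  m <- matrix(epochs$data, nrow = d[1L] * d[2L], ncol = d[3L])
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (d[3L] - 1L))
  bad <- which(sdv == 0)
  if (length(bad)) {
    tr <- (bad[1L] - 1L) %% d[1L] + 1L
    ch <- (bad[1L] - 1L) %/% d[1L] + 1L
    stop("zscore: zero-variance channel (trial ", tr, ", channel ", ch, ")",
         call. = FALSE)
  }
  out <- epochs
  out$data <- array((m - mu) / sdv, dim = d)
  out
}

#' Pearson correlation matrix of one trial
#'
#' Sample Pearson correlations (1/(n-1) convention) between all channel
#' pairs of a single trial.
#'
#' @param trial numeric matrix, channels x samples, >= 2 samples, no
#'   zero-variance channel.
#' @return symmetric `N x N` matrix with unit diagonal.
#' @export
pearson_matrix <- function(trial) {
  if (ncol(trial) < 2L)
    stop("pearson_matrix: need >= 2 samples", call. = FALSE)
  sds <- apply(trial, 1L, stats::sd)
  if (any(sds == 0))
    stop("pearson_matrix: zero-variance channel ", which(sds == 0)[1L],
         call. = FALSE)
  r <- stats::cor(t(trial))
  diag(r) <- 1
  r
}

#' Rank channels by mean correlation
#'
#' Orders channels by decreasing mean of their correlation-matrix row (the
#' diagonal is included by default); ties are broken by ascending channel
#' index.
#'
#' @param r an `N x N` correlation matrix.
#' @param exclude_diagonal drop the unit diagonal from the row means
#'   (default `FALSE`).
#' @return integer vector of channel indices, most correlated first.
#' @export
rank_channels <- function(r, exclude_diagonal = FALSE) {
  n <- nrow(r)
  rm <- if (exclude_diagonal) (rowSums(r) - diag(r)) / (n - 1L) else rowMeans(r)
  order(-rm, seq_len(n))
}

#' Select channels by cross-trial correlation voting
#'
#' For each of the first `Nt` trials (after z-scoring): compute the trial's
#' Pearson correlation matrix and keep the `Ns` channels with the highest
#' mean row correlation. Over the resulting `Nt x Ns` picks, the `Ns` most
#' frequently appearing channels are selected. Vote ties are broken by the
#' higher mean row-mean across the voting trials, then by channel index.
#'
#' @param epochs an `epoch_set` (raw; z-scoring is applied internally).
#' @param ns number of channels to select (`<=` channel count).
#' @param nt number of trials to vote with (default: all trials).
#' @param exclude_diagonal see [rank_channels()].
#' @return a `channel_selection`: list with `selected` (ordered indices),
#'   `selected_names`, `votes` (per-channel counts), and `mean_row_means`.
#' @export
select_channels <- function(epochs, ns, nt = NULL, exclude_diagonal = FALSE) {
  nch <- n_channels(epochs)
  if (ns > nch)
    stop("select_channels: ns (", ns, ") exceeds channel count (", nch, ")",
         call. = FALSE)
  if (is.null(nt)) nt <- n_trials(epochs)
  nt <- min(nt, n_trials(epochs))
  z <- zscore_epochs(epochs)
  votes <- integer(nch)
  row_mean_sum <- numeric(nch)
  for (i in seq_len(nt)) {
    r <- pearson_matrix(z$data[i, , ])
    rm <- if (exclude_diagonal) (rowSums(r) - diag(r)) / (nch - 1L)
          else rowMeans(r)
    top <- order(-rm, seq_len(nch))[seq_len(ns)]
    votes[top] <- votes[top] + 1L
    row_mean_sum <- row_mean_sum + rm
  }
  mean_rm <- row_mean_sum / nt
  sel <- order(-votes, -mean_rm, seq_len(nch))[seq_len(ns)]
  structure(list(selected = sel,
                 selected_names = epochs$channel_names[sel],
                 votes = votes, mean_row_means = mean_rm, ns = ns, nt = nt),
            class = "channel_selection")
}

#' @export
print.channel_selection <- function(x, ...) {
  cat("<channel_selection>", x$ns, "of", length(x$votes),
      "channels over", x$nt, "trials:\n ",
      paste(x$selected_names, collapse = ", "), "\n")
  invisible(x)
}
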