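#' Parameters for the synthetic motor-imagery EEG generator
#'
#' The generator emulates the phenomenology that the decoding pipeline
#' exploits: every channel carries 1/f^gamma background noise plus a
#' band-limited oscillation (the "sensorimotor rhythm"); during the planted
#' time window the oscillation's amplitude on the informative channels of a
#' trial's class is attenuated by `sqrt(1 - erd_depth)` - an event-related
#' desynchronization (ERD), a class-dependent band-power decrease confined
#' to a known time window, frequency band and channel subset.
#'
#' Defaults describe a realistic two-class session: 100 trials per class,
#' 16 channels at 125 Hz, 4-s trials starting at task onset, an alpha-band
#' rhythm (9-13 Hz) of 6 uV RMS over a 10 uV 1/f background, with a deep
#' (0.8) ERD planted at 0.5-2.5 s on two channels per class.
#'
#' @param n_trials_per_class trials per class (labels 0 and 1, balanced).
#' @param n_channels number of channels.
#' @param sfreq sampling rate, Hz.
#' @param trial_length trial duration, seconds.
#' @param t0 time of the first sample relative to task onset, seconds.
#' @param planted_segment a [tf_segment()]: the oscillation band and the ERD
#'   time window.
#' @param informative_channels list with elements `class0` and `class1`:
#'   1-based channel indices showing the ERD for trials of that class.
#' @param erd_depth fractional band-power attenuation in `[0, 1]`.
#' @param background_scale standard deviation of the 1/f background, uV.
#' @param osc_scale RMS amplitude of the band-limited oscillation, uV.
#' @param noise_exponent spectral slope gamma of the 1/f^gamma background.
#' @param ramp_sec raised-cosine on/off ramp of the ERD window, seconds.
#' @param common_mode_channels optional 1-based channel indices receiving an
#'   additional shared (identical across those channels) band-limited
#'   component - used to plant a mutually correlated channel group.
#' @param common_mode_scale RMS amplitude of the shared component, uV.
#' @param seed RNG seed; generation is bit-reproducible given the seed.
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(n_trials_per_class = 100L,
                         n_channels = 16L,
                         sfreq = 125,
                         trial_length = 4,
                         t0 = 0,
                         planted_segment = tf_segment(9, 4, 0.5, 2),
                         informative_channels = list(class0 = c(3L, 4L),
                                                     class1 = c(11L, 12L)),
                         erd_depth = 0.8,
                         background_scale = 10,
                         osc_scale = 6,
                         noise_exponent = 1,
                         ramp_sec = 0.1,
                         common_mode_channels = NULL,
                         common_mode_scale = 0,
                         seed = 1L) {
  p <- structure(as.list(environment()), class = "synth_params")
  validate_synth_params(p)
  p
}

validate_synth_params <- function(p) {
  seg <- p$planted_segment
  t_end <- p$t0 + p$trial_length
  if (seg$tstart < p$t0 || seg$tstart + seg$twidth > t_end)
    stop("synth_params: planted time window outside the trial extent",
         call. = FALSE)
  if (seg$fstart <= 0 || seg$fstart + seg$fwidth >= p$sfreq / 2)
    stop("synth_params: planted band outside (0, Nyquist)", call. = FALSE)
  if (p$erd_depth < 0 || p$erd_depth > 1)
    stop("synth_params: erd_depth must be in [0, 1]", call. = FALSE)
  all_inf <- unlist(p$informative_channels)
  if (length(all_inf) && (min(all_inf) < 1 || max(all_inf) > p$n_channels))
    stop("synth_params: informative channels outside the channel range",
         call. = FALSE)
  if (!is.null(p$common_mode_channels) &&
      (min(p$common_mode_channels) < 1 ||
       max(p$common_mode_channels) > p$n_channels))
    stop("synth_params: common-mode channels outside the channel range",
         call. = FALSE)
  invisible(p)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# n x m matrix of independent noise signals with amplitude spectrum
# proportional to `weights` (length n, weight 0 at DC), each column scaled
# to unit variance analytically, not empirically.
shaped_noise <- function(n, m, weights) {
  z <- matrix(stats::rnorm(n * m), n, m)
  zf <- stats::mvfft(z) * weights
  x <- Re(stats::mvfft(zf, inverse = TRUE)) / n
  # Var(x) = mean(weights^2) for white unit-variance input
  x / sqrt(mean(weights^2))
}

# spectral weights for 1/f^gamma background over FFT bin frequencies
pink_weights <- function(n, sfreq, gamma) {
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) * sfreq / n
  w <- numeric(n)
  w[f > 0] <- f[f > 0]^(-gamma / 2)
  w
}

# spectral weights of an ideal band-limited process on [lo, hi]
band_weights <- function(n, sfreq, lo, hi) {
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) * sfreq / n
  as.numeric(f >= lo & f <= hi)
}

# raised-cosine plateau window: 0 outside [a, b], ramps of `ramp` s inside
erd_window <- function(times, a, b, ramp) {
  w <- numeric(length(times))
  inside <- times >= a & times < b
  w[inside] <- 1
  if (ramp > 0) {
    up <- times >= a & times < a + ramp
    w[up] <- 0.5 * (1 - cos(pi * (times[up] - a) / ramp))
    dn <- times >= b - ramp & times < b
    w[dn] <- 0.5 * (1 - cos(pi * (b - times[dn]) / ramp))
  }
  w
}

#' Generate a synthetic two-class motor-imagery epoch_set
#'
#' See [synth_params()] for the generative model. Trials are labelled 0 and
#' 1 in equal numbers; the output is deterministic given `params$seed` and
#' does not disturb the caller's RNG state.
#'
#' @param params a `synth_params` object.
#' @return an `epoch_set` with `2 * n_trials_per_class` trials.
#' @export
generate_epochs <- function(params) {
  validate_synth_params(params)
  with_seed(params$seed, {
    ns <- as.integer(round(params$trial_length * params$sfreq))
    n_tr <- 2L * params$n_trials_per_class
    nch <- params$n_channels
    seg <- params$planted_segment
    times <- params$t0 + (seq_len(ns) - 1L) / params$sfreq

    labels <- rep(c(0L, 1L), each = params$n_trials_per_class)

    bg <- shaped_noise(ns, n_tr * nch,
                       pink_weights(ns, params$sfreq, params$noise_exponent)) *
      params$background_scale
    osc <- shaped_noise(ns, n_tr * nch,
                        band_weights(ns, params$sfreq,
                                     seg$fstart, seg$fstart + seg$fwidth)) *
      params$osc_scale

    # ERD: attenuate the oscillation inside the planted window on the
    # informative channels of the trial's class
    w <- erd_window(times, seg$tstart, seg$tstart + seg$twidth, params$ramp_sec)
    atten <- 1 - (1 - sqrt(1 - params$erd_depth)) * w
    inf <- list(params$informative_channels$class0,
                params$informative_channels$class1)
    for (i in seq_len(n_tr)) {
      chans <- inf[[labels[i] + 1L]]
      for (ch in chans) {
        col <- (i - 1L) * nch + ch
        osc[, col] <- osc[, col] * atten
      }
    }

    x <- bg + osc

    if (!is.null(params$common_mode_channels) && params$common_mode_scale > 0) {
      cm <- shaped_noise(ns, n_tr,
                         band_weights(ns, params$sfreq,
                                      seg$fstart, seg$fstart + seg$fwidth)) *
        params$common_mode_scale
      for (i in seq_len(n_tr)) {
        cols <- (i - 1L) * nch + params$common_mode_channels
        x[, cols] <- x[, cols] + cm[, i]
      }
    }

    # columns are (trial-major, channel-minor); reshape to [trial, ch, sample]
    data <- aperm(array(x, dim = c(ns, nch, n_tr)), c(3L, 2L, 1L))
    epoch_set(data, labels = labels, sfreq = params$sfreq, t0 = params$t0)
  })
}

#' Band power of epochs within a time-frequency segment
#'
#' Mean squared amplitude of the segment-bandpassed, time-cropped signal,
#' averaged over the given channels: the direct band-power measure used as
#' a test oracle for the generator and for segment application.
#'
#' @param epochs an `epoch_set`.
#' @param segment a `tf_segment` within the data extent.
#' @param channels 1-based channel indices (non-empty).
#' @return numeric vector, one power value per trial.
#' @export
band_power <- function(epochs, segment, channels) {
  if (length(channels) == 0L)
    stop("band_power: empty channel set", call. = FALSE)
  filt <- apply_segment(epochs, segment)
  apply(filt$data[, channels, , drop = FALSE]^2, 1L, mean)
}
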