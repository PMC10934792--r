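# small constructors used across test files

# epoch_set holding one identical signal on every trial/channel
sine_epochs <- function(freq, sfreq = 250, n_sec = 4, n_trials = 1L,
                        n_channels = 1L, amplitude = 1, t0 = 0) {
  t <- (seq_len(n_sec * sfreq) - 1L) / sfreq
  x <- amplitude * sin(2 * pi * freq * t)
  data <- array(0, c(n_trials, n_channels, length(t)))
  for (i in seq_len(n_trials))
    for (j in seq_len(n_channels))
      data[i, j, ] <- x
  epoch_set(data, labels = rep_len(c(0L, 1L), n_trials), sfreq = sfreq, t0 = t0)
}

random_epochs <- function(n_trials = 4L, n_channels = 3L, n_samples = 100L,
                          sfreq = 100, t0 = 0, seed = 42L) {
  set.seed(seed)
  epoch_set(array(rnorm(n_trials * n_channels * n_samples),
                  c(n_trials, n_channels, n_samples)),
            labels = rep_len(c(0L, 1L), n_trials), sfreq = sfreq, t0 = t0)
}

# steady-state amplitude, excluding `edge` seconds at both ends
steady_amp <- function(epochs, trial = 1L, channel = 1L, edge = 0.5) {
  x <- epochs$data[trial, channel, ]
  k <- as.integer(edge * epochs$sfreq)
  max(abs(x[(k + 1L):(length(x) - k)]))
}

# small synthetic set shared by pipeline tests (cheap: 8 channels, short)
small_synth <- function(seed = 7L, erd_depth = 0.8, n_per_class = 30L) {
  synth_params(
    n_trials_per_class = n_per_class, n_channels = 8L, sfreq = 125,
    trial_length = 3, planted_segment = tf_segment(9, 4, 0.5, 1.5),
    informative_channels = list(class0 = c(2L, 3L), class1 = c(6L, 7L)),
    erd_depth = erd_depth, seed = seed)
}

# cheap pipeline config for structural tests
small_config <- function() {
  cfg <- default_config()
  cfg$ssa$n <- 4L
  cfg$ssa$itermax <- 3L
  cfg$bounds$tmax <- 3
  cfg$svm$k <- 3L
  validate_config(cfg)
}
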