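#' Time-frequency segment
#'
#' The unit of search: a rectangle in the time-frequency plane described by
#' its frequency start and width (Hz) and its time start and width (s). The
#' optimizer's 4-dimensional positions decode to one of these.
#'
#' @param fstart,fwidth frequency start and width in Hz (`fwidth > 0`).
#' @param tstart,twidth time start and width in seconds (`twidth > 0`).
#' @return an object of class `tf_segment`.
#' @export
tf_segment <- function(fstart, fwidth, tstart, twidth) {
  if (fwidth <= 0 || twidth <= 0)
    stop("tf_segment: widths must be strictly positive", call. = FALSE)
  structure(list(fstart = fstart, fwidth = fwidth,
                 tstart = tstart, twidth = twidth), class = "tf_segment")
}

#' @export
print.tf_segment <- function(x, ...) {
  cat(sprintf("<tf_segment> %.2f-%.2f Hz, %.2f-%.2f s\n",
              x$fstart, x$fstart + x$fwidth, x$tstart, x$tstart + x$twidth))
  invisible(x)
}

#' Search bounds for segment optimization
#'
#' Defaults: time 0-4 s after task onset, frequency 1-40 Hz (covering the
#' sensorimotor alpha 8-12 Hz and beta 14-30 Hz rhythms), minimum widths
#' 2 Hz and 0.5 s.
#'
#' @param fmin,fmax frequency range in Hz.
#' @param tmin,tmax time range in seconds.
#' @param min_fwidth,min_twidth minimum segment widths.
#' @return an object of class `search_bounds`.
#' @export
search_bounds <- function(fmin = 1, fmax = 40, tmin = 0, tmax = 4,
                          min_fwidth = 2, min_twidth = 0.5) {
  stopifnot(fmax > fmin, tmax > tmin,
            min_fwidth > 0, min_fwidth <= fmax - fmin,
            min_twidth > 0, min_twidth <= tmax - tmin)
  structure(list(fmin = fmin, fmax = fmax, tmin = tmin, tmax = tmax,
                 min_fwidth = min_fwidth, min_twidth = min_twidth),
            class = "search_bounds")
}

bounds_from_config <- function(cfg) {
  b <- cfg$bounds
  search_bounds(fmin = b$fmin, fmax = b$fmax, tmin = b$tmin, tmax = b$tmax,
                min_fwidth = b$min_fwidth, min_twidth = b$min_twidth)
}

#' Decode a normalized search position into a segment
#'
#' The optimizer works in normalized `[0,1]^4` coordinates so that its
#' multiplicative position updates contract every dimension equally; this
#' map takes a raw position to a physically valid segment. Components are
#' clipped to `[0,1]` and then mapped affinely: the start coordinates span
#' `[min, max - min_width]` and the width coordinates span
#' `[min_width, max - start]`. By construction every position, however
#' extreme, yields a valid segment - there is no rejection.
#'
#' @param position numeric length-4 vector `(p_fstart, p_fwidth, p_tstart,
#'   p_twidth)`; finite, any range.
#' @param bounds a [search_bounds()].
#' @return a `tf_segment` satisfying the bounds.
#' @export
decode_position <- function(position, bounds) {
  stopifnot(length(position) == 4L, all(is.finite(position)))
  p <- pmin(pmax(position, 0), 1)
  fstart <- bounds$fmin + p[1L] * (bounds$fmax - bounds$min_fwidth - bounds$fmin)
  fwidth <- bounds$min_fwidth + p[2L] * (bounds$fmax - fstart - bounds$min_fwidth)
  tstart <- bounds$tmin + p[3L] * (bounds$tmax - bounds$min_twidth - bounds$tmin)
  twidth <- bounds$min_twidth + p[4L] * (bounds$tmax - tstart - bounds$min_twidth)
  tf_segment(fstart, fwidth, tstart, twidth)
}

#' Apply a time-frequency segment to an epoch_set
#'
#' Crops the epochs to the segment's time window `[tstart, tstart + twidth)`
#' and then bandpass-filters to `[fstart, fstart + fwidth]`. The
#' crop-then-filter order is fixed; with zero-phase reflect-padded filtering
#' the difference from filter-then-crop is confined to the window edges.
#'
#' @param epochs an `epoch_set`.
#' @param seg a `tf_segment`.
#' @return a cropped, filtered `epoch_set`.
#' @export
apply_segment <- function(epochs, seg) {
  hi <- seg$fstart + seg$fwidth
  if (hi >= epochs$sfreq / 2)
    stop("apply_segment: segment top (", hi, " Hz) reaches Nyquist (",
         epochs$sfreq / 2, " Hz)", call. = FALSE)
  out <- crop_time(epochs, seg$tstart, seg$tstart + seg$twidth)
  bandpass(out, seg$fstart, hi)
}

#' Interval Jaccard overlap between two segments
#'
#' Intersection-over-union of the time intervals and of the frequency
#' intervals of two segments; used to score recovery of a planted segment.
#'
#' @param a,b `tf_segment` objects.
#' @return named numeric: `time` and `freq` Jaccard indices in `[0,1]`.
#' @export
segment_jaccard <- function(a, b) {
  iou <- function(s1, w1, s2, w2) {
    inter <- max(0, min(s1 + w1, s2 + w2) - max(s1, s2))
    uni <- max(s1 + w1, s2 + w2) - min(s1, s2)
    if (uni <= 0) return(0)
    inter / uni
  }
  c(time = iou(a$tstart, a$twidth, b$tstart, b$twidth),
    freq = iou(a$fstart, a$fwidth, b$fstart, b$fwidth))
}
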