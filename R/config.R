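#' Default run configuration
#'
#' All tunable parameters of the decoding framework, centralized in one
#' nested list. The defaults are the values used throughout: sparrow search
#' with `n = 10` sparrows for `itermax = 20` iterations, producer ratio 0.7
#' and scout ratio 0.2; search bounds of 0-4 s after task onset and 1-40 Hz
#' with minimum segment widths of 2 Hz and 0.5 s; regularized CSP with
#' `m = 2` filter pairs, covariance mixing `alpha = 0.4` and shrinkage
#' `beta = 0.01`; RBF-SVM grid search over C and g in
#' \{0.001, 0.01, 0.1, 1, 10, 100, 1000\} with stratified five-fold
#' cross-validation; a stratified 7:3 train/test split.
#'
#' `ccs$ns` / `ccs$nt` default to `NULL`, meaning all channels are retained
#' and all available training trials vote. `svm$fast_grid = TRUE` restricts
#' the grid to a 3x3 subgrid (\{0.01, 1, 100\}) inside the optimizer's fitness
#' evaluations only; the final model is always tuned on the full 7x7 grid.
#'
#' @return a nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    ssa = list(n = 10L, itermax = 20L, producer_ratio = 0.7,
               scout_ratio = 0.2, k_sign_range = c(-1, 1)),
    bounds = list(tmin = 0, tmax = 4, fmin = 1, fmax = 40,
                  min_fwidth = 2, min_twidth = 0.5),
    ccs = list(ns = NULL, nt = NULL, exclude_diagonal = FALSE),
    rcsp = list(m = 2L, alpha = 0.4, beta = 0.01),
    svm = list(c_grid = c(0.001, 0.01, 0.1, 1, 10, 100, 1000),
               g_grid = c(0.001, 0.01, 0.1, 1, 10, 100, 1000),
               fast_c_grid = c(0.01, 1, 100),
               fast_g_grid = c(0.01, 1, 100),
               k = 5L, fast_grid = TRUE, standardize = TRUE),
    split = list(train_frac = 0.7, stratified = TRUE)
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' The config dialect is YAML mirroring the structure of
#' [default_config()]; any key absent from the file keeps its default.
#' Unknown keys and out-of-range values are errors.
#'
#' @param path path to a YAML file, or `NULL` for pure defaults.
#' @return a `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop("config file must be a YAML mapping", call. = FALSE)
  for (section in names(user)) {
    if (!section %in% names(cfg))
      stop("unknown config section: `", section, "`", call. = FALSE)
    for (key in names(user[[section]])) {
      if (!key %in% names(cfg[[section]]))
        stop("unknown config key: `", section, ".", key, "`", call. = FALSE)
      cfg[[section]][[key]] <- user[[section]][[key]]
    }
  }
  validate_config(cfg)
}

#' Validate a run configuration
#'
#' @param cfg a `run_config` list.
#' @return `cfg`, with integer-valued fields coerced, invisibly usable.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config: ", msg, call. = FALSE)
  cfg$ssa$n <- as.integer(cfg$ssa$n)
  cfg$ssa$itermax <- as.integer(cfg$ssa$itermax)
  chk(cfg$ssa$n >= 2, "ssa.n must be >= 2")
  chk(cfg$ssa$itermax >= 1, "ssa.itermax must be >= 1")
  chk(cfg$ssa$producer_ratio > 0 && cfg$ssa$producer_ratio <= 1,
      "ssa.producer_ratio must be in (0, 1]")
  chk(cfg$ssa$scout_ratio >= 0 && cfg$ssa$scout_ratio <= 1,
      "ssa.scout_ratio must be in [0, 1]")
  b <- cfg$bounds
  chk(b$tmax > b$tmin, "bounds: tmax must exceed tmin")
  chk(b$fmin > 0 && b$fmax > b$fmin, "bounds: need 0 < fmin < fmax")
  chk(b$min_fwidth > 0 && b$min_fwidth <= b$fmax - b$fmin,
      "bounds: min_fwidth must be positive and fit in the frequency range")
  chk(b$min_twidth > 0 && b$min_twidth <= b$tmax - b$tmin,
      "bounds: min_twidth must be positive and fit in the time range")
  if (!is.null(cfg$ccs$ns)) {
    cfg$ccs$ns <- as.integer(cfg$ccs$ns)
    chk(cfg$ccs$ns >= 1, "ccs.ns must be >= 1")
  }
  if (!is.null(cfg$ccs$nt)) {
    cfg$ccs$nt <- as.integer(cfg$ccs$nt)
    chk(cfg$ccs$nt >= 1, "ccs.nt must be >= 1")
  }
  cfg$rcsp$m <- as.integer(cfg$rcsp$m)
  chk(cfg$rcsp$m >= 1, "rcsp.m must be >= 1")
  chk(cfg$rcsp$alpha >= 0 && cfg$rcsp$alpha <= 1, "rcsp.alpha must be in [0, 1]")
  chk(cfg$rcsp$beta >= 0 && cfg$rcsp$beta <= 1, "rcsp.beta must be in [0, 1]")
  cfg$svm$k <- as.integer(cfg$svm$k)
  chk(cfg$svm$k >= 2, "svm.k must be >= 2")
  chk(all(cfg$svm$c_grid > 0) && all(cfg$svm$g_grid > 0),
      "svm grids must be positive")
  chk(cfg$split$train_frac > 0 && cfg$split$train_frac < 1,
      "split.train_frac must be in (0, 1)")
  structure(cfg, class = "run_config")
}
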