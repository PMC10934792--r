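#' @name ssa
#' @title Sparrow search algorithm (SSA)
#'
#' @description
#' A swarm metaheuristic with three behavioural roles, minimizing a scalar
#' fitness over the box `[0,1]^d`. After every evaluation the population is
#' sorted by fitness (ascending, ties by original index): the best
#' `ceil(producer_ratio * n)` sparrows are producers, the rest scroungers,
#' and each iteration an independent random 20% of the whole population
#' additionally act as scouts. Update rules:
#'
#' * **Producers** (rank `i` among producers): if the alarm value
#'   `R2 ~ U(0,1)` (drawn once per iteration) is below the safety threshold
#'   `ST ~ U(0.5,1)` (drawn once per run), the position contracts
#'   multiplicatively, `x <- x * exp(-i / (alpha * itermax))` with
#'   `alpha ~ U(0,1]` per sparrow; otherwise it takes a common normal step
#'   `x <- x + Q` with `Q ~ N(0,1)` per sparrow, added to every dimension.
#' * **Scroungers** (rank `i` among the `n2` scroungers): the worse half
#'   (`i > n2/2`) jump to `Q * exp((x_worst - x) / i^2)` componentwise with
#'   `Q ~ N(0,1)` per sparrow; the better half move to the best producer's
#'   position plus the mean over dimensions of `r_j * |x_j - xbest_j|`,
#'   `r_j ~ U(-1,1)` per dimension - a scalar offset applied to all
#'   dimensions.
#' * **Scouts**: a sparrow not currently at the best fitness moves to
#'   `xbest + beta * (x - xbest)` with `beta ~ N(0,1)`; a sparrow already at
#'   the best fitness takes a step `K * (x - x_worst) / ((f_i - f_w) + eps)`
#'   with `K ~ U(-1,1)` and `eps = 1e-10`.
#'
#' All positions are clipped to `[0,1]^d` after every update. The returned
#' optimum is elitist: the best position ever evaluated is retained even if
#' the population later moves away, so the best-fitness history is
#' non-increasing by construction.
NULL

SSA_EPS <- 1e-10

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' SSA configuration
#'
#' @param n population size (default 10).
#' @param itermax iteration limit (default 20).
#' @param producer_ratio fraction of the population acting as producers
#'   (default 0.7).
#' @param scout_ratio fraction acting as scouts each iteration (default 0.2).
#' @param k_sign_range range of the scout direction factor K (default
#'   `c(-1, 1)`; set `c(0, 1)` for the one-sided variant).
#' @return an object of class `ssa_config`.
#' @export
ssa_config <- function(n = 10L, itermax = 20L, producer_ratio = 0.7,
                       scout_ratio = 0.2, k_sign_range = c(-1, 1)) {
  if (n < 2L) stop("ssa_config: n must be >= 2", call. = FALSE)
  structure(list(n = as.integer(n), itermax = as.integer(itermax),
                 producer_ratio = producer_ratio, scout_ratio = scout_ratio,
                 k_sign_range = k_sign_range),
            class = "ssa_config")
}

#' Initialize a sparrow population
#'
#' Positions are drawn uniformly on `[0,1]^d` from the current RNG stream;
#' fitness is unset until the first evaluation.
#'
#' @param config an [ssa_config()].
#' @param d search dimension.
#' @return a `sparrow_population`: list with position matrix `X` (n x d),
#'   fitness `F` (NA until evaluated), and iteration counter `t`.
#' @export
ssa_init_population <- function(config, d) {
  structure(list(
    X = matrix(stats::runif(config$n * d), config$n, d),
    F = rep(NA_real_, config$n),
    t = 0L, Xbest = NULL, Xworst = NULL, fg = NA_real_, fw = NA_real_,
    n_producers = NA_integer_, scout_idx = NULL),
    class = "sparrow_population")
}

#' Sort the population and assign roles
#'
#' Sparrows are reordered by ascending fitness (stable in the original
#' index for ties); after sorting, rows `1..ceil(producer_ratio * n)` are
#' producers and the remainder scroungers. A scout subset of size
#' `round(scout_ratio * n)` is drawn uniformly from the whole population,
#' independent of role, using the current RNG stream. Best/worst trackers
#' (`Xbest`, `Xworst`, `fg`, `fw`) are refreshed.
#'
#' @param pop a `sparrow_population` with evaluated fitness.
#' @param config an [ssa_config()].
#' @return the updated `sparrow_population`.
#' @export
ssa_assign_roles <- function(pop, config) {
  if (anyNA(pop$F)) stop("assign_roles: fitness not evaluated", call. = FALSE)
  ord <- order(pop$F, seq_along(pop$F))
  pop$X <- pop$X[ord, , drop = FALSE]
  pop$F <- pop$F[ord]
  n <- config$n
  pop$n_producers <- as.integer(ceiling(config$producer_ratio * n))
  pop$Xbest <- pop$X[1L, ]
  pop$Xworst <- pop$X[n, ]
  pop$fg <- pop$F[1L]
  pop$fw <- pop$F[n]
  n_scouts <- as.integer(round(config$scout_ratio * n))
  pop$scout_idx <- if (n_scouts > 0L) sample.int(n, n_scouts) else integer(0)
  pop
}

#' Producer position update
#'
#' See the rule in the package SSA description. Draw order from the current
#' RNG stream: first the per-iteration alarm `R2 ~ U(0,1)`, then one random
#' scalar per producer in rank order (`alpha` on the contraction branch, `Q`
#' on the escape branch).
#'
#' @param pop a role-assigned `sparrow_population`.
#' @param config an [ssa_config()].
#' @param st safety threshold for this run (drawn once per run in
#'   [ssa_optimize()]).
#' @return the updated `sparrow_population`.
#' @export
ssa_update_producers <- function(pop, config, st) {
  r2 <- stats::runif(1)
  for (i in seq_len(pop$n_producers)) {
    if (r2 < st) {
      alpha <- stats::runif(1)
      pop$X[i, ] <- pop$X[i, ] * exp(-i / (alpha * config$itermax))
    } else {
      q <- stats::rnorm(1)
      pop$X[i, ] <- pop$X[i, ] + q
    }
    pop$X[i, ] <- clip01(pop$X[i, ])
  }
  pop
}

#' Scrounger position update
#'
#' Ranks are within the scrounger block (rows after the producers). The
#' reference best position is the best producer's already-updated position
#' (row 1). Draw order per scrounger in rank order: `Q ~ N(0,1)` on the
#' leave branch, `d` i.i.d. `U(-1,1)` variates on the follow branch.
#'
#' @inheritParams ssa_update_producers
#' @return the updated `sparrow_population`.
#' @export
ssa_update_scroungers <- function(pop, config, st) {
  n <- config$n
  np <- pop$n_producers
  n2 <- n - np
  if (n2 <= 0L) return(pop)
  d <- ncol(pop$X)
  xbest_new <- pop$X[1L, ]
  for (i in seq_len(n2)) {
    r <- np + i
    if (i > n2 / 2) {
      q <- stats::rnorm(1)
      pop$X[r, ] <- q * exp((pop$Xworst - pop$X[r, ]) / i^2)
    } else {
      rr <- stats::runif(d, -1, 1)
      pop$X[r, ] <- xbest_new + mean(rr * abs(pop$X[r, ] - xbest_new))
    }
    pop$X[r, ] <- clip01(pop$X[r, ])
  }
  pop
}

#' Scout position update
#'
#' Applied to the scout subset drawn in [ssa_assign_roles()], in draw
#' order. Reference positions and fitness (`Xbest`, `Xworst`, `fg`, `fw`)
#' are those recorded at the start of the iteration. Draw order per scout:
#' `beta ~ N(0,1)` if the scout is not at the best fitness, otherwise
#' `K ~ U(k_sign_range)`.
#'
#' @inheritParams ssa_update_producers
#' @return the updated `sparrow_population`.
#' @export
ssa_update_scouts <- function(pop, config, st) {
  kr <- config$k_sign_range
  for (s in pop$scout_idx) {
    if (pop$F[s] != pop$fg) {
      beta <- stats::rnorm(1)
      pop$X[s, ] <- pop$Xbest + beta * (pop$X[s, ] - pop$Xbest)
    } else {
      k <- stats::runif(1, kr[1L], kr[2L])
      pop$X[s, ] <- pop$X[s, ] +
        k * (pop$X[s, ] - pop$Xworst) / ((pop$F[s] - pop$fw) + SSA_EPS)
    }
    pop$X[s, ] <- clip01(pop$X[s, ])
  }
  pop
}

#' Run the sparrow search optimizer
#'
#' Minimizes `fitness_fn` over `[0,1]^d`: evaluate, assign roles, update
#' producers, scroungers and scouts, repeat for `itermax` iterations. The
#' safety threshold `ST ~ U(0.5, 1)` is drawn once at the start of the run.
#' Uses the caller's RNG stream (seed outside for reproducibility).
#'
#' @param fitness_fn function mapping a length-`d` position in `[0,1]^d` to
#'   a finite scalar (lower is better). Must not error; wrap failures as
#'   worst-case fitness if needed.
#' @param config an [ssa_config()].
#' @param d search dimension.
#' @return list with `best_position`, `best_fitness` (elitist best-ever),
#'   `history` (best-so-far fitness after each iteration, non-increasing),
#'   `n_evaluations`, and the final `population`.
#' @export
ssa_optimize <- function(fitness_fn, config, d) {
  eval_count <- 0L
  eval_all <- function(X) {
    apply(X, 1L, function(x) {
      eval_count <<- eval_count + 1L
      v <- tryCatch(fitness_fn(x), error = function(e)
        stop("fitness evaluation failed at evaluation ", eval_count + 0L,
             ": ", conditionMessage(e), call. = FALSE))
      if (!is.finite(v)) stop("fitness returned a non-finite value",
                              call. = FALSE)
      v
    })
  }
  st <- stats::runif(1, 0.5, 1)
  pop <- ssa_init_population(config, d)
  pop$F <- eval_all(pop$X)
  best_i <- which.min(pop$F)
  best_pos <- pop$X[best_i, ]
  best_fit <- pop$F[best_i]
  history <- numeric(config$itermax)
  for (t in seq_len(config$itermax)) {
    pop$t <- t
    pop <- ssa_assign_roles(pop, config)
    pop <- ssa_update_producers(pop, config, st)
    pop <- ssa_update_scroungers(pop, config, st)
    pop <- ssa_update_scouts(pop, config, st)
    pop$F <- eval_all(pop$X)
    it_best <- which.min(pop$F)
    if (pop$F[it_best] < best_fit) {
      best_fit <- pop$F[it_best]
      best_pos <- pop$X[it_best, ]
    }
    history[t] <- best_fit
  }
  list(best_position = best_pos, best_fitness = best_fit,
       history = history, n_evaluations = eval_count, population = pop)
}
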