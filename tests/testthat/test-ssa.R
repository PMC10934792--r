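test_that("initial population is uniform on the unit box and seed-stable", {
  cfg <- ssa_config(n = 10L)
  set.seed(1); a <- ssa_init_population(cfg, 4L)
  set.seed(1); b <- ssa_init_population(cfg, 4L)
  expect_identical(a$X, b$X)
  expect_identical(dim(a$X), c(10L, 4L))
  expect_true(all(a$X >= 0 & a$X <= 1))
  set.seed(2)
  big <- ssa_init_population(ssa_config(n = 10000L), 4L)
  expect_lt(abs(mean(big$X) - 0.5), 0.02)
  expect_error(ssa_config(n = 1L), "n must be >= 2")
})

test_that("roles split 70/30 by fitness with stable ties and 20% scouts", {
  ep <- evaluated_pop(3)
  set.seed(4)
  pop <- ssa_assign_roles(ep$pop, ep$cfg)
  expect_identical(pop$n_producers, 7L)
  expect_identical(length(pop$scout_idx), 2L)
  expect_identical(pop$F, sort(pop$F))      # best first: best is a producer
  expect_identical(pop$fg, min(pop$F))
  expect_identical(pop$fw, max(pop$F))
  # all-equal fitness: stable index order
  ep2 <- evaluated_pop(5)
  ep2$pop$F <- rep(0.5, 10)
  X_before <- ep2$pop$X
  set.seed(6)
  pop2 <- ssa_assign_roles(ep2$pop, ep2$cfg)
  expect_identical(pop2$X, X_before)
  expect_error(ssa_assign_roles(ssa_init_population(ep$cfg, 4L), ep$cfg),
               "not evaluated")
})

test_that("producer update matches its literal transcription and contracts", {
  ep <- evaluated_pop(7)
  set.seed(8); pop <- ssa_assign_roles(ep$pop, ep$cfg)
  for (st in c(1, 0)) {   # force the contraction branch, then the escape one
    set.seed(9); got <- ssa_update_producers(pop, ep$cfg, st)
    set.seed(9); want <- oracle_producers(pop$X, pop$n_producers,
                                          ep$cfg$itermax, st)
    expect_lt(max(abs(got$X - want)), 1e-12)
  }
  # contraction: componentwise no larger in magnitude
  set.seed(10); contr <- ssa_update_producers(pop, ep$cfg, st = 1)
  np <- pop$n_producers
  expect_true(all(contr$X[1:np, ] <= pop$X[1:np, ] + 1e-15))
  expect_true(all(contr$X >= 0 & contr$X <= 1))
})

test_that("scrounger update matches its transcription; fixed points hold", {
  ep <- evaluated_pop(11)
  set.seed(12); pop <- ssa_assign_roles(ep$pop, ep$cfg)
  pop <- ssa_update_producers(pop, ep$cfg, st = 1)
  set.seed(13); got <- ssa_update_scroungers(pop, ep$cfg, st = 1)
  set.seed(13); want <- oracle_scroungers(pop$X, pop$n_producers, pop$Xworst)
  expect_lt(max(abs(got$X - want)), 1e-12)
  expect_true(all(got$X >= 0 & got$X <= 1))
  # follower scrounger already at the best position stays there
  pop2 <- pop
  pop2$X[8, ] <- pop2$X[1, ]       # rank i = 1 of n2 = 3, i <= n2/2
  set.seed(14); fixed <- ssa_update_scroungers(pop2, ep$cfg, st = 1)
  expect_equal(fixed$X[8, ], pop2$X[1, ], tolerance = 1e-15)
  # leaving scrounger exactly at Xworst: position becomes Q (then clipped)
  pop3 <- pop
  pop3$X[10, ] <- pop3$Xworst      # rank i = 3 > n2/2
  set.seed(15); left <- ssa_update_scroungers(pop3, ep$cfg, st = 1)
  # draw order: rank 1 (follow) uses runif(4); ranks 2 and 3 (leave) one
  # rnorm each -> the rank-3 Q is the second rnorm after runif(4)
  set.seed(15); runif(4); q2 <- rnorm(2)[2]
  expect_equal(left$X[10, ], pmin(pmax(rep(q2, 4), 0), 1), tolerance = 1e-12)
})

test_that("scout update matches its transcription; fixed points hold", {
  ep <- evaluated_pop(16)
  set.seed(17); pop <- ssa_assign_roles(ep$pop, ep$cfg)
  set.seed(18); got <- ssa_update_scouts(pop, ep$cfg, st = 1)
  set.seed(18); want <- oracle_scouts(pop$X, pop$F, pop$scout_idx,
                                      pop$Xbest, pop$Xworst, pop$fg, pop$fw)
  expect_lt(max(abs(got$X - want)), 1e-12)
  # scout at Xbest with fi != fg remains at Xbest
  pop2 <- pop
  pop2$scout_idx <- 5L
  pop2$X[5, ] <- pop2$Xbest
  set.seed(19); fixed <- ssa_update_scouts(pop2, ep$cfg, st = 1)
  expect_equal(fixed$X[5, ], pop2$Xbest, tolerance = 1e-15)
  # scout with the best fitness sitting at Xworst: numerator zero, unchanged
  pop3 <- pop
  pop3$scout_idx <- 1L
  pop3$X[1, ] <- pop3$Xworst
  x_before <- pop3$X[1, ]
  set.seed(20); same <- ssa_update_scouts(pop3, ep$cfg, st = 1)
  expect_equal(same$X[1, ], x_before, tolerance = 1e-15)
})

test_that("optimizer respects the box, elitism, and the evaluation budget", {
  sphere <- function(x) sum((x - 0.3)^2)
  for (s in 1:5) {
    set.seed(s)
    r <- ssa_optimize(sphere, ssa_config(), 4L)
    expect_true(all(diff(r$history) <= 0))
    expect_identical(r$n_evaluations, 210L)            # n * (itermax + 1)
    expect_true(all(r$population$X >= 0 & r$population$X <= 1))
    expect_true(all(r$best_position >= 0 & r$best_position <= 1))
    expect_lte(r$best_fitness, min(r$history))
  }
  # constant fitness: flat history, no error
  set.seed(30)
  flat <- ssa_optimize(function(x) 1, ssa_config(), 4L)
  expect_true(all(flat$history == 1))
  # erroring fitness aborts with context
  set.seed(31)
  expect_error(ssa_optimize(function(x) stop("boom"), ssa_config(), 4L),
               "fitness evaluation failed")
})

test_that("sparrow search solves the sphere benchmark and beats random search", {
  sphere <- function(x) sum((x - 0.3)^2)
  n_seeds <- 20L
  finals <- numeric(n_seeds); wins <- 0L
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    r <- ssa_optimize(sphere, ssa_config(), 4L)
    finals[s] <- r$best_fitness
    set.seed(s + 10000L)
    rnd <- min(apply(matrix(runif(200 * 4), 200, 4), 1, sphere))
    if (r$best_fitness < rnd) wins <- wins + 1L
  }
  expect_lt(median(finals), 1e-2)
  expect_gte(wins, 18L)   # 90% of seeds
})
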