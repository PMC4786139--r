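test_that("exploration ratio follows the stepped 10^w * t/T schedule", {
  expect_equal(exploration_ratio(5, 100), 1)        # pre-threshold regime
  expect_equal(exploration_ratio(20, 100), 20)      # w = 2
  expect_equal(exploration_ratio(60, 100), 600)     # w = 3
  expect_equal(exploration_ratio(80, 100), 8e3)     # w = 4
  expect_equal(exploration_ratio(92, 100), 9.2e4)   # w = 5
  expect_equal(exploration_ratio(96, 100), 9.6e5)   # w = 6
  expect_error(exploration_ratio(101, 100), "0 <= t <= T")
  expect_error(exploration_ratio(1, 0), "at least 1")
  # non-decreasing over the whole iteration range
  vals <- vapply(0:200, exploration_ratio, numeric(1), T_max = 200)
  expect_true(all(diff(vals) >= 0))
  expect_true(all(vals >= 1))
})

test_that("chaotic ratio interpolates between exploration and the base envelope", {
  expect_equal(chaotic_exploration_ratio(20, 100, 0.5), sqrt(20))
  expect_equal(chaotic_exploration_ratio(20, 100, 1), 20)    # recovers base
  expect_equal(chaotic_exploration_ratio(5, 100, 0.7), 1)    # early phase
  # bounded by [1, base ratio] along a whole tent orbit
  xs <- chaos_sequence(chaotic_map("tent"), 70)
  for (t in seq_len(70)) {
    r <- chaotic_exploration_ratio(t, 70, xs[t])
    expect_gte(r, 1)
    expect_lte(r, exploration_ratio(t, 70))
  }
  # replace coupling ignores the envelope
  expect_equal(chaotic_exploration_ratio(5, 100, 0.25, coupling = "replace"), 4)
})

test_that("bounds shrink symmetrically and centre on the antlion", {
  s <- shrink_bounds(c(0, 0), c(1, 1), 10)
  expect_equal(s$lower, c(0, 0))
  expect_equal(s$upper, c(0.1, 0.1))
  expect_equal(shrink_bounds(-1, 1, 2), list(lower = -0.5, upper = 0.5))
  s1 <- shrink_bounds(c(0.2, 0.4), c(0.8, 0.9), 1)
  expect_equal(s1, list(lower = c(0.2, 0.4), upper = c(0.8, 0.9))) # identity
  expect_error(shrink_bounds(0, 1, 0.5), ">= 1")

  cb <- center_bounds(-0.05, 0.05, 0.5)
  expect_equal(cb, list(lower = 0.45, upper = 0.55))
  expect_equal(center_bounds(c(-0.1, -0.2), c(0.1, 0.2), c(0, 0)),
               list(lower = c(-0.1, -0.2), upper = c(0.1, 0.2)))
  # translation preserves interval width
  cb2 <- center_bounds(c(-0.3, 0.1), c(0.2, 0.4), c(5, -2))
  expect_equal(cb2$upper - cb2$lower, c(0.5, 0.3))
  expect_error(center_bounds(c(0, 0), c(1, 1), 0.5), "equal length")
})

test_that("random walks take unit steps from zero", {
  expect_equal(random_walk(5, u = rep(0.9, 5)), 0:5)    # all-up walk
  expect_equal(random_walk(5, u = rep(0.1, 5)), -(0:5)) # all-down walk
  expect_equal(random_walk(4, u = rep(0.5, 4)), -(0:4)) # draw == 0.5 steps down
  set.seed(9)
  w <- random_walk(200)
  expect_equal(w[1], 0)
  expect_true(all(abs(diff(w)) == 1))
})

test_that("walk normalization maps extremes onto the interval bounds", {
  expect_equal(normalize_walk(c(0, 1, 2), 0.4, 0.6), c(0.4, 0.5, 0.6))
  expect_equal(normalize_walk(c(-3, -3), 0.4, 0.6), c(0.5, 0.5)) # degenerate
  set.seed(4)
  for (i in 1:20) {
    w <- random_walk(50)
    lo <- runif(1, 0, 0.4); hi <- lo + runif(1, 0.1, 0.5)
    nw <- normalize_walk(w, lo, hi)
    expect_equal(min(nw), lo)
    expect_equal(max(nw), hi)
    expect_true(all(nw >= lo & nw <= hi))
  }
  expect_error(normalize_walk(c(0, 1), 0.6, 0.4), "exceed")
})

test_that("roulette selection favours lower fitness under minimization", {
  expect_identical(roulette_select(0.3), 1L)
  set.seed(7)
  # equal fitness -> uniform over agents
  draws <- replicate(6000, roulette_select(rep(0.5, 3)))
  freq <- tabulate(draws, 3) / 6000
  expect_true(all(abs(freq - 1 / 3) < 0.03))
  # weights (max - f + eps): the worse agent has weight ~eps, so the
  # better one is selected essentially always
  draws <- replicate(10000, roulette_select(c(0.1, 0.9)))
  expect_true(all(draws == 1L))
  expect_error(roulette_select(numeric(0)), "empty")
  expect_error(roulette_select(c(1, NA)), "finite")
})

test_that("ant repositioning averages the two walks and clips to the domain", {
  expect_equal(reposition_ant(0.3, 0.3), 0.3)
  expect_equal(reposition_ant(0.2, 0.4), 0.3)
  expect_equal(reposition_ant(1.4, 1.0, lower = 0, upper = 1), 1)
  expect_equal(reposition_ant(-0.5, 0.1, lower = 0, upper = 1), 0)
})

test_that("greedy replacement absorbs strictly fitter ants only", {
  state <- list(
    ants = rbind(c(1, 1), c(2, 2), c(3, 3)),
    antlions = rbind(c(9, 9), c(8, 8), c(7, 7)),
    ant_fitness = c(0.1, 0.3, 0.2),
    antlion_fitness = c(0.2, 0.2, 0.2))
  out <- greedy_replacement(state)
  expect_equal(out$antlions[1, ], c(1, 1))     # fitter ant caught
  expect_equal(out$antlions[2, ], c(8, 8))     # worse ant ignored
  expect_equal(out$antlions[3, ], c(7, 7))     # tie leaves antlion unchanged
  expect_equal(out$antlion_fitness, c(0.1, 0.2, 0.2))
  expect_true(all(out$antlion_fitness <= state$antlion_fitness))
})

test_that("the optimizer converges on the sphere function", {
  res <- alo_run(function(x) sum(x^2), dim = 5, lower = -1, upper = 1,
                 agents = 8, iterations = 70, seed = 1)
  expect_lt(res$best_fitness, 0.05)
})

test_that("runs are deterministic and leave the caller's RNG unharmed", {
  sphere <- function(x) sum(x^2)
  set.seed(123)
  before <- runif(1)
  r1 <- alo_run(sphere, dim = 4, lower = -1, upper = 1, seed = 11,
                iterations = 30)
  r2 <- alo_run(sphere, dim = 4, lower = -1, upper = 1, seed = 11,
                iterations = 30)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$best_position, r2$best_position)
  set.seed(123)
  expect_identical(runif(1), before)
})

test_that("elite fitness traces never increase and positions stay in-domain", {
  seen <- new.env(); seen$bad <- 0L
  watched <- function(x) {
    if (any(x < -1 - 1e-12 | x > 1 + 1e-12)) seen$bad <- seen$bad + 1L
    sum((x - 0.2)^2)
  }
  for (mode in list(alo_schedule("base"),
                    alo_schedule("chaotic", chaotic_map("tent")),
                    alo_schedule("chaotic", chaotic_map("logistic")))) {
    res <- alo_run(watched, dim = 6, lower = -1, upper = 1, seed = 5,
                   iterations = 40, schedule = mode)
    expect_true(all(diff(res$trace) <= 0))
  }
  expect_identical(seen$bad, 0L)
})

test_that("forced positions bound the initial elite from above", {
  sphere <- function(x) sum(x^2)
  forced <- rep(1, 4)
  res <- alo_run(sphere, dim = 4, lower = 0, upper = 1, seed = 2,
                 iterations = 10, forced = forced)
  expect_lte(res$trace[1], sphere(forced))
  expect_lte(res$best_fitness, sphere(forced))
})

test_that("the engine validates its inputs", {
  sphere <- function(x) sum(x^2)
  expect_error(alo_run(sphere, dim = 3, lower = 1, upper = 0, seed = 1),
               "lower bounds")
  expect_error(alo_run(sphere, dim = 3, schedule = "chaotic", seed = 1),
               "alo_schedule")
  expect_error(alo_run(function(x) NaN, dim = 3, seed = 1),
               "non-finite")
  expect_error(alo_schedule("chaotic", map = "tent"), "chaotic_map")
})
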