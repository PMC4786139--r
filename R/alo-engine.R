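# The antlion optimizer engine: shrinking walk bounds, random walks,
# roulette selection, greedy replacement, elitism, and the chaotic
# exploration schedule.

#' Exploration ratio of the antlion optimizer
#'
#' The ratio `I` divides the random-walk bounds at iteration `t` of `T`,
#' shrinking them as the search progresses: `I = 10^w * t/T`, where the
#' exponent `w` steps through 2, 3, 4, 5, 6 as `t/T` crosses 0.1, 0.5,
#' 0.75, 0.9 and 0.95. Below `t = 0.1 T` no shrinking is applied and the
#' ratio is 1 (full exploration).
#'
#' @param t current iteration, `0 <= t <= T`.
#' @param T_max total number of iterations, at least 1.
#' @return a scalar ratio `>= 1`, non-decreasing in `t`.
#' @export
exploration_ratio <- function(t, T_max) {
  if (T_max < 1) stop("T_max must be at least 1", call. = FALSE)
  if (t < 0 || t > T_max) stop("iteration t must satisfy 0 <= t <= T_max",
                               call. = FALSE)
  ratio <- t / T_max
  if (ratio <= 0.1) return(1)
  w <- if (ratio > 0.95) 6
       else if (ratio > 0.9) 5
       else if (ratio > 0.75) 4
       else if (ratio > 0.5) 3
       else 2
  max(1, 10^w * ratio)
}

#' Exploration schedule configuration
#'
#' In `"base"` mode the optimizer uses the quasi-linear ratio of
#' [exploration_ratio()] unchanged. In `"chaotic"` mode a chaotic map is
#' advanced once per optimizer iteration and its value `x_t` in `(0, 1)`
#' modulates the ratio, alternating phases of exploration and exploitation
#' instead of a monotone hand-over.
#'
#' Two couplings are available:
#' \describe{
#'   \item{`"exponent"` (default)}{effective ratio
#'     \eqn{\hat I_t = \max(1, I_t^{x_t})}: as \eqn{x_t \to 0} the walk is
#'     unbounded again (exploration), as \eqn{x_t \to 1} the base
#'     exploitation envelope \eqn{I_t} is recovered, so the chaotic ratio is
#'     always confined to \eqn{[1, I_t]}.}
#'   \item{`"replace"`}{envelope-free alternative, \eqn{1/\hat I_t = x_t}:
#'     the map value directly sets the exploration rate, ignoring the base
#'     schedule. Provided for sensitivity checks.}
#' }
#'
#' @param mode `"base"` or `"chaotic"`.
#' @param map a [chaotic_map()]; required in chaotic mode.
#' @param coupling `"exponent"` or `"replace"`; see Details.
#' @return an object of class `alo_schedule`.
#' @export
alo_schedule <- function(mode = c("base", "chaotic"), map = NULL,
                         coupling = c("exponent", "replace")) {
  mode <- match.arg(mode)
  coupling <- match.arg(coupling)
  if (mode == "chaotic") {
    if (is.null(map)) map <- chaotic_map("tent")
    if (!inherits(map, "chaotic_map")) {
      stop("map must be a chaotic_map object", call. = FALSE)
    }
  }
  structure(list(mode = mode, map = map, coupling = coupling),
            class = "alo_schedule")
}

#' Chaos-modulated exploration ratio
#'
#' Applies the schedule's coupling to the base ratio `I_t` of
#' [exploration_ratio()] given the current chaos value `x`.
#'
#' @param t,T_max current and total iterations.
#' @param x current chaotic map value in `[0, 1]`.
#' @param coupling `"exponent"` or `"replace"`; see [alo_schedule()].
#' @return effective ratio `>= 1`; for the exponent coupling it is bounded
#'   above by `exploration_ratio(t, T_max)`.
#' @export
chaotic_exploration_ratio <- function(t, T_max, x,
                                      coupling = c("exponent", "replace")) {
  coupling <- match.arg(coupling)
  base <- exploration_ratio(t, T_max)
  if (coupling == "exponent") {
    max(1, base^x)
  } else {
    max(1, 1 / max(x, .Machine$double.eps))
  }
}

#' Shrink the global walk bounds by the exploration ratio
#'
#' Divides both the lower and upper bound vectors by `I`, shrinking the
#' admissible random-walk interval radius by the factor `1/I`. (Dividing
#' only one of the two would invert intervals; the shrink is applied
#' symmetrically.)
#'
#' @param lower,upper numeric bound vectors of equal length.
#' @param I exploration ratio `>= 1`.
#' @return list with shrunken `lower` and `upper` vectors.
#' @export
shrink_bounds <- function(lower, upper, I) {
  if (I < 1) stop("exploration ratio I must be >= 1", call. = FALSE)
  list(lower = lower / I, upper = upper / I)
}

#' Centre walk bounds on an antlion
#'
#' Translates the shrunken bounds to the selected antlion's position so the
#' ant's random walk happens around its trap: `c_i = c_t + antlion`,
#' `d_i = d_t + antlion`. The interval width is preserved.
#'
#' @param lower,upper shrunken bound vectors (from [shrink_bounds()]).
#' @param antlion antlion position vector, same length.
#' @return list with translated `lower` and `upper`.
#' @export
center_bounds <- function(lower, upper, antlion) {
  if (length(lower) != length(antlion) || length(upper) != length(antlion)) {
    stop("bound and position vectors must have equal length", call. = FALSE)
  }
  list(lower = lower + antlion, upper = upper + antlion)
}

#' Unit-step random walk
#'
#' Generates the cumulative sum `X` of `n_steps` Bernoulli steps: each step
#' is `+1` when a uniform draw exceeds 0.5 and `-1` otherwise, with
#' `X[1] = 0` prepended. Consecutive values always differ by exactly 1.
#'
#' @param n_steps number of steps, at least 1.
#' @param u optional vector of `n_steps` uniform draws in `[0, 1]`; by
#'   default drawn from the current RNG stream.
#' @return numeric vector of length `n_steps + 1` starting at 0.
#' @export
random_walk <- function(n_steps, u = stats::runif(n_steps)) {
  if (n_steps < 1) stop("n_steps must be at least 1", call. = FALSE)
  steps <- ifelse(u > 0.5, 1, -1)
  c(0, cumsum(steps))
}

#' Min-max normalize a random walk into an interval
#'
#' Affinely maps the walk so that its minimum lands on `lower` and its
#' maximum on `upper`. A constant walk (degenerate case) maps every entry
#' to the interval midpoint.
#'
#' @param walk numeric vector.
#' @param lower,upper scalar interval bounds with `upper > lower`.
#' @return vector of the same length, every entry in `[lower, upper]`.
#' @export
normalize_walk <- function(walk, lower, upper) {
  if (upper <= lower) stop("upper must exceed lower", call. = FALSE)
  a <- min(walk)
  b <- max(walk)
  if (a == b) return(rep((lower + upper) / 2, length(walk)))
  # clamp away float rounding so the output honours the interval exactly
  clamp((walk - a) * (upper - lower) / (b - a) + lower, lower, upper)
}

#' Roulette-wheel selection under minimization
#'
#' Selects an index with probability proportional to the max-shifted weight
#' `w_j = max(fitness) - fitness_j + 1e-12`, so lower (better) fitness is
#' strictly more probable whenever fitnesses differ, and equal fitnesses
#' yield a uniform draw.
#'
#' @param fitness finite numeric vector of minimized fitness values.
#' @return a single index in `1:length(fitness)`.
#' @export
roulette_select <- function(fitness) {
  if (length(fitness) == 0) stop("fitness vector is empty", call. = FALSE)
  if (any(!is.finite(fitness))) stop("fitness values must be finite",
                                     call. = FALSE)
  if (length(fitness) == 1) return(1L)
  w <- (max(fitness) - fitness) + 1e-12
  sample.int(length(fitness), 1L, prob = w)
}

#' Reposition an ant from its two guided walks
#'
#' The new position is the arithmetic mean of the walk around the
#' roulette-selected antlion and the walk around the elite, clipped into
#' the global search domain.
#'
#' @param walk_selected,walk_elite same-iteration normalized walk values
#'   (scalars or vectors of equal length).
#' @param lower,upper global domain bounds.
#' @return clipped mean position.
#' @export
reposition_ant <- function(walk_selected, walk_elite, lower = 0, upper = 1) {
  clamp((walk_selected + walk_elite) / 2, lower, upper)
}

#' Greedy antlion replacement
#'
#' An antlion that has caught a fitter ant relocates to the ant's position:
#' for each agent `i`, if `ant_fitness[i] < antlion_fitness[i]` (strict),
#' the antlion takes the ant's position and fitness. Ties leave the antlion
#' unchanged.
#'
#' @param state list with matrices `ants`, `antlions` (agents x dimensions)
#'   and vectors `ant_fitness`, `antlion_fitness`.
#' @return the state with updated `antlions` and `antlion_fitness`.
#' @export
greedy_replacement <- function(state) {
  caught <- state$ant_fitness < state$antlion_fitness
  if (any(caught)) {
    state$antlions[caught, ] <- state$ants[caught, , drop = FALSE]
    state$antlion_fitness[caught] <- state$ant_fitness[caught]
  }
  state
}

# Centre the shrunken bounds on a guide with the reference ALO's random
# sign flip: each bound keeps or flips its sign with probability 1/2
# before translation, so the walk interval can lie on either side of the
# guide. Without the flip a zero lower bound pins every interval above
# the guide and coordinates can never decrease once the population
# converges.
signed_center <- function(shrunk_lower, shrunk_upper, guide) {
  lo <- if (stats::runif(1) < 0.5) shrunk_lower else -shrunk_lower
  hi <- if (stats::runif(1) < 0.5) shrunk_upper else -shrunk_upper
  list(lower = pmin(lo, hi) + guide, upper = pmax(lo, hi) + guide)
}

# One guided walk value per dimension: fresh n_steps-walk per dimension,
# min-max normalized into the (shrunken, centred) per-dimension interval,
# read at walk index t (0-based; position t + 1).
guided_walk_values <- function(t, n_steps, lower_i, upper_i) {
  dim <- length(lower_i)
  steps <- matrix(ifelse(stats::runif(n_steps * dim) > 0.5, 1, -1),
                  nrow = n_steps, ncol = dim)
  walks <- rbind(0, col_cumsum(steps))        # (n_steps + 1) x dim
  a <- apply(walks, 2L, min)
  b <- apply(walks, 2L, max)
  val <- walks[t + 1L, ]
  span <- b - a
  out <- ifelse(span == 0, (lower_i + upper_i) / 2,
                (val - a) * (upper_i - lower_i) / span + lower_i)
  out
}

#' Run the (chaotic) antlion optimizer
#'
#' Minimizes `objective` over the box `[lower, upper]^dim` with `agents`
#' ants and antlions for `iterations` iterations. Each iteration, every ant
#' random-walks around a roulette-selected antlion and around the elite
#' within bounds shrunk by the exploration ratio (base or chaos-modulated,
#' per `schedule`) and centred on the guide with a random sign flip per
#' bound (the trap neighbourhood may lie on either side of the guide),
#' takes the mean of the two walks (clipped to the domain), and is
#' re-evaluated; antlions greedily absorb fitter ants and
#' the elite is updated. The chaotic map advances exactly once per
#' iteration.
#'
#' Rows of `forced` overwrite the first agents of both initial populations,
#' e.g. the all-ones position in feature selection, which guarantees the
#' returned best fitness never exceeds the full-feature fitness.
#'
#' @param objective function mapping a length-`dim` numeric position to a
#'   finite scalar to be minimized.
#' @param dim problem dimensionality.
#' @param lower,upper global domain bounds (scalars or length-`dim`
#'   vectors); default unit box.
#' @param agents number of search agents, at least 2; default 8.
#' @param iterations number of iterations; default 70.
#' @param schedule an [alo_schedule()]; default base mode.
#' @param seed optional integer seed; the same seed and configuration give
#'   a bit-identical result. The caller's RNG state is restored on exit.
#' @param forced optional numeric vector or matrix of positions forced into
#'   the initial populations.
#' @return an object of class `alo_result`: list with `best_position`,
#'   `best_fitness`, `trace` (elite fitness per iteration, non-increasing),
#'   `evaluations`, and the call configuration.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- alo_run(sphere, dim = 3, lower = -1, upper = 1, seed = 1,
#'                agents = 6, iterations = 30)
#' res$best_fitness
#' @export
alo_run <- function(objective, dim, lower = 0, upper = 1, agents = 8,
                    iterations = 70, schedule = alo_schedule("base"),
                    seed = NULL, forced = NULL) {
  stopifnot(is.function(objective), dim >= 1, agents >= 2, iterations >= 1)
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(lower >= upper)) stop("lower bounds must be below upper bounds",
                                call. = FALSE)
  if (!inherits(schedule, "alo_schedule")) {
    stop("schedule must be an alo_schedule object", call. = FALSE)
  }

  evaluate <- function(pos) {
    f <- objective(as.numeric(pos))
    if (!is.numeric(f) || length(f) != 1 || !is.finite(f)) {
      stop("objective returned a non-finite value at position [",
           paste(signif(pos, 4), collapse = ", "), "]", call. = FALSE)
    }
    f
  }

  with_seed(seed, {
    init <- function() {
      u <- matrix(stats::runif(agents * dim), agents, dim)
      sweep(sweep(u, 2L, upper - lower, "*"), 2L, lower, "+")
    }
    ants <- init()
    antlions <- init()
    if (!is.null(forced)) {
      forced <- matrix(as.numeric(forced), ncol = dim)
      nf <- min(nrow(forced), agents)
      ants[seq_len(nf), ] <- forced[seq_len(nf), ]
      antlions[seq_len(nf), ] <- forced[seq_len(nf), ]
    }
    ant_fitness <- apply(ants, 1L, evaluate)
    antlion_fitness <- apply(antlions, 1L, evaluate)
    n_evals <- 2L * agents

    elite_idx <- which.min(antlion_fitness)
    elite_pos <- antlions[elite_idx, ]
    elite_fit <- antlion_fitness[elite_idx]

    chaos <- if (schedule$mode == "chaotic") {
      chaos_sequence(schedule$map, iterations)
    } else NULL

    trace <- numeric(iterations)
    for (t in seq_len(iterations)) {
      I_t <- if (is.null(chaos)) {
        exploration_ratio(t, iterations)
      } else {
        chaotic_exploration_ratio(t, iterations, chaos[t], schedule$coupling)
      }
      shrunk <- shrink_bounds(lower, upper, I_t)
      for (i in seq_len(agents)) {
        j <- roulette_select(antlion_fitness)
        b_sel <- signed_center(shrunk$lower, shrunk$upper, antlions[j, ])
        b_eli <- signed_center(shrunk$lower, shrunk$upper, elite_pos)
        walk_sel <- guided_walk_values(t, iterations, b_sel$lower, b_sel$upper)
        walk_eli <- guided_walk_values(t, iterations, b_eli$lower, b_eli$upper)
        ants[i, ] <- reposition_ant(walk_sel, walk_eli, lower, upper)
      }
      ant_fitness <- apply(ants, 1L, evaluate)
      n_evals <- n_evals + agents
      st <- greedy_replacement(list(ants = ants, antlions = antlions,
                                    ant_fitness = ant_fitness,
                                    antlion_fitness = antlion_fitness))
      antlions <- st$antlions
      antlion_fitness <- st$antlion_fitness
      best <- which.min(antlion_fitness)
      if (antlion_fitness[best] < elite_fit) {
        elite_fit <- antlion_fitness[best]
        elite_pos <- antlions[best, ]
      }
      trace[t] <- elite_fit
    }

    structure(list(best_position = elite_pos, best_fitness = elite_fit,
                   trace = trace, evaluations = n_evals, agents = agents,
                   iterations = iterations, schedule = schedule, seed = seed),
              class = "alo_result")
  })
}

#' @export
print.alo_result <- function(x, ...) {
  mode <- if (x$schedule$mode == "chaotic") {
    paste0("chaotic (", x$schedule$map$name, ")")
  } else "base"
  cat("<alo_result> best fitness ", signif(x$best_fitness, 6), " after ",
      x$iterations, " iterations (", x$agents, " agents, ", mode,
      " schedule)\n", sep = "")
  invisible(x)
}
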