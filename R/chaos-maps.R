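# Chaotic maps used to modulate the exploration/exploitation schedule.

#' Construct a chaotic map
#'
#' A chaotic map is a deterministic recurrence on `(0, 1)` with sensitive
#' dependence on its initial condition. Five classical one-dimensional maps
#' are supported; their iterates drive the chaotic exploration schedule of
#' [alo_run()].
#'
#' The recurrences are, for state \eqn{x_k}:
#' \describe{
#'   \item{logistic}{\eqn{x_{k+1} = a x_k (1 - x_k)}, \eqn{a \in (0, 4]}.}
#'   \item{sinusoidal}{\eqn{x_{k+1} = a x_k^2 \sin(\pi x_k)}, chaotic for
#'     \eqn{a = 2.3}.}
#'   \item{tent}{\eqn{x_{k+1} = x_k / 0.7} for \eqn{x_k < 0.7}, else
#'     \eqn{(10/3)\, x_k (1 - x_k)}.}
#'   \item{singer}{\eqn{x_{k+1} = \mu (7.86 x_k - 23.31 x_k^2 + 28.75 x_k^3
#'     - 13.3 x_k^4)}, \eqn{\mu \in [0.9, 1.08]}.}
#'   \item{piecewise}{a four-branch tent-like map with breakpoints at
#'     \eqn{p}, \eqn{0.5} and \eqn{1 - p}, \eqn{p \in (0,1)}, \eqn{p \neq 0.5}.}
#' }
#'
#' Initial conditions whose logistic orbit provably collapses
#' (`x0` in `{0.25, 0.5, 0.75}`: fixed points or preimages of them at `a = 4`)
#' are rejected at construction time.
#'
#' @param name one of `"logistic"`, `"sinusoidal"`, `"tent"`, `"singer"`,
#'   `"piecewise"`.
#' @param x0 initial state, strictly inside `(0, 1)`.
#' @param a multiplier for the logistic (default 4) and sinusoidal
#'   (default 2.3) maps; ignored otherwise.
#' @param mu singer-map multiplier in `[0.9, 1.08]`; default 1.07.
#' @param p piecewise-map breakpoint in `(0, 1)`, not 0.5; default 0.4.
#' @return an object of class `chaotic_map`.
#' @examples
#' m <- chaotic_map("tent")
#' chaos_sequence(m, 5)
#' @export
chaotic_map <- function(name = c("logistic", "sinusoidal", "tent", "singer",
                                 "piecewise"),
                        x0 = 0.7, a = NULL, mu = 1.07, p = 0.4) {
  if (is.character(name) && length(name) == 1 &&
      !name %in% c("logistic", "sinusoidal", "tent", "singer", "piecewise")) {
    stop("unknown chaotic map '", name, "'", call. = FALSE)
  }
  name <- match.arg(name)
  if (!is.numeric(x0) || length(x0) != 1 || x0 <= 0 || x0 >= 1) {
    stop("x0 must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (is.null(a)) a <- switch(name, logistic = 4, sinusoidal = 2.3, NA_real_)
  if (name == "logistic") {
    if (a <= 0 || a > 4) stop("logistic multiplier a must be in (0, 4]",
                              call. = FALSE)
    if (x0 %in% c(0.25, 0.5, 0.75)) {
      stop("logistic x0 in {0.25, 0.5, 0.75} collapses to a degenerate orbit",
           call. = FALSE)
    }
  }
  if (name == "singer" && (mu < 0.9 || mu > 1.08)) {
    stop("singer multiplier mu must be in [0.9, 1.08]", call. = FALSE)
  }
  if (name == "piecewise" && (p <= 0 || p >= 1 || p == 0.5)) {
    stop("piecewise breakpoint p must be in (0, 1) and not 0.5", call. = FALSE)
  }
  structure(list(name = name, x0 = x0, a = a, mu = mu, p = p),
            class = "chaotic_map")
}

#' Advance a chaotic map by one step
#'
#' Evaluates the map's recurrence once at state `x`. The tent map's first
#' branch applies for `x < 0.7`; the value 0.7 itself takes the second
#' branch (it is a fixed point of it).
#'
#' @param map a [chaotic_map()] object.
#' @param x current state in `[0, 1]`.
#' @return the next state, in `[0, 1]`.
#' @export
map_step <- function(map, x) {
  if (!inherits(map, "chaotic_map")) stop("map must be a chaotic_map object",
                                          call. = FALSE)
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop("map state x must be a single value in [0, 1]", call. = FALSE)
  }
  out <- switch(map$name,
    logistic   = map$a * x * (1 - x),
    sinusoidal = map$a * x^2 * sin(pi * x),
    tent       = if (x < 0.7) x / 0.7 else (10 / 3) * x * (1 - x),
    singer     = map$mu * (7.86 * x - 23.31 * x^2 + 28.75 * x^3 - 13.3 * x^4),
    piecewise  = {
      p <- map$p
      if (x < p)            x / p
      else if (x < 0.5)     (x - p) / (0.5 - p)
      else if (x < (1 - p)) (1 - p - x) / (0.5 - p)
      else                  (1 - x) / p
    }
  )
  # clip away sub-eps float excursions; the maps are analytically in [0, 1]
  min(max(out, 0), 1)
}

#' Iterate a chaotic map
#'
#' Produces the orbit `x_1, ..., x_n` starting from the map's `x0`
#' (`x_1 = map_step(map, x0)`). The sequence is fully determined by the map
#' specification; no random number generation is involved.
#'
#' @param map a [chaotic_map()] object.
#' @param n number of iterates, at least 1.
#' @return numeric vector of length `n`, all values in `[0, 1]`.
#' @export
chaos_sequence <- function(map, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  out <- numeric(n)
  x <- map$x0
  for (k in seq_len(n)) {
    x <- map_step(map, x)
    out[k] <- x
  }
  out
}

#' @export
print.chaotic_map <- function(x, ...) {
  par <- switch(x$name,
    logistic = paste0("a = ", x$a),
    sinusoidal = paste0("a = ", x$a),
    singer = paste0("mu = ", x$mu),
    piecewise = paste0("p = ", x$p),
    "")
  cat("<chaotic_map> ", x$name,
      if (nzchar(par)) paste0(" (", par, ")"), ", x0 = ", x$x0, "\n", sep = "")
  invisible(x)
}
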