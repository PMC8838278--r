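#' Shrink coefficient schedule of the whale optimizer
#'
#' Linear decrease from 2 at iteration 0 to 0 at the final iteration:
#' `2 - t * 2 / max_iter`.
#'
#' @param t Iteration counter, `0 <= t <= max_iter`.
#' @param max_iter Total number of iterations (>= 1).
#' @return Scalar in [0, 2].
#' @export
update_shrink <- function(t, max_iter) {
  if (max_iter < 1) stop("max_iter must be at least 1")
  if (t < 0 || t > max_iter) stop("t must lie in [0, max_iter]")
  2 - t * 2 / max_iter
}

#' One whale-optimization position update
#'
#' Applies one of the three WOA moves to a single agent, chosen by the random
#' draws: with probability 1/2 (ran < 0.5) a shrinking-encircling move toward
#' the best-known position when the coefficient vector V2 is small
#' (exploitation), or a move relative to a randomly chosen agent when V2 is
#' large (exploration); otherwise (ran >= 0.5) a logarithmic spiral around
#' the best position. The coefficient vectors are `V1 = 2 r` and
#' `V2 = 2 a r - a` with `r ~ U[0,1]^D` and `a` the shrink coefficient; the
#' exploration switch fires when the magnitude of the representative (first)
#' component of V2 is at least 1, so exploration is frequent while `a` is
#' near 2 and impossible once `a < 1`. The spiral constant is b = 1. The
#' result is clamped to the box `[lower, upper]^D`.
#'
#' @param position Current position (D-vector).
#' @param best Best-known position (D-vector).
#' @param random_agent Position of a randomly selected agent (D-vector).
#' @param shrink_alpha Shrink coefficient a in [0, 2].
#' @param draws List with `r` (D-vector in [0,1]), `h` (scalar in [-1,1]),
#'   `ran` (scalar in [0,1]). Supplying the draws explicitly makes the update
#'   a pure function, which the optimizer exploits for reproducibility.
#' @param lower,upper Box bounds (scalars).
#' @return Updated position (D-vector), clamped to the box.
#' @export
woa_position_update <- function(position, best, random_agent, shrink_alpha,
                                draws, lower = 0, upper = 1) {
  d <- length(position)
  if (length(best) != d || length(random_agent) != d || length(draws$r) != d)
    stop("dimension mismatch")
  v1 <- 2 * draws$r
  v2 <- 2 * shrink_alpha * draws$r - shrink_alpha
  if (draws$ran < 0.5) {
    if (abs(v2[1]) < 1) {             # encircling (exploitation)
      psi <- abs(v1 * best - position)
      newpos <- best - v2 * psi
    } else {                          # exploration toward a random agent
      psi <- abs(v1 * random_agent - position)
      newpos <- abs(random_agent - psi * v2)
    }
  } else {                            # spiral bubble-net move
    psi <- abs(best - position)
    newpos <- psi * exp(draws$h) * cos(2 * pi * draws$h) + best
  }
  pmin(pmax(newpos, lower), upper)
}

#' Whale optimization of a continuous objective
#'
#' Population metaheuristic alternating prey-encircling (exploitation),
#' spiral bubble-net movement, and random-agent exploration. Minimizes `fn`
#' over a box; the best-so-far fitness trace is non-increasing by
#' construction. Fully deterministic given `seed`.
#'
#' @param fn Objective `function(x) -> scalar`, lower is better.
#' @param dim Problem dimension D.
#' @param n_agents Number of search agents.
#' @param max_iter Number of iterations.
#' @param lower,upper Box bounds (scalars).
#' @param seed Integer seed.
#' @return List with `best_position`, `best_fitness`, `trace` (best fitness
#'   after each iteration, length `max_iter`) and `n_evaluations`.
#' @examples
#' woa_optimize(function(x) sum(x^2), dim = 2, n_agents = 10,
#'              max_iter = 25, lower = -1, upper = 1, seed = 1)$best_fitness
#' @export
woa_optimize <- function(fn, dim, n_agents = 20L, max_iter = 50L,
                         lower = 0, upper = 1, seed = 0L) {
  stopifnot(dim >= 1, n_agents >= 2, max_iter >= 1, lower < upper)
  rng <- local_rng(seed)
  pos <- matrix(rng$runif(n_agents * dim, lower, upper), n_agents, dim)
  fit <- apply(pos, 1, fn)
  best_i <- which.min(fit)
  best <- pos[best_i, ]
  best_fit <- fit[best_i]
  trace <- numeric(max_iter)
  for (t in seq_len(max_iter)) {
    a <- update_shrink(t - 1, max_iter)
    for (i in seq_len(n_agents)) {
      j <- rng$sample_int(n_agents)
      draws <- list(r = rng$runif(dim), h = rng$runif(1, -1, 1),
                    ran = rng$runif(1))
      pos[i, ] <- woa_position_update(pos[i, ], best, pos[j, ], a, draws,
                                      lower, upper)
      f <- fn(pos[i, ])
      if (f < best_fit) {
        best_fit <- f
        best <- pos[i, ]
      }
    }
    trace[t] <- best_fit
  }
  list(best_position = best, best_fitness = best_fit, trace = trace,
       n_evaluations = n_agents * (max_iter + 1L))
}

## internal: private RNG stream that never touches the global .Random.seed
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  with_state <- function(expr_fn) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    })
    expr_fn()
  }
  list(
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    rnorm = function(n, mean = 0, sd = 1) with_state(function() stats::rnorm(n, mean, sd)),
    sample_int = function(n, size = 1L) with_state(function() sample.int(n, size)),
    sample_vec = function(x) with_state(function() sample(x))
  )
}
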