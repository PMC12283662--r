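#' Particle swarm optimizer configuration
#'
#' @param n_particles Swarm size (>= 1).
#' @param n_iters Number of iterations (>= 1).
#' @param c1,c2 Cognitive and social learning factors (>= 0). `c1` weighs
#'   attraction to a particle's own best position (`pbest`), `c2` attraction
#'   to the swarm best (`gbest`).
#' @param omega Inertia factor; larger values favour global exploration,
#'   smaller ones local refinement. Default 0.7, inside the practical
#'   0.4--0.9 tuning range.
#' @param bounds `[d x 2]` matrix of per-dimension `(lo, hi)` box bounds.
#' @param seed Integer seed controlling initialization and the velocity
#'   random factors.
#' @param rand_mode `"per_dimension"` draws the two random factors per
#'   particle per dimension (default); `"per_particle"` draws one scalar pair
#'   per particle.
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(n_particles = 10L, n_iters = 100L, c1 = 1.7, c2 = 1.7,
                       omega = 0.7, bounds, seed = 1L,
                       rand_mode = c("per_dimension", "per_particle")) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L || any(bounds[, 1] >= bounds[, 2]))
    stopf("bounds must be a [d x 2] matrix with lo < hi per dimension")
  if (any(!is.finite(bounds))) stopf("bounds must be finite")
  if (n_particles < 1L || n_iters < 1L)
    stopf("n_particles and n_iters must be at least 1")
  if (c1 < 0 || c2 < 0) stopf("c1 and c2 must be non-negative")
  structure(list(n_particles = as.integer(n_particles),
                 n_iters = as.integer(n_iters), c1 = c1, c2 = c2,
                 omega = omega, bounds = bounds, seed = as.integer(seed),
                 rand_mode = match.arg(rand_mode)),
            class = "pso_config")
}

eval_fitness <- function(fitness, x) {
  f <- tryCatch(fitness(x), error = function(e) Inf)
  if (!is.numeric(f) || length(f) != 1L || is.na(f)) Inf else f
}

#' One particle swarm step
#'
#' Velocity update
#' `v <- omega*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)` with `r1`, `r2`
#' drawn independently in (0, 1), followed by the canonical position update
#' `x <- x + v`. Velocities are clamped to +/-(hi - lo) and positions clipped
#' to the bounds per dimension (required for stability when `c1 + c2 > 4`,
#' as in the 4.494/4.494 weight-search setting). A candidate with non-finite
#' fitness is rejected: `pbest` stays unchanged.
#'
#' @param state Swarm state as produced by [pso_optimize()] internals: list
#'   with matrices `x`, `v`, `pbest` (`[n_particles x d]`), vectors
#'   `pbest_fit`, `gbest`, scalar `gbest_fit`.
#' @param cfg A [pso_config()].
#' @param fitness Function mapping a position vector to a scalar to minimize.
#' @param rand1,rand2 Optional fixed random-factor matrices
#'   (`[n_particles x d]`) replayed instead of fresh draws -- used for
#'   deterministic verification of the update rule.
#' @return The updated state.
#' @export
pso_step <- function(state, cfg, fitness, rand1 = NULL, rand2 = NULL) {
  d <- ncol(state$x); np <- nrow(state$x)
  lo <- cfg$bounds[, 1]; hi <- cfg$bounds[, 2]
  draw <- function() {
    if (cfg$rand_mode == "per_dimension")
      matrix(stats::runif(np * d), np, d)
    else matrix(rep(stats::runif(np), d), np, d)
  }
  if (is.null(rand1)) rand1 <- draw()
  if (is.null(rand2)) rand2 <- draw()
  v <- cfg$omega * state$v +
    cfg$c1 * rand1 * (state$pbest - state$x) +
    cfg$c2 * rand2 * (sweep(-state$x, 2, state$gbest, "+"))
  vmax <- hi - lo
  v <- pmin(pmax(v, matrix(-vmax, np, d, byrow = TRUE)),
            matrix(vmax, np, d, byrow = TRUE))
  x <- state$x + v
  x <- pmin(pmax(x, matrix(lo, np, d, byrow = TRUE)),
            matrix(hi, np, d, byrow = TRUE))
  state$x <- x; state$v <- v
  for (i in seq_len(np)) {
    f <- eval_fitness(fitness, x[i, ])
    if (f < state$pbest_fit[i]) {
      state$pbest_fit[i] <- f
      state$pbest[i, ] <- x[i, ]
      if (f < state$gbest_fit) {
        state$gbest_fit <- f
        state$gbest <- x[i, ]
      }
    }
  }
  state
}

#' Run a particle swarm optimization
#'
#' Minimizes `fitness` over the box in `cfg$bounds`: particles start at
#' uniform-random positions with zero velocities, then take `n_iters`
#' [pso_step()]s. The per-iteration `gbest` fitness trace (element 1 is the
#' initial swarm's best) is returned for convergence plots and is
#' non-increasing by construction.
#'
#' @param fitness Function position -> scalar (minimized).
#' @param cfg A [pso_config()].
#' @return List with `par` (best position), `value` (its fitness) and
#'   `trace` (numeric vector of length `n_iters + 1`).
#' @export
pso_optimize <- function(fitness, cfg) {
  stopifnot(inherits(cfg, "pso_config"))
  d <- nrow(cfg$bounds)
  with_seed(cfg$seed, {
    lo <- cfg$bounds[, 1]; hi <- cfg$bounds[, 2]
    x <- matrix(stats::runif(cfg$n_particles * d), cfg$n_particles, d)
    x <- sweep(sweep(x, 2, hi - lo, "*"), 2, lo, "+")
    pbest_fit <- apply(x, 1, function(p) eval_fitness(fitness, p))
    best <- which.min(pbest_fit)
    state <- list(x = x, v = matrix(0, cfg$n_particles, d), pbest = x,
                  pbest_fit = pbest_fit, gbest = x[best, ],
                  gbest_fit = pbest_fit[best])
    trace <- numeric(cfg$n_iters + 1L)
    trace[1L] <- state$gbest_fit
    for (it in seq_len(cfg$n_iters)) {
      state <- pso_step(state, cfg, fitness)
      trace[it + 1L] <- state$gbest_fit
    }
    list(par = state$gbest, value = state$gbest_fit, trace = trace)
  })
}
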