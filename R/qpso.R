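# Quantum-behaved particle swarm optimization (QPSO), bound-constrained,
# in its canonical mbest / attractor / logarithmic-jump formulation:
# each particle jumps to  p +/- beta * |mbest - x| * ln(1/u)  around the
# stochastic attractor p = phi*pbest + (1-phi)*gbest, with the
# contraction-expansion coefficient beta annealed over iterations.

#' QPSO configuration
#'
#' @param bounds Per-dimension box constraints: a d x 2 matrix (columns
#'   low, high) or a list of `(low, high)` pairs.
#' @param swarm_size Number of particles (>= 2); default 20.
#' @param max_iters Iteration budget; default 100.
#' @param beta_start,beta_end Contraction-expansion coefficient, annealed
#'   linearly from `beta_start` to `beta_end`; must satisfy
#'   `0 < beta_end <= beta_start <= 2`.  Defaults 1.0 and 0.5.
#' @param seed Optional integer seed; when set, [qpso_optimize()] is fully
#'   reproducible.
#' @param patience Early stop after this many iterations without a global
#'   best improvement exceeding 1e-6; default 20.
#' @param init_positions Optional matrix of starting positions (one row
#'   per particle) seeded into the swarm in place of uniform draws;
#'   fewer rows than `swarm_size` leaves the remaining particles uniform.
#'   Used to warm-start the search at known-reasonable solutions.
#' @return An object of class `qpso_config`.
#' @export
qpso_config <- function(bounds, swarm_size = 20, max_iters = 100,
                        beta_start = 1.0, beta_end = 0.5, seed = NULL,
                        patience = 20, init_positions = NULL) {
  if (is.list(bounds)) bounds <- do.call(rbind, lapply(bounds, as.numeric))
  bounds <- matrix(as.numeric(bounds), ncol = 2)
  if (any(!is.finite(bounds)) || any(bounds[, 1] >= bounds[, 2]))
    stop2("each bound pair must satisfy low < high")
  if (swarm_size < 2) stop2("`swarm_size` must be >= 2")
  if (!(beta_end > 0 && beta_end <= beta_start && beta_start <= 2))
    stop2("require 0 < beta_end <= beta_start <= 2")
  if (!is.null(init_positions)) {
    init_positions <- matrix(as.numeric(init_positions),
                             ncol = nrow(bounds))
    if (nrow(init_positions) > swarm_size)
      stop2("more `init_positions` rows than particles")
  }
  structure(list(bounds = bounds, swarm_size = as.integer(swarm_size),
                 max_iters = as.integer(max_iters),
                 beta_start = beta_start, beta_end = beta_end,
                 seed = seed, patience = as.integer(patience),
                 init_positions = init_positions),
            class = "qpso_config")
}

# Uniformly initialize the swarm inside the bounds; personal bests start
# at the initial positions (fitness filled in by the caller).
qpso_init <- function(config) {
  d <- nrow(config$bounds)
  S <- config$swarm_size
  pos <- matrix(stats::runif(S * d), S, d)
  pos <- sweep(pos, 2, config$bounds[, 2] - config$bounds[, 1], `*`)
  pos <- sweep(pos, 2, config$bounds[, 1], `+`)
  if (!is.null(config$init_positions)) {
    k <- nrow(config$init_positions)
    pos[seq_len(k), ] <- pmin(pmax(config$init_positions,
                                   rep(config$bounds[, 1], each = k)),
                              rep(config$bounds[, 2], each = k))
  }
  list(positions = pos,
       pbest_positions = pos,
       pbest_fitness = rep(Inf, S),
       gbest_position = pos[1, ],
       gbest_fitness = Inf,
       evaluations = 0L,
       nonfinite = 0L)
}

.qpso_eval <- function(state, objective, x) {
  v <- objective(x)
  state$evaluations <- state$evaluations + 1L
  if (!is.finite(v)) {
    state$nonfinite <- state$nonfinite + 1L
    v <- Inf
  }
  list(state = state, value = v)
}

# Score current positions and update personal / global bests.
.qpso_score <- function(state, objective) {
  for (i in seq_len(nrow(state$positions))) {
    ev <- .qpso_eval(state, objective, state$positions[i, ])
    state <- ev$state
    if (ev$value < state$pbest_fitness[i]) {
      state$pbest_fitness[i] <- ev$value
      state$pbest_positions[i, ] <- state$positions[i, ]
    }
    if (ev$value < state$gbest_fitness) {
      state$gbest_fitness <- ev$value
      state$gbest_position <- state$positions[i, ]
    }
  }
  state
}

#' One QPSO update step
#'
#' Moves every particle to \eqn{x' = p \pm \beta\,|m - x|\,\ln(1/u)} with
#' attractor \eqn{p = \phi\,\mathrm{pbest} + (1-\phi)\,\mathrm{gbest}}
#' (\eqn{\phi, u \sim U(0,1)} per dimension, sign chosen with probability
#' 1/2), where \eqn{m} is the mean of the personal-best positions.
#' Positions are clipped to the bounds and bests updated from the
#' objective.  With `beta = 0` every particle lands exactly on its
#' attractor.
#'
#' @param state Swarm state (internal structure from the optimizer).
#' @param objective Function mapping a position vector to a scalar to be
#'   minimized; non-finite values are treated as `+Inf`.
#' @param beta Contraction-expansion coefficient for this step.
#' @param bounds d x 2 bound matrix.
#' @return The updated swarm state.
#' @export
qpso_step <- function(state, objective, beta, bounds) {
  S <- nrow(state$positions)
  d <- ncol(state$positions)
  mbest <- colMeans(state$pbest_positions)
  for (i in seq_len(S)) {
    phi <- stats::runif(d)
    p <- phi * state$pbest_positions[i, ] + (1 - phi) * state$gbest_position
    u <- stats::runif(d)
    jump <- beta * abs(mbest - state$positions[i, ]) * log(1 / u)
    sgn <- ifelse(stats::runif(d) < 0.5, 1, -1)
    x <- p + sgn * jump
    state$positions[i, ] <- pmin(pmax(x, bounds[, 1]), bounds[, 2])
  }
  .qpso_score(state, objective)
}

#' Run the QPSO optimizer
#'
#' Minimizes `objective` over the configured box.  The
#' contraction-expansion coefficient is annealed linearly from
#' `beta_start` to `beta_end` across `max_iters` iterations; the search
#' stops early after `patience` iterations without improvement of the
#' global best beyond 1e-6.
#'
#' @param objective Function from a position vector (length =
#'   `nrow(bounds)`) to a scalar; minimized.
#' @param config A [qpso_config()].
#' @return Object of class `qpso_result` with `best_position`,
#'   `best_fitness`, the per-iteration `history` of the global best
#'   (non-increasing), `evaluations` and `iterations`.
#' @examples
#' cfg <- qpso_config(bounds = cbind(0, 10), swarm_size = 10,
#'                    max_iters = 50, seed = 1)
#' qpso_optimize(function(x) (x - 3)^2, cfg)$best_position
#' @export
qpso_optimize <- function(objective, config) {
  if (!inherits(config, "qpso_config")) stop2("`config` must be a qpso_config")
  with_seed(config$seed, {
    state <- qpso_init(config)
    state <- .qpso_score(state, objective)
    history <- state$gbest_fitness
    stall <- 0L
    iters_run <- 0L
    for (it in seq_len(config$max_iters)) {
      frac <- if (config$max_iters > 1) (it - 1) / (config$max_iters - 1) else 0
      beta <- config$beta_start + frac * (config$beta_end - config$beta_start)
      prev <- state$gbest_fitness
      state <- qpso_step(state, objective, beta, config$bounds)
      history <- c(history, state$gbest_fitness)
      iters_run <- it
      stall <- if (prev - state$gbest_fitness > 1e-6) 0L else stall + 1L
      if (stall >= config$patience) break
    }
    structure(list(best_position = state$gbest_position,
                   best_fitness = state$gbest_fitness,
                   history = history,
                   evaluations = state$evaluations,
                   iterations = iters_run,
                   nonfinite_evaluations = state$nonfinite),
              class = "qpso_result")
  })
}

#' @export
print.qpso_result <- function(x, ...) {
  cat(sprintf("<qpso_result: best fitness %.6g after %d evaluations (%d iterations)>\n",
              x$best_fitness, x$evaluations, x$iterations))
  invisible(x)
}
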