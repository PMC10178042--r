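#' Box-constrained search space
#'
#' @param lb,ub numeric vectors of lower/upper bounds (recycled scalars are
#'   expanded against `dim` when supplied).
#' @param dim optional dimensionality when `lb`/`ub` are scalars.
#' @return An object of class `search_space`.
#' @export
search_space <- function(lb, ub, dim = NULL) {
  if (!is.null(dim)) {
    lb <- rep_len(lb, dim)
    ub <- rep_len(ub, dim)
  }
  if (length(lb) != length(ub)) stop("lb and ub must have equal length")
  if (!all(lb < ub)) stop("lb must be strictly below ub element-wise")
  structure(list(lb = as.numeric(lb), ub = as.numeric(ub),
                 dim = length(lb)), class = "search_space")
}

#' Honey badger algorithm configuration
#'
#' @param pop_size population size `N` (default 50).
#' @param max_iter iteration budget `tmax` (default 300).
#' @param C density-factor constant, >= 1 (default 2).
#' @param beta_ability digging-strength ("ability to get food") constant
#'   (default 6).
#' @param seed optional integer seed.
#' @return An object of class `hba_config`.
#' @export
hba_config <- function(pop_size = 50, max_iter = 300, C = 2,
                       beta_ability = 6, seed = NULL) {
  if (pop_size < 2) stop("pop_size must be >= 2")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (C < 1) stop("C must be >= 1")
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 C = C, beta_ability = beta_ability, seed = seed),
            class = "hba_config")
}

#' Adaptive t-distribution HBA configuration
#'
#' Extends [hba_config()] with the mutation controls: each agent, in each
#' iteration, is perturbed with probability `mutation_prob` by a Student-t
#' multiplicative mutation whose degrees of freedom equal the iteration
#' number (Cauchy-like early, Gaussian-like late).
#'
#' @inheritParams hba_config
#' @param mutation_prob mutation probability `P` in `[0, 1]` (default 0.8).
#' @param mutation_accept `"greedy"` keeps a mutant only when it improves the
#'   agent's fitness; `"always"` keeps it unconditionally.
#' @param mutation_rdist the t-variate generator, a `function(n, df)`
#'   (default [stats::rt()]); injectable for testing.
#' @return An object of class `c("thba_config", "hba_config")`.
#' @export
thba_config <- function(pop_size = 50, max_iter = 300, C = 2,
                        beta_ability = 6, mutation_prob = 0.8,
                        mutation_accept = c("greedy", "always"),
                        mutation_rdist = stats::rt, seed = NULL) {
  cfg <- hba_config(pop_size, max_iter, C, beta_ability, seed)
  if (mutation_prob < 0 || mutation_prob > 1)
    stop("mutation_prob must lie in [0, 1]")
  cfg$mutation_prob <- mutation_prob
  cfg$mutation_accept <- match.arg(mutation_accept)
  cfg$mutation_rdist <- mutation_rdist
  class(cfg) <- c("thba_config", "hba_config")
  cfg
}

#' Initialise a population uniformly inside the search box
#'
#' Each coordinate is `lb + r1 * (ub - lb)` with `r1 ~ U(0, 1)`.
#'
#' @param space a [search_space()].
#' @param n population size.
#' @param r optional `n x dim` matrix of uniforms overriding the random draw
#'   (used for boundary tests).
#' @return Numeric matrix `n x dim` of positions, all within bounds.
#' @export
init_population <- function(space, n, r = NULL) {
  stopifnot(inherits(space, "search_space"))
  if (is.null(r)) r <- matrix(stats::runif(n * space$dim), n, space$dim)
  sweep(sweep(r, 2, space$ub - space$lb, "*"), 2, space$lb, "+")
}

#' Smell intensity of the prey
#'
#' Inverse-square attraction term: `I = r2 * S / (4 * pi * d^2)` per
#' dimension, with source strength `S = (x_i - x_next)^2` and distance
#' `d = prey - x_i`; `d^2` is epsilon-guarded against division by zero.
#'
#' @param position agent position `x_i`.
#' @param next_position neighbouring agent `x_{i+1}` (the last agent wraps to
#'   the first).
#' @param prey current best position.
#' @param r2 scalar uniform in `[0, 1]`; drawn internally when `NULL`.
#' @param eps guard added to `d^2` (default 1e-12).
#' @return Numeric vector of per-dimension intensities.
#' @export
smell_intensity <- function(position, next_position, prey, r2 = NULL,
                            eps = 1e-12) {
  if (length(position) != length(next_position) ||
      length(position) != length(prey))
    stop("position, next_position and prey must have equal length")
  if (is.null(r2)) r2 <- stats::runif(1)
  s <- (position - next_position)^2
  d <- prey - position
  r2 * s / (4 * pi * (d^2 + eps))
}

#' Density factor schedule
#'
#' Exponentially decaying exploration-to-exploitation schedule
#' `alpha = C * exp(-t / tmax)`.
#'
#' @param t current iteration, `1 <= t <= tmax`.
#' @param tmax iteration budget.
#' @param C constant >= 1 (default 2).
#' @return Scalar `alpha`.
#' @export
density_factor <- function(t, tmax, C = 2) {
  if (t < 1 || t > tmax) stop("t must satisfy 1 <= t <= tmax")
  C * exp(-t / tmax)
}

clamp <- function(x, space) pmin(pmax(x, space$lb), space$ub)

# evaluate one position, with context in the error message
eval_fitness <- function(fitness_fn, x, agent, iter) {
  f <- fitness_fn(x)
  if (!is.finite(f))
    stop(sprintf("non-finite fitness for agent %d at iteration %d", agent, iter))
  f
}

#' One population sweep of the honey badger algorithm
#'
#' For each agent a new position is proposed in either "digging" mode
#' (smell-intensity-guided, probability 1/2) or "honey" mode (move along the
#' prey direction), with the direction flag `F` equal to +1 or -1 with equal
#' probability. Proposals are clamped to the box and accepted greedily (only
#' when they improve the agent's fitness); the prey is updated whenever a
#' proposal beats it.
#'
#' @param positions `N x dim` matrix of agent positions.
#' @param fitnesses numeric vector of their fitness values.
#' @param fitness_fn the objective (minimised).
#' @param prey current best position.
#' @param prey_fitness its fitness.
#' @param alpha density factor for this iteration.
#' @param space the [search_space()].
#' @param config an [hba_config()].
#' @param iter iteration number (for error context).
#' @return List with updated `positions`, `fitnesses`, `prey`, `prey_fitness`
#'   and the number of fitness evaluations performed (`n_evals = N`).
#' @export
hba_step <- function(positions, fitnesses, fitness_fn, prey, prey_fitness,
                     alpha, space, config, iter = 1L) {
  n <- nrow(positions)
  for (i in seq_len(n)) {
    xi <- positions[i, ]
    xnext <- positions[if (i == n) 1L else i + 1L, ]
    intensity <- smell_intensity(xi, xnext, prey, r2 = stats::runif(1))
    f_sign <- if (stats::runif(1) < 0.5) 1 else -1
    d <- prey - xi
    if (stats::runif(1) < 0.5) {
      r3 <- stats::runif(1); r4 <- stats::runif(1); r5 <- stats::runif(1)
      x_new <- prey + f_sign * config$beta_ability * intensity * prey +
        f_sign * r3 * alpha * d * abs(cos(2 * pi * r4) * (1 - cos(2 * pi * r5)))
    } else {
      r7 <- stats::runif(1)
      x_new <- prey + f_sign * r7 * alpha * d
    }
    x_new <- clamp(x_new, space)
    f_new <- eval_fitness(fitness_fn, x_new, i, iter)
    if (f_new < fitnesses[i]) {
      positions[i, ] <- x_new
      fitnesses[i] <- f_new
    }
    if (f_new < prey_fitness) {
      prey <- x_new
      prey_fitness <- f_new
    }
  }
  list(positions = positions, fitnesses = fitnesses,
       prey = prey, prey_fitness = prey_fitness, n_evals = n)
}

#' Adaptive t-distribution mutation
#'
#' Multiplicative Student-t perturbation `x' = x + x * t_df`, one independent
#' t-variate per dimension, with degrees of freedom equal to the (1-based)
#' iteration number: heavy-tailed Cauchy-like jumps early in the run,
#' near-Gaussian refinement late.
#'
#' @param position numeric vector to perturb.
#' @param iter iteration number, >= 1 (the t-distribution df).
#' @param rdist t-variate generator `function(n, df)` (default [stats::rt()]).
#' @return Mutated position vector.
#' @export
t_mutation <- function(position, iter, rdist = stats::rt) {
  if (iter < 1) stop("iter must be >= 1 (it is the t-distribution df)")
  position + position * rdist(length(position), iter)
}

optimizer_run <- function(best_position, best_fitness, history, evals_history,
                          n_evaluations, n_mutation_evals = 0L) {
  structure(list(best_position = best_position, best_fitness = best_fitness,
                 history = history, evals_history = evals_history,
                 n_evaluations = n_evaluations,
                 n_mutation_evals = n_mutation_evals),
            class = "optimizer_run")
}

#' @export
print.optimizer_run <- function(x, ...) {
  cat(sprintf("optimizer_run: %d iterations, %d evaluations, best fitness %.6g\n",
              length(x$history), x$n_evaluations, x$best_fitness))
  invisible(x)
}

# shared HBA/tHBA driver; P = 0 takes exactly the HBA random path
badger_loop <- function(fitness_fn, space, config, mutation_prob = 0,
                        mutation_accept = "greedy", rdist = stats::rt) {
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$pop_size
  tmax <- config$max_iter
  positions <- init_population(space, n)
  fitnesses <- vapply(seq_len(n), function(i)
    eval_fitness(fitness_fn, positions[i, ], i, 0L), numeric(1))
  n_evals <- n
  n_mut <- 0L
  best <- which.min(fitnesses)
  prey <- positions[best, ]
  prey_fitness <- fitnesses[best]
  history <- numeric(tmax)
  evals_history <- integer(tmax)
  for (t in seq_len(tmax)) {
    alpha <- density_factor(t, tmax, config$C)
    st <- hba_step(positions, fitnesses, fitness_fn, prey, prey_fitness,
                   alpha, space, config, iter = t)
    positions <- st$positions; fitnesses <- st$fitnesses
    prey <- st$prey; prey_fitness <- st$prey_fitness
    n_evals <- n_evals + st$n_evals
    if (mutation_prob > 0) {
      for (i in seq_len(n)) {
        if (stats::runif(1) < mutation_prob) {
          x_mut <- clamp(t_mutation(positions[i, ], t, rdist), space)
          f_mut <- eval_fitness(fitness_fn, x_mut, i, t)
          n_evals <- n_evals + 1L
          n_mut <- n_mut + 1L
          if (mutation_accept == "always" || f_mut < fitnesses[i]) {
            positions[i, ] <- x_mut
            fitnesses[i] <- f_mut
          }
          if (f_mut < prey_fitness) {
            prey <- x_mut
            prey_fitness <- f_mut
          }
        }
      }
    }
    history[t] <- prey_fitness
    evals_history[t] <- n_evals
  }
  optimizer_run(prey, prey_fitness, history, evals_history, n_evals, n_mut)
}

#' Minimise a fitness function with the honey badger algorithm
#'
#' Runs the digging/honey population search for `max_iter` iterations and
#' tracks the best-so-far fitness per iteration.
#'
#' @param fitness_fn objective function of a position vector, minimised; must
#'   return a finite scalar everywhere in the box.
#' @param space a [search_space()].
#' @param config an [hba_config()] (or [thba_config()] for
#'   [thba_optimize()]).
#' @return An `optimizer_run` with `best_position`, `best_fitness`,
#'   `history` (best-so-far per iteration, non-increasing), `evals_history`
#'   (cumulative evaluations), `n_evaluations` and `n_mutation_evals`.
#' @export
hba_optimize <- function(fitness_fn, space, config = hba_config()) {
  stopifnot(inherits(space, "search_space"), inherits(config, "hba_config"))
  badger_loop(fitness_fn, space, config, mutation_prob = 0)
}

#' @rdname hba_optimize
#' @export
thba_optimize <- function(fitness_fn, space, config = thba_config()) {
  stopifnot(inherits(space, "search_space"), inherits(config, "thba_config"))
  badger_loop(fitness_fn, space, config,
              mutation_prob = config$mutation_prob,
              mutation_accept = config$mutation_accept,
              rdist = config$mutation_rdist)
}

#' Genetic algorithm configuration
#'
#' Real-coded GA baseline: tournament selection (size 3), arithmetic
#' crossover, per-gene Gaussian mutation, elitism of one.
#'
#' @param pop_size population size (default 50).
#' @param max_iter number of generations (default 300).
#' @param crossover_rate arithmetic-crossover probability (default 0.8).
#' @param mutation_rate per-gene mutation probability (default 0.05).
#' @param mutation_sd_frac mutation sigma as a fraction of the box width
#'   (default 0.1).
#' @param tournament_size selection tournament size (default 3).
#' @param seed optional integer seed.
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(pop_size = 50, max_iter = 300, crossover_rate = 0.8,
                      mutation_rate = 0.05, mutation_sd_frac = 0.1,
                      tournament_size = 3, seed = NULL) {
  if (pop_size < 2) stop("pop_size must be >= 2")
  if (max_iter < 1) stop("max_iter must be >= 1")
  structure(list(pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 mutation_sd_frac = mutation_sd_frac,
                 tournament_size = as.integer(tournament_size),
                 seed = seed),
            class = "ga_config")
}

#' @rdname hba_optimize
#' @param ga_cfg a [ga_config()] for the GA baseline.
#' @export
ga_optimize <- function(fitness_fn, space, ga_cfg = ga_config()) {
  stopifnot(inherits(space, "search_space"), inherits(ga_cfg, "ga_config"))
  if (!is.null(ga_cfg$seed)) set.seed(ga_cfg$seed)
  n <- ga_cfg$pop_size
  positions <- init_population(space, n)
  fitnesses <- vapply(seq_len(n), function(i)
    eval_fitness(fitness_fn, positions[i, ], i, 0L), numeric(1))
  n_evals <- n
  history <- numeric(ga_cfg$max_iter)
  evals_history <- integer(ga_cfg$max_iter)
  width <- space$ub - space$lb
  tournament <- function() {
    cand <- sample.int(n, ga_cfg$tournament_size, replace = TRUE)
    cand[which.min(fitnesses[cand])]
  }
  for (t in seq_len(ga_cfg$max_iter)) {
    elite <- which.min(fitnesses)
    new_pos <- matrix(0, n, space$dim)
    new_fit <- numeric(n)
    new_pos[1, ] <- positions[elite, ]
    new_fit[1] <- fitnesses[elite]
    for (i in 2:n) {
      p1 <- positions[tournament(), ]
      child <- if (stats::runif(1) < ga_cfg$crossover_rate) {
        p2 <- positions[tournament(), ]
        u <- stats::runif(1)
        u * p1 + (1 - u) * p2
      } else p1
      mut <- stats::runif(space$dim) < ga_cfg$mutation_rate
      if (any(mut))
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, ga_cfg$mutation_sd_frac * width[mut])
      child <- clamp(child, space)
      new_pos[i, ] <- child
      new_fit[i] <- eval_fitness(fitness_fn, child, i, t)
      n_evals <- n_evals + 1L
    }
    positions <- new_pos
    fitnesses <- new_fit
    history[t] <- min(fitnesses)
    evals_history[t] <- n_evals
  }
  best <- which.min(fitnesses)
  optimizer_run(positions[best, ], fitnesses[best], history, evals_history,
                n_evals)
}

#' Write an optimiser convergence trace as CSV
#'
#' Columns `iteration,best_fitness,n_evals` -- the per-iteration best-so-far
#' fitness and cumulative evaluation count, for convergence plots.
#'
#' @param run an `optimizer_run`.
#' @param path output CSV path.
#' @export
write_trace <- function(run, path) {
  stopifnot(inherits(run, "optimizer_run"))
  utils::write.csv(data.frame(iteration = seq_along(run$history),
                              best_fitness = run$history,
                              n_evals = run$evals_history),
                   path, row.names = FALSE)
  invisible(path)
}
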