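#' Configuration for the DEPS hybrid global optimizer
#'
#' DEPS mixes differential evolution (DE) and particle swarm optimization
#' (PSO): each generation every agent takes, with probability
#' `de_probability`, a DE/rand/1/bin step (greedy selection) and otherwise a
#' PSO velocity step (non-greedy move; personal and global bests keep the
#' record). Box bounds are enforced by clamping. Runs are fully
#' deterministic for a fixed seed.
#'
#' @param bounds two-column matrix (or 2-row rbind) of per-parameter
#'   `(lower, upper)` box bounds, one row per parameter.
#' @param population_size number of agents (>= 8, default 40).
#' @param max_generations generation budget (default 2000).
#' @param de_weight DE differential weight F in (0, 2) (default 0.8).
#' @param crossover_rate DE binomial crossover rate CR in (0, 1) (default 0.9).
#' @param inertia PSO inertia weight w (default 0.72).
#' @param cognitive,social PSO acceleration coefficients c1, c2 (default 1.49).
#' @param de_probability chance an agent takes a DE step rather than a PSO
#'   step each generation (default 0.5).
#' @param seed RNG seed (mandatory for reproducible fits).
#' @param tolerance objective stagnation tolerance (default 1e-10).
#' @param stagnation_window generations without improvement beyond
#'   `tolerance` that trigger convergence (default 100; wide enough
#'   that narrow curved valleys are not declared converged prematurely).
#' @return An object of class `deps_config`.
#' @export
deps_config <- function(bounds, population_size = 40L, max_generations = 2000L,
                        de_weight = 0.8, crossover_rate = 0.9, inertia = 0.72,
                        cognitive = 1.49, social = 1.49, de_probability = 0.5,
                        seed = 1L, tolerance = 1e-10, stagnation_window = 100L) {
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2) stop("bounds must have two columns (lower, upper)", call. = FALSE)
  if (any(!is.finite(bounds))) stop("bounds must be finite", call. = FALSE)
  if (any(bounds[, 1] >= bounds[, 2]))
    stop("each lower bound must be strictly below its upper bound", call. = FALSE)
  if (population_size < 8) stop("population_size must be at least 8", call. = FALSE)
  stopifnot(de_weight > 0, de_weight < 2, crossover_rate > 0, crossover_rate < 1,
            de_probability >= 0, de_probability <= 1, max_generations >= 1)
  structure(list(bounds = bounds, population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 de_weight = de_weight, crossover_rate = crossover_rate,
                 inertia = inertia, cognitive = cognitive, social = social,
                 de_probability = de_probability, seed = as.integer(seed),
                 tolerance = tolerance,
                 stagnation_window = as.integer(stagnation_window)),
            class = "deps_config")
}

#' Minimize an objective with the DEPS hybrid optimizer
#'
#' @param objective function of a parameter vector returning a scalar;
#'   non-finite values are treated as +Inf penalties.
#' @param config a [deps_config()].
#' @return A list of class `deps_result`: `best_params`, `best_objective`,
#'   `generations_used`, `converged`, and `trace` (nonincreasing
#'   per-generation best objective).
#' @export
deps_minimize <- function(objective, config) {
  stopifnot(inherits(config, "deps_config"))
  lo <- config$bounds[, 1]; hi <- config$bounds[, 2]
  d <- length(lo); np <- config$population_size

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(config$seed)

  eval_fn <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) Inf else v
  }
  clamp <- function(x) pmin(pmax(x, lo), hi)

  X <- matrix(stats::runif(np * d, rep(lo, each = np), rep(hi, each = np)),
              nrow = np, ncol = d)
  Vel <- matrix(0, np, d)
  fit <- apply(X, 1, eval_fn)
  pbest <- X; pbest_f <- fit
  g <- which.min(fit)
  gbest <- X[g, ]; gbest_f <- fit[g]

  trace <- numeric(config$max_generations)
  stagnant <- 0L; gen <- 0L; converged <- FALSE

  for (gen in seq_len(config$max_generations)) {
    prev_best <- gbest_f
    for (i in seq_len(np)) {
      if (stats::runif(1) < config$de_probability) {
        # DE/rand/1/bin with greedy selection
        r <- sample(setdiff(seq_len(np), i), 3)
        mutant <- X[r[1], ] + config$de_weight * (X[r[2], ] - X[r[3], ])
        jrand <- sample.int(d, 1)
        cross <- stats::runif(d) < config$crossover_rate
        cross[jrand] <- TRUE
        trial <- clamp(ifelse(cross, mutant, X[i, ]))
        f_trial <- eval_fn(trial)
        if (f_trial <= fit[i]) {
          X[i, ] <- trial; fit[i] <- f_trial
        }
      } else {
        # PSO velocity step (non-greedy position update)
        Vel[i, ] <- config$inertia * Vel[i, ] +
          config$cognitive * stats::runif(d) * (pbest[i, ] - X[i, ]) +
          config$social * stats::runif(d) * (gbest - X[i, ])
        X[i, ] <- clamp(X[i, ] + Vel[i, ])
        fit[i] <- eval_fn(X[i, ])
      }
      if (fit[i] < pbest_f[i]) { pbest[i, ] <- X[i, ]; pbest_f[i] <- fit[i] }
      if (fit[i] < gbest_f) { gbest <- X[i, ]; gbest_f <- fit[i] }
    }
    trace[gen] <- gbest_f
    if (prev_best - gbest_f < config$tolerance) stagnant <- stagnant + 1L else stagnant <- 0L
    if (stagnant >= config$stagnation_window) { converged <- TRUE; break }
  }

  structure(list(best_params = gbest, best_objective = gbest_f,
                 generations_used = gen, converged = converged,
                 trace = trace[seq_len(gen)]),
            class = "deps_result")
}

#' @export
print.deps_result <- function(x, ...) {
  cat(sprintf("<deps_result> objective %.6g after %d generations (%s)\n",
              x$best_objective, x$generations_used,
              if (x$converged) "converged" else "budget exhausted"))
  invisible(x)
}
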