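#' Particle swarm optimizer configuration
#'
#' Defaults mirror the classic bound-constrained global-best PSO with
#' adaptive inertia: acceleration coefficients 1.49 (self and social),
#' inertia adapted within `[0.1, 1.1]`, velocities clamped to the box
#' width, reflective handling at the bounds, and termination when the
#' relative improvement of the best objective over `stall_iterations`
#' consecutive iterations falls below `function_tolerance`.  Swarm size
#' defaults to 10 particles per dimension.
#'
#' @param lower,upper Finite bound vectors (equal length = dimension).
#' @param swarm_size Number of particles (>= 2).
#' @param inertia_range Adaptive inertia range `(min, max)`.
#' @param self_weight,social_weight Acceleration coefficients.
#' @param max_iterations Hard iteration cap (default 200 per dimension).
#' @param stall_iterations Window for the stall-based stopping rule.
#' @param function_tolerance Relative-improvement threshold.
#' @param seed Optional integer seed; if given, [pso_minimize()] seeds the
#'   RNG so runs are reproducible bit-for-bit.
#' @param max_nonfinite_frac Abort if more than this fraction of objective
#'   evaluations is non-finite.
#' @return List of class `pso_config`.
#' @export
pso_config <- function(lower, upper,
                       swarm_size = 10L * length(lower),
                       inertia_range = c(0.1, 1.1),
                       self_weight = 1.49, social_weight = 1.49,
                       max_iterations = 200L * length(lower),
                       stall_iterations = 20L,
                       function_tolerance = 1e-6, seed = NULL,
                       max_nonfinite_frac = 0.5) {
  check_finite(lower, "lower"); check_finite(upper, "upper")
  if (length(lower) != length(upper) || any(lower >= upper)) {
    abort_invalid("bounds must be finite with lower < upper componentwise")
  }
  if (swarm_size < 2L) abort_invalid("swarm_size must be >= 2")
  if (function_tolerance <= 0) abort_invalid("function_tolerance must be > 0")
  if (stall_iterations < 1L || max_iterations < 1L) {
    abort_invalid("iteration counts must be >= 1")
  }
  structure(list(lower = as.numeric(lower), upper = as.numeric(upper),
                 swarm_size = as.integer(swarm_size),
                 inertia_range = inertia_range,
                 self_weight = self_weight, social_weight = social_weight,
                 max_iterations = as.integer(max_iterations),
                 stall_iterations = as.integer(stall_iterations),
                 function_tolerance = function_tolerance,
                 seed = seed, max_nonfinite_frac = max_nonfinite_frac),
            class = "pso_config")
}

#' Global-best particle swarm minimization
#'
#' Minimizes `objective` over the box given in `config`.  Each iteration
#' updates particle velocities toward the personal and global best
#' positions, clamps velocities to the box width, reflects positions at
#' the bounds, and adapts the inertia weight (doubled while the swarm
#' improves, halved after repeated stalls).  Non-finite objective values
#' are treated as `+Inf`; if their fraction exceeds
#' `config$max_nonfinite_frac` an optimization error is raised.
#'
#' @param objective Function of a numeric parameter vector, returning a
#'   scalar to minimize.
#' @param config A [pso_config()].
#' @return List of class `pso_result` with elements `par` (best point),
#'   `value` (best objective), `history` (best objective per iteration,
#'   nonincreasing), `iterations`, `evaluations` and `seed`.
#' @export
#' @examples
#' res <- pso_minimize(function(x) sum(x^2),
#'                     pso_config(c(-10, -10), c(10, 10), seed = 1))
#' res$value
pso_minimize <- function(objective, config) {
  if (!inherits(config, "pso_config")) abort_invalid("config must be a pso_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  lo <- config$lower; up <- config$upper
  d <- length(lo); n <- config$swarm_size
  width <- up - lo

  n_eval <- 0L; n_bad <- 0L
  evalf <- function(x) {
    v <- objective(x)
    n_eval <<- n_eval + 1L
    if (!is.finite(v)) { n_bad <<- n_bad + 1L; v <- Inf }
    if (n_bad / n_eval > config$max_nonfinite_frac && n_eval >= 2L * n) {
      abort_optim(sprintf(
        "objective non-finite at %d of %d evaluations", n_bad, n_eval))
    }
    v
  }

  X <- matrix(runif(n * d, rep(lo, each = n), rep(up, each = n)), n, d)
  V <- matrix(runif(n * d, rep(-width, each = n), rep(width, each = n)), n, d)
  f <- apply(X, 1L, evalf)
  pbest_x <- X; pbest_f <- f
  g <- which.min(pbest_f)
  gbest_x <- pbest_x[g, ]; gbest_f <- pbest_f[g]
  f_init <- gbest_f

  W <- config$inertia_range[2]
  stall_counter <- 0L
  history <- numeric(0)
  iterations <- config$max_iterations

  min_neigh <- max(2L, floor(n * 0.25))
  neigh <- min_neigh

  for (it in seq_len(config$max_iterations)) {
    # adaptive-neighborhood social attractor: each particle is pulled
    # toward the best personal best within a random subset of the swarm;
    # the subset grows while the swarm stalls and shrinks on improvement
    local_best <- matrix(unlist(lapply(seq_len(n), function(i) {
      nb <- c(i, sample.int(n, neigh))
      pbest_x[nb[which.min(pbest_f[nb])], ]
    })), n, d, byrow = TRUE)
    r1 <- matrix(runif(n * d), n, d)
    r2 <- matrix(runif(n * d), n, d)
    V <- W * V +
      config$self_weight   * r1 * (pbest_x - X) +
      config$social_weight * r2 * (local_best - X)
    V <- pmin(pmax(V, matrix(-width, n, d, byrow = TRUE)),
              matrix(width, n, d, byrow = TRUE))
    X <- X + V
    # reflective bounds: fold back into the box, reverse that velocity
    for (j in seq_len(d)) {
      bad_lo <- X[, j] < lo[j]
      bad_up <- X[, j] > up[j]
      if (any(bad_lo)) {
        X[bad_lo, j] <- pmin(2 * lo[j] - X[bad_lo, j], up[j])
        V[bad_lo, j] <- -V[bad_lo, j]
      }
      if (any(bad_up)) {
        X[bad_up, j] <- pmax(2 * up[j] - X[bad_up, j], lo[j])
        V[bad_up, j] <- -V[bad_up, j]
      }
    }
    f <- apply(X, 1L, evalf)
    improved_p <- f < pbest_f
    pbest_x[improved_p, ] <- X[improved_p, , drop = FALSE]
    pbest_f[improved_p] <- f[improved_p]
    g <- which.min(pbest_f)
    improved_g <- pbest_f[g] < gbest_f
    if (improved_g) { gbest_x <- pbest_x[g, ]; gbest_f <- pbest_f[g] }
    history[it] <- gbest_f

    # adaptive inertia: reward improvement with exploration, damp stalls
    if (improved_g) {
      stall_counter <- max(0L, stall_counter - 1L)
      neigh <- min_neigh
    } else {
      stall_counter <- stall_counter + 1L
      neigh <- min(neigh + min_neigh, n - 1L)
    }
    if (stall_counter < 2L) W <- 2 * W
    if (stall_counter > 5L) W <- W / 2
    W <- min(max(W, config$inertia_range[1]), config$inertia_range[2])

    if (it >= config$stall_iterations) {
      f_ref <- if (it == config$stall_iterations) f_init
               else history[it - config$stall_iterations]
      # scale-free stall criterion: improvement relative to the objective
      # itself, so behaviour does not depend on the concentration unit
      rel <- (f_ref - gbest_f) / max(abs(f_ref), .Machine$double.eps)
      if (rel < config$function_tolerance) { iterations <- it; break }
    }
  }

  structure(list(par = gbest_x, value = gbest_f, history = history,
                 iterations = iterations, evaluations = n_eval,
                 seed = config$seed),
            class = "pso_result")
}

#' @export
print.pso_result <- function(x, ...) {
  cat(sprintf("PSO result: best objective %.6g after %d iterations (%d evaluations)\n",
              x$value, x$iterations, x$evaluations))
  cat("best point:", format(x$par, digits = 6), "\n")
  invisible(x)
}
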