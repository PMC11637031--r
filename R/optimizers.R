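# Population metaheuristics over the unit hypercube: the sea-horse optimizer
# (SHO), the sine-cosine algorithm (SCA) position update, and three
# SHO/SCA hybrids (SHOSCA full / motor / breeding). All operators clip to
# [0, 1]; selection is elitist truncation, so convergence traces are
# non-increasing. Deterministic under set.seed(); the *_optimize() drivers
# take an explicit `seed`.
#
# Low-level kernels (spiral_step, brownian_step, predation_kernel,
# sca_kernel, breed_pair) are pure functions of their random draws so the
# algebra is unit-testable; the *_update() wrappers supply the draws.

clip01 <- function(x) pmin(pmax(x, 0), 1)

# ---- configurations ---------------------------------------------------------

#' Sea-horse optimizer configuration
#'
#' @param l Brownian drift coefficient (default 0.05).
#' @param u,v Logarithmic spiral constants (defaults 0.05).
#' @param s Levy step scale (default 0.01).
#' @param lambda Levy stability exponent (default 1.5).
#' @param lambda_random Draw `lambda` uniformly on (0, 2] at every step
#'   instead of using the fixed value (default FALSE).
#' @param predation_threshold Success threshold for the predation phase:
#'   `r2 > threshold` is a successful hunt (default 0.1, success rate 90%).
#' @param levy_literal Use the plain (un-exponentiated) sigma and uniform
#'   `[0,1]` draws for `w`, `K` in the Levy step instead of the Mantegna
#'   normal-draw recipe (default FALSE).
#' @param theta_per_coord Draw the spiral angle per coordinate rather than
#'   once per agent (default FALSE).
#' @return An `sho_config` list.
#' @export
sho_config <- function(l = 0.05, u = 0.05, v = 0.05, s = 0.01, lambda = 1.5,
                       lambda_random = FALSE, predation_threshold = 0.1,
                       levy_literal = FALSE, theta_per_coord = FALSE) {
  stopifnot(l > 0, u > 0, v > 0, s > 0, lambda > 0, lambda <= 2)
  structure(list(l = l, u = u, v = v, s = s, lambda = lambda,
                 lambda_random = lambda_random,
                 predation_threshold = predation_threshold,
                 levy_literal = levy_literal,
                 theta_per_coord = theta_per_coord),
            class = "sho_config")
}

#' Sine-cosine algorithm configuration
#'
#' @param a Amplitude constant controlling the linearly decaying `b1 = a -
#'   t*a/T` (default 2).
#' @param literal_ranges Draw `b2`, `b3` on `[0, 1]` instead of the canonical
#'   `[0, 2*pi]` and `[0, 2]` (default FALSE).
#' @return An `sca_config` list.
#' @export
sca_config <- function(a = 2, literal_ranges = FALSE) {
  stopifnot(a > 0)
  structure(list(a = a, literal_ranges = literal_ranges), class = "sca_config")
}

# ---- Levy flight ------------------------------------------------------------

#' Mantegna sigma for a Levy flight of exponent lambda
#'
#' `sigma = (Gamma(1+lambda) sin(pi lambda/2) / (Gamma((1+lambda)/2) lambda
#' 2^((lambda-1)/2)))^(1/lambda)`; with `literal = TRUE` the outer `1/lambda`
#' exponent is omitted.
#'
#' @param lambda Stability exponent in (0, 2].
#' @param literal Omit the outer exponent (default FALSE).
#' @return Positive scalar.
#' @export
levy_sigma <- function(lambda, literal = FALSE) {
  base <- gamma(1 + lambda) * sin(pi * lambda / 2) /
    (gamma((1 + lambda) / 2) * lambda * 2^((lambda - 1) / 2))
  if (literal) base else base^(1 / lambda)
}

#' One Levy-flight step length
#'
#' `step = s * w * sigma / |K|^(1/lambda)`. Under the default Mantegna
#' recipe `w` and `K` are standard normal; under `levy_literal` they are
#' uniform on `[0, 1]` and sigma is the un-exponentiated form. `|K|` is
#' floored at 1e-12 to guard against underflow.
#'
#' @param cfg An [sho_config()].
#' @return Scalar step.
#' @export
levy_step <- function(cfg = sho_config()) {
  lambda <- if (isTRUE(cfg$lambda_random)) stats::runif(1, 0, 2) else cfg$lambda
  sig <- levy_sigma(lambda, literal = cfg$levy_literal)
  if (cfg$levy_literal) {
    w <- stats::runif(1); K <- stats::runif(1)
  } else {
    w <- stats::rnorm(1); K <- stats::rnorm(1)
  }
  cfg$s * w * sig / max(abs(K), 1e-12)^(1 / lambda)
}

# ---- movement (pure kernels + RNG wrappers) ---------------------------------

# Spiral drift toward the elite: X + Levy * ((elite - X) * x*y*z + elite),
# with x = rho cos(theta), y = rho sin(theta), z = rho theta,
# rho = u * exp(theta v).
spiral_step <- function(x, elite, lev, theta, u, v) {
  rho <- u * exp(theta * v)
  xs <- rho * cos(theta); ys <- rho * sin(theta); zs <- rho * theta
  x + lev * ((elite - x) * xs * ys * zs + elite)
}

# Brownian drift: X + rand * l * beta * (X - beta * elite), beta the standard
# normal density evaluated at the draw(s) in `bx`.
brownian_step <- function(x, elite, rand, bx, l) {
  beta <- exp(-bx^2 / 2) / sqrt(2 * pi)
  x + rand * l * beta * (x - beta * elite)
}

#' Sea-horse movement update (spiral or Brownian motion)
#'
#' Draws `r1 ~ N(0, 1)`; if `r1 > 0` the agent spirals around the elite with
#' a Levy-flight step (angle drawn once per agent unless
#' `theta_per_coord`), otherwise it drifts by Brownian motion with the
#' normal-density walk coefficient evaluated at a fresh standard-normal draw
#' per coordinate. The result is clipped to `[0, 1]`.
#'
#' @param x,elite Numeric position vectors of equal length.
#' @param cfg An [sho_config()].
#' @return Proposed position (same length, in `[0, 1]`).
#' @export
movement_update <- function(x, elite, cfg = sho_config()) {
  r1 <- stats::rnorm(1)
  if (r1 > 0) {
    theta <- if (isTRUE(cfg$theta_per_coord)) {
      stats::runif(length(x)) * 2 * pi
    } else stats::runif(1) * 2 * pi
    xn <- spiral_step(x, elite, levy_step(cfg), theta, cfg$u, cfg$v)
  } else {
    xn <- brownian_step(x, elite, stats::runif(1), stats::rnorm(length(x)), cfg$l)
  }
  clip01(xn)
}

# ---- predation --------------------------------------------------------------

# alpha * ((elite - rand * xn1) + (1 - alpha) * elite) on success,
# (1 - alpha) * ((xn1 - rand * elite) + alpha * xn1) on failure.
predation_kernel <- function(xn1, elite, alpha, success, rand) {
  if (success) {
    alpha * ((elite - rand * xn1) + (1 - alpha) * elite)
  } else {
    (1 - alpha) * ((xn1 - rand * elite) + alpha * xn1)
  }
}

#' Sea-horse predation update
#'
#' Computes the decaying step modifier `alpha = (1 - t/T)^(2t/T)` and draws
#' `r2 ~ U[0, 1]`; `r2 > predation_threshold` (default 0.1) is a successful
#' hunt pulling the agent onto the elite, otherwise the agent explores around
#' its own position. Clipped to `[0, 1]`.
#'
#' @param xn1 Position after the movement phase.
#' @param elite Elite position.
#' @param t,T Current iteration (0..T) and total iterations (T >= 1).
#' @param cfg An [sho_config()].
#' @return Proposed position in `[0, 1]`.
#' @export
predation_update <- function(xn1, elite, t, T, cfg = sho_config()) {
  if (T < 1) stop("predation_update: T must be >= 1", call. = FALSE)
  alpha <- (1 - t / T)^(2 * t / T)
  success <- stats::runif(1) > cfg$predation_threshold
  clip01(predation_kernel(xn1, elite, alpha, success, stats::runif(1)))
}

# ---- sine-cosine update -----------------------------------------------------

sca_kernel <- function(x, elite, b1, b2, b3, b4) {
  amp <- ifelse(b4 < 0.5, sin(b2), cos(b2))
  x + b1 * amp * abs(b3 * elite - x)
}

#' Sine-cosine position update
#'
#' `b1 = a - t*a/T` decays linearly; per coordinate, `b2`, `b3`, `b4` are
#' drawn (canonically on `[0, 2*pi]`, `[0, 2]`, `[0, 1]`) and the sine branch
#' is taken when `b4 < 0.5`, the cosine branch otherwise. Clipped to `[0, 1]`.
#'
#' @param x,elite Position vectors.
#' @param t,T Current and total iterations.
#' @param cfg An [sca_config()].
#' @return Proposed position in `[0, 1]`.
#' @export
sca_position_update <- function(x, elite, t, T, cfg = sca_config()) {
  b1 <- cfg$a - t * cfg$a / T
  n <- length(x)
  if (cfg$literal_ranges) {
    b2 <- stats::runif(n); b3 <- stats::runif(n)
  } else {
    b2 <- stats::runif(n, 0, 2 * pi); b3 <- stats::runif(n, 0, 2)
  }
  clip01(sca_kernel(x, elite, b1, b2, b3, stats::runif(n)))
}

# ---- breeding ---------------------------------------------------------------

breed_pair <- function(father, mother, r3) r3 * father + (1 - r3) * mother

#' Sea-horse breeding (convex recombination of sorted halves)
#'
#' Agents are sorted ascending by fitness; the best `ceiling(P/2)` act as
#' fathers, the remainder as mothers. Each mother is paired with a distinct
#' randomly chosen father and each pair produces one offspring
#' `r3 * father + (1 - r3) * mother` with a scalar `r3 ~ U[0, 1]` per pair.
#'
#' @param positions `P x Dim` matrix of agent positions.
#' @param fitness Numeric vector of length `P` (all finite).
#' @return `floor(P/2) x Dim` matrix of offspring.
#' @export
breeding_update <- function(positions, fitness) {
  P <- nrow(positions)
  if (anyNA(fitness) || any(!is.finite(fitness))) {
    stop("breeding_update: all agents must have evaluated finite fitness",
         call. = FALSE)
  }
  ord <- order(fitness)
  sorted <- positions[ord, , drop = FALSE]
  nf <- ceiling(P / 2)
  nm <- P - nf
  fathers <- sorted[seq_len(nf), , drop = FALSE]
  mothers <- sorted[nf + seq_len(nm), , drop = FALSE]
  pick <- sample.int(nf, nm)
  off <- matrix(0, nm, ncol(positions))
  for (i in seq_len(nm)) {
    off[i, ] <- breed_pair(fathers[pick[i], ], mothers[i, ], stats::runif(1))
  }
  off
}

# ---- population plumbing ----------------------------------------------------

#' Initialize a population on the unit hypercube
#'
#' @param P Population size (>= 4; breeding needs two parent groups).
#' @param Dim Dimension (>= 1).
#' @param lb,ub Bounds (defaults 0 and 1).
#' @return `P x Dim` matrix of uniform positions.
#' @export
initialize_population <- function(P, Dim, lb = 0, ub = 1) {
  if (P < 4) stop("initialize_population: P must be >= 4", call. = FALSE)
  if (Dim < 1) stop("initialize_population: Dim must be >= 1", call. = FALSE)
  matrix(lb + stats::runif(P * Dim) * (ub - lb), nrow = P, ncol = Dim)
}

evaluate_positions <- function(positions, objective) {
  vapply(seq_len(nrow(positions)), function(i) {
    f <- objective(positions[i, ])
    if (!is.finite(f)) {
      stop("objective returned a non-finite value at position [",
           paste(signif(positions[i, ], 4), collapse = ", "), "]",
           call. = FALSE)
    }
    f
  }, numeric(1))
}

optimizer_result <- function(best_position, best_fitness, trace, evaluations,
                             elapsed, seed, algorithm) {
  structure(list(best_position = best_position, best_fitness = best_fitness,
                 trace = trace, evaluations = evaluations, elapsed = elapsed,
                 seed = seed, algorithm = algorithm),
            class = "optimizer_result")
}

#' @export
print.optimizer_result <- function(x, ...) {
  cat(sprintf("<optimizer_result %s: best %.6g after %d evaluations, %.2fs>\n",
              x$algorithm, x$best_fitness, x$evaluations, x$elapsed))
  invisible(x)
}

# Shared driver: `step_fun(positions, fitness, elite_pos, t)` returns the
# candidate positions for iteration t; the selection pool is the current
# population plus candidates (plus breeding offspring when `breed`),
# truncated elitistically to P. `pool_current = FALSE` (plain SCA) replaces
# positions unconditionally, canonical-SCA style.
run_population_optimizer <- function(objective, P, Dim, T, seed, algorithm,
                                     step_fun, breed = TRUE,
                                     init_positions = NULL,
                                     pool_current = TRUE) {
  t0 <- proc.time()[["elapsed"]]
  if (!is.null(seed)) set.seed(seed)
  positions <- initialize_population(P, Dim)
  if (!is.null(init_positions)) {
    init_positions <- matrix(init_positions, ncol = Dim)
    k <- min(nrow(init_positions), P)
    positions[seq_len(k), ] <- init_positions[seq_len(k), , drop = FALSE]
  }
  fitness <- evaluate_positions(positions, objective)
  evals <- P
  best_i <- which.min(fitness)
  elite_pos <- positions[best_i, ]
  elite_fit <- fitness[best_i]
  trace <- numeric(T + 1)
  trace[1] <- elite_fit
  if (T > 0) {
    for (t in seq_len(T)) {
      newpos <- step_fun(positions, fitness, elite_pos, t)
      newfit <- evaluate_positions(newpos, objective)
      evals <- evals + nrow(newpos)
      if (pool_current) {
        pool <- rbind(positions, newpos); poolfit <- c(fitness, newfit)
      } else {
        pool <- newpos; poolfit <- newfit
      }
      if (breed && nrow(newpos) >= 4) {
        off <- clip01(breeding_update(newpos, newfit))
        offfit <- evaluate_positions(off, objective)
        evals <- evals + nrow(off)
        pool <- rbind(pool, off); poolfit <- c(poolfit, offfit)
      }
      bi <- which.min(poolfit)
      if (poolfit[bi] < elite_fit) {
        elite_fit <- poolfit[bi]
        elite_pos <- pool[bi, ]
      }
      keep <- order(poolfit)[seq_len(P)]
      positions <- pool[keep, , drop = FALSE]
      fitness <- poolfit[keep]
      trace[t + 1] <- elite_fit
    }
  }
  optimizer_result(elite_pos, elite_fit, trace, evals,
                   proc.time()[["elapsed"]] - t0, seed, algorithm)
}

# ---- drivers ----------------------------------------------------------------

#' Sea-horse optimizer
#'
#' Per iteration each agent moves (spiral/Brownian), then hunts (predation
#' toward the elite); the updated agents breed, and the next generation is
#' the elitist truncation of current agents, updated agents and offspring
#' back to `P`, so good positions survive a bad perturbation.
#'
#' @param objective Function mapping a position in `[0,1]^Dim` to a finite
#'   scalar (lower is better).
#' @param P Population size (default 10).
#' @param Dim Dimension.
#' @param T Iterations (default 50).
#' @param cfg An [sho_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param init_positions Optional matrix of positions injected over the first
#'   rows of the initial population.
#' @return An `optimizer_result`: `best_position`, `best_fitness`, `trace`
#'   (best-so-far per iteration, entry 1 = initial population), `evaluations`,
#'   `elapsed`, `seed`.
#' @export
sho_optimize <- function(objective, P = 10, Dim, T = 50, cfg = sho_config(),
                         seed = NULL, init_positions = NULL) {
  step_fun <- function(positions, fitness, elite_pos, t) {
    out <- positions
    for (i in seq_len(nrow(positions))) {
      xn1 <- movement_update(positions[i, ], elite_pos, cfg)
      out[i, ] <- predation_update(xn1, elite_pos, t, T, cfg)
    }
    out
  }
  run_population_optimizer(objective, P, Dim, T, seed, "sho", step_fun,
                           breed = TRUE, init_positions = init_positions)
}

#' Sine-cosine algorithm
#'
#' Plain SCA: every agent is updated by the sine/cosine rule around the
#' best-ever position, replacing its previous position; the best-ever agent
#' is tracked separately so the convergence trace stays non-increasing.
#'
#' @inheritParams sho_optimize
#' @param cfg An [sca_config()].
#' @return An `optimizer_result`.
#' @export
sca_optimize <- function(objective, P = 10, Dim, T = 50, cfg = sca_config(),
                         seed = NULL, init_positions = NULL) {
  step_fun <- function(positions, fitness, elite_pos, t) {
    out <- positions
    for (i in seq_len(nrow(positions))) {
      out[i, ] <- sca_position_update(positions[i, ], elite_pos, t, T, cfg)
    }
    out
  }
  run_population_optimizer(objective, P, Dim, T, seed, "sca", step_fun,
                           breed = FALSE, init_positions = init_positions,
                           pool_current = FALSE)
}

#' Hybrid sea-horse / sine-cosine optimizer (SHOSCA)
#'
#' Three hybridizations of the sea-horse optimizer with the sine-cosine
#' position update:
#' * `"full"` — movement, then the SCA update replaces predation, then
#'   breeding (the headline hybrid);
#' * `"motor"` — the SCA update replaces movement; predation and breeding
#'   are retained;
#' * `"breeding"` — movement and predation as in SHO, but the SCA update
#'   replaces mating: it is applied to every agent and the pool of
#'   pre- and post-SCA agents is truncated to `P` (no offspring).
#'
#' @inheritParams sho_optimize
#' @param sho_cfg An [sho_config()].
#' @param sca_cfg An [sca_config()].
#' @param variant `"full"`, `"motor"` or `"breeding"`.
#' @param worst_half_only In the `"breeding"` variant, apply the SCA update
#'   only to the worse half of the population (default FALSE).
#' @return An `optimizer_result`.
#' @export
shosca_optimize <- function(objective, P = 10, Dim, T = 50,
                            sho_cfg = sho_config(), sca_cfg = sca_config(),
                            variant = c("full", "motor", "breeding"),
                            seed = NULL, init_positions = NULL,
                            worst_half_only = FALSE) {
  variant <- match.arg(variant)
  if (variant == "full") {
    step_fun <- function(positions, fitness, elite_pos, t) {
      out <- positions
      for (i in seq_len(nrow(positions))) {
        xn1 <- movement_update(positions[i, ], elite_pos, sho_cfg)
        out[i, ] <- sca_position_update(xn1, elite_pos, t, T, sca_cfg)
      }
      out
    }
    return(run_population_optimizer(objective, P, Dim, T, seed, "shosca",
                                    step_fun, breed = TRUE,
                                    init_positions = init_positions))
  }
  if (variant == "motor") {
    step_fun <- function(positions, fitness, elite_pos, t) {
      out <- positions
      for (i in seq_len(nrow(positions))) {
        xn1 <- sca_position_update(positions[i, ], elite_pos, t, T, sca_cfg)
        out[i, ] <- predation_update(xn1, elite_pos, t, T, sho_cfg)
      }
      out
    }
    return(run_population_optimizer(objective, P, Dim, T, seed, "shosca-motor",
                                    step_fun, breed = TRUE,
                                    init_positions = init_positions))
  }
  # breeding variant: SHO movement + predation, then the SCA update applied
  # to the agents in place of mating; pool = pre-SCA union post-SCA.
  step_fun <- function(positions, fitness, elite_pos, t) {
    xn2 <- positions
    for (i in seq_len(nrow(positions))) {
      xn1 <- movement_update(positions[i, ], elite_pos, sho_cfg)
      xn2[i, ] <- predation_update(xn1, elite_pos, t, T, sho_cfg)
    }
    idx <- seq_len(nrow(xn2))
    if (worst_half_only) {
      # positions are entered sorted by fitness only at t = 1; use the
      # current fitness ordering to pick the worse half
      idx <- order(fitness, decreasing = TRUE)[seq_len(floor(nrow(xn2) / 2))]
    }
    z <- xn2
    for (i in idx) z[i, ] <- sca_position_update(xn2[i, ], elite_pos, t, T, sca_cfg)
    rbind(xn2, z[idx, , drop = FALSE])
  }
  run_population_optimizer(objective, P, Dim, T, seed, "shosca-breeding",
                           step_fun, breed = FALSE,
                           init_positions = init_positions)
}

#' Look up an optimizer driver by name
#'
#' Known names: `"sho"`, `"sca"`, `"shosca"` (full hybrid),
#' `"shosca-motor"`, `"shosca-breeding"`. Custom optimizers can be supplied
#' anywhere a name is accepted by passing a function with the same signature
#' `function(objective, P, Dim, T, seed, init_positions)`.
#'
#' @param name Optimizer name.
#' @param sho_cfg,sca_cfg Configurations forwarded to the drivers.
#' @return A driver `function(objective, P, Dim, T, seed, init_positions)`.
#' @export
get_optimizer <- function(name, sho_cfg = sho_config(), sca_cfg = sca_config()) {
  if (is.function(name)) return(name)
  known <- c("sho", "sca", "shosca", "shosca-motor", "shosca-breeding")
  if (!name %in% known) {
    stop("unknown optimizer '", name, "'; choices: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  switch(name,
    "sho" = function(objective, P, Dim, T, seed = NULL, init_positions = NULL)
      sho_optimize(objective, P, Dim, T, sho_cfg, seed, init_positions),
    "sca" = function(objective, P, Dim, T, seed = NULL, init_positions = NULL)
      sca_optimize(objective, P, Dim, T, sca_cfg, seed, init_positions),
    "shosca" = function(objective, P, Dim, T, seed = NULL, init_positions = NULL)
      shosca_optimize(objective, P, Dim, T, sho_cfg, sca_cfg, "full",
                      seed, init_positions),
    "shosca-motor" = function(objective, P, Dim, T, seed = NULL, init_positions = NULL)
      shosca_optimize(objective, P, Dim, T, sho_cfg, sca_cfg, "motor",
                      seed, init_positions),
    "shosca-breeding" = function(objective, P, Dim, T, seed = NULL, init_positions = NULL)
      shosca_optimize(objective, P, Dim, T, sho_cfg, sca_cfg, "breeding",
                      seed, init_positions)
  )
}
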