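## Sooty tern optimization (STOA) and its improved variant (ISTOA).
##
## STOA models migration (collision avoidance, convergence toward the best
## individual) and a spiral attack around the best. ISTOA adds three
## strategies: Bernoulli-chaotic population initialization, Cauchy mutation
## of the incumbent best (heavy-tailed escape jumps), and longitudinal-lateral
## (crisscross) crossover with greedy acceptance.

#' Optimizer control parameters
#'
#' @param population_size Number of candidates (>= 4; crossover pairs
#'   individuals).
#' @param max_iterations Iteration budget.
#' @param bernoulli_lambda Bernoulli chaotic-map parameter, strictly in (0,1);
#'   default 0.4.
#' @param cauchy_probability Per-iteration probability of applying the Cauchy
#'   perturbation to the incumbent best (ISTOA only).
#' @param crossover_horizontal_prob Per-pair probability of lateral
#'   (between-individual) crossover.
#' @param crossover_vertical_prob Per-individual probability of longitudinal
#'   (between-dimension) crossover.
#' @param seed Integer seed; one seeded stream drives the whole run.
#' @param control_factor_cf Migration control constant Cf; the collision
#'   avoidance weight decays linearly from Cf to 0 over the run.
#' @param spiral_u,spiral_v Spiral shape constants: the attack radius at
#'   spiral angle theta is `u * exp(-theta * v)` (a tightening spiral).
#' @return A list of class `stoa_control`.
#' @export
stoa_control <- function(population_size = 30L, max_iterations = 500L,
                         bernoulli_lambda = 0.4, cauchy_probability = 0.5,
                         crossover_horizontal_prob = 1.0,
                         crossover_vertical_prob = 0.6,
                         seed = 1L, control_factor_cf = 2,
                         spiral_u = 1, spiral_v = 1) {
  if (!is.numeric(bernoulli_lambda) || bernoulli_lambda <= 0 ||
      bernoulli_lambda >= 1)
    stop("'bernoulli_lambda' must lie strictly between 0 and 1")
  if (population_size < 4)
    stop("'population_size' must be at least 4 (crossover pairs individuals)")
  if (max_iterations < 1) stop("'max_iterations' must be positive")
  for (p in c(cauchy_probability, crossover_horizontal_prob,
              crossover_vertical_prob))
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  structure(list(population_size = as.integer(population_size),
                 max_iterations = as.integer(max_iterations),
                 bernoulli_lambda = bernoulli_lambda,
                 cauchy_probability = cauchy_probability,
                 crossover_horizontal_prob = crossover_horizontal_prob,
                 crossover_vertical_prob = crossover_vertical_prob,
                 seed = as.integer(seed),
                 control_factor_cf = control_factor_cf,
                 spiral_u = spiral_u, spiral_v = spiral_v),
            class = "stoa_control")
}

#' Bernoulli chaotic map sequence
#'
#' Iterates the piecewise-linear Bernoulli shift
#' x_{n+1} = x_n / (1 - lambda) on 0 < x_n < 1 - lambda, and
#' x_{n+1} = (x_n - (1 - lambda)) / lambda on 1 - lambda < x_n < 1.
#' The sequence is ergodic on (0, 1) and highly sensitive to the initial
#' value, which makes it a better spreader of small initial populations than
#' plain uniform draws.
#'
#' @param x0 Initial value in (0, 1), excluding the fixed/boundary points
#'   0, 1 - lambda and 1.
#' @param lambda Map parameter in (0, 1); default 0.4.
#' @param length Number of iterates to return.
#' @return Numeric vector of `length` values, all strictly inside (0, 1);
#'   the first element is the first iterate (x0 itself is not returned).
#' @examples
#' bernoulli_map(0.2, 0.4, 5)
#' @export
bernoulli_map <- function(x0, lambda = 0.4, length = 1L) {
  if (!is.numeric(lambda) || lambda <= 0 || lambda >= 1)
    stop("'lambda' must lie strictly between 0 and 1")
  if (!is.numeric(x0) || x0 <= 0 || x0 >= 1)
    stop("'x0' must lie strictly between 0 and 1")
  if (length < 1) stop("'length' must be at least 1")
  out <- numeric(length)
  x <- x0
  for (n in seq_len(length)) {
    x <- if (x < 1 - lambda) x / (1 - lambda) else (x - (1 - lambda)) / lambda
    ## finite-precision iterates can collide with a boundary; re-inject
    if (x <= 0 || x >= 1) x <- ((x + pi / 31) %% 1) + 1e-12
    out[n] <- x
  }
  out
}

#' Chaotic population initialization
#'
#' Fills a `population_size` x `dimension` position matrix from one
#' continuing Bernoulli-map stream (row by row), mapping each chaotic value
#' v into `lower + v * (upper - lower)`. The stream's starting point is drawn
#' from the current RNG state, so the whole run is reproducible from the
#' optimizer seed.
#'
#' @param control A [stoa_control()] object.
#' @param lower,upper Bounds, scalars or length-`dimension` vectors.
#' @param dimension Problem dimension.
#' @return A numeric matrix of in-bounds positions.
#' @export
chaotic_init <- function(control, lower, upper, dimension) {
  lower <- rep_len(lower, dimension); upper <- rep_len(upper, dimension)
  if (any(lower >= upper)) stop("invalid bounds: need lower < upper")
  n <- control$population_size
  lam <- control$bernoulli_lambda
  x0 <- stats::runif(1)
  while (x0 %in% c(0, 1 - lam, 1)) x0 <- stats::runif(1)
  v <- bernoulli_map(x0, lam, n * dimension)
  pos <- matrix(v, nrow = n, ncol = dimension, byrow = TRUE)
  sweep(sweep(pos, 2, upper - lower, `*`), 2, lower, `+`)
}

#' One migration-and-attack update of the sooty tern population
#'
#' Every candidate moves by the STOA rule: collision-avoided position
#' `C = Sa * P` with `Sa` decaying linearly from Cf to 0 over the run;
#' convergence toward the best `M = Cb * (best - P)` with `Cb = 0.5 * rand`;
#' `D = C + M`; then the spiral attack `P <- D * (x' + y' + z') * best`,
#' where `x' = r sin(theta)`, `y' = r cos(theta)`, `z' = r theta`, and
#' `r = u * exp(-theta * v)` — a tightening spiral whose radius decays over
#' the turn — at a spiral angle theta drawn uniformly in [0, 2*pi] per
#' candidate and dimension (as in the base algorithm's component-wise
#' formulation; a widening spiral makes the attack factor explode and the
#' search degenerate). Positions are clamped to bounds and re-evaluated; the
#' incumbent best is replaced only by an improvement.
#'
#' @param positions n x d matrix of candidate positions.
#' @param fitness Length-n vector of their objective values.
#' @param best_position,best_fitness Incumbent best.
#' @param iteration Current iteration (1-based).
#' @param control A [stoa_control()] object.
#' @param objective Vectorized objective: matrix of row-points -> vector.
#' @param lower,upper Bounds.
#' @return List with updated `positions`, `fitness`, `best_position`,
#'   `best_fitness`.
#' @export
stoa_step <- function(positions, fitness, best_position, best_fitness,
                      iteration, control, objective, lower, upper) {
  n <- nrow(positions); d <- ncol(positions)
  cf <- control$control_factor_cf
  sa <- cf - iteration * (cf / control$max_iterations)
  cb <- 0.5 * matrix(stats::runif(n * d), n, d)
  theta <- matrix(stats::runif(n * d, 0, 2 * pi), n, d)
  r <- control$spiral_u * exp(-theta * control$spiral_v)
  spiral <- r * sin(theta) + r * cos(theta) + r * theta
  bestm <- matrix(best_position, n, d, byrow = TRUE)
  D <- sa * positions + cb * (bestm - positions)
  newpos <- clamp(D * spiral * bestm, lower, upper)
  newfit <- objective(newpos)
  i <- which.min(newfit)
  if (newfit[i] < best_fitness) {
    best_fitness <- newfit[i]
    best_position <- newpos[i, ]
  }
  list(positions = newpos, fitness = newfit,
       best_position = best_position, best_fitness = best_fitness)
}

#' Cauchy mutation of the incumbent best
#'
#' Proposes `x_new = x_best + x_best * c`, each component of `c` an
#' independent standard-Cauchy draw (location 0, scale 1). The heavy tails
#' produce occasional large escape jumps out of local basins. The proposal is
#' clamped to bounds and accepted only if it improves the objective.
#'
#' @param best_position,best_fitness Incumbent best and its value.
#' @param objective Vectorized objective.
#' @param lower,upper Bounds.
#' @return List `(position, fitness, accepted)`.
#' @export
cauchy_perturb_best <- function(best_position, best_fitness, objective,
                                lower, upper) {
  d <- length(best_position)
  prop <- clamp(best_position + best_position * stats::rcauchy(d),
                rep_len(lower, d), rep_len(upper, d))
  f <- objective(matrix(prop, nrow = 1))
  if (f < best_fitness)
    list(position = prop, fitness = f, accepted = TRUE)
  else
    list(position = best_position, fitness = best_fitness, accepted = FALSE)
}

#' Longitudinal-lateral (crisscross) crossover with greedy acceptance
#'
#' Lateral (horizontal) crossover pairs shuffled individuals i, j and, per
#' dimension, proposes `r*x_i + (1-r)*x_j + c*(x_i - x_j)` with r ~ U(0,1),
#' c ~ U(-1,1) (and symmetrically for j). Longitudinal (vertical) crossover
#' mixes two distinct dimensions of one individual:
#' `r*x[d1] + (1-r)*x[d2]` written into d1. Every offspring replaces its
#' parent only if it improves the objective, preserving elitism.
#'
#' @param positions,fitness Current population.
#' @param control A [stoa_control()] object.
#' @param objective Vectorized objective.
#' @param lower,upper Bounds.
#' @return List with updated `positions` and `fitness`.
#' @export
crossover_mutate <- function(positions, fitness, control, objective,
                             lower, upper) {
  n <- nrow(positions); d <- ncol(positions)
  ## lateral: random pairing
  perm <- sample(n)
  npair <- n %/% 2
  if (npair >= 1) {
    off <- positions; touched <- logical(n)
    for (k in seq_len(npair)) {
      if (stats::runif(1) > control$crossover_horizontal_prob) next
      i <- perm[2 * k - 1]; j <- perm[2 * k]
      r1 <- stats::runif(d); r2 <- stats::runif(d)
      c1 <- stats::runif(d, -1, 1); c2 <- stats::runif(d, -1, 1)
      off[i, ] <- r1 * positions[i, ] + (1 - r1) * positions[j, ] +
        c1 * (positions[i, ] - positions[j, ])
      off[j, ] <- r2 * positions[j, ] + (1 - r2) * positions[i, ] +
        c2 * (positions[j, ] - positions[i, ])
      touched[c(i, j)] <- TRUE
    }
    if (any(touched)) {
      off <- clamp(off, lower, upper)
      newfit <- objective(off[touched, , drop = FALSE])
      idx <- which(touched)
      better <- newfit < fitness[idx]
      positions[idx[better], ] <- off[idx[better], , drop = FALSE]
      fitness[idx[better]] <- newfit[better]
    }
  }
  ## longitudinal: mix two dimensions within an individual
  if (d >= 2) {
    apply_v <- stats::runif(n) < control$crossover_vertical_prob
    if (any(apply_v)) {
      off <- positions[apply_v, , drop = FALSE]
      for (k in seq_len(nrow(off))) {
        dd <- sample.int(d, 2)
        r <- stats::runif(1)
        off[k, dd[1]] <- r * off[k, dd[1]] + (1 - r) * off[k, dd[2]]
      }
      off <- clamp(off, lower, upper)
      newfit <- objective(off)
      idx <- which(apply_v)
      better <- newfit < fitness[idx]
      positions[idx[better], ] <- off[better, , drop = FALSE]
      fitness[idx[better]] <- newfit[better]
    }
  }
  list(positions = positions, fitness = fitness)
}

#' Run the sooty tern optimizer (plain or improved variant)
#'
#' `variant = "STOA"` is the base algorithm: uniform random initialization
#' followed by the migration-and-attack update. `variant = "ISTOA"` adds
#' Bernoulli-chaotic initialization, Cauchy mutation of the incumbent best
#' (applied each iteration with probability `control$cauchy_probability`),
#' and crisscross crossover with greedy acceptance. Both variants are
#' elitist: the best-so-far trace is non-increasing. A single seeded stream
#' (from `control$seed`) drives every random draw, so identical
#' configurations reproduce bit-identical traces.
#'
#' @param objective Objective function to minimize. By default a function of
#'   one numeric vector; set `vectorized = TRUE` if it maps an n x d matrix
#'   of row-points to n values (much faster for cheap objectives).
#' @param lower,upper Bounds (scalars or length-`dimension` vectors).
#' @param dimension Problem dimension.
#' @param control A [stoa_control()] object.
#' @param variant `"ISTOA"` (default) or `"STOA"`.
#' @param vectorized Whether `objective` is matrix-vectorized.
#' @return An object of class `stoa_trace`: list with `best_position`,
#'   `best_fitness`, `trace` (best-so-far per iteration),
#'   `evaluations_used`, `variant`, `control`.
#' @examples
#' f <- get_benchmark("F1", dimension = 5)
#' fit <- stoa_optim(f$evaluate, f$lower, f$upper, 5,
#'                   stoa_control(max_iterations = 50, seed = 1),
#'                   vectorized = TRUE)
#' fit$best_fitness
#' @export
stoa_optim <- function(objective, lower, upper, dimension,
                       control = stoa_control(),
                       variant = c("ISTOA", "STOA"), vectorized = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(control, "stoa_control"))
  lower <- rep_len(lower, dimension); upper <- rep_len(upper, dimension)
  if (any(lower >= upper)) stop("invalid bounds: need lower < upper")

  n_eval <- 0L
  obj <- if (vectorized) {
    function(X) { n_eval <<- n_eval + nrow(X); objective(X) }
  } else {
    function(X) { n_eval <<- n_eval + nrow(X); apply(X, 1, objective) }
  }

  ## seeded run; caller's RNG state restored on exit
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_seed) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(control$seed)

  n <- control$population_size
  positions <- if (variant == "ISTOA") {
    chaotic_init(control, lower, upper, dimension)
  } else {
    matrix(stats::runif(n * dimension), n, dimension) *
      matrix(upper - lower, n, dimension, byrow = TRUE) +
      matrix(lower, n, dimension, byrow = TRUE)
  }
  fitness <- obj(positions)
  i <- which.min(fitness)
  best_position <- positions[i, ]
  best_fitness <- fitness[i]

  trace <- numeric(control$max_iterations)
  for (t in seq_len(control$max_iterations)) {
    st <- stoa_step(positions, fitness, best_position, best_fitness,
                    t, control, obj, lower, upper)
    positions <- st$positions; fitness <- st$fitness
    best_position <- st$best_position; best_fitness <- st$best_fitness
    if (variant == "ISTOA") {
      if (stats::runif(1) < control$cauchy_probability) {
        cp <- cauchy_perturb_best(best_position, best_fitness, obj,
                                  lower, upper)
        best_position <- cp$position; best_fitness <- cp$fitness
      }
      cm <- crossover_mutate(positions, fitness, control, obj, lower, upper)
      positions <- cm$positions; fitness <- cm$fitness
      i <- which.min(fitness)
      if (fitness[i] < best_fitness) {
        best_fitness <- fitness[i]
        best_position <- positions[i, ]
      }
    }
    trace[t] <- best_fitness
  }

  structure(list(best_position = best_position, best_fitness = best_fitness,
                 trace = trace, evaluations_used = n_eval,
                 variant = variant, control = control),
            class = "stoa_trace")
}

#' @export
print.stoa_trace <- function(x, ...) {
  cat(sprintf("%s run: pop %d, %d iterations, %d evaluations\n",
              x$variant, x$control$population_size,
              x$control$max_iterations, x$evaluations_used))
  cat(sprintf("  best fitness: %.6g\n", x$best_fitness))
  invisible(x)
}

#' @export
plot.stoa_trace <- function(x, log = "y", ...) {
  tr <- x$trace
  if (any(tr <= 0) && grepl("y", log)) log <- ""
  graphics::plot(seq_along(tr), tr, type = "l", log = log,
                 xlab = "iteration", ylab = "best fitness",
                 main = paste(x$variant, "convergence"), ...)
  invisible(x)
}
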