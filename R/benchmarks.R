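## Classical 23-function single-objective benchmark suite (Sphere ... Shekel-10)
## used to compare the plain and improved sooty tern optimizers. F1-F13 are
## scalable (30-D by default); F14-F23 have fixed low dimension.

new_benchmark <- function(name, dimension, lower, upper, fmin, xmin, fn,
                          noisy = FALSE, scalable = FALSE) {
  structure(
    list(name = name, dimension = as.integer(dimension),
         lower = rep_len(lower, dimension), upper = rep_len(upper, dimension),
         global_minimum_value = fmin, global_optimizer = xmin,
         evaluate = fn, noisy = noisy, scalable = scalable),
    class = "benchmark_fn")
}

## All evaluators take an n x d matrix of row-points (a bare vector is treated
## as a single point) and return a length-n numeric vector.
pts <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != d)
    stop("expected points of dimension ", d, ", got ", ncol(x))
  x
}

## Penalty term shared by the two penalized functions.
u_pen <- function(x, a, k, m) {
  out <- matrix(0, nrow(x), ncol(x))
  hi <- x > a; lo <- x < -a
  out[hi] <- k * (x[hi] - a)^m
  out[lo] <- k * (-x[lo] - a)^m
  rowSums(out)
}

## Fixed-dimension constant tables (canonical values).
.fox_a1 <- rep(c(-32, -16, 0, 16, 32), times = 5)
.fox_a2 <- rep(c(-32, -16, 0, 16, 32), each = 5)
.kow_a <- c(0.1957, 0.1947, 0.1735, 0.16, 0.0844, 0.0627, 0.0456, 0.0342,
            0.0323, 0.0235, 0.0246)
.kow_b <- 1 / c(0.25, 0.5, 1, 2, 4, 6, 8, 10, 12, 14, 16)
.hart_c <- c(1, 1.2, 3, 3.2)
.hart3_a <- rbind(c(3, 10, 30), c(0.1, 10, 35), c(3, 10, 30), c(0.1, 10, 35))
.hart3_p <- rbind(c(0.3689, 0.1170, 0.2673), c(0.4699, 0.4387, 0.7470),
                  c(0.1091, 0.8732, 0.5547), c(0.03815, 0.5743, 0.8828))
.hart6_a <- rbind(c(10, 3, 17, 3.5, 1.7, 8), c(0.05, 10, 17, 0.1, 8, 14),
                  c(3, 3.5, 1.7, 10, 17, 8), c(17, 8, 0.05, 10, 0.1, 14))
.hart6_p <- rbind(
  c(0.1312, 0.1696, 0.5569, 0.0124, 0.8283, 0.5886),
  c(0.2329, 0.4135, 0.8307, 0.3736, 0.1004, 0.9991),
  c(0.2348, 0.1451, 0.3522, 0.2883, 0.3047, 0.6650),
  c(0.4047, 0.8828, 0.8732, 0.5743, 0.1091, 0.0381))
.shek_a <- rbind(c(4, 4, 4, 4), c(1, 1, 1, 1), c(8, 8, 8, 8), c(6, 6, 6, 6),
                 c(3, 7, 3, 7), c(2, 9, 2, 9), c(5, 5, 3, 3), c(8, 1, 8, 1),
                 c(6, 2, 6, 2), c(7, 3.6, 7, 3.6))
.shek_c <- 0.1 * c(1, 2, 2, 4, 4, 6, 3, 7, 5, 5)

hartman_eval <- function(a, p) {
  d <- ncol(a)
  function(x) {
    x <- pts(x, d)
    -apply(x, 1, function(z) {
      zm <- matrix(z, 4, d, byrow = TRUE)
      sum(.hart_c * exp(-rowSums(a * (zm - p)^2)))
    })
  }
}

shekel_eval <- function(m) {
  a <- .shek_a[seq_len(m), , drop = FALSE]
  cc <- .shek_c[seq_len(m)]
  function(x) {
    x <- pts(x, 4)
    -apply(x, 1, function(z) {
      zm <- matrix(z, m, 4, byrow = TRUE)
      sum(1 / (rowSums((zm - a)^2) + cc))
    })
  }
}

build_suite <- function(dim_scalable = 30) {
  d <- dim_scalable
  fns <- list(
    new_benchmark("F1", d, -100, 100, 0, rep(0, d), function(x) {
      x <- pts(x, d); rowSums(x^2)
    }, scalable = TRUE),
    new_benchmark("F2", d, -10, 10, 0, rep(0, d), function(x) {
      x <- pts(x, d); a <- abs(x); rowSums(a) + apply(a, 1, prod)
    }, scalable = TRUE),
    new_benchmark("F3", d, -100, 100, 0, rep(0, d), function(x) {
      x <- pts(x, d)
      cs <- t(apply(x, 1, cumsum))
      if (is.null(dim(cs))) cs <- matrix(cs, nrow = nrow(x))
      rowSums(cs^2)
    }, scalable = TRUE),
    new_benchmark("F4", d, -100, 100, 0, rep(0, d), function(x) {
      x <- pts(x, d); apply(abs(x), 1, max)
    }, scalable = TRUE),
    new_benchmark("F5", d, -30, 30, 0, rep(1, d), function(x) {
      x <- pts(x, d)
      x1 <- x[, -d, drop = FALSE]; x2 <- x[, -1, drop = FALSE]
      rowSums(100 * (x2 - x1^2)^2 + (x1 - 1)^2)
    }, scalable = TRUE),
    new_benchmark("F6", d, -100, 100, 0, rep(0, d), function(x) {
      x <- pts(x, d); rowSums(floor(x + 0.5)^2)
    }, scalable = TRUE),
    ## F7 adds uniform [0,1) observation noise drawn from the caller's RNG
    ## stream, so runs remain reproducible under a seeded experiment.
    new_benchmark("F7", d, -1.28, 1.28, 0, rep(0, d), function(x) {
      x <- pts(x, d)
      iw <- matrix(seq_len(d), nrow(x), d, byrow = TRUE)
      rowSums(iw * x^4) + stats::runif(nrow(x))
    }, noisy = TRUE, scalable = TRUE),
    new_benchmark("F8", d, -500, 500, -418.982887272433 * d,
                  rep(420.9687488146, d), function(x) {
      x <- pts(x, d); rowSums(-x * sin(sqrt(abs(x))))
    }, scalable = TRUE),
    new_benchmark("F9", d, -5.12, 5.12, 0, rep(0, d), function(x) {
      x <- pts(x, d); rowSums(x^2 - 10 * cos(2 * pi * x) + 10)
    }, scalable = TRUE),
    new_benchmark("F10", d, -32, 32, 0, rep(0, d), function(x) {
      x <- pts(x, d)
      -20 * exp(-0.2 * sqrt(rowMeans(x^2))) - exp(rowMeans(cos(2 * pi * x))) +
        20 + exp(1)
    }, scalable = TRUE),
    new_benchmark("F11", d, -600, 600, 0, rep(0, d), function(x) {
      x <- pts(x, d)
      sq <- matrix(sqrt(seq_len(d)), nrow(x), d, byrow = TRUE)
      rowSums(x^2) / 4000 - apply(cos(x / sq), 1, prod) + 1
    }, scalable = TRUE),
    new_benchmark("F12", d, -50, 50, 0, rep(-1, d), function(x) {
      x <- pts(x, d)
      y <- 1 + (x + 1) / 4
      y1 <- y[, -d, drop = FALSE]; y2 <- y[, -1, drop = FALSE]
      (pi / d) * (10 * sin(pi * y[, 1])^2 +
                    rowSums((y1 - 1)^2 * (1 + 10 * sin(pi * y2)^2)) +
                    (y[, d] - 1)^2) + u_pen(x, 10, 100, 4)
    }, scalable = TRUE),
    new_benchmark("F13", d, -50, 50, 0, rep(1, d), function(x) {
      x <- pts(x, d)
      x1 <- x[, -d, drop = FALSE]; x2 <- x[, -1, drop = FALSE]
      0.1 * (sin(3 * pi * x[, 1])^2 +
               rowSums((x1 - 1)^2 * (1 + sin(3 * pi * x2)^2)) +
               (x[, d] - 1)^2 * (1 + sin(2 * pi * x[, d])^2)) +
        u_pen(x, 5, 100, 4)
    }, scalable = TRUE),
    new_benchmark("F14", 2, -65.536, 65.536, 0.998003837798,
                  c(-31.9776515891, -31.9776516769), function(x) {
      x <- pts(x, 2)
      apply(x, 1, function(z)
        1 / (1 / 500 + sum(1 / (1:25 + (z[1] - .fox_a1)^6 + (z[2] - .fox_a2)^6))))
    }),
    new_benchmark("F15", 4, -5, 5, 0.000307486236695,
                  c(0.1928235180, 0.1911887839, 0.1232484261, 0.1359194546),
                  function(x) {
      x <- pts(x, 4)
      apply(x, 1, function(z)
        sum((.kow_a - z[1] * (.kow_b^2 + .kow_b * z[2]) /
               (.kow_b^2 + .kow_b * z[3] + z[4]))^2))
    }),
    new_benchmark("F16", 2, -5, 5, -1.03162845349,
                  c(0.0898420515, -0.7126557142), function(x) {
      x <- pts(x, 2)
      4 * x[, 1]^2 - 2.1 * x[, 1]^4 + x[, 1]^6 / 3 + x[, 1] * x[, 2] -
        4 * x[, 2]^2 + 4 * x[, 2]^4
    }),
    new_benchmark("F17", 2, c(-5, 0), c(10, 15), 0.39788735773,
                  c(-3.1415926486, 12.275), function(x) {
      x <- pts(x, 2)
      (x[, 2] - 5.1 / (4 * pi^2) * x[, 1]^2 + 5 / pi * x[, 1] - 6)^2 +
        10 * (1 - 1 / (8 * pi)) * cos(x[, 1]) + 10
    }),
    new_benchmark("F18", 2, -2, 2, 3, c(0, -1), function(x) {
      x <- pts(x, 2)
      x1 <- x[, 1]; x2 <- x[, 2]
      (1 + (x1 + x2 + 1)^2 *
         (19 - 14 * x1 + 3 * x1^2 - 14 * x2 + 6 * x1 * x2 + 3 * x2^2)) *
        (30 + (2 * x1 - 3 * x2)^2 *
           (18 - 32 * x1 + 12 * x1^2 + 48 * x2 - 36 * x1 * x2 + 27 * x2^2))
    }),
    new_benchmark("F19", 3, 0, 1, -3.86278214779,
                  c(0.1146177629, 0.5556487827, 0.8525464915),
                  hartman_eval(.hart3_a, .hart3_p)),
    new_benchmark("F20", 6, 0, 1, -3.32236801141,
                  c(0.2016897231, 0.1500106754, 0.4768732080, 0.2753323732,
                    0.3116517108, 0.6573005522),
                  hartman_eval(.hart6_a, .hart6_p)),
    new_benchmark("F21", 4, 0, 10, -10.1531996791,
                  c(4.0000371536, 4.0001332792, 4.0000371536, 4.0001332792),
                  shekel_eval(5)),
    new_benchmark("F22", 4, 0, 10, -10.4029405668,
                  c(4.0005729275, 4.0006893798, 3.9994896987, 3.9996061511),
                  shekel_eval(7)),
    new_benchmark("F23", 4, 0, 10, -10.5364098167,
                  c(4.0007465465, 4.0005929458, 3.9996633913, 3.9995097910),
                  shekel_eval(10))
  )
  names(fns) <- vapply(fns, `[[`, "", "name")
  fns
}

#' Look up one of the 23 classical benchmark functions
#'
#' The suite is the standard collection of classical single-objective test
#' landscapes used throughout the swarm-optimization literature: F1-F7
#' unimodal scalable, F8-F13 multimodal scalable (30-D by default), F14-F23
#' fixed-dimension multimodal (Shekel's Foxholes, Kowalik, Six-Hump Camel,
#' Branin, Goldstein-Price, Hartman 3/6, Shekel 5/7/10).
#'
#' @param name Function identifier, one of `"F1"` ... `"F23"`.
#' @param dimension Dimension for the scalable functions F1-F13 (default 30).
#'   Ignored, with a warning, for the fixed-dimension functions.
#' @return An object of class `benchmark_fn`: a list with fields `name`,
#'   `dimension`, `lower`, `upper`, `global_minimum_value`, `global_optimizer`
#'   and `evaluate` (a vectorized function mapping an n x d matrix of
#'   row-points, or a single d-vector, to n objective values).
#' @examples
#' f <- get_benchmark("F10")
#' f$evaluate(rep(0, 30))  # Ackley at the origin
#' @export
get_benchmark <- function(name, dimension = 30) {
  valid <- paste0("F", 1:23)
  if (length(name) != 1 || !name %in% valid)
    stop("unknown benchmark function '", name, "'; valid names are ",
         paste(valid, collapse = ", "))
  idx <- match(name, valid)
  if (idx <= 13) {
    build_suite(dim_scalable = dimension)[[name]]
  } else {
    if (!missing(dimension) && !identical(dimension, 30))
      warning(name, " has fixed dimension; 'dimension' ignored")
    build_suite()[[name]]
  }
}

#' The full ordered benchmark suite
#'
#' @param dimension Dimension used for the scalable functions F1-F13.
#' @return Named list of 23 `benchmark_fn` objects in F1..F23 order.
#' @export
benchmark_suite <- function(dimension = 30) build_suite(dimension)

#' Suite metadata as a data frame
#'
#' One row per function: name, dimension, bounds, and the known global
#' minimum value. Useful for documentation or export as a delimited table.
#' @param dimension Dimension used for the scalable functions.
#' @return A `data.frame`.
#' @export
benchmark_table <- function(dimension = 30) {
  s <- benchmark_suite(dimension)
  data.frame(
    name = vapply(s, `[[`, "", "name"),
    dimension = vapply(s, `[[`, 0L, "dimension"),
    lower = vapply(s, function(f) f$lower[1], 0),
    upper = vapply(s, function(f) f$upper[1], 0),
    global_minimum = vapply(s, `[[`, 0, "global_minimum_value"),
    noisy = vapply(s, `[[`, FALSE, "noisy"),
    row.names = NULL)
}

#' @export
print.benchmark_fn <- function(x, ...) {
  cat(sprintf("Benchmark %s: dim %d, bounds [%g, %g], global minimum %g%s\n",
              x$name, x$dimension, x$lower[1], x$upper[1],
              x$global_minimum_value,
              if (x$noisy) " (stochastic noise term)" else ""))
  invisible(x)
}
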