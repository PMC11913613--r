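#' @keywords internal
"_PACKAGE"

## Shared internal helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

## Componentwise clamp to closed box bounds. `lower`/`upper` are scalars or
## vectors recycled along the columns of a matrix (or the elements of a vector).
clamp <- function(x, lower, upper) {
  if (is.matrix(x)) {
    lower <- rep_len(lower, ncol(x))
    upper <- rep_len(upper, ncol(x))
    x <- pmax(x, matrix(lower, nrow(x), ncol(x), byrow = TRUE))
    x <- pmin(x, matrix(upper, nrow(x), ncol(x), byrow = TRUE))
  } else {
    x <- pmin(pmax(x, lower), upper)
  }
  x
}

## Run `expr` under a temporary RNG state seeded with `seed`, restoring the
## caller's stream afterwards. Keeps stochastic model fits from perturbing the
## optimizer's seeded stream, so objective evaluations are pure functions of
## their arguments.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Stratified fold assignment: within each class, fold labels 1..k are dealt
## out evenly and shuffled. Depends only on (y, k, seed).
make_folds <- function(y, k, seed) {
  stopifnot(k >= 2)
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

is_binary01 <- function(x) all(x %in% c(0, 1))
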