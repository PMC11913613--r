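## Feature self-recognition wrapper: the improved sooty tern optimizer
## searches continuous positions that are binarized into feature masks; each
## mask is scored by the cross-validated accuracy of a base classifier
## trained on the retained columns only.

#' Binarize a continuous optimizer position into a feature mask
#'
#' Default rule: sigmoid transfer `S(x) = 1/(1+exp(-x))`, bit = 1 iff
#' `S(x) > 0.5` (equivalently x > 0). The alternative `"threshold"` rule cuts
#' positions (assumed in \[0,1\]) at 0.5. An all-zero mask is repaired by
#' forcing the bit with the largest transfer value to 1, since an empty
#' feature set is infeasible.
#'
#' @param position Numeric vector of finite position components.
#' @param rule `"sigmoid"` (default) or `"threshold"`.
#' @return Integer 0/1 vector with at least one 1.
#' @export
binarize_position <- function(position, rule = c("sigmoid", "threshold")) {
  rule <- match.arg(rule)
  if (any(!is.finite(position))) stop("position components must be finite")
  transfer <- if (rule == "sigmoid") stats::plogis(position) else position
  bits <- as.integer(transfer > 0.5)
  if (!any(bits)) bits[which.max(transfer)] <- 1L
  bits
}

## Extract predictor matrix + 0/1 label from a cohort data frame.
cohort_xy <- function(cohort, label = "nodule") {
  if (!label %in% names(cohort))
    stop("cohort has no '", label, "' label column")
  y <- cohort[[label]]
  if (!is_binary01(y)) stop("label column must be coded 0/1")
  x <- as.matrix(cohort[setdiff(names(cohort), label)])
  if (!is.numeric(x)) stop("all predictor columns must be numeric")
  list(x = x, y = as.integer(y))
}

#' Wrapper objective: one minus mean cross-validated accuracy of a mask
#'
#' Scores a binary feature mask by stratified k-fold cross-validation of the
#' base model trained on the retained columns only, and returns
#' `1 - mean(fold accuracies) + sparsity_weight * mean(mask)`. Minimizing
#' this maximizes accuracy. Fold assignment depends only on (labels, folds,
#' seed), and model fits run under an isolated RNG state, so the value is a
#' pure function of its arguments.
#'
#' @param mask Integer/logical 0/1 vector over the predictor columns; at
#'   least one 1.
#' @param cohort Data frame with predictor columns and a 0/1 label column.
#' @param base_model One of [base_models()].
#' @param folds Number of CV folds.
#' @param seed Seed controlling fold assignment and model fits.
#' @param sparsity_weight Optional penalty per retained-feature fraction
#'   (default 0: accuracy alone is the objective).
#' @param label Name of the label column.
#' @return The objective value (lower is better).
#' @export
mask_objective <- function(mask, cohort, base_model, folds = 5L, seed = 1L,
                           sparsity_weight = 0, label = "nodule") {
  xy <- cohort_xy(cohort, label)
  mask <- as.integer(as.logical(mask))
  if (length(mask) != ncol(xy$x))
    stop("mask length ", length(mask), " does not match ", ncol(xy$x),
         " predictors")
  if (!any(mask)) stop("empty feature mask is infeasible")
  if (min(table(xy$y)) < folds)
    stop("degenerate cohort: need at least 'folds' subjects per class")
  xsel <- xy$x[, mask == 1L, drop = FALSE]
  fold <- make_folds(xy$y, folds, seed)
  acc <- vapply(seq_len(folds), function(k) {
    tr <- fold != k
    if (length(unique(xy$y[tr])) < 2)
      stop("degenerate cohort: a training fold lacks both classes")
    cls <- fit_predict_class(base_model, xsel[tr, , drop = FALSE], xy$y[tr],
                             xsel[!tr, , drop = FALSE],
                             seed = seed + 1000L * k)
    mean(cls == xy$y[!tr])
  }, 0)
  1 - mean(acc) + sparsity_weight * mean(mask)
}

#' Exact train/test split sizes
#'
#' @param n Total sample size (>= 2).
#' @param train_fraction Fraction assigned to training, in (0, 1).
#' @return Integer vector `c(train, test)` with
#'   `train = round(n * train_fraction)`.
#' @examples
#' train_test_split_counts(4861, 0.8)  # 3889 972
#' @export
train_test_split_counts <- function(n, train_fraction = 0.8) {
  if (n < 2) stop("'n' must be at least 2")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("'train_fraction' must lie in (0, 1)")
  tr <- as.integer(round(n * train_fraction))
  c(train = tr, test = as.integer(n) - tr)
}

#' Stratified train/test index split
#'
#' @param y 0/1 label vector.
#' @param train_fraction Training fraction.
#' @param seed Seed (split depends only on `y`, the fraction, and the seed).
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, train_fraction = 0.8, seed = 1L) {
  with_local_seed(seed, {
    tr <- integer(0)
    for (cls in unique(y)) {
      idx <- which(y == cls)
      tr <- c(tr, sample(idx, round(length(idx) * train_fraction)))
    }
    tr <- sort(tr)
    list(train = tr, test = setdiff(seq_along(y), tr))
  })
}

#' Fit a feature self-recognition model
#'
#' Runs the improved sooty tern optimizer (ISTOA) over continuous positions
#' of dimension = number of predictors; each position is binarized into a
#' feature mask ([binarize_position()]) and scored by [mask_objective()] —
#' cross-validated accuracy of the chosen base classifier on the retained
#' columns. The best mask's model is then refit on all supplied rows
#' restricted to the selected features. Mask scores are memoised, so
#' revisited masks cost nothing.
#'
#' @param data Data frame holding the predictors and the label column
#'   (typically the training partition; keep the held-out test set outside).
#' @param label Name of the 0/1 label column (default `"nodule"`).
#' @param base_model One of [base_models()].
#' @param folds Inner CV folds used by the wrapper objective.
#' @param control A [stoa_control()]; the default is sized for a 33-feature
#'   cohort (population 20, 40 iterations).
#' @param binarize_rule Passed to [binarize_position()].
#' @param position_bound Half-width b of the symmetric search box
#'   \[-b, b\]^p for the continuous positions.
#' @param sparsity_weight Passed to [mask_objective()] (default 0).
#' @return An object of class `fsrml` with components `mask` (named 0/1
#'   vector), `selected` (retained feature names), `cv_accuracy`, `trace`
#'   (the `stoa_trace`), `fitted` (final model), plus the configuration.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`.
#' @examples
#' \donttest{
#' cohort <- generate_logistic_cohort(cohort_spec(n = 300, seed = 7))
#' fit <- fsrml(cohort, base_model = "LR",
#'              control = stoa_control(population_size = 8,
#'                                     max_iterations = 5, seed = 1))
#' print(fit)
#' }
#' @export
fsrml <- function(data, label = "nodule", base_model = "XGBoost",
                  folds = 5L,
                  control = stoa_control(population_size = 20L,
                                         max_iterations = 40L),
                  binarize_rule = "sigmoid", position_bound = 4,
                  sparsity_weight = 0) {
  get_model(base_model)  # validate early
  xy <- cohort_xy(data, label)
  p <- ncol(xy$x)
  feature_names <- colnames(xy$x)
  seed <- control$seed

  cache <- new.env(parent = emptyenv())
  score_mask <- function(bits) {
    key <- paste(bits, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- mask_objective(bits, data, base_model, folds = folds, seed = seed,
                          sparsity_weight = sparsity_weight, label = label)
    cache[[key]] <- val
    val
  }
  objective <- function(position)
    score_mask(binarize_position(position, binarize_rule))

  ## sigmoid rule: symmetric box around 0 (bit = sign). threshold rule:
  ## unit box with a 0.5 cut, under which the optimizer's contraction
  ## toward the origin doubles as sparsity pressure on the mask.
  bounds <- if (binarize_rule == "threshold") c(0, 1)
            else c(-position_bound, position_bound)
  trace <- stoa_optim(objective, lower = bounds[1], upper = bounds[2],
                      dimension = p, control = control, variant = "ISTOA",
                      vectorized = FALSE)

  mask <- binarize_position(trace$best_position, binarize_rule)
  names(mask) <- feature_names
  cv_acc <- 1 - mask_objective(mask, data, base_model, folds = folds,
                               seed = seed, sparsity_weight = 0,
                               label = label)
  m <- get_model(base_model)
  fitted <- with_local_seed(seed, m$fit(xy$x[, mask == 1L, drop = FALSE],
                                        xy$y))

  structure(list(call = match.call(), base_model = base_model,
                 mask = mask, selected = feature_names[mask == 1L],
                 cv_accuracy = cv_acc, trace = trace, fitted = fitted,
                 feature_names = feature_names, folds = folds, seed = seed,
                 control = control, binarize_rule = binarize_rule,
                 label = label, n = nrow(data),
                 schema = attr(data, "schema")),
            class = "fsrml")
}

#' @export
print.fsrml <- function(x, ...) {
  cat("Feature self-recognition model (ISTOA wrapper)\n")
  cat(sprintf("  base model: %s; n = %d; %d/%d features selected\n",
              x$base_model, x$n, sum(x$mask), length(x$mask)))
  cat(sprintf("  %d-fold CV accuracy at the selected mask: %.4f\n",
              x$folds, x$cv_accuracy))
  invisible(x)
}

#' @export
summary.fsrml <- function(object, ...) {
  structure(list(fit = object), class = "summary.fsrml")
}

#' @export
print.summary.fsrml <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  selected features:\n")
  cat(paste0("    ", f$selected, collapse = "\n"), "\n")
  tr <- f$trace$trace
  cat(sprintf("  wrapper objective: %.4f (start) -> %.4f (final), %d mask evaluations\n",
              tr[1], tr[length(tr)], f$trace$evaluations_used))
  invisible(x)
}

#' @export
coef.fsrml <- function(object, ...) object$mask

#' Predict nodule risk for new subjects
#'
#' @param object A fitted `fsrml` model.
#' @param newdata Data frame containing at least every feature the model's
#'   mask retains; a missing feature is an error naming it.
#' @param type `"prob"` for predicted probabilities, `"class"` for 0/1 calls
#'   at `threshold`.
#' @param threshold Probability cut for `type = "class"`.
#' @param ... Unused.
#' @return Numeric vector of probabilities or integer 0/1 vector.
#' @export
predict.fsrml <- function(object, newdata, type = c("prob", "class"),
                          threshold = 0.5, ...) {
  type <- match.arg(type)
  missing_ft <- setdiff(object$selected, names(newdata))
  if (length(missing_ft))
    stop("newdata is missing required feature(s): ",
         paste(missing_ft, collapse = ", "))
  x <- as.matrix(as.data.frame(newdata)[object$selected])
  p <- with_local_seed(object$seed,
                       get_model(object$base_model)$prob(object$fitted, x))
  if (type == "prob") unname(p) else as.integer(p >= threshold)
}

#' @export
plot.fsrml <- function(x, ...) {
  tr <- x$trace$trace
  graphics::plot(seq_along(tr), 1 - tr, type = "l",
                 xlab = "ISTOA iteration", ylab = "best CV accuracy",
                 main = sprintf("Wrapper convergence (%s)", x$base_model),
                 ...)
  invisible(x)
}
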