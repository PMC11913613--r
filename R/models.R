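## Pluggable base classifiers behind the wrapper. Each entry supplies
## fit(x, y) and prob(fit, x) on a numeric matrix x and 0/1 label y.
## Hyperparameters are library defaults (fixed here once); the wrapper's
## contribution is the feature search, not base-model tuning.

fit_logistic <- function(x, y) {
  xm <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(
    stats::glm.fit(xm, y, family = stats::binomial()))
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  list(coef = cf)
}

model_registry <- list(
  LR = list(
    fit = fit_logistic,
    prob = function(fit, x)
      drop(stats::plogis(cbind(1, x) %*% fit$coef))
  ),
  DT = list(
    fit = function(x, y) {
      df <- data.frame(.y = factor(y, levels = c(0, 1)), x)
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    prob = function(fit, x) {
      p <- predict(fit, newdata = data.frame(x), type = "prob")
      if ("1" %in% colnames(p)) p[, "1"] else rep(0, nrow(x))
    }
  ),
  KNN = list(
    ## lazy learner: store standardized training data, k = 5
    fit = function(x, y) {
      ctr <- colMeans(x)
      scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
      list(x = scale(x, ctr, scl), y = factor(y, levels = c(0, 1)),
           center = ctr, scale = scl, k = 5)
    },
    prob = function(fit, x) {
      xs <- scale(x, fit$center, fit$scale)
      pr <- class::knn(fit$x, xs, fit$y, k = fit$k, prob = TRUE)
      w <- attr(pr, "prob")
      ifelse(pr == "1", w, 1 - w)
    }
  ),
  BP = list(
    ## single-hidden-layer feed-forward network on standardized inputs
    fit = function(x, y) {
      ctr <- colMeans(x)
      scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
      net <- nnet::nnet(scale(x, ctr, scl), y, size = 5, decay = 0.01,
                        maxit = 150, entropy = TRUE, trace = FALSE)
      list(net = net, center = ctr, scale = scl)
    },
    prob = function(fit, x)
      drop(predict(fit$net, scale(x, fit$center, fit$scale)))
  ),
  SVM = list(
    fit = function(x, y)
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial",
                 probability = TRUE),
    prob = function(fit, x) {
      p <- attr(predict(fit, x, probability = TRUE), "probabilities")
      p[, "1"]
    },
    ## class-only path skips Platt scaling: much cheaper inside the wrapper
    fit_cls = function(x, y)
      e1071::svm(x, factor(y, levels = c(0, 1)), kernel = "radial"),
    cls = function(fit, x) as.integer(predict(fit, x) == "1")
  ),
  RF = list(
    fit = function(x, y)
      randomForest::randomForest(x, factor(y, levels = c(0, 1)),
                                 ntree = 200),
    prob = function(fit, x) predict(fit, x, type = "prob")[, "1"]
  ),
  XGBoost = list(
    fit = function(x, y)
      xgboost::xgb.train(
        params = list(objective = "binary:logistic", max_depth = 4,
                      eta = 0.3, nthread = 1),
        data = xgboost::xgb.DMatrix(x, label = y, nthread = 1),
        nrounds = 60, verbose = 0),
    prob = function(fit, x)
      predict(fit, xgboost::xgb.DMatrix(x, nthread = 1))
  )
)

#' Available base classifiers
#'
#' @return Character vector of base-model identifiers accepted by [fsrml()]
#'   and related functions: logistic regression (LR), decision tree (DT),
#'   k-nearest neighbours (KNN), feed-forward neural network (BP), support
#'   vector machine (SVM), random forest (RF), and gradient boosting
#'   (XGBoost).
#' @export
base_models <- function() names(model_registry)

get_model <- function(name) {
  if (length(name) != 1 || !name %in% names(model_registry))
    stop("unknown base model '", name, "'; valid models are ",
         paste(names(model_registry), collapse = ", "))
  model_registry[[name]]
}

## Fit on (x, y) and return out-of-sample probabilities for x_new, under an
## isolated RNG state so stochastic learners stay reproducible and do not
## perturb the caller's stream.
fit_predict_prob <- function(model_name, x, y, x_new, seed) {
  m <- get_model(model_name)
  with_local_seed(seed, {
    fit <- m$fit(x, y)
    m$prob(fit, x_new)
  })
}

## Class-prediction counterpart used by the wrapper objective, where only
## 0/1 calls matter; falls back to thresholding probabilities at 0.5.
fit_predict_class <- function(model_name, x, y, x_new, seed) {
  m <- get_model(model_name)
  with_local_seed(seed, {
    if (!is.null(m$cls)) {
      fit <- (m$fit_cls %||% m$fit)(x, y)
      m$cls(fit, x_new)
    } else {
      fit <- m$fit(x, y)
      as.integer(m$prob(fit, x_new) >= 0.5)
    }
  })
}
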