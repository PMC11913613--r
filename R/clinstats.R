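## Univariate cohort statistics (Pearson chi-square on 2x2 counts, pooled-
## variance two-sample t from summary statistics) and forward-stepwise
## multivariable logistic regression with Wald reporting.

#' Pearson chi-square test on a 2x2 table
#'
#' Without continuity correction by default, i.e.
#' `N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on 1 df — the convention used by
#' SPSS-style univariate screens of large cohorts. Yates' correction is
#' available as an option.
#'
#' @param counts 2x2 non-negative matrix (rows = feature yes/no,
#'   columns = outcome negative/positive) with positive margins.
#' @param correct Apply Yates' continuity correction (default `FALSE`).
#' @return List with `statistic`, `df`, `p.value`.
#' @examples
#' chi_square_2x2(matrix(c(1469, 2224, 815, 353), 2))
#' @export
chi_square_2x2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("counts must be 2x2")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero marginal: every row and column sum must be positive")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value)
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's (equal-variance) t from group (mean, sd, n):
#' `sp^2 = ((n1-1)s1^2 + (n2-1)s2^2) / (n1+n2-2)`,
#' `t = |m2 - m1| / (sp * sqrt(1/n1 + 1/n2))`, two-sided p on n1+n2-2 df.
#' The statistic is reported as a positive magnitude.
#'
#' @param mean1,sd1,n1 First group summary (sd > 0, n >= 2).
#' @param mean2,sd2,n2 Second group summary.
#' @return List with `statistic`, `df`, `p.value`.
#' @examples
#' pooled_t(33.87, 8.43, 3693, 43.32, 9.16, 1168)
#' @export
pooled_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop("group sds must be positive")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  tt <- abs(mean2 - mean1) / (sp * sqrt(1 / n1 + 1 / n2))
  list(statistic = tt, df = df, p.value = 2 * stats::pt(-tt, df))
}

#' Univariate screen of every predictor against the outcome
#'
#' Binary columns get the chi-square test on the 2x2 feature-by-outcome
#' table; continuous columns get the pooled-variance t test on the two
#' outcome groups. Column kinds come from the cohort's schema attribute when
#' present, otherwise a column whose values all lie in {0,1} is treated as
#' binary. Constant columns are skipped with a note.
#'
#' @param cohort Data frame with predictor columns and a 0/1 label column.
#' @param label Label column name.
#' @param alpha Significance flag level (default 0.05).
#' @return A data frame (class `univariate_screen`) with one row per
#'   predictor: feature, kind, group summaries (counts/percent or
#'   mean +/- sd), statistic, p, significance flag and a skipped note.
#' @export
univariate_screen <- function(cohort, label = "nodule", alpha = 0.05) {
  xy <- cohort_xy(cohort, label)
  schema <- attr(cohort, "schema")
  feats <- colnames(xy$x)
  kind <- if (!is.null(schema)) {
    k <- schema$kind[match(feats, schema$name)]
    if (anyNA(k)) stop("schema mismatch: no kind declared for ",
                       paste(feats[is.na(k)], collapse = ", "))
    k
  } else {
    ifelse(apply(xy$x, 2, is_binary01), "binary", "continuous")
  }
  y <- xy$y
  rows <- lapply(seq_along(feats), function(j) {
    v <- xy$x[, j]
    out <- data.frame(feature = feats[j], kind = kind[j],
                      summary_negative = NA_character_,
                      summary_positive = NA_character_,
                      statistic = NA_real_, p = NA_real_,
                      significant = NA, note = "")
    if (stats::sd(v) == 0) {
      out$note <- "skipped: constant column"
      return(out)
    }
    if (kind[j] == "binary") {
      tab <- rbind(c(sum(v == 1 & y == 0), sum(v == 1 & y == 1)),
                   c(sum(v == 0 & y == 0), sum(v == 0 & y == 1)))
      if (any(rowSums(tab) == 0)) {
        out$note <- "skipped: degenerate 2x2 table"
        return(out)
      }
      ht <- chi_square_2x2(tab)
      out$summary_negative <- sprintf("%d (%.2f%%)", tab[1, 1],
                                      100 * tab[1, 1] / sum(y == 0))
      out$summary_positive <- sprintf("%d (%.2f%%)", tab[1, 2],
                                      100 * tab[1, 2] / sum(y == 1))
    } else {
      ht <- pooled_t(mean(v[y == 0]), stats::sd(v[y == 0]), sum(y == 0),
                     mean(v[y == 1]), stats::sd(v[y == 1]), sum(y == 1))
      out$summary_negative <- sprintf("%.2f +/- %.2f", mean(v[y == 0]),
                                      stats::sd(v[y == 0]))
      out$summary_positive <- sprintf("%.2f +/- %.2f", mean(v[y == 1]),
                                      stats::sd(v[y == 1]))
    }
    out$statistic <- ht$statistic
    out$p <- ht$p.value
    out$significant <- ht$p.value < alpha
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("univariate_screen", "data.frame")
  res
}

#' @export
print.univariate_screen <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$statistic <- round(y$statistic, digits)
  y$p <- signif(y$p, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

## Wald rows (excluding the intercept) from a fitted glm.
wald_table <- function(fit) {
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  beta <- sm[, 1]; se <- sm[, 2]
  data.frame(feature = rownames(sm), beta = beta, se = se,
             wald = (beta / se)^2,
             p = stats::pchisq((beta / se)^2, df = 1, lower.tail = FALSE),
             odds_ratio = exp(beta),
             ci_low = exp(beta - 1.96 * se),
             ci_high = exp(beta + 1.96 * se),
             row.names = NULL)
}

#' Forward-stepwise multivariable logistic regression
#'
#' Forward selection by Wald p value with backward removal: at each step the
#' candidate whose Wald p (in the model extended by it) is smallest enters
#' if below `enter_p`; after each entry, any in-model term whose Wald p
#' exceeds `remove_p` is dropped. Fits are maximum-likelihood logistic
#' regressions (IRLS via `glm`). The final table reports beta, SE,
#' Wald = (beta/SE)^2, p, EXP(B) = exp(beta) and the log-symmetric 95% CI
#' exp(beta +/- 1.96 SE).
#'
#' @param cohort Data frame with the outcome and candidate columns.
#' @param candidate_features Character vector of candidate columns (default:
#'   all predictors).
#' @param label Outcome column name (0/1).
#' @param enter_p,remove_p Entry / removal thresholds (SPSS-style defaults
#'   0.05 / 0.10).
#' @param max_steps Step cap.
#' @return A data frame (class `stepwise_logistic`) with one row per
#'   selected feature (possibly zero rows); the intercept and the selection
#'   path are attached as attributes. A separation warning is raised when a
#'   coefficient diverges.
#' @export
stepwise_logistic <- function(cohort, candidate_features = NULL,
                              label = "nodule", enter_p = 0.05,
                              remove_p = 0.10, max_steps = 50L) {
  xy <- cohort_xy(cohort, label)
  candidates <- candidate_features %||% colnames(xy$x)
  miss <- setdiff(candidates, colnames(xy$x))
  if (length(miss))
    stop("candidate features not in cohort: ", paste(miss, collapse = ", "))
  df <- data.frame(.y = xy$y, xy$x[, candidates, drop = FALSE])
  selected <- character(0)
  path <- character(0)

  fit_for <- function(vars) {
    fml <- if (length(vars))
      stats::reformulate(vars, response = ".y") else .y ~ 1
    suppressWarnings(stats::glm(fml, family = stats::binomial(), data = df,
                                control = stats::glm.control(maxit = 50)))
  }

  for (step in seq_len(max_steps)) {
    changed <- FALSE
    remaining <- setdiff(candidates, selected)
    if (length(remaining)) {
      pvals <- vapply(remaining, function(v) {
        fit <- fit_for(c(selected, v))
        wt <- wald_table(fit)
        wt$p[match(v, wt$feature)]
      }, 0)
      pvals <- pvals[!is.na(pvals)]
      if (length(pvals) && min(pvals) < enter_p) {
        selected <- c(selected, names(which.min(pvals)))
        path <- c(path, paste0("+", names(which.min(pvals))))
        changed <- TRUE
      }
    }
    if (length(selected)) {
      wt <- wald_table(fit_for(selected))
      worst <- wt$feature[which.max(wt$p)]
      if (max(wt$p) > remove_p) {
        selected <- setdiff(selected, worst)
        path <- c(path, paste0("-", worst))
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  fit <- fit_for(selected)
  if (length(selected)) {
    res <- wald_table(fit)
    res <- res[match(selected, res$feature), , drop = FALSE]
    rownames(res) <- NULL
    if (any(abs(res$beta) > 15) || !fit$converged)
      warning("possible separation: a coefficient diverged or the fit did not converge")
  } else {
    res <- data.frame(feature = character(0), beta = numeric(0),
                      se = numeric(0), wald = numeric(0), p = numeric(0),
                      odds_ratio = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0))
  }
  attr(res, "intercept") <- unname(stats::coef(fit)["(Intercept)"])
  attr(res, "path") <- path
  class(res) <- c("stepwise_logistic", "data.frame")
  res
}

#' @export
print.stepwise_logistic <- function(x, digits = 3, ...) {
  if (!nrow(x)) {
    cat("Stepwise logistic regression: no feature entered the model\n")
    return(invisible(x))
  }
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y, row.names = FALSE)
  cat(sprintf("Intercept: %.3f\n", attr(x, "intercept")))
  invisible(x)
}
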