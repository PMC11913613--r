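# Published univariate statistics recomputed from the printed summaries:
# 2x2 count tables (feature yes/no x outcome negative/positive) and
# (mean, sd, n) group summaries for the two continuous risk features.
published_tables <- list(
  smoking = list(counts = rbind(c(1469, 815), c(2224, 353)), chi2 = 320.600),
  occupational = list(counts = rbind(c(443, 350), c(3250, 818)),
                      chi2 = 209.891),
  family_history = list(counts = rbind(c(517, 338), c(3176, 830)),
                        chi2 = 136.618),
  chronic_lung = list(counts = rbind(c(187, 121), c(3506, 1047)),
                      chi2 = 41.936),
  elevated_cea = list(counts = rbind(c(61, 58), c(3632, 1110)),
                      chi2 = 40.807),
  stress = list(counts = rbind(c(775, 327), c(2918, 814)), chi2 = 29.163))

published_t <- list(
  age = list(neg = c(33.87, 8.43, 3693), pos = c(43.32, 9.16, 1168),
             t = 32.691),
  albumin = list(neg = c(49.14, 11.23, 3693), pos = c(44.92, 9.33, 1168),
                 t = 11.635))

test_that("chi-square reproduces the published cohort statistics to 3 dp", {
  for (nm in names(published_tables)) {
    ref <- published_tables[[nm]]
    got <- chi_square_2x2(ref$counts)
    expect_equal(round(got$statistic, 3), ref$chi2, label = nm)
    expect_lt(got$p.value, 0.001)
  }
})

test_that("chi-square equals the brute-force expected-count formula", {
  set.seed(17)
  for (i in 1:25) {
    tab <- matrix(rpois(4, 40) + 1, 2)
    got <- chi_square_2x2(tab)$statistic
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(got, sum((tab - E)^2 / E), tolerance = 1e-9)
  }
  # independence: balanced table scores zero
  expect_equal(chi_square_2x2(matrix(50, 2, 2))$statistic, 0)
  expect_error(chi_square_2x2(rbind(c(0, 0), c(5, 5))), "marginal")
})

test_that("pooled t reproduces the published statistics and self-consistency", {
  for (nm in names(published_t)) {
    ref <- published_t[[nm]]
    got <- pooled_t(ref$neg[1], ref$neg[2], ref$neg[3],
                    ref$pos[1], ref$pos[2], ref$pos[3])
    expect_equal(round(got$statistic, 3), ref$t, label = nm)
    expect_equal(got$df, ref$neg[3] + ref$pos[3] - 2)
  }
  expect_equal(pooled_t(5, 1, 10, 5, 1, 10)$statistic, 0)
  expect_error(pooled_t(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("pooled t from summaries equals Student's t on the raw data", {
  set.seed(23)
  for (i in 1:10) {
    a <- rnorm(40, 1, 2); b <- rnorm(60, 0.5, 2)
    ours <- pooled_t(mean(a), sd(a), 40, mean(b), sd(b), 60)
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(ours$statistic, abs(unname(ref$statistic)),
                 tolerance = 1e-9)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-9)
  }
})

test_that("univariate screen flags calibrated contrasts and skips constants", {
  cohort <- generate_cohort(cohort_spec(), seed = 1)
  cohort$flatline <- 1  # constant column rides along
  attr(cohort, "schema") <- NULL  # fall back to kind inference
  scr <- univariate_screen(cohort)
  expect_equal(nrow(scr), 34)
  informative <- names(cohort_spec()$effects)
  got <- scr[match(informative, scr$feature), ]
  expect_true(all(got$significant))
  expect_match(scr$note[scr$feature == "flatline"], "constant")
  expect_true(is.na(scr$p[scr$feature == "flatline"]))
  # kinds inferred correctly
  expect_identical(scr$kind[scr$feature == "smoking"], "binary")
  expect_identical(scr$kind[scr$feature == "age"], "continuous")
})

test_that("a saturated 2x2 logistic fit recovers the log odds ratio", {
  # single binary predictor: beta = log(ad/(bc))
  a <- 30; b <- 70; c <- 10; d <- 90
  x <- rep(c(1, 1, 0, 0), c(a, b, c, d))
  y <- rep(c(1, 0, 1, 0), c(a, b, c, d))
  cohort <- data.frame(exposure = x, nodule = y)
  res <- stepwise_logistic(cohort, enter_p = 0.5)
  expect_equal(res$beta[res$feature == "exposure"], log(a * d / (b * c)),
               tolerance = 1e-6)
  expect_equal(res$wald, (res$beta / res$se)^2, tolerance = 1e-9)
  expect_equal(res$odds_ratio, exp(res$beta), tolerance = 1e-12)
  expect_equal(res$ci_low, exp(res$beta - 1.96 * res$se), tolerance = 1e-12)
})

test_that("stepwise selection stays near-empty under the null", {
  # pure-noise candidates: forward entry at 0.05 admits only the occasional
  # false positive; the final model should stay small in most runs
  small <- 0L
  for (s in 1:10) {
    set.seed(800 + s)
    cohort <- data.frame(matrix(rnorm(400 * 10), 400, 10))
    names(cohort) <- paste0("noise", 1:10)
    cohort$nodule <- rbinom(400, 1, 0.3)
    res <- stepwise_logistic(cohort)
    if (nrow(res) <= 2) small <- small + 1L
  }
  expect_gte(small, 8L)
})

test_that("stepwise logistic recovers generating coefficients on synthetic data", {
  spec <- cohort_spec(n = 5000, seed = 31)
  cohort <- generate_logistic_cohort(spec)
  std <- attr(cohort, "metadata")$standardization
  zs <- cohort
  for (j in seq_len(nrow(std)))
    zs[[std$name[j]]] <- (cohort[[std$name[j]]] - std$center[j]) / std$scale[j]
  res <- stepwise_logistic(zs)
  truth <- spec$effects
  for (nm in names(truth)) {
    expect_true(nm %in% res$feature, label = nm)
    expect_lt(abs(res$beta[res$feature == nm] - truth[[nm]]), 0.15)
  }
})
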