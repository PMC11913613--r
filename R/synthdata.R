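## Seeded synthetic physical-examination cohorts with a 33-predictor schema
## (11 binary + 22 continuous: demographics, lifestyle, and routine
## laboratory panels) and a binary pulmonary-nodule label. Two generators:
##   * generate_cohort()          - class-conditional sampling, calibrated so
##     that the eight risk features carry the published group contrasts in
##     expectation (the remaining 25 features carry none);
##   * generate_logistic_cohort() - predictors from pooled marginals, label
##     from a logistic link over standardized predictors, with the generating
##     coefficients recorded as ground truth for recovery tests.

default_schema <- function() {
  b <- function(name, p_neg, p_pos = p_neg, cal = FALSE)
    data.frame(name = name, kind = "binary", units = "",
               p_neg = p_neg, p_pos = p_pos,
               mean_neg = NA_real_, sd_neg = NA_real_,
               mean_pos = NA_real_, sd_pos = NA_real_,
               calibrated = cal)
  cc <- function(name, units, m_neg, s_neg, m_pos = m_neg, s_pos = s_neg,
                 cal = FALSE)
    data.frame(name = name, kind = "continuous", units = units,
               p_neg = NA_real_, p_pos = NA_real_,
               mean_neg = m_neg, sd_neg = s_neg,
               mean_pos = m_pos, sd_pos = s_pos,
               calibrated = cal)
  rbind(
    ## general information (12)
    b("gender_male", 0.55),
    cc("age", "year", 33.87, 8.43, 43.32, 9.16, cal = TRUE),
    b("smoking", 0.3978, 0.6978, cal = TRUE),
    b("alcohol", 0.30),
    b("occupational_exposure", 0.12, 0.2997, cal = TRUE),
    b("education_college", 0.40),
    b("chronic_lung_disease", 0.0506, 0.1036, cal = TRUE),
    b("family_history_lung_cancer", 0.14, 0.2894, cal = TRUE),
    b("regular_exercise", 0.35),
    cc("bmi", "kg/m2", 23.5, 3.2),
    b("psychological_stress", 0.2099, 0.2866, cal = TRUE),
    b("depressive_symptoms", 0.10),
    ## laboratory results (21)
    b("elevated_cea", 0.0165, 0.0497, cal = TRUE),
    cc("tsh", "mIU/L", 2.0, 1.0),
    cc("wbc", "10^9/L", 6.3, 1.5),
    cc("lymphocyte_count", "10^9/L", 2.0, 0.6),
    cc("platelet_count", "10^9/L", 250, 60),
    cc("hemoglobin", "g/L", 145, 15),
    cc("eosinophil_count", "10^9/L", 0.15, 0.10),
    cc("basophil_count", "10^9/L", 0.03, 0.02),
    cc("albumin", "g/L", 49.14, 11.23, 44.92, 9.33, cal = TRUE),
    cc("globulin", "g/L", 28, 4),
    cc("ag_ratio", "", 1.6, 0.3),
    cc("alt", "U/L", 25, 12),
    cc("ast", "U/L", 24, 10),
    cc("indirect_bilirubin", "umol/L", 10, 4),
    cc("hdl", "mmol/L", 1.3, 0.3),
    cc("ldl", "mmol/L", 2.8, 0.8),
    cc("triglycerides", "mmol/L", 1.4, 0.8),
    cc("fasting_glucose", "mmol/L", 5.2, 0.8),
    cc("creatinine", "umol/L", 75, 15),
    cc("bun", "mmol/L", 5.0, 1.3),
    cc("uric_acid", "umol/L", 330, 80)
  )
}

default_effects <- function() {
  c(age = 1.536, smoking = 1.231, psychological_stress = 0.515,
    occupational_exposure = 1.067, chronic_lung_disease = 0.742,
    family_history_lung_cancer = 0.7, albumin = -0.5, elevated_cea = 1.011)
}

#' Default synthetic-cohort specification
#'
#' Returns the cohort specification the package's simulations run under:
#' 4,861 subjects with nodule prevalence 1168/4861, a 33-predictor schema
#' (11 binary, 22 continuous), class-conditional marginals for the eight
#' informative risk features (age, smoking, psychological stress,
#' occupational exposure, chronic lung disease, family history of lung
#' cancer, albumin, elevated CEA), reference-interval placeholder marginals
#' for the other 25, and standardized log-odds effects over the informative
#' features for the logistic-link generator.
#'
#' @param n Cohort size.
#' @param prevalence Nodule prevalence in (0, 1).
#' @param seed Default seed used by the generators.
#' @param effects Named vector of standardized log-odds generating
#'   coefficients (names must be schema feature names).
#' @param intercept Logistic-link intercept.
#' @return An object of class `cohort_spec`.
#' @examples
#' spec <- cohort_spec(n = 500)
#' spec$schema[spec$schema$calibrated, c("name", "kind")]
#' @export
cohort_spec <- function(n = 4861L, prevalence = 1168 / 4861, seed = 1L,
                        effects = default_effects(), intercept = -2.3) {
  if (n < 1) stop("invalid spec: 'n' must be positive")
  if (prevalence <= 0 || prevalence >= 1)
    stop("invalid spec: 'prevalence' must lie in (0, 1)")
  schema <- default_schema()
  if (length(effects) && !all(names(effects) %in% schema$name))
    stop("invalid spec: unknown effect names ",
         paste(setdiff(names(effects), schema$name), collapse = ", "))
  structure(list(n = as.integer(n), prevalence = prevalence,
                 seed = as.integer(seed), schema = schema,
                 effects = effects, intercept = intercept),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic cohort spec: n = %d, prevalence = %.4f, %d predictors (%d binary, %d continuous)\n",
    x$n, x$prevalence, nrow(x$schema), sum(x$schema$kind == "binary"),
    sum(x$schema$kind == "continuous")))
  cat(sprintf("  informative features: %s\n",
              paste(names(x$effects), collapse = ", ")))
  invisible(x)
}

## Pooled (marginal) parameters implied by the class-conditional spec.
pooled_params <- function(spec) {
  s <- spec$schema; pr <- spec$prevalence
  p_pool <- (1 - pr) * s$p_neg + pr * s$p_pos
  mean_pool <- (1 - pr) * s$mean_neg + pr * s$mean_pos
  var_pool <- (1 - pr) * (s$sd_neg^2 + s$mean_neg^2) +
    pr * (s$sd_pos^2 + s$mean_pos^2) - mean_pool^2
  data.frame(name = s$name, kind = s$kind, p = p_pool,
             mean = mean_pool, sd = sqrt(var_pool))
}

## Standardization constants (theoretical pooled mean/sd) used by the
## logistic generator and by recovery tests; exact, not sample-based.
standardization_table <- function(spec) {
  pp <- pooled_params(spec)
  ctr <- ifelse(pp$kind == "binary", pp$p, pp$mean)
  scl <- ifelse(pp$kind == "binary", sqrt(pp$p * (1 - pp$p)), pp$sd)
  data.frame(name = pp$name, center = ctr, scale = scl)
}

finish_cohort <- function(x, label, spec, metadata) {
  x <- as.data.frame(x)
  x$nodule <- label
  attr(x, "schema") <- spec$schema
  attr(x, "metadata") <- metadata
  class(x) <- c("fsrml_cohort", "data.frame")
  x
}

#' Generate a class-conditional synthetic cohort
#'
#' Labels are Bernoulli(prevalence); within each class, binary features are
#' Bernoulli with the class prevalence and continuous features Normal with
#' the class mean/sd from the schema, independently. The eight informative
#' features therefore carry their calibrated group contrasts in expectation;
#' the 25 placeholder features carry none.
#'
#' @param spec A [cohort_spec()].
#' @param n,seed Override the spec's size and seed.
#' @return A `data.frame` of class `fsrml_cohort` with the 33 predictors and
#'   a `nodule` column in {0,1}; the schema and generation metadata are
#'   stored as attributes.
#' @export
generate_cohort <- function(spec = cohort_spec(), n = spec$n,
                            seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  s <- spec$schema
  with_local_seed(seed, {
    y <- stats::rbinom(n, 1, spec$prevalence)
    cols <- lapply(seq_len(nrow(s)), function(j) {
      if (s$kind[j] == "binary") {
        p <- ifelse(y == 1, s$p_pos[j], s$p_neg[j])
        stats::rbinom(n, 1, p)
      } else {
        m <- ifelse(y == 1, s$mean_pos[j], s$mean_neg[j])
        sd <- ifelse(y == 1, s$sd_pos[j], s$sd_neg[j])
        stats::rnorm(n, m, sd)
      }
    })
    names(cols) <- s$name
    finish_cohort(cols, y, spec,
                  list(generator = "class_conditional", seed = seed, n = n,
                       prevalence = spec$prevalence))
  })
}

#' Generate a logistic-link synthetic cohort with known coefficients
#'
#' Predictors are drawn independently from their pooled marginals; the label
#' is Bernoulli(plogis(intercept + sum(beta_j * z_j))) where z_j is the
#' predictor standardized by its theoretical pooled mean and sd (for a
#' binary feature, by p and sqrt(p(1-p))). The generating coefficients,
#' intercept and standardization constants are recorded in the cohort
#' metadata as ground truth for parameter- and feature-recovery tests.
#'
#' @inheritParams generate_cohort
#' @return An `fsrml_cohort` data frame; `attr(x, "metadata")$effects` holds
#'   the generating standardized log-odds.
#' @export
generate_logistic_cohort <- function(spec = cohort_spec(), n = spec$n,
                                     seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!length(spec$effects)) stop("spec$effects must be set")
  pp <- pooled_params(spec)
  std <- standardization_table(spec)
  with_local_seed(seed, {
    cols <- lapply(seq_len(nrow(pp)), function(j) {
      if (pp$kind[j] == "binary") stats::rbinom(n, 1, pp$p[j])
      else stats::rnorm(n, pp$mean[j], pp$sd[j])
    })
    names(cols) <- pp$name
    x <- do.call(cbind, cols)
    z <- sweep(sweep(x, 2, std$center, `-`), 2, std$scale, `/`)
    beta <- setNames(numeric(nrow(pp)), pp$name)
    beta[names(spec$effects)] <- spec$effects
    eta <- spec$intercept + drop(z %*% beta)
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    finish_cohort(as.data.frame(x), y, spec,
                  list(generator = "logistic", seed = seed, n = n,
                       effects = as.list(spec$effects),
                       intercept = spec$intercept,
                       standardization = std))
  })
}

#' Write / read a cohort as CSV plus a JSON sidecar
#'
#' The CSV holds the 33 predictors and the `nodule` label; the sidecar
#' (`<path>.json`) holds the schema and generation metadata (seed,
#' generating coefficients), so ground truth round-trips unchanged.
#'
#' @param cohort An `fsrml_cohort`.
#' @param path CSV file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the restored `fsrml_cohort`.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  side <- list(schema = attr(cohort, "schema"),
               metadata = attr(cohort, "metadata"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    attr(x, "schema") <- as.data.frame(side$schema)
    md <- side$metadata
    if (!is.null(md$standardization))
      md$standardization <- as.data.frame(md$standardization)
    attr(x, "metadata") <- md
  }
  class(x) <- c("fsrml_cohort", "data.frame")
  x
}

#' Write / read a cohort specification as YAML
#'
#' Serializes the spec's size, prevalence, seed, intercept, effects and full
#' schema table; reading reconstructs an identical [cohort_spec()].
#'
#' @param spec A [cohort_spec()].
#' @param path YAML file path.
#' @return `write_cohort_spec` returns `path` invisibly; `read_cohort_spec`
#'   returns the restored spec.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  yaml::write_yaml(list(n = spec$n, prevalence = spec$prevalence,
                        seed = spec$seed, intercept = spec$intercept,
                        effects = as.list(spec$effects),
                        schema = lapply(seq_len(nrow(spec$schema)),
                                        function(i) as.list(spec$schema[i, ]))),
                   path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- cohort_spec(n = y$n, prevalence = y$prevalence, seed = y$seed,
                      effects = unlist(y$effects), intercept = y$intercept)
  spec$schema <- do.call(rbind, lapply(y$schema, function(r)
    as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v))))
  spec
}

#' One-subject template at the generator's low- or high-risk mode
#'
#' Builds a single-row data frame: at `mode = "high"` every informative risk
#' feature is set adverse (binary risks present, age one sd above the
#' positive-class mean, albumin one sd below it); at `mode = "low"` the
#' opposite. All other features sit at their pooled means.
#'
#' @param spec A [cohort_spec()].
#' @param mode `"low"` or `"high"`.
#' @return A one-row `data.frame` with the 33 predictor columns.
#' @export
subject_template <- function(spec = cohort_spec(), mode = c("low", "high")) {
  mode <- match.arg(mode)
  pp <- pooled_params(spec)
  s <- spec$schema
  vals <- ifelse(pp$kind == "binary", round(pp$p), pp$mean)
  names(vals) <- pp$name
  risky <- names(spec$effects)
  for (nm in risky) {
    j <- match(nm, s$name)
    adverse <- sign(spec$effects[[nm]])  # +1: high value raises risk
    if (s$kind[j] == "binary") {
      vals[nm] <- if (mode == "high") (adverse > 0) + 0 else (adverse < 0) + 0
    } else {
      shift <- if (mode == "high") adverse else -adverse
      vals[nm] <- if (mode == "high") s$mean_pos[j] + shift * s$sd_pos[j]
                  else s$mean_neg[j] - adverse * s$sd_neg[j]
    }
  }
  as.data.frame(as.list(vals))
}
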