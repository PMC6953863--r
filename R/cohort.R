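# Synthetic cohort generation: features drawn from the schema marginals,
# outcome from a planted logistic model on unit-scaled features.

#' Evaluate expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded package operations never disturb the session stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Planted logistic outcome model
#'
#' A log-odds model for the probability of the positive outcome (treated)
#' given the feature row. Coefficients act on features min-max scaled to
#' \[0, 1\] using the schema ranges, so magnitudes are comparable across
#' indicators, the ordinal fibrosis stage and age.
#'
#' @param coefficients named numeric vector; names must be a subset of the
#'   schema variable ids. Unnamed variables get coefficient 0.
#' @param intercept log-odds intercept (calibrate with
#'   [calibrate_intercept()]).
#' @return an `outcome_model` object.
#' @export
outcome_model <- function(coefficients = numeric(0), intercept = 0) {
  if (length(coefficients) && is.null(names(coefficients)))
    stop("coefficients must be named by variable id")
  if (any(!is.finite(coefficients)) || !is.finite(intercept))
    stop("coefficients and intercept must be finite")
  structure(list(coefficients = coefficients, intercept = intercept),
            class = "outcome_model")
}

#' Default planted outcome model
#'
#' Places nonzero effects on the variables the sparse classifiers are expected
#' to recover — OST PWID (X3), recent PWID (X4), therapy-naive status (X8),
#' fibrosis stage (X11), age (X13) and genotype 3 (X16) — with recent PWID
#' carrying the dominant negative effect on treatment uptake, mirroring its
#' role as the main barrier to therapy.
#'
#' @return an `outcome_model` (intercept uncalibrated, 0).
#' @export
default_outcome_model <- function() {
  outcome_model(c(X3 = -0.8, X4 = -6, X8 = -0.6, X11 = 1.6,
                  X13 = 0.8, X16 = 0.7))
}

#' @export
print.outcome_model <- function(x, ...) {
  cat("outcome_model (logistic, unit-scaled features)\n")
  cat("  intercept:", format(x$intercept, digits = 4), "\n")
  if (length(x$coefficients)) {
    cat("  coefficients:\n")
    print(x$coefficients)
  } else cat("  no nonzero coefficients\n")
  invisible(x)
}

# Min-max scale a feature matrix to [0,1] using schema-implied ranges:
# indicators are already 0/1; ordinal and continuous variables use their
# declared level range / truncation bounds.
schema_unit_scale <- function(schema, X) {
  Z <- X
  for (id in schema$variables$id) {
    kind <- schema$variables$kind[schema$variables$id == id]
    if (kind == "ordinal") {
      lev <- schema$params[[id]]$levels
      Z[, id] <- (X[, id] - min(lev)) / (max(lev) - min(lev))
    } else if (kind == "continuous") {
      p <- schema$params[[id]]
      Z[, id] <- (X[, id] - p$min) / (p$max - p$min)
    }
  }
  Z
}

# Sample the feature block only (no outcome); used by both the cohort
# sampler and the Monte Carlo prevalence calibration.
sample_features <- function(schema, n) {
  v <- schema$variables
  X <- matrix(0, nrow = n, ncol = 17L, dimnames = list(NULL, v$id))
  if (n == 0L) return(X)
  for (g in unique(stats::na.omit(v$group))) {
    ids <- v$id[!is.na(v$group) & v$group == g]
    pick <- sample(seq_along(ids), n, replace = TRUE,
                   prob = v$prob[match(ids, v$id)])
    for (k in seq_along(ids)) X[, ids[k]] <- as.numeric(pick == k)
  }
  for (id in v$id[v$kind == "binary"])
    X[, id] <- stats::rbinom(n, 1L, v$prob[v$id == id])
  for (id in v$id[v$kind == "ordinal"]) {
    p <- schema$params[[id]]
    X[, id] <- sample(p$levels, n, replace = TRUE, prob = p$level_probs)
  }
  for (id in v$id[v$kind == "continuous"]) {
    p <- schema$params[[id]]
    lo <- stats::pnorm((p$min - p$mean) / p$sd)
    hi <- stats::pnorm((p$max - p$mean) / p$sd)
    X[, id] <- p$mean + p$sd * stats::qnorm(stats::runif(n, lo, hi))
  }
  X
}

#' Sample a synthetic cohort
#'
#' Draws `n` patients from the schema marginals — one draw per one-hot block
#' (multinomial), independent Bernoullis for the free indicators, the ordinal
#' stage from its level probabilities, age from a truncated normal — and the
#' outcome from the logistic `model` applied to unit-scaled features.
#' Reproducible: the same `(schema, model, n, seed)` gives a bit-identical
#' table.
#'
#' @param schema a `variable_schema`.
#' @param model an `outcome_model`.
#' @param n number of patients (>= 0).
#' @param seed integer RNG seed.
#' @return a `cohort_table`: list with `features` (n x 17 numeric matrix,
#'   columns in schema order), `outcome` (0/1 vector), `ids`, `provenance`.
#' @examples
#' sch <- default_schema()
#' coh <- sample_cohort(sch, outcome_model(), n = 100, seed = 1)
#' mean(coh$outcome)
#' @export
sample_cohort <- function(schema, model, n, seed = 1L) {
  validate_schema(schema)
  if (length(n) != 1L || n < 0 || n != round(n)) stop("n must be a count >= 0")
  n <- as.integer(n)
  with_seed(seed, {
    X <- sample_features(schema, n)
    eta <- model$intercept +
      as.vector(schema_unit_scale(schema, X) %*% coef_vector(model, schema))
    y <- if (n) stats::rbinom(n, 1L, stats::plogis(eta)) else integer(0)
    cohort_table(X, y, provenance = "synthetic", schema = schema)
  })
}

# Full-length coefficient vector in schema order.
coef_vector <- function(model, schema) {
  b <- stats::setNames(numeric(17L), schema$variables$id)
  unknown <- setdiff(names(model$coefficients), names(b))
  if (length(unknown))
    stop("coefficients reference unknown variables: ",
         paste(unknown, collapse = ", "))
  b[names(model$coefficients)] <- model$coefficients
  b
}

#' Construct a cohort table
#'
#' @param features numeric matrix (n x 17, columns named by variable id).
#' @param outcome 0/1 vector, length n (1 = treated).
#' @param ids optional row identifiers.
#' @param provenance `"synthetic"` or `"external"`.
#' @param schema optional schema; when given, invariants (one-hot closure,
#'   age bounds, outcome coding) are checked.
#' @return a `cohort_table`.
#' @export
cohort_table <- function(features, outcome, ids = NULL,
                         provenance = c("synthetic", "external"),
                         schema = NULL) {
  provenance <- match.arg(provenance)
  features <- as.matrix(features)
  if (nrow(features) != length(outcome))
    stop("features and outcome disagree on the number of patients")
  if (length(outcome) && !all(outcome %in% c(0, 1)))
    stop("outcome must be coded 0 (untreated) / 1 (treated)")
  if (is.null(ids)) ids <- seq_len(nrow(features))
  coh <- structure(list(features = features, outcome = as.integer(outcome),
                        ids = ids, provenance = provenance),
                   class = "cohort_table")
  if (!is.null(schema)) validate_cohort(coh, schema)
  coh
}

#' Check a cohort against its schema
#'
#' Asserts one-hot closure (exactly one active indicator per block per row),
#' 0/1 coding for indicators and outcome, ordinal levels within range, and
#' age inside the schema truncation bounds.
#'
#' @param cohort a `cohort_table`.
#' @param schema a `variable_schema`.
#' @return the cohort, invisibly; stops on violation.
#' @export
validate_cohort <- function(cohort, schema) {
  X <- cohort$features
  v <- schema$variables
  if (!identical(colnames(X), v$id))
    stop("cohort columns must match the schema order: ",
         paste(v$id, collapse = ", "))
  if (nrow(X) == 0L) return(invisible(cohort))
  for (g in unique(stats::na.omit(v$group))) {
    ids <- v$id[!is.na(v$group) & v$group == g]
    if (!all(rowSums(X[, ids, drop = FALSE]) == 1))
      stop("one-hot group '", g, "' violated: rows without exactly one 1")
  }
  bin <- v$id[v$kind %in% c("binary", "onehot")]
  if (!all(X[, bin] %in% c(0, 1))) stop("indicator columns must be 0/1")
  for (id in v$id[v$kind == "ordinal"])
    if (!all(X[, id] %in% schema$params[[id]]$levels))
      stop("ordinal variable '", id, "' outside its level set")
  for (id in v$id[v$kind == "continuous"]) {
    p <- schema$params[[id]]
    if (any(X[, id] < p$min | X[, id] > p$max))
      stop("continuous variable '", id, "' outside [", p$min, ", ", p$max, "]")
  }
  invisible(cohort)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table: %d patients x %d features (%s)\n",
              nrow(x$features), ncol(x$features), x$provenance))
  if (length(x$outcome))
    cat(sprintf("  treated prevalence: %.4f\n", mean(x$outcome)))
  invisible(x)
}

#' Calibrate the outcome-model intercept to a target prevalence
#'
#' Holds the coefficients fixed and finds the intercept at which the expected
#' positive-class prevalence under the schema marginals equals
#' `target_prevalence`. The expectation is estimated once by Monte Carlo
#' (deterministic given `seed`); because the expected prevalence is strictly
#' increasing in the intercept, bisection converges to machine tolerance on
#' the fixed sample.
#'
#' @param model an `outcome_model`.
#' @param schema a `variable_schema`.
#' @param target_prevalence target in (0, 1).
#' @param tol acceptable |expected - target| (default 1e-4).
#' @param n_mc Monte Carlo sample size (default 2e5).
#' @param seed RNG seed for the Monte Carlo draw.
#' @return the model with calibrated intercept and attributes
#'   `achieved_prevalence`, `mc_n`.
#' @examples
#' m <- calibrate_intercept(outcome_model(), default_schema(), 0.664)
#' m$intercept  # qlogis(0.664) when all coefficients are zero
#' @export
calibrate_intercept <- function(model, schema, target_prevalence,
                                tol = 1e-4, n_mc = 2e5, seed = 1L) {
  if (target_prevalence <= 0 || target_prevalence >= 1)
    stop("target_prevalence must lie in (0, 1)")
  eta <- with_seed(seed, {
    X <- sample_features(schema, n_mc)
    as.vector(schema_unit_scale(schema, X) %*% coef_vector(model, schema))
  })
  prev <- function(b0) mean(stats::plogis(b0 + eta))
  lo <- -40; hi <- 40
  if (prev(lo) > target_prevalence || prev(hi) < target_prevalence)
    stop("target prevalence unattainable for these coefficient magnitudes")
  root <- stats::uniroot(function(b0) prev(b0) - target_prevalence,
                         c(lo, hi), tol = 1e-10)$root
  achieved <- prev(root)
  if (abs(achieved - target_prevalence) > tol)
    stop("calibration failed: achieved ", achieved,
         " vs target ", target_prevalence)
  out <- outcome_model(model$coefficients, root)
  attr(out, "achieved_prevalence") <- achieved
  attr(out, "mc_n") <- n_mc
  out
}

#' Write / read a cohort as headered CSV
#'
#' Columns `id`, `X1`..`X17` in schema order, final column `y`.
#'
#' @param cohort a `cohort_table`.
#' @param path file path.
#' @return `write_cohort`: the path, invisibly. `read_cohort`: a
#'   `cohort_table` with provenance `"external"`.
#' @export
write_cohort <- function(cohort, path) {
  df <- data.frame(id = cohort$ids, cohort$features, y = cohort$outcome,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param schema optional `variable_schema` to validate against on read.
#' @rdname write_cohort
#' @export
read_cohort <- function(path, schema = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  feat_cols <- setdiff(names(df), c("id", "y"))
  cohort_table(as.matrix(df[, feat_cols, drop = FALSE]), df$y,
               ids = df$id, provenance = "external", schema = schema)
}
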