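# Basis-specific input scaling and the train/generalisation holdout split.

# Target ranges per basis family. Product units need strictly positive
# inputs bounded away from 0 (negative exponents otherwise explode) and a
# modest upper bound; sigmoid units are kept off their saturated tails;
# Gaussian bases are centred on the origin.
basis_range <- function(basis) {
  switch(match.arg(basis, c("PU", "SU", "RBF")),
         PU  = c(1, 2),
         SU  = c(0.1, 0.9),
         RBF = c(-1, 1))
}

#' Fit a per-column min-max scaler for a basis family
#'
#' Captures each feature column's minimum and maximum from the (training)
#' cohort and records the basis-specific target range: \[1, 2\] for product
#' units, \[0.1, 0.9\] for sigmoid units, \[-1, 1\] for radial basis
#' functions. Constant columns are flagged and later mapped to the range
#' midpoint.
#'
#' @param table a `cohort_table` or numeric feature matrix.
#' @param basis `"PU"`, `"SU"` or `"RBF"`.
#' @return a `scaling_spec`.
#' @export
fit_scaler <- function(table, basis) {
  X <- feature_matrix(table)
  if (nrow(X) == 0L) stop("cannot fit a scaler on an empty table")
  structure(list(
    basis = match.arg(basis, c("PU", "SU", "RBF")),
    columns = colnames(X),
    min = apply(X, 2, min),
    max = apply(X, 2, max),
    range = basis_range(basis)
  ), class = "scaling_spec")
}

#' Apply a fitted scaler
#'
#' Affine per-column transform
#' `x* = (x - min) / (max - min) * (high - low) + low` with the min/max
#' captured at fit time. Values from the fitted data land inside the target
#' range; out-of-range values on new data are transformed by the same affine
#' map and may exceed it (no clipping). Constant columns map to the range
#' midpoint.
#'
#' @param spec a `scaling_spec` from [fit_scaler()].
#' @param table a `cohort_table` or numeric matrix with the fitted columns.
#' @return scaled numeric matrix.
#' @export
apply_scaler <- function(spec, table) {
  X <- feature_matrix(table)
  if (!identical(colnames(X), spec$columns))
    stop("columns do not match the fitted scaler")
  lo <- spec$range[1]; hi <- spec$range[2]
  span <- spec$max - spec$min
  out <- X
  for (j in seq_along(spec$columns)) {
    out[, j] <- if (span[j] == 0) (lo + hi) / 2 else
      (X[, j] - spec$min[j]) / span[j] * (hi - lo) + lo
  }
  out
}

#' Invert a fitted scaler
#'
#' Maps scaled values back to the original units on non-constant columns.
#' @param spec a `scaling_spec`.
#' @param scaled scaled matrix as produced by [apply_scaler()].
#' @return matrix in original units (constant columns restored to their
#'   fitted constant value).
#' @export
invert_scaler <- function(spec, scaled) {
  lo <- spec$range[1]; hi <- spec$range[2]
  span <- spec$max - spec$min
  out <- scaled
  for (j in seq_along(spec$columns)) {
    out[, j] <- if (span[j] == 0) spec$min[j] else
      (scaled[, j] - lo) / (hi - lo) * span[j] + spec$min[j]
  }
  out
}

#' @export
print.scaling_spec <- function(x, ...) {
  cat(sprintf("scaling_spec: %s basis, target range [%g, %g], %d columns\n",
              x$basis, x$range[1], x$range[2], length(x$columns)))
  invisible(x)
}

#' Serialise / restore a scaling spec as JSON
#' @param spec a `scaling_spec`.
#' @param path file path.
#' @return `write_scaler`: path invisibly; `read_scaler`: a `scaling_spec`.
#' @export
write_scaler <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_scaler
#' @export
read_scaler <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(basis = x$basis, columns = x$columns,
                 min = stats::setNames(as.numeric(x$min), x$columns),
                 max = stats::setNames(as.numeric(x$max), x$columns),
                 range = as.numeric(x$range)),
            class = "scaling_spec")
}

feature_matrix <- function(table) {
  if (inherits(table, "cohort_table")) table$features else as.matrix(table)
}

#' Default training-set size for a cohort
#'
#' The reference experiment used 2193 of 2940 patients for training (74.6%,
#' despite the stated 75%); the printed counts win. For other cohort sizes
#' the same fraction is used.
#' @param n cohort size.
#' @return training-set size.
#' @export
default_n_train <- function(n) if (n == 2940L) 2193L else as.integer(round(0.746 * n))

#' Holdout split into training and generalisation sets
#'
#' Random permutation split, reproducible per seed. With `stratified = TRUE`
#' (the default) the split is drawn within each outcome class so class
#' proportions are preserved to within one patient per class — this protects
#' the minimum-sensitivity metric on imbalanced data.
#'
#' @param table a `cohort_table`.
#' @param n_train number of training rows (default [default_n_train()]).
#' @param seed RNG seed.
#' @param stratified preserve class proportions (default `TRUE`).
#' @return a `split_result`: list with `train`, `generalisation`
#'   (`cohort_table`s), `train_idx`, `seed`, `stratified`.
#' @export
holdout_split <- function(table, n_train = default_n_train(nrow(table$features)),
                          seed = 1L, stratified = TRUE) {
  n <- nrow(table$features)
  if (n_train <= 0 || n_train >= n)
    stop("n_train must satisfy 0 < n_train < ", n)
  idx <- with_seed(seed, {
    if (stratified) {
      frac <- n_train / n
      cls <- split(seq_len(n), table$outcome)
      # largest-remainder apportionment keeps per-class counts within 1
      want <- vapply(cls, function(i) frac * length(i), numeric(1))
      k <- floor(want)
      rem <- n_train - sum(k)
      if (rem > 0) {
        ord <- order(want - k, decreasing = TRUE)
        k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
      }
      sort(unlist(mapply(function(i, ki) sample(i, ki), cls, k,
                         SIMPLIFY = FALSE), use.names = FALSE))
    } else sort(sample.int(n, n_train))
  })
  subset_rows <- function(rows) cohort_table(
    table$features[rows, , drop = FALSE], table$outcome[rows],
    ids = table$ids[rows], provenance = table$provenance)
  structure(list(train = subset_rows(idx),
                 generalisation = subset_rows(setdiff(seq_len(n), idx)),
                 train_idx = idx, seed = seed, stratified = stratified),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("split_result: %d training / %d generalisation (%s, seed %d)\n",
              nrow(x$train$features), nrow(x$generalisation$features),
              if (x$stratified) "stratified" else "plain", x$seed))
  invisible(x)
}
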