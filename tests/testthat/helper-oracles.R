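# Independent oracles, deliberately written as naive loops so they share no
# code path with the package implementations they check.

# Hand-evaluated forward pass: explicit per-node, per-input loops.
oracle_forward <- function(genome, x_row) {
  acc <- genome$beta0
  for (j in seq_len(ncol(genome$W))) {
    idx <- which(genome$conn[, j])
    b <- switch(genome$basis,
      PU = {
        prod_val <- 1
        for (i in idx) prod_val <- prod_val * x_row[i]^genome$W[i, j]
        prod_val
      },
      SU = {
        s <- genome$bias[j]
        for (i in idx) s <- s + genome$W[i, j] * x_row[i]
        1 / (1 + exp(-s))
      },
      RBF = {
        d2 <- 0
        for (i in idx) d2 <- d2 + (x_row[i] - genome$W[i, j])^2
        exp(-d2 / (2 * genome$radius[j]^2))
      })
    acc <- acc + genome$beta[j] * b
  }
  1 / (1 + exp(-acc))
}

# Mann-Whitney AUC: all cross-class pairs, half weight on score ties.
oracle_auc <- function(truth, scores) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# Confusion tally by explicit enumeration.
oracle_confusion <- function(truth, predicted) {
  out <- matrix(0L, 2, 2)
  for (k in seq_along(truth)) {
    i <- if (truth[k] == 1) 1L else 2L
    j <- if (predicted[k] == 1) 1L else 2L
    out[i, j] <- out[i, j] + 1L
  }
  out
}

# Precision-recall curve by brute-force threshold enumeration.
oracle_pr_auc <- function(truth, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  recall <- precision <- numeric(length(th))
  for (k in seq_along(th)) {
    pred <- as.integer(scores >= th[k])
    tp <- sum(pred == 1 & truth == 1)
    recall[k] <- tp / sum(truth == 1)
    precision[k] <- tp / sum(pred == 1)
  }
  r <- c(0, recall); p <- c(precision[1], precision)
  sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
}

# Random valid genome built directly (independent of init_population).
random_test_genome <- function(basis, d, max_nodes = 2L) {
  M <- sample.int(max_nodes, 1L)
  conn <- matrix(FALSE, d, M)
  W <- matrix(0, d, M)
  for (j in seq_len(M)) {
    idx <- sample.int(d, sample.int(d, 1L))
    conn[idx, j] <- TRUE
    W[idx, j] <- runif(length(idx), -2, 2)
  }
  network_genome(basis, W, conn,
                 beta = runif(M, -3, 3), beta0 = runif(1, -2, 2),
                 bias = if (basis == "SU") runif(M, -2, 2),
                 radius = if (basis == "RBF") runif(M, 0.2, 3))
}

# Scaled inputs appropriate for a basis family.
random_scaled_inputs <- function(basis, n, d) {
  r <- switch(basis, PU = c(1, 2), SU = c(0.1, 0.9), RBF = c(-1, 1))
  matrix(runif(n * d, r[1], r[2]), n, d)
}

# Margin-separated 2-input toy problem: linearly separable with a margin,
# realisable by all three basis families.
make_toy <- function(seed, n = 50L, margin = 0.1) {
  set.seed(seed)
  x <- matrix(runif(6 * n), ncol = 2, dimnames = list(NULL, c("a", "b")))
  s <- x[, 1] + x[, 2] - 1
  keep <- which(abs(s) > margin)[seq_len(n)]
  list(x = x[keep, ], y = as.integer(s[keep] > 0))
}

# Label vectors reproducing a printed 2x2 confusion matrix
# (rows true (treated, untreated), cols predicted).
labels_from_cm <- function(cm) {
  truth <- c(rep(1L, cm[1, 1] + cm[1, 2]), rep(0L, cm[2, 1] + cm[2, 2]))
  pred <- c(rep(1L, cm[1, 1]), rep(0L, cm[1, 2]),
            rep(1L, cm[2, 1]), rep(0L, cm[2, 2]))
  list(truth = truth, pred = pred)
}

# Small calibrated synthetic cohort shared by the heavier tests.
toy_cohort <- function(n, seed = 11L, model = default_outcome_model()) {
  sch <- default_schema()
  sample_cohort(sch, calibrate_intercept(model, sch, 0.664, seed = 5L),
                n, seed = seed)
}
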