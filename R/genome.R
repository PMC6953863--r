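# Sparse evolvable network genomes for the three basis families.
#
# A genome holds M hidden nodes (1..max, default max 4) over d inputs:
#   W    d x M matrix of input-layer parameters (PU exponents, SU weights,
#        RBF centre coordinates), meaningful only where `conn` is TRUE
#   conn d x M logical connectivity mask; every node needs >= 1 connection
#   bias length-M sigmoid node biases (SU only)
#   radius length-M positive Gaussian radii (RBF only; one shared radius
#        per node, not per dimension)
#   beta length-M output weights, beta0 the output bias
# The output unit is logistic: p(treated) = plogis(beta0 + sum beta_j B_j(x)).

#' Construct a network genome
#'
#' @param basis `"PU"`, `"SU"` or `"RBF"`.
#' @param W d x M numeric matrix of input-layer parameters.
#' @param conn d x M logical connectivity mask.
#' @param beta length-M output weights.
#' @param beta0 output bias.
#' @param bias length-M node biases (SU; ignored otherwise).
#' @param radius length-M positive radii (RBF; ignored otherwise).
#' @param max_hidden architecture upper bound recorded for validation.
#' @return a `network_genome`.
#' @export
network_genome <- function(basis, W, conn, beta, beta0,
                           bias = NULL, radius = NULL, max_hidden = 4L) {
  basis <- match.arg(basis, c("PU", "SU", "RBF"))
  W <- as.matrix(W); conn <- as.matrix(conn)
  g <- structure(list(basis = basis, n_inputs = nrow(W), W = W,
                      conn = conn, bias = bias, radius = radius,
                      beta = as.numeric(beta), beta0 = as.numeric(beta0),
                      max_hidden = as.integer(max_hidden)),
                 class = "network_genome")
  validate_genome(g)
  g
}

#' Validate a network genome
#'
#' Enforces the structural invariants: hidden-node count within
#' \[1, max_hidden\], at least one input connection per hidden node, an
#' output weight per node, positive RBF radii, finite parameters.
#'
#' @param genome a `network_genome`.
#' @return the genome, invisibly; stops on violation.
#' @export
validate_genome <- function(genome) {
  M <- ncol(genome$W)
  if (M < 1L || M > genome$max_hidden)
    stop("hidden-node count ", M, " outside [1, ", genome$max_hidden, "]")
  if (!identical(dim(genome$conn), dim(genome$W)))
    stop("connectivity mask and parameter matrix dimensions differ")
  if (any(colSums(genome$conn) == 0))
    stop("every hidden node needs at least one input connection")
  if (length(genome$beta) != M)
    stop("every hidden node needs an output weight")
  if (genome$basis == "RBF") {
    if (length(genome$radius) != M || any(genome$radius <= 0))
      stop("RBF genomes need one positive radius per node")
  }
  if (genome$basis == "SU" && length(genome$bias) != M)
    stop("SU genomes need one node bias per node")
  if (any(!is.finite(genome$W[genome$conn])) || any(!is.finite(genome$beta)) ||
      !is.finite(genome$beta0))
    stop("genome parameters must be finite")
  invisible(genome)
}

#' @export
print.network_genome <- function(x, ...) {
  cat(sprintf("network_genome: %s basis, %d hidden node(s), %d inputs (%d active)\n",
              x$basis, ncol(x$W), x$n_inputs, length(active_inputs(x))))
  cat(sprintf("  connections: %d\n", count_connections(x)))
  invisible(x)
}

# Reusable input transforms shared across many forward passes (the EA
# evaluates thousands of genomes on the same scaled matrix).
precompute_inputs <- function(basis, X) {
  X <- as.matrix(X)
  out <- list(X = X)
  if (basis == "PU") {
    if (any(X <= 0))
      stop("product-unit inputs must be strictly positive (scale to [1, 2])")
    out$logX <- log(X)
  }
  if (basis == "RBF") out$X2 <- X^2
  out
}

# Hidden-layer output matrix, N x M, for all nodes at once.
hidden_outputs <- function(genome, pre) {
  Wm <- genome$W * genome$conn
  switch(genome$basis,
    PU = exp(pre$logX %*% Wm),
    SU = stats::plogis(sweep(pre$X %*% Wm, 2, genome$bias, `+`)),
    RBF = {
      # squared distance over connected inputs only:
      # sum_i (x_i - c_i)^2 = sum x_i^2 - 2 sum x_i c_i + sum c_i^2
      d2 <- pre$X2 %*% genome$conn - 2 * pre$X %*% Wm
      d2 <- sweep(d2, 2, colSums(genome$W^2 * genome$conn), `+`)
      exp(-sweep(d2, 2, 2 * genome$radius^2, `/`))
    })
}

#' Basis-function output of one hidden node
#'
#' Evaluates a single hidden node over scaled input rows: product units
#' return the product of connected inputs raised to their exponents, sigmoid
#' units the logistic of bias plus weighted sum, Gaussian radial units
#' `exp(-||x - c||^2 / (2 r^2))`, each sum/product running over connected
#' inputs only.
#'
#' @param genome a `network_genome`.
#' @param x scaled input row (length d) or matrix (N x d). Product-unit
#'   inputs must be strictly positive.
#' @param node hidden-node index.
#' @return numeric vector of node outputs.
#' @export
basis_output <- function(genome, x, node = 1L) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != genome$n_inputs) stop("input dimension mismatch")
  if (node < 1L || node > ncol(genome$W)) stop("no such hidden node")
  pre <- precompute_inputs(genome$basis, x)
  as.vector(hidden_outputs(genome, pre)[, node])
}

#' Forward pass: probability of the positive (treated) class
#'
#' `p = plogis(beta0 + sum_j beta_j B_j(x))` with `B_j` the basis outputs.
#'
#' @param genome a `network_genome`.
#' @param x scaled input row or N x d matrix.
#' @param pre optional precomputed transforms from internal callers.
#' @return numeric vector of probabilities in \[0, 1\].
#' @examples
#' g <- network_genome("RBF", W = matrix(0, 2, 1), conn = matrix(TRUE, 2, 1),
#'                     beta = 8.957, beta0 = 0, radius = 1)
#' forward(g, c(0, 0))  # at the centre: plogis(8.957)
#' @export
forward <- function(genome, x, pre = NULL) {
  if (is.null(pre)) {
    if (is.null(dim(x))) x <- matrix(x, nrow = 1)
    if (ncol(x) != genome$n_inputs) stop("input dimension mismatch")
    pre <- precompute_inputs(genome$basis, x)
  }
  as.vector(stats::plogis(genome$beta0 + hidden_outputs(genome, pre) %*% genome$beta))
}

#' Hard labels from a genome
#'
#' @param object a `network_genome`.
#' @param x scaled input matrix.
#' @param type `"prob"` or `"label"` (label 1 iff p >= 0.5).
#' @param ... unused.
#' @return probabilities or 0/1 labels.
#' @export
predict.network_genome <- function(object, x, type = c("prob", "label"), ...) {
  p <- forward(object, x)
  if (match.arg(type) == "prob") p else as.integer(p >= 0.5)
}

#' Connection count of a genome
#'
#' The parsimony measure: input-to-hidden links plus hidden-to-output weights
#' plus the output bias. Sigmoid node biases and Gaussian radii are node
#' parameters, not connections, and are not counted — under this convention a
#' single-node Gaussian model on six inputs has 6 + 1 + 1 = 8 connections.
#'
#' @param genome a `network_genome`.
#' @return integer connection count.
#' @export
count_connections <- function(genome) {
  sum(genome$conn) + length(genome$beta) + 1L
}

#' Active inputs of a genome
#'
#' Indices of inputs with at least one surviving connection — the variables
#' the evolved model actually consumes. Architecture evolution prunes
#' connections, so this set is how the method performs implicit variable
#' selection.
#'
#' @param genome a `network_genome`.
#' @return sorted integer vector of input indices.
#' @export
active_inputs <- function(genome) {
  which(rowSums(genome$conn) > 0)
}

#' Serialise / restore a genome as JSON
#'
#' Nodes are written with their sparse connection lists and parameters;
#' reading restores the genome bit-exactly (numbers are written at full
#' precision).
#'
#' @param genome a `network_genome`.
#' @param path file path.
#' @return `write_genome`: path invisibly; `read_genome`: a
#'   `network_genome`.
#' @export
write_genome <- function(genome, path) {
  nodes <- lapply(seq_len(ncol(genome$W)), function(j) {
    idx <- which(genome$conn[, j])
    nd <- list(inputs = idx, params = genome$W[idx, j], beta = genome$beta[j])
    if (genome$basis == "SU") nd$bias <- genome$bias[j]
    if (genome$basis == "RBF") nd$radius <- genome$radius[j]
    nd
  })
  doc <- list(basis = genome$basis, n_inputs = genome$n_inputs,
              max_hidden = genome$max_hidden, beta0 = genome$beta0,
              nodes = nodes)
  # 17 significant digits round-trips IEEE doubles bit-exactly
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  d <- doc$n_inputs
  M <- length(doc$nodes)
  W <- matrix(0, d, M); conn <- matrix(FALSE, d, M)
  beta <- numeric(M); bias <- numeric(M); radius <- numeric(M)
  for (j in seq_len(M)) {
    nd <- doc$nodes[[j]]
    idx <- unlist(nd$inputs)
    W[idx, j] <- unlist(nd$params)
    conn[idx, j] <- TRUE
    beta[j] <- nd$beta
    if (!is.null(nd$bias)) bias[j] <- nd$bias
    if (!is.null(nd$radius)) radius[j] <- nd$radius
  }
  network_genome(doc$basis, W, conn, beta, doc$beta0,
                 bias = if (doc$basis == "SU") bias else NULL,
                 radius = if (doc$basis == "RBF") radius else NULL,
                 max_hidden = doc$max_hidden)
}

#' Write predictions as CSV
#'
#' @param genome a `network_genome`.
#' @param x scaled input matrix.
#' @param path file path.
#' @param ids optional row identifiers.
#' @return the path, invisibly; file has columns id, probability, label.
#' @export
write_predictions <- function(genome, x, path, ids = seq_len(nrow(x))) {
  p <- forward(genome, x)
  utils::write.csv(data.frame(id = ids, probability = p,
                              label = as.integer(p >= 0.5)),
                   path, row.names = FALSE)
  invisible(path)
}
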