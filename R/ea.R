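# Evolutionary-programming trainer: mutation-only search over both the
# architecture (hidden nodes, sparse connections) and the numeric parameters
# of a network genome.

#' Evolutionary-algorithm configuration
#'
#' Defaults follow the reference training regime: 600 generations, hidden
#' nodes bounded by 1 (minimum), 2 (initialisation maximum) and 4 (overall
#' maximum), structural add/delete counts drawn uniformly from \{1, 2\},
#' input-layer initialisation in \[-1, 1\] for product units and \[-5, 5\]
#' otherwise, output-layer initialisation in \[-5, 5\]. Population size and
#' the mutation-scale schedule are free parameters of this implementation
#' (mutation only, no crossover; 10% elitism).
#'
#' @param basis `"PU"`, `"SU"` or `"RBF"`.
#' @param pop_size population size (default 500).
#' @param generations generation budget (default 600).
#' @param min_hidden,init_max_hidden,max_hidden hidden-node bounds
#'   (defaults 1, 2, 4).
#' @param struct_count_range inclusive integer range for how many nodes or
#'   connections one structural mutation adds/deletes (default `c(1, 2)`).
#' @param input_init_range input-layer initialisation range; defaults to
#'   \[-1, 1\] for PU, \[-5, 5\] otherwise.
#' @param output_init_range output-layer initialisation range (default
#'   \[-5, 5\]).
#' @param elite_frac fraction copied unchanged each generation (default 0.1).
#' @param mut_sd_init initial parametric-mutation standard deviation
#'   (default 0.5); decays linearly to `mut_sd_final_frac` of itself over the
#'   generation budget.
#' @param mut_sd_final_frac final fraction of the initial scale (default 0.1).
#' @param radius_floor lower bound for initial Gaussian radii (default 1e-3).
#' @param seed integer RNG seed.
#' @return an `ea_config` object.
#' @export
ea_config <- function(basis, pop_size = 500L, generations = 600L,
                      min_hidden = 1L, init_max_hidden = 2L, max_hidden = 4L,
                      struct_count_range = c(1L, 2L),
                      input_init_range = if (basis == "PU") c(-1, 1) else c(-5, 5),
                      output_init_range = c(-5, 5),
                      elite_frac = 0.1, mut_sd_init = 0.5,
                      mut_sd_final_frac = 0.1, radius_floor = 1e-3,
                      seed = 1L) {
  basis <- match.arg(basis, c("PU", "SU", "RBF"))
  stopifnot(pop_size >= 2, generations >= 1,
            1 <= min_hidden, min_hidden <= init_max_hidden,
            init_max_hidden <= max_hidden,
            struct_count_range[1] >= 1,
            struct_count_range[1] <= struct_count_range[2],
            input_init_range[1] < input_init_range[2],
            output_init_range[1] < output_init_range[2],
            elite_frac > 0, elite_frac < 1, mut_sd_init >= 0,
            radius_floor > 0)
  structure(list(basis = basis, pop_size = as.integer(pop_size),
                 generations = as.integer(generations),
                 min_hidden = as.integer(min_hidden),
                 init_max_hidden = as.integer(init_max_hidden),
                 max_hidden = as.integer(max_hidden),
                 struct_count_range = as.integer(struct_count_range),
                 input_init_range = input_init_range,
                 output_init_range = output_init_range,
                 elite_frac = elite_frac, mut_sd_init = mut_sd_init,
                 mut_sd_final_frac = mut_sd_final_frac,
                 radius_floor = radius_floor, seed = as.integer(seed)),
            class = "ea_config")
}

#' @export
print.ea_config <- function(x, ...) {
  cat(sprintf("ea_config: %s basis, population %d, %d generations\n",
              x$basis, x$pop_size, x$generations))
  cat(sprintf("  hidden nodes [%d, %d] (init max %d); elitism %.0f%%\n",
              x$min_hidden, x$max_hidden, x$init_max_hidden,
              100 * x$elite_frac))
  invisible(x)
}

#' Read / write an EA configuration as YAML
#' @param config an `ea_config`.
#' @param path file path.
#' @return `write_ea_config`: path invisibly; `read_ea_config`: `ea_config`.
#' @export
write_ea_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_ea_config
#' @export
read_ea_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(ea_config, x)
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

# One random hidden node: non-empty input subset, parameters from the init
# ranges. Returns list(idx, w, beta, bias, radius).
random_node <- function(config, n_inputs) {
  k <- sample.int(n_inputs, 1L)
  idx <- sort(sample.int(n_inputs, k))
  list(idx = idx,
       w = runif_range(k, config$input_init_range),
       beta = runif_range(1L, config$output_init_range),
       bias = runif_range(1L, config$input_init_range),
       radius = max(abs(runif_range(1L, config$input_init_range)),
                    config$radius_floor))
}

assemble_genome <- function(config, n_inputs, nodes, beta0) {
  M <- length(nodes)
  W <- matrix(0, n_inputs, M); conn <- matrix(FALSE, n_inputs, M)
  beta <- numeric(M); bias <- numeric(M); radius <- numeric(M)
  for (j in seq_len(M)) {
    nd <- nodes[[j]]
    W[nd$idx, j] <- nd$w; conn[nd$idx, j] <- TRUE
    beta[j] <- nd$beta; bias[j] <- nd$bias; radius[j] <- nd$radius
  }
  network_genome(config$basis, W, conn, beta, beta0,
                 bias = if (config$basis == "SU") bias else NULL,
                 radius = if (config$basis == "RBF") radius else NULL,
                 max_hidden = config$max_hidden)
}

#' Initialise a population of network genomes
#'
#' Hidden-node counts uniform between the minimum and the initialisation
#' maximum (1 and 2 by default); each node connects to a uniformly sized,
#' uniformly chosen non-empty input subset; parameters uniform in the
#' basis-specific ranges; radii the absolute value of a range draw floored at
#' `radius_floor`. Deterministic given the RNG state.
#'
#' @param config an `ea_config`.
#' @param n_inputs input dimension.
#' @return list of `pop_size` genomes.
#' @export
init_population <- function(config, n_inputs) {
  lapply(seq_len(config$pop_size), function(i) {
    M <- sample(config$min_hidden:config$init_max_hidden, 1L)
    nodes <- lapply(seq_len(M), function(j) random_node(config, n_inputs))
    assemble_genome(config, n_inputs, nodes,
                    runif_range(1L, config$output_init_range))
  })
}

#' Fitness of a genome on a scaled training set
#'
#' `fitness = 1 / (1 + E)` with `E` the mean binary cross-entropy of the
#' forward probabilities against the 0/1 outcomes; probabilities are clamped
#' to \[1e-12, 1 - 1e-12\] before the logarithm. Bounded in (0, 1\],
#' strictly decreasing in the error.
#'
#' @param genome a `network_genome`.
#' @param x scaled feature matrix (per the genome's basis family).
#' @param y 0/1 outcome vector.
#' @param pre optional precomputed input transforms (internal fast path).
#' @return fitness in (0, 1].
#' @export
fitness <- function(genome, x, y, pre = NULL) {
  p <- forward(genome, x, pre = pre)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  e <- -mean(y * log(p) + (1 - y) * log(1 - p))
  1 / (1 + e)
}

# -- structural operators ----------------------------------------------------

genome_nodes <- function(genome) {
  lapply(seq_len(ncol(genome$W)), function(j) {
    idx <- which(genome$conn[, j])
    list(idx = idx, w = genome$W[idx, j], beta = genome$beta[j],
         bias = if (length(genome$bias)) genome$bias[j] else 0,
         radius = if (length(genome$radius)) genome$radius[j] else 1)
  })
}

#' Structural mutation
#'
#' Applies one uniformly chosen structural operator — add nodes, delete
#' nodes, add connections, delete connections — with a count drawn uniformly
#' from the configured range (\{1, 2\} by default). Infeasible steps are
#' truncated rather than rejected: node counts are clamped to
#' \[min_hidden, max_hidden\], a deletion that would leave a node with no
#' input connection retains that connection, and adding to a saturated
#' genome is a no-op. The result always satisfies the genome invariants.
#'
#' @param genome a `network_genome`.
#' @param config an `ea_config`.
#' @return mutated `network_genome`.
#' @export
structural_mutation <- function(genome, config) {
  op <- sample(c("add_node", "del_node", "add_conn", "del_conn"), 1L)
  count <- sample(config$struct_count_range[1]:config$struct_count_range[2], 1L)
  nodes <- genome_nodes(genome)
  d <- genome$n_inputs
  for (i in seq_len(count)) {
    if (op == "add_node") {
      if (length(nodes) < config$max_hidden)
        nodes[[length(nodes) + 1L]] <- random_node(config, d)
    } else if (op == "del_node") {
      if (length(nodes) > config$min_hidden)
        nodes[[sample.int(length(nodes), 1L)]] <- NULL
    } else if (op == "add_conn") {
      free <- which(vapply(nodes, function(nd) length(nd$idx) < d, logical(1)))
      if (length(free)) {
        j <- free[sample.int(length(free), 1L)]
        cand <- setdiff(seq_len(d), nodes[[j]]$idx)
        new <- cand[sample.int(length(cand), 1L)]
        ord <- order(c(nodes[[j]]$idx, new))
        nodes[[j]]$idx <- c(nodes[[j]]$idx, new)[ord]
        nodes[[j]]$w <- c(nodes[[j]]$w,
                          runif_range(1L, config$input_init_range))[ord]
      }
    } else {
      # delete a connection, but never strand a node on zero connections
      rich <- which(vapply(nodes, function(nd) length(nd$idx) > 1, logical(1)))
      if (length(rich)) {
        j <- rich[sample.int(length(rich), 1L)]
        k <- sample.int(length(nodes[[j]]$idx), 1L)
        nodes[[j]]$idx <- nodes[[j]]$idx[-k]
        nodes[[j]]$w <- nodes[[j]]$w[-k]
      }
    }
  }
  assemble_genome(config, d, nodes, genome$beta0)
}

# Linearly decaying mutation scale: from mut_sd_init at generation 1 to
# mut_sd_final_frac * mut_sd_init at the last generation.
mutation_scale <- function(config, generation) {
  if (config$generations == 1L) return(config$mut_sd_init)
  frac <- (generation - 1) / (config$generations - 1)
  config$mut_sd_init * (1 - (1 - config$mut_sd_final_frac) * frac)
}

#' Parametric mutation
#'
#' Gaussian perturbation of every numeric parameter (connected input-layer
#' weights, node biases, radii, output weights and bias) with standard
#' deviation [mutation_scale()] at the given generation. Radii stay positive
#' by reflection (absolute value).
#'
#' @param genome a `network_genome`.
#' @param config an `ea_config`.
#' @param generation current generation (drives the decay schedule).
#' @return mutated `network_genome`.
#' @export
parametric_mutation <- function(genome, config, generation = 1L) {
  s <- mutation_scale(config, generation)
  if (s == 0) return(genome)
  g <- genome
  nconn <- sum(g$conn)
  g$W[g$conn] <- g$W[g$conn] + stats::rnorm(nconn, 0, s)
  if (g$basis == "SU") g$bias <- g$bias + stats::rnorm(length(g$bias), 0, s)
  if (g$basis == "RBF")
    g$radius <- pmax(abs(g$radius + stats::rnorm(length(g$radius), 0, s)),
                     1e-8)
  g$beta <- g$beta + stats::rnorm(length(g$beta), 0, s)
  g$beta0 <- g$beta0 + stats::rnorm(1L, 0, s)
  g
}

#' Evolve a network genome on a scaled training set
#'
#' Evolutionary-programming loop: evaluate fitness; copy the elite fraction
#' unchanged into the next generation (displacing the worst individuals);
#' refill the population from the best non-displaced ranks, applying
#' parametric mutation to the better half of that remainder and structural
#' mutation to the rest; repeat for the full generation budget (no early
#' stopping). Elitism makes the best-fitness sequence non-decreasing.
#'
#' @param x scaled training feature matrix.
#' @param y 0/1 training outcomes.
#' @param config an `ea_config`; `config$seed` fixes the whole run.
#' @param trace_genomes also snapshot the per-generation best genome
#'   (default `FALSE`; the final best genome is always returned).
#' @return an `evolution_trace`: data frame `history` (generation, best and
#'   mean fitness), `best_genome`, `best_fitness`, `warnings`, and
#'   `snapshots` when requested.
#' @export
evolve <- function(x, y, config, trace_genomes = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("training set is empty")
  if (nrow(x) != length(y)) stop("x and y disagree on the number of rows")
  warnings <- character(0)
  if (length(unique(y)) < 2L)
    warnings <- "training outcomes contain a single class"
  pre <- precompute_inputs(config$basis, x)
  with_seed(config$seed, {
    pop <- init_population(config, ncol(x))
    fit <- vapply(pop, fitness, numeric(1), x = x, y = y, pre = pre)
    n_elite <- max(1L, as.integer(round(config$elite_frac * config$pop_size)))
    hist_best <- numeric(config$generations)
    hist_mean <- numeric(config$generations)
    snaps <- if (trace_genomes) vector("list", config$generations)
    for (gen in seq_len(config$generations)) {
      ord <- order(fit, decreasing = TRUE)
      pop <- pop[ord]; fit <- fit[ord]
      hist_best[gen] <- fit[1]; hist_mean[gen] <- mean(fit)
      if (trace_genomes) snaps[[gen]] <- pop[[1]]
      if (gen == config$generations) break
      n_rest <- config$pop_size - n_elite
      n_param <- n_rest %/% 2L
      parents <- pop[seq_len(n_rest)]
      children <- vector("list", n_rest)
      for (i in seq_len(n_rest)) {
        children[[i]] <- if (i <= n_param)
          parametric_mutation(parents[[i]], config, gen)
        else structural_mutation(parents[[i]], config)
      }
      child_fit <- vapply(children, fitness, numeric(1), x = x, y = y,
                          pre = pre)
      pop <- c(pop[seq_len(n_elite)], children)
      fit <- c(fit[seq_len(n_elite)], child_fit)
    }
    ord <- order(fit, decreasing = TRUE)
    structure(list(
      history = data.frame(generation = seq_len(config$generations),
                           best_fitness = hist_best,
                           mean_fitness = hist_mean),
      best_genome = pop[[ord[1]]], best_fitness = fit[ord[1]],
      config = config, warnings = warnings,
      snapshots = if (trace_genomes) snaps), class = "evolution_trace")
  })
}

#' @export
print.evolution_trace <- function(x, ...) {
  cat(sprintf("evolution_trace: %s basis, %d generations, best fitness %.4f\n",
              x$config$basis, nrow(x$history), x$best_fitness))
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

#' Write an evolution trace as CSV
#' @param trace an `evolution_trace`.
#' @param path file path.
#' @return the path, invisibly (columns generation, best_fitness,
#'   mean_fitness).
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace$history, path, row.names = FALSE)
  invisible(path)
}

#' Grid search over EA hyperparameters by k-fold cross-validation
#'
#' Optional tuning driver: every row of `grid` overrides fields of a base
#' configuration; each candidate is scored by k-fold cross-validated correct
#' classification rate on the training cohort (scaler refitted inside each
#' fold).
#'
#' @param cohort a training `cohort_table`.
#' @param base_config an `ea_config`.
#' @param grid data frame of configuration overrides, one candidate per row.
#' @param folds number of folds (default 5).
#' @param seed seed for the fold assignment.
#' @return list with `results` (grid plus mean CV accuracy) and
#'   `best_config`.
#' @export
cv_grid_search <- function(cohort, base_config, grid, folds = 5L, seed = 1L) {
  n <- nrow(cohort$features)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  score <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    cfg <- base_config
    for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][gi]
    cfg <- do.call(ea_config, unclass(cfg))
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f); te <- which(fold_id == f)
      sc <- fit_scaler(cohort$features[tr, , drop = FALSE], cfg$basis)
      xt <- apply_scaler(sc, cohort$features[tr, , drop = FALSE])
      xv <- apply_scaler(sc, cohort$features[te, , drop = FALSE])
      trace <- evolve(xt, cohort$outcome[tr], cfg)
      pred <- as.integer(forward(trace$best_genome, xv) >= 0.5)
      acc[f] <- mean(pred == cohort$outcome[te])
    }
    score[gi] <- mean(acc)
  }
  best <- which.max(score)
  cfg <- base_config
  for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][best]
  list(results = cbind(grid, cv_ccr = score),
       best_config = do.call(ea_config, unclass(cfg)))
}
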