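test_that("initial populations respect init ranges and node bounds", {
  cfg <- ea_config("PU", pop_size = 60, generations = 10, seed = 1)
  pop <- with_seed(5, init_population(cfg, 7))
  expect_length(pop, 60)
  for (g in pop) {
    expect_lte(ncol(g$W), 2)  # init max
    expect_gte(ncol(g$W), 1)
    expect_true(all(g$W[g$conn] >= -1 & g$W[g$conn] <= 1))
    expect_true(all(g$beta >= -5 & g$beta <= 5))
  }
  rcfg <- ea_config("RBF", pop_size = 30, generations = 10)
  rpop <- with_seed(5, init_population(rcfg, 7))
  for (g in rpop) expect_true(all(g$radius >= rcfg$radius_floor))
  expect_identical(with_seed(5, init_population(cfg, 7)),
                   with_seed(5, init_population(cfg, 7)))
})

test_that("fitness follows 1/(1 + cross-entropy) closed forms", {
  # null network: p = 0.5 everywhere, E = ln 2
  g <- network_genome("SU", W = matrix(0, 2, 1), conn = matrix(TRUE, 2, 1),
                      beta = 0, beta0 = 0, bias = 0)
  x <- random_scaled_inputs("SU", 16, 2)
  y <- rep(c(0L, 1L), 8)
  expect_equal(fitness(g, x, y), 1 / (1 + log(2)), tolerance = 1e-12)
  # confident correct predictions push fitness towards 1
  sep <- network_genome("SU", W = matrix(c(60, 0), 2, 1),
                        conn = matrix(c(TRUE, FALSE), 2, 1),
                        beta = 1000, beta0 = -500, bias = -30)
  xs <- cbind(a = rep(c(0.1, 0.9), 8), b = 0.5)
  ys <- rep(c(0L, 1L), 8)
  expect_gt(fitness(sep, xs, ys), 0.999)
})

test_that("fitness matches a hand-computed cross-entropy on a tiny set", {
  set.seed(9)
  g <- random_test_genome("RBF", 3)
  x <- random_scaled_inputs("RBF", 4, 3)
  y <- c(1L, 0L, 1L, 1L)
  p <- vapply(1:4, function(r) oracle_forward(g, x[r, ]), numeric(1))
  e <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(fitness(g, x, y), 1 / (1 + e), tolerance = 1e-12)
})

test_that("structural mutation keeps genomes valid and within bounds", {
  cfg <- ea_config("RBF", pop_size = 10, generations = 10, seed = 1)
  set.seed(77)
  for (rep in 1:200) {
    g <- random_test_genome("RBF", 4, max_nodes = 4L)
    m <- structural_mutation(g, cfg)
    expect_silent(validate_genome(m))
    expect_gte(ncol(m$W), 1)
    expect_lte(ncol(m$W), 4)
    expect_true(all(colSums(m$conn) >= 1))  # never a dangling node
  }
})

test_that("structural mutation clamps at the architecture bounds", {
  cfg <- ea_config("SU", pop_size = 10, generations = 10)
  # saturated genome: 4 nodes, all inputs connected -> only deletions change it
  full <- network_genome("SU", W = matrix(1, 3, 4), conn = matrix(TRUE, 3, 4),
                         beta = rep(1, 4), beta0 = 0, bias = rep(0, 4),
                         max_hidden = 4L)
  one <- network_genome("SU", W = matrix(1, 3, 1),
                        conn = matrix(c(TRUE, FALSE, FALSE), 3, 1),
                        beta = 1, beta0 = 0, bias = 0)
  set.seed(3)
  for (rep in 1:100) {
    expect_lte(ncol(structural_mutation(full, cfg)$W), 4)
    m1 <- structural_mutation(one, cfg)
    expect_gte(ncol(m1$W), 1)           # delete-node clamps at the minimum
    expect_gte(sum(m1$conn[, 1]), 1)    # lone connection is retained
  }
})

test_that("parametric mutation is the identity at scale zero and keeps radii positive", {
  cfg0 <- ea_config("RBF", pop_size = 10, generations = 10, mut_sd_init = 0)
  set.seed(2)
  g <- random_test_genome("RBF", 4)
  expect_identical(parametric_mutation(g, cfg0, 1), g)
  cfg <- ea_config("RBF", pop_size = 10, generations = 10, mut_sd_init = 2)
  m <- g
  for (i in 1:200) {
    m <- parametric_mutation(m, cfg, 1)
    expect_true(all(m$radius > 0))
  }
})

test_that("parametric perturbations follow the configured Gaussian scale", {
  cfg <- ea_config("SU", pop_size = 10, generations = 100, mut_sd_init = 0.5)
  d <- 50
  g <- network_genome("SU", W = matrix(0, d, 1), conn = matrix(TRUE, d, 1),
                      beta = 0, beta0 = 0, bias = 0)
  set.seed(11)
  draws <- unlist(lapply(1:2000, function(i) {
    parametric_mutation(g, cfg, 1)$W[, 1]
  }))
  expect_length(draws, 1e5)
  expect_equal(sd(draws), 0.5, tolerance = 0.05 * 0.5 / 2)  # well within 5%
  expect_equal(mean(draws), 0, tolerance = 0.01)
  # decay schedule: final scale is 10% of the initial one
  expect_equal(evonnet:::mutation_scale(cfg, 100), 0.05, tolerance = 1e-12)
  expect_equal(evonnet:::mutation_scale(cfg, 1), 0.5, tolerance = 1e-12)
})

test_that("evolution is elitist, bounded, reproducible and beats initialisation", {
  toy <- make_toy(21, n = 40)
  sc <- fit_scaler(toy$x, "SU")
  xs <- apply_scaler(sc, toy$x)
  cfg <- ea_config("SU", pop_size = 40, generations = 40, seed = 7)
  tr <- evolve(xs, toy$y, cfg, trace_genomes = TRUE)
  expect_true(all(diff(tr$history$best_fitness) >= 0))
  expect_gte(tr$best_fitness, tr$history$best_fitness[1])
  for (g in tr$snapshots) {
    expect_lte(ncol(g$W), 4)
    expect_gte(ncol(g$W), 1)
  }
  tr2 <- evolve(xs, toy$y, cfg)
  expect_identical(tr$history, tr2$history)
  expect_identical(tr$best_genome, tr2$best_genome)
  tr3 <- evolve(xs, toy$y, ea_config("SU", pop_size = 40, generations = 40,
                                     seed = 8))
  expect_false(identical(tr$history$best_fitness, tr3$history$best_fitness))
})

test_that("single-class training data runs but is flagged", {
  x <- random_scaled_inputs("SU", 10, 2)
  tr <- evolve(x, rep(1L, 10), ea_config("SU", pop_size = 10,
                                         generations = 3, seed = 1))
  expect_match(tr$warnings, "single class")
  expect_error(evolve(x[0, , drop = FALSE], integer(0),
                      ea_config("SU", pop_size = 10, generations = 3)),
               "empty")
})

test_that("trace CSV and EA config YAML round-trip", {
  toy <- make_toy(5, n = 20)
  xs <- apply_scaler(fit_scaler(toy$x, "RBF"), toy$x)
  cfg <- ea_config("RBF", pop_size = 12, generations = 5, seed = 2)
  tr <- evolve(xs, toy$y, cfg)
  tpath <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, tpath)
  expect_equal(utils::read.csv(tpath), tr$history, tolerance = 1e-12)
  ypath <- withr::local_tempfile(fileext = ".yaml")
  write_ea_config(cfg, ypath)
  expect_equal(read_ea_config(ypath), cfg)
})

test_that("the cross-validated grid search ranks configurations", {
  coh <- toy_cohort(80, seed = 31)
  base <- ea_config("SU", pop_size = 10, generations = 4, seed = 1)
  grid <- data.frame(generations = c(2L, 4L))
  res <- cv_grid_search(coh, base, grid, folds = 2, seed = 3)
  expect_equal(nrow(res$results), 2)
  expect_true(all(res$results$cv_ccr >= 0 & res$results$cv_ccr <= 1))
  expect_s3_class(res$best_config, "ea_config")
})
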