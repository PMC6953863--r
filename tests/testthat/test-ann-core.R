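test_that("basis functions hit their closed-form anchor points", {
  d <- 3
  pu <- network_genome("PU", W = matrix(0, d, 1), conn = matrix(TRUE, d, 1),
                       beta = 1, beta0 = 0)
  expect_equal(basis_output(pu, c(1.5, 1.2, 1.9)), 1)  # zero exponents
  su <- network_genome("SU", W = matrix(0, d, 1), conn = matrix(TRUE, d, 1),
                       beta = 1, beta0 = 0, bias = 0)
  expect_equal(basis_output(su, c(0.3, 0.5, 0.7)), 0.5)  # logistic(0)
  ctr <- c(-0.2, 0.4, 0.9)
  rb <- network_genome("RBF", W = matrix(ctr, d, 1),
                       conn = matrix(TRUE, d, 1), beta = 1, beta0 = 0,
                       radius = 0.7)
  expect_equal(basis_output(rb, ctr), 1)  # exp(0) at the centre
})

test_that("null networks output probability one half everywhere", {
  g <- network_genome("SU", W = matrix(1, 4, 2), conn = matrix(TRUE, 4, 2),
                      beta = c(0, 0), beta0 = 0, bias = c(1, -1))
  x <- random_scaled_inputs("SU", 20, 4)
  expect_equal(forward(g, x), rep(0.5, 20))
})

test_that("a single on-centre Gaussian node with output weight 8.957 saturates", {
  g <- network_genome("RBF", W = matrix(0, 6, 1), conn = matrix(TRUE, 6, 1),
                      beta = 8.957, beta0 = 0, radius = 1)
  expect_equal(forward(g, rep(0, 6)), plogis(8.957), tolerance = 1e-12)
  expect_gt(forward(g, rep(0, 6)), 0.9998)
})

test_that("forward pass matches the brute-force oracle on random genomes", {
  set.seed(17)
  worst <- 0
  for (basis in c("PU", "SU", "RBF")) {
    for (rep in 1:350) {
      d <- sample(2:4, 1)
      g <- random_test_genome(basis, d)
      x <- random_scaled_inputs(basis, 3, d)
      got <- forward(g, x)
      want <- vapply(seq_len(nrow(x)), function(r) oracle_forward(g, x[r, ]),
                     numeric(1))
      worst <- max(worst, max(abs(got - want)))
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("connection counting follows the links-plus-output-bias convention", {
  rb <- network_genome("RBF", W = matrix(0.1, 17, 1),
                       conn = matrix(c(rep(TRUE, 6), rep(FALSE, 11)), 17, 1),
                       beta = 1, beta0 = 0, radius = 1)
  expect_equal(count_connections(rb), 8L)  # 6 links + 1 output weight + bias
  su <- network_genome("SU", W = matrix(1, 5, 2),
                       conn = matrix(c(rep(TRUE, 3), rep(FALSE, 2)) , 5, 2),
                       beta = c(1, 1), beta0 = 0, bias = c(0, 0))
  expect_equal(count_connections(su), 3L + 3L + 2L + 1L)  # 11
})

test_that("active inputs track surviving connections", {
  conn <- matrix(FALSE, 17, 2)
  conn[c(3, 4, 8), 1] <- TRUE
  conn[c(11, 13, 16), 2] <- TRUE
  g <- network_genome("SU", W = matrix(1, 17, 2) * conn, conn = conn,
                      beta = c(1, 1), beta0 = 0, bias = c(0, 0))
  expect_equal(active_inputs(g), c(3L, 4L, 8L, 11L, 13L, 16L))
  full <- network_genome("SU", W = matrix(1, 17, 1),
                         conn = matrix(TRUE, 17, 1), beta = 1, beta0 = 0,
                         bias = 0)
  expect_equal(active_inputs(full), 1:17)
  # removing every connection to an input removes it from the set
  conn2 <- conn; conn2[4, ] <- FALSE
  g2 <- network_genome("SU", W = matrix(1, 17, 2) * conn2, conn = conn2,
                       beta = c(1, 1), beta0 = 0, bias = c(0, 0))
  expect_false(4L %in% active_inputs(g2))
})

test_that("product units are scale-sensitive by exactly 2^w", {
  set.seed(4)
  w <- runif(3, -1.5, 1.5)
  g <- network_genome("PU", W = matrix(w, 3, 1), conn = matrix(TRUE, 3, 1),
                      beta = 1, beta0 = 0)
  x <- c(1.2, 1.5, 1.8)
  for (i in 1:3) {
    x2 <- x; x2[i] <- 2 * x2[i]
    expect_equal(basis_output(g, x2), basis_output(g, x) * 2^w[i],
                 tolerance = 1e-12)
  }
})

test_that("basis outputs respect their analytic ranges", {
  set.seed(23)
  for (rep in 1:50) {
    d <- sample(2:5, 1)
    su <- random_test_genome("SU", d)
    rb <- random_test_genome("RBF", d)
    bs <- basis_output(su, random_scaled_inputs("SU", 5, d))
    br <- basis_output(rb, random_scaled_inputs("RBF", 5, d))
    expect_true(all(bs > 0 & bs < 1))
    expect_true(all(br > 0 & br <= 1))
  }
})

test_that("invalid genomes and inputs are rejected", {
  expect_error(network_genome("SU", W = matrix(1, 3, 1),
                              conn = matrix(FALSE, 3, 1), beta = 1,
                              beta0 = 0, bias = 0), "connection")
  expect_error(network_genome("RBF", W = matrix(1, 3, 1),
                              conn = matrix(TRUE, 3, 1), beta = 1,
                              beta0 = 0, radius = 0), "radius|positive")
  expect_error(network_genome("SU", W = matrix(1, 2, 5),
                              conn = matrix(TRUE, 2, 5), beta = rep(1, 5),
                              beta0 = 0, bias = rep(0, 5)), "outside")
  g <- network_genome("PU", W = matrix(1, 2, 1), conn = matrix(TRUE, 2, 1),
                      beta = 1, beta0 = 0)
  expect_error(forward(g, c(1, 2, 3)), "dimension")
  expect_error(forward(g, c(0.5, -1)), "positive")
})

test_that("genome JSON serialisation is bit-exact", {
  set.seed(31)
  for (basis in c("PU", "SU", "RBF")) {
    g <- random_test_genome(basis, 5, max_nodes = 3L)
    path <- withr::local_tempfile(fileext = ".json")
    write_genome(g, path)
    back <- read_genome(path)
    expect_identical(back$basis, g$basis)
    expect_equal(back$W, g$W, tolerance = 0)
    expect_identical(back$conn, g$conn)
    expect_equal(back$beta, g$beta, tolerance = 0)
    expect_equal(back$beta0, g$beta0, tolerance = 0)
    x <- random_scaled_inputs(basis, 8, 5)
    expect_identical(forward(back, x), forward(g, x))
  }
})

test_that("predictions export probabilities and hard labels", {
  g <- network_genome("SU", W = matrix(2, 2, 1), conn = matrix(TRUE, 2, 1),
                      beta = 4, beta0 = -2, bias = 0)
  x <- random_scaled_inputs("SU", 10, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictions(g, x, path)
  out <- utils::read.csv(path)
  expect_equal(out$probability, forward(g, x), tolerance = 1e-12)
  expect_equal(out$label, as.integer(out$probability >= 0.5))
  expect_equal(predict(g, x, type = "label"),
               as.integer(forward(g, x) >= 0.5))
})
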