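cv <- function(leaf, p1, p2, p3, p4, p5)
  c(n_leaf = leaf, n_pod1 = p1, n_pod2 = p2, n_pod3 = p3, n_pod4 = p4,
    n_pod5 = p5)

test_that("four-view aggregation is a componentwise sum", {
  views <- rbind(cv(3, 0, 1, 0, 0, 0), cv(4, 0, 2, 1, 0, 0),
                 cv(0, 1, 3, 0, 0, 1), cv(2, 0, 4, 2, 1, 0))
  tot <- aggregate_views(views)
  expect_equal(unname(tot["n_pod2"]), 10)
  expect_equal(unname(tot["n_leaf"]), 9)
  expect_equal(aggregate_views(views[c(3, 1, 4, 2), ]), tot)
  expect_equal(aggregate_views(matrix(0, 4, 6,
                                      dimnames = list(NULL, names(tot)))),
               setNames(rep(0, 6), names(tot)))
  expect_error(aggregate_views(views[1:3, ]), "exactly 4")
})

test_that("seed number weighs each pod type by its seeds", {
  expect_equal(seed_number(cv(10, 2, 3, 4, 1, 0)), 2 + 6 + 12 + 4)
  expect_equal(seed_number(cv(0, 0, 0, 0, 0, 0)), 0)
})

test_that("a single training pair predicts its own target everywhere", {
  m <- grnn_fit(matrix(c(1, 2, 3), 1, 3), 7, sigma = 0.5)
  expect_equal(grnn_predict(m, matrix(c(0, 0, 0), 1, 3)), 7)
  expect_equal(grnn_predict(m, matrix(c(100, -5, 3), 1, 3)), 7)
})

test_that("duplicated training pairs leave predictions unchanged", {
  set.seed(83)
  X <- matrix(runif(9), 3, 3)
  y <- c(2, 5, 9)
  m1 <- grnn_fit(X, y, sigma = 0.7, standardize = FALSE)
  m2 <- grnn_fit(rbind(X, X), c(y, y), sigma = 0.7, standardize = FALSE)
  q <- matrix(runif(15), 5, 3)
  expect_equal(grnn_predict(m1, q), grnn_predict(m2, q), tolerance = 1e-12)
})

test_that("the kernel-weighted mean matches direct evaluation", {
  m <- grnn_fit(matrix(c(0, 2), 2, 1), c(0, 10), sigma = 1,
                standardize = FALSE)
  # symmetric kernels: midpoint predicts the midpoint target
  expect_equal(grnn_predict(m, matrix(1)), 5)
  want <- 10 * exp(-1.125) / (exp(-0.125) + exp(-1.125))
  expect_equal(grnn_predict(m, matrix(0.5)), want, tolerance = 1e-12)
})

test_that("bandwidth limits recover nearest neighbour and the global mean", {
  set.seed(89)
  X <- matrix(runif(30, 0, 10), 15, 2)
  y <- runif(15, 50, 150)
  m_small <- grnn_fit(X, y, sigma = 1e-6 * 10, standardize = FALSE)
  q <- X + matrix(runif(30, -0.01, 0.01), 15, 2)
  nn <- y[apply(as.matrix(dist(rbind(q, X)))[1:15, 16:30], 1, which.min)]
  expect_equal(grnn_predict(m_small, q), nn)
  m_big <- grnn_fit(X, y, sigma = 1e8, standardize = FALSE)
  expect_equal(grnn_predict(m_big, q), rep(mean(y), 15), tolerance = 1e-6)
  # predictions never leave the training target range
  set.seed(90)
  for (s in c(0.05, 0.5, 5)) {
    m <- grnn_fit(X, y, sigma = s, standardize = FALSE)
    p <- grnn_predict(m, matrix(runif(40, -5, 15), 20, 2))
    expect_true(all(p >= min(y) - 1e-9 & p <= max(y) + 1e-9))
  }
})

test_that("vectorized GRNN equals the literal loop transcription", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(3:12, 1); p <- sample(1:4, 1)
    X <- matrix(runif(n * p, -2, 2), n, p)
    y <- runif(n, -5, 5)
    sigma <- 10^runif(1, -0.5, 1)
    q <- matrix(runif(3 * p, -2, 2), 3, p)
    m <- grnn_fit(X, y, sigma = sigma, standardize = FALSE)
    expect_equal(grnn_predict(m, q), grnn_loop_oracle(X, y, q, sigma),
                 tolerance = 1e-10)
  }
})

test_that("automatic bandwidth beats an absurdly wide one on smooth data", {
  set.seed(103)
  X <- matrix(runif(60, 0, 4), 30, 2)
  y <- 3 * X[, 1] + 2 * X[, 2]
  m_auto <- grnn_fit(X, y, sigma = "auto")
  m_wide <- grnn_fit(X, y, sigma = 1e3)
  q <- matrix(runif(40, 0.5, 3.5), 20, 2)
  truth <- 3 * q[, 1] + 2 * q[, 2]
  err_auto <- mean((grnn_predict(m_auto, q) - truth)^2)
  err_wide <- mean((grnn_predict(m_wide, q) - truth)^2)
  expect_lt(err_auto, err_wide)
})

test_that("GRNN models persist to JSON and back", {
  set.seed(107)
  X <- matrix(runif(24), 8, 3)
  y <- runif(8, 10, 20)
  m <- grnn_fit(X, y, sigma = "auto")
  f <- tempfile(fileext = ".json")
  grnn_save(m, f)
  m2 <- grnn_load(f)
  q <- matrix(runif(9), 3, 3)
  expect_equal(grnn_predict(m2, q), grnn_predict(m, q), tolerance = 1e-12)
  unlink(f)
})

test_that("GRNN rejects empty or non-finite training data", {
  expect_error(grnn_fit(matrix(numeric(0), 0, 2), numeric(0)), "empty")
  expect_error(grnn_fit(matrix(1:4, 2, 2), c(1, NA)), "non-finite")
  expect_error(grnn_fit(matrix(1:4, 2, 2), c(1, 2), sigma = -1), "positive")
})

test_that("PLSR recovers an exact linear map through one latent component", {
  set.seed(109)
  counts <- data.frame(n_leaf = rpois(20, 40), n_pod1 = rpois(20, 5),
                       n_pod2 = rpois(20, 20), n_pod3 = rpois(20, 18),
                       n_pod4 = rpois(20, 6), n_pod5 = rpois(20, 2))
  y <- 3 * counts$n_pod3
  m <- plsr_fit(counts, y, ncomp = "auto")
  expect_equal(plsr_predict(m, counts), y, tolerance = 1e-6)
})

test_that("constant targets are reproduced by both baselines", {
  set.seed(113)
  X <- matrix(runif(40, 0, 10), 10, 4)
  y <- rep(12, 10)
  mp <- plsr_fit(X, y)
  expect_equal(plsr_predict(mp, X), y, tolerance = 1e-8)
  mb <- bpnn_fit(X, y, seed = 1)
  expect_equal(bpnn_predict(mb, X), y, tolerance = 0.05)
})

test_that("BPNN training is reproducible from its seed", {
  set.seed(127)
  X <- matrix(runif(60, 0, 5), 15, 4)
  y <- X %*% c(1, 2, 0, 1) + rnorm(15, 0, 0.1)
  m1 <- bpnn_fit(X, drop(y), seed = 99)
  m2 <- bpnn_fit(X, drop(y), seed = 99)
  q <- matrix(runif(20, 0, 5), 5, 4)
  expect_identical(bpnn_predict(m1, q), bpnn_predict(m2, q))
})

test_that("ACC is one minus the mean relative absolute deviation", {
  expect_equal(acc(c(5, 8, 13), c(5, 8, 13)), 1)
  expect_equal(acc(c(100, 200), c(90, 210)), 0.925)
  expect_equal(acc(c(50, 70), 2 * c(50, 70)), 0)
  expect_error(acc(c(10, 0), c(9, 1)), "positive")
  expect_error(acc(1:3, 1:2), "length")
})

test_that("run accuracies average arithmetically", {
  expect_equal(mean_run_accuracy(0.971), 0.971)
  expect_equal(mean_run_accuracy(c(0.9, 0.95, 1)), 0.95)
  expect_error(mean_run_accuracy(numeric(0)), "no runs")
})

test_that("yield accumulation weighs grains by pod type", {
  w <- seed_weights()
  counts <- cv(7, 2, 3, 4, 1, 0)
  expect_equal(yield_grams(counts, w, "per_type"), 4.834)
  expect_equal(yield_grams(counts, w, "uniform"), 24 * 0.203)
  expect_equal(yield_grams(cv(5, 0, 0, 0, 0, 0), w), 0)
  expect_error(yield_grams(cv(0, -1, 0, 0, 0, 0), w), "non-negative")
  expect_error(seed_weights(w = c(0.2, 0.2, 0.2, 0.2, -1)), "positive")
})

test_that("yield accumulation is linear and mode-consistent", {
  set.seed(131)
  w <- seed_weights()
  a <- cv(3, 1, 4, 2, 0, 1); b <- cv(9, 2, 0, 5, 3, 0)
  expect_equal(yield_grams(a + b, w), yield_grams(a, w) + yield_grams(b, w))
  expect_equal(yield_grams(3 * a, w), 3 * yield_grams(a, w))
  flat <- seed_weights(w = rep(0.203, 5), w_a = 0.203)
  for (x in list(a, b, a + b))
    expect_equal(yield_grams(x, flat, "per_type"),
                 yield_grams(x, flat, "uniform"), tolerance = 1e-12)
})
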