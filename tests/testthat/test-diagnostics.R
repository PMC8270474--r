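test_that("intercept-only Poisson GLM recovers the closed-form rate", {
  Y <- c(4, 6, 2); E <- c(5, 5, 2)
  fit <- fit_poisson_glm(Y, E, NULL)
  expect_equal(unname(exp(fit$coefficients[1])), sum(Y) / sum(E),
               tolerance = 1e-10)
})

test_that("GLM estimates recover simulated truth and match two oracles", {
  set.seed(11)
  n <- 500
  x <- rnorm(n)
  E <- runif(n, 2, 10)
  Y <- rpois(n, E * exp(0.5 + 0.3 * x))
  fit <- fit_poisson_glm(Y, E, cbind(x = x))
  expect_lt(abs(fit$coefficients[1] - 0.5), 3 * fit$se[1])
  expect_lt(abs(fit$coefficients[2] - 0.3), 3 * fit$se[2])

  # oracle 1: stats::glm IRLS
  ref <- glm(Y ~ x, family = poisson(), offset = log(E))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)

  # oracle 2: direct numerical maximization of the Poisson log-likelihood
  nll <- function(b) -sum(dpois(Y, E * exp(b[1] + b[2] * x), log = TRUE))
  opt <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(unname(fit$coefficients), opt$par, tolerance = 1e-5)
})

test_that("GLM input validation", {
  expect_error(fit_poisson_glm(c(1, 2), c(1, 0), NULL), "positive")
  expect_error(fit_poisson_glm(c(1, 2), c(1, 1), cbind(c(1, 2), c(2, 4))),
               "rank")
})

test_that("residual risk ratios behave and satisfy the score identity", {
  set.seed(2)
  n <- 60
  x <- rnorm(n)
  E <- runif(n, 2, 8)
  Y <- rpois(n, E * exp(0.2 + 0.4 * x))
  fit <- fit_poisson_glm(Y, E, cbind(x = x))
  rr <- residual_risk_ratio(Y, E, fit)
  expect_equal(rr$ratio, Y / fit$fitted)
  # intercept score equation: mu-weighted mean of ratios is 1
  expect_equal(sum(rr$ratio * rr$mu_hat) / sum(rr$mu_hat), 1,
               tolerance = 1e-9)
  expect_equal(residual_risk_ratio(fit$fitted, E, fit)$ratio, rep(1, n))
})

test_that("Moran's I hand examples evaluate exactly", {
  g22 <- make_lattice(2, 2)
  expect_equal(morans_i(c(1, -1, -1, 1), g22), -1)
  path4 <- make_lattice(1, 4)
  expect_equal(morans_i(c(1, 1, -1, -1), path4), 1 / 3)
  expect_error(morans_i(rep(1, 4), g22), "variance")
  expect_error(morans_i(1:2, build_adjacency(NULL, c("A", "B"))), "no edges")
})

test_that("Moran's I is affine-invariant and matches the dense oracle", {
  set.seed(9)
  for (rep in 1:25) {
    g <- random_graph()
    if (nrow(g$edges) == 0L) next
    y <- rnorm(g$n)
    i1 <- morans_i(y, g)
    expect_equal(i1, moran_oracle(y, g), tolerance = 1e-12)
    expect_equal(morans_i(-2.5 * y + 7, g), i1, tolerance = 1e-9)
  }
})

test_that("permutation test is deterministic given the seed and exact at the floor", {
  g <- make_lattice(5, 5)
  set.seed(30)
  # strongly clustered field: smooth gradient
  y <- rep(1:5, each = 5) + rnorm(25, 0, 0.1)
  r1 <- morans_i_permutation_test(y, g, 999, seed = 5)
  r2 <- morans_i_permutation_test(y, g, 999, seed = 5)
  expect_equal(r1$p_value, r2$p_value)
  expect_equal(r1$p_value, 1 / 1000)  # gradient beats every permutation
  expect_error(morans_i_permutation_test(y, g, 50, seed = 1), "99")
})

test_that("ICAR-correlated fields push permutation p-values below the null mean", {
  g <- make_lattice(8, 8)
  set.seed(77)
  ps <- replicate(25, {
    y <- simulate_structured_field(g, 1) + rnorm(g$n, 0, 0.3)
    morans_i_permutation_test(y, g, 199, seed = sample.int(1e6, 1))$p_value
  })
  expect_lt(mean(ps), 0.25)
})
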