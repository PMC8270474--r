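test_that("ICAR conditional is the neighbor mean with variance sigma2/degree", {
  g <- build_adjacency(rbind(c("A", "B"), c("A", "C")), c("A", "B", "C", "D"))
  cond <- icar_conditional(c(0, 1, 3, 0), g, 1, sigma2_eta = 2)
  expect_equal(cond$mean, 2)
  expect_equal(cond$variance, 1)
  cond_b <- icar_conditional(c(5, 0, 0, 0), g, 2, sigma2_eta = 3)
  expect_equal(cond_b$mean, 5)
  expect_equal(cond_b$variance, 3)
  expect_equal(icar_conditional(c(0, 0, 0, 0), g, 1, 1)$mean, 0)
  expect_error(icar_conditional(c(0, 0, 0, 0), g, 4, 1), "island")
})

test_that("ICAR quadratic form matches the pairwise-difference oracle", {
  g1 <- build_adjacency(rbind(c("A", "B")), c("A", "B"))
  expect_equal(icar_quadratic_form(c(0, 2), g1), 4)
  g <- make_lattice(4, 5)
  expect_equal(icar_quadratic_form(rep(3.7, g$n), g), 0)
  set.seed(6)
  for (rep in 1:20) {
    gg <- random_graph()
    eta <- rnorm(gg$n)
    brute <- 0
    for (e in seq_len(nrow(gg$edges))) {
      brute <- brute + (eta[gg$edges[e, 1]] - eta[gg$edges[e, 2]])^2
    }
    expect_equal(icar_quadratic_form(eta, gg), brute, tolerance = 1e-12)
  }
})

test_that("RW(1) conditional follows the three-case step function", {
  phi <- c(0.5, 0, 4, -1)
  interior <- rw1_conditional(phi, 3, 4, sigma2_phi = 2)
  expect_equal(interior$mean, -0.5)
  expect_equal(rw1_conditional(c(1, 0, 4, 9), 2, 4, 2)$mean, 2.5)
  expect_equal(interior$variance, 1)
  first <- rw1_conditional(phi, 1, 4, sigma2_phi = 2)
  expect_equal(first$mean, 0)
  expect_equal(first$variance, 2)
  last <- rw1_conditional(phi, 4, 4, sigma2_phi = 2)
  expect_equal(last$mean, 4)
  expect_equal(last$variance, 2)
  expect_error(rw1_conditional(0.3, 1, 1, 1), "2 periods")
})

test_that("precision full conditionals use the right shape, rate and rank", {
  a <- 0.1; b <- 0.01
  # iid, all-zero effects: Gamma(a + n/2, b)
  set.seed(1)
  d <- update_precision(rep(0, 20), "iid", prior = c(a, b), n_draws = 2e4)
  expect_equal(attr(d, "shape"), a + 10)
  expect_equal(attr(d, "rate"), b)
  expect_equal(mean(d), (a + 10) / b, tolerance = 0.02)
  # ICAR on a two-component graph: rank n - 2
  g <- build_adjacency(rbind(c("A", "B"), c("C", "D")), c("A", "B", "C", "D"))
  d2 <- update_precision(c(0, 1, 2, 2), "icar", graph = g, prior = c(a, b))
  expect_equal(attr(d2, "shape"), a + (4 - 2) / 2)
  expect_equal(attr(d2, "rate"), b + 0.5 * 1)
  # RW(1) with constant phi: q = 0, shape a + (T-1)/2
  d3 <- update_precision(rep(2, 5), "rw1", prior = c(a, b))
  expect_equal(attr(d3, "shape"), a + 2)
  expect_equal(attr(d3, "rate"), b)
})

test_that("split-chain R-hat separates mixed from unmixed chains", {
  set.seed(8)
  m <- cbind(rnorm(5000), rnorm(5000))
  expect_lt(gelman_rubin(m), 1.01)
  expect_gt(gelman_rubin(cbind(rnorm(500), rnorm(500, 10))), 5)
  same <- rnorm(100)
  expect_equal(gelman_rubin(cbind(same, same)), 1, tolerance = 1e-6)
  expect_error(gelman_rubin(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("null data (Y = E) concentrate alpha near zero", {
  g <- make_lattice(5, 5)
  ct <- dismap:::new_count_table(region_ids(g),
                                 Y = matrix(5L, 25, 1),
                                 E = matrix(5, 25, 1))
  fit <- quiet_fit(ct, NULL, g,
                   model_spec(n_chains = 2, n_iter = 3000, n_burn = 1000,
                              thin = 2, seed = 2))
  a <- param_draws(fit, "alpha")
  expect_lt(abs(mean(a)), 2 * sd(a))
})

test_that("retained eta and phi draws sum to zero (identifiability)", {
  sc <- simulation_scenario(nrows = 4, ncols = 5, n_periods = 3,
                            beta = NULL, total_cases = 1500, seed = 21)
  sim <- simulate_registry(sc)
  ct <- counts_from_truth(sim)
  fit <- suppressWarnings(
    fit_spatiotemporal(ct, NULL, sim$graph,
                       model_spec(n_chains = 2, n_iter = 2000, n_burn = 500,
                                  thin = 5, seed = 3)))
  eta_cols <- grep("^eta\\[", fit$parameters, value = TRUE)
  phi_cols <- grep("^phi\\[", fit$parameters, value = TRUE)
  for (ch in fit$chains) {
    expect_lt(max(abs(rowSums(ch[, eta_cols]))), 1e-9)
    expect_lt(max(abs(rowSums(ch[, phi_cols]))), 1e-9)
  }
})

test_that("spatial fit recovers a known covariate effect within 3 posterior SDs", {
  sc <- simulation_scenario(nrows = 8, ncols = 8, beta = c(sesi = -0.105),
                            total_cases = 3000, seed = 14)
  sim <- simulate_registry(sc)
  ct <- expected_counts(sim$cases, sim$populations, region_ids(sim$graph))
  fit <- quiet_fit(ct, sim$covariates[, c("region_id", "sesi")], sim$graph,
                   model_spec(n_chains = 2, n_iter = 6000, n_burn = 2000,
                              thin = 2, seed = 15))
  b <- param_draws(fit, "beta[sesi]")
  expect_lt(abs(mean(b) - (-0.105)), 3 * sd(b))
})

test_that("misaligned inputs and degenerate configs error cleanly", {
  g <- make_lattice(2, 2)
  ct <- dismap:::new_count_table(region_ids(g), matrix(1L, 4, 1),
                                 matrix(1, 4, 1))
  g2 <- make_lattice(2, 3)
  expect_error(fit_spatial(ct, NULL, g2), "aligned")
  expect_error(model_spec(n_iter = 100, n_burn = 100), "smaller")
  expect_error(model_spec(prior_tau_shape = -1), "positive")
  expect_error(model_spec(fix_tau = c(bogus = 1)), "fix_tau")
})
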