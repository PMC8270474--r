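test_that("lattice graphs have the expected shape", {
  g22 <- make_lattice(2, 2)
  expect_equal(nrow(g22$edges), 4L)
  expect_equal(unname(degrees(g22)), rep(2L, 4))
  path <- make_lattice(1, 5)
  expect_equal(unname(degrees(path)), c(1L, 2L, 2L, 2L, 1L))
  g <- make_lattice(8, 12)
  expect_equal(g$n, 96L)
  expect_equal(nrow(g$edges), 2L * 8L * 12L - 8L - 12L)  # 172
  expect_error(make_lattice(0, 3), ">= 1")
})

test_that("structured fields live on the sum-to-zero subspace", {
  g <- make_lattice(5, 5)
  expect_equal(simulate_structured_field(g, 0), rep(0, 25))
  f <- simulate_structured_field(g, 1.5, seed = 4)
  expect_lt(abs(sum(f)), 1e-9)
  # disconnected graph: each component centered, islands exactly zero
  g2 <- build_adjacency(rbind(c("A", "B"), c("C", "D")),
                        c("A", "B", "C", "D", "E"))
  f2 <- simulate_structured_field(g2, 2, seed = 9)
  expect_lt(abs(f2[1] + f2[2]), 1e-9)
  expect_lt(abs(f2[3] + f2[4]), 1e-9)
  expect_equal(f2[5], 0)
})

test_that("structured fields are positively autocorrelated and scale with sigma2", {
  g <- make_lattice(10, 10)
  set.seed(12)
  morans <- replicate(60, morans_i(simulate_structured_field(g, 1), g))
  expect_gte(mean(morans > 0), 0.95)
  # E[eta' Q eta] = sigma2 * (n - 1) for a connected graph
  set.seed(13)
  q <- replicate(2000, icar_quadratic_form(simulate_structured_field(g, 0.7), g))
  expect_equal(mean(q), 0.7 * 99, tolerance = 0.05)
})

test_that("the registry generator is deterministic and conserves cases", {
  sc <- simulation_scenario(nrows = 4, ncols = 4, total_cases = 600, seed = 31)
  s1 <- simulate_registry(sc)
  s2 <- simulate_registry(sc)
  expect_identical(s1$cases, s2$cases)
  expect_identical(s1$populations, s2$populations)
  ct <- aggregate_counts(s1$cases, region_ids(s1$graph))
  expect_equal(sum(ct$Y), nrow(s1$cases))
  # sub-site classes partition all cases
  cls <- classify_subsite(s1$cases$topography)
  expect_equal(sum(table(cls)), nrow(s1$cases))
})

test_that("null scenario has unit true risk everywhere", {
  sc <- simulation_scenario(nrows = 3, ncols = 3, beta = NULL, alpha = 0,
                            sigma2_u = 0, sigma2_eta = 0,
                            total_cases = 500, seed = 5)
  sim <- simulate_registry(sc)
  expect_equal(unname(sim$truth$risk[, 1]), rep(1, 9))
})

test_that("counts_from_truth pairs observed counts with design-based E", {
  sc <- simulation_scenario(nrows = 4, ncols = 4, n_periods = 3,
                            beta = NULL, total_cases = 900, seed = 8)
  sim <- simulate_registry(sc)
  ct <- counts_from_truth(sim)
  expect_equal(dim(ct$Y), c(16L, 3L))
  expect_equal(sum(ct$Y), nrow(sim$cases))
  # E is flat across periods (constant population and rates) and near the
  # per-period case budget
  expect_equal(ct$E[, 1], ct$E[, 2])
  expect_equal(sum(ct$E), 900, tolerance = 0.02)
})

test_that("written registries emit the pipeline CSV dialects", {
  sc <- simulation_scenario(nrows = 3, ncols = 3, total_cases = 300, seed = 2)
  sim <- simulate_registry(sc)
  dir <- tempfile()
  paths <- write_registry(sim, dir)
  expect_true(all(file.exists(paths)))
  cases <- read_cases_csv(paths["cases"])
  expect_equal(nrow(cases), nrow(sim$cases))
  pops <- read_populations_csv(paths["populations"])
  g <- read_edge_csv(paths["edges"], region_ids(sim$graph))
  expect_equal(g$edges, sim$graph$edges)
  cv <- read_covariates_csv(paths["covariates"], region_ids(sim$graph))
  expect_equal(cv$sesi, sim$covariates$sesi, tolerance = 1e-6)
})
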