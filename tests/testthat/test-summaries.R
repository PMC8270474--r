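# hand-built posterior_draws stub: one chain whose columns we control
fake_draws <- function(cols, region_ids = character(0), periods = NULL,
                       covariate_names = character(0)) {
  m <- do.call(cbind, cols)
  colnames(m) <- names(cols)
  structure(list(chains = list(m), parameters = names(cols),
                 region_ids = region_ids, periods = periods,
                 covariate_names = covariate_names,
                 temporal = !is.null(periods), spec = NULL, seed = 1L),
            class = "posterior_draws")
}

test_that("degenerate beta draws give a point IRR", {
  d <- fake_draws(list("beta[sesi]" = rep(log(0.9), 100)),
                  covariate_names = "sesi")
  irr <- irr_summary(d)
  expect_equal(irr$IRR, 0.9)
  expect_equal(irr$lower95, 0.9)
  expect_equal(irr$upper95, 0.9)
  expect_error(irr_summary(d, "nope"), "unknown covariate")
})

test_that("Gaussian beta draws match the closed-form quantiles", {
  set.seed(5)
  b <- rnorm(1e5, 0, 0.01)
  d <- fake_draws(list("beta[x]" = b), covariate_names = "x")
  irr <- irr_summary(d)
  expect_equal(irr$lower95, exp(-0.0196), tolerance = 2e-3)
  expect_equal(irr$upper95, exp(0.0196), tolerance = 2e-3)
  expect_false(irr$significant)
  # tight negative effect is flagged, diffuse one is not
  d2 <- fake_draws(list("beta[x]" = rnorm(1e5, -0.15, 0.01)),
                   covariate_names = "x")
  expect_true(irr_summary(d2)$significant)
  d3 <- fake_draws(list("beta[x]" = rnorm(1e5, -0.15, 0.5)),
                   covariate_names = "x")
  expect_false(irr_summary(d3)$significant)
})

test_that("IRR summary is equivariant under beta sign flip", {
  set.seed(6)
  b <- rnorm(5000, -0.2, 0.3)
  d_pos <- fake_draws(list("beta[x]" = b), covariate_names = "x")
  d_neg <- fake_draws(list("beta[x]" = -b), covariate_names = "x")
  s_pos <- irr_summary(d_pos); s_neg <- irr_summary(d_neg)
  expect_equal(s_neg$IRR, 1 / s_pos$IRR, tolerance = 1e-12)
  expect_equal(s_neg$lower95, 1 / s_pos$upper95, tolerance = 1e-12)
  expect_equal(s_neg$upper95, 1 / s_pos$lower95, tolerance = 1e-12)
})

test_that("smoothed risks are exp(u + eta) with exceedance flags", {
  n_draw <- 500
  d <- fake_draws(list("u[A]" = rep(0, n_draw), "eta[A]" = rep(0, n_draw),
                       "u[B]" = rep(1, n_draw), "eta[B]" = rep(0, n_draw)),
                  region_ids = c("A", "B"))
  rk <- smoothed_region_risk(d)
  expect_equal(rk$risk_median, c(1, exp(1)))
  expect_equal(rk$elevated, c(FALSE, TRUE))
  expect_error(smoothed_region_risk(d, temporal = TRUE), "spatial fit")
})

test_that("temporal risk surface multiplies in exp(gamma + phi)", {
  n_draw <- 200
  d <- fake_draws(list("u[A]" = rep(0.5, n_draw), "eta[A]" = rep(0, n_draw),
                       "gamma[1]" = rep(0, n_draw), "phi[1]" = rep(-0.5, n_draw),
                       "gamma[2]" = rep(0.2, n_draw), "phi[2]" = rep(0.3, n_draw)),
                  region_ids = "A", periods = c("P1", "P2"))
  rk <- smoothed_region_risk(d, temporal = TRUE)
  expect_equal(rk$risk_median, c(exp(0), exp(1)))
  expect_equal(rk$period, c("P1", "P2"))
})

test_that("risk categorization covers quantile and fixed schemes with tie rule", {
  q <- categorize_risk(1:10)
  expect_equal(unname(q$counts), rep(2L, 5))
  f <- categorize_risk(c(0.5, 0.9, 1.1, 2.0), scheme = "fixed",
                       breaks = c(0.8, 1.0, 1.25))
  expect_equal(f$category, 1:4)
  tied <- categorize_risk(rep(1, 7))
  expect_equal(unname(tied$counts), c(7L, 0L, 0L, 0L, 0L))
  expect_equal(sum(tied$counts), 7L)
  expect_error(categorize_risk(1:4, scheme = "fixed", breaks = c(2, 2)),
               "increasing")
  expect_error(categorize_risk(c(1, Inf)), "finite")
})
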