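test_that("perfectly correlated indicators give scores proportional to them", {
  set.seed(1)
  z <- rnorm(20)
  ind <- data.frame(income = z, employment = z, education = z)
  s <- compute_sesi(ind)
  expect_equal(cor(s, z, method = "spearman"), 1)
  expect_gt(cor(s, z), 0.999999)
})

test_that("loadings match a direct eigendecomposition of the reduced matrix", {
  set.seed(7)
  X <- matrix(rnorm(96 * 3), 96, 3)
  X[, 2] <- X[, 1] * 0.6 + X[, 2]
  X[, 3] <- X[, 1] * 0.4 + X[, 3]
  colnames(X) <- c("income", "employment", "education")
  s <- compute_sesi(as.data.frame(X))
  l <- attr(s, "loadings")
  h2 <- attr(s, "communalities")
  R <- cor(X)
  diag(R) <- h2
  es <- eigen(R, symmetric = TRUE)
  v <- es$vectors[, 1] * sqrt(es$values[1])
  if (sum(v * l) < 0) v <- -v
  expect_equal(unname(l), unname(v), tolerance = 1e-6)
})

test_that("scores are invariant to affine rescaling of indicators", {
  set.seed(3)
  ind <- data.frame(income = rnorm(30, 50000, 8000),
                    employment = rnorm(30, 60, 5),
                    education = rnorm(30, 40, 6))
  s1 <- compute_sesi(ind)
  ind2 <- ind
  ind2$income <- ind2$income / 1000 + 7
  ind2$education <- ind2$education * 3 - 100
  s2 <- compute_sesi(ind2)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-9)
  expect_gte(cor(s1, ind$income), 0)
})

test_that("rescale option hits the requested endpoints exactly", {
  set.seed(4)
  ind <- data.frame(income = rnorm(20), employment = rnorm(20),
                    education = rnorm(20))
  s <- compute_sesi(ind, rescale = c(0.643397, 9.4163))
  expect_equal(min(s), 0.643397)
  expect_equal(max(s), 9.4163)
})

test_that("degenerate indicator input is rejected", {
  ind <- data.frame(income = rep(1, 10), employment = rnorm(10),
                    education = rnorm(10))
  expect_error(compute_sesi(ind), "constant")
  expect_error(compute_sesi(data.frame(income = rnorm(3),
                                       employment = rnorm(3),
                                       education = rnorm(3))),
               "at least 4")
})

test_that("assemble_covariates aligns, range-checks and centers", {
  regions <- c("A", "B", "C", "D")
  shuffled <- c(D = 4, B = 2, A = 1, C = 3)
  tab <- assemble_covariates(shuffled, shuffled * 10, shuffled * 5, regions)
  expect_equal(tab$region_id, regions)
  expect_equal(tab$sesi, c(1, 2, 3, 4))
  expect_error(
    assemble_covariates(shuffled, c(A = 101, B = 1, C = 1, D = 1),
                        shuffled, regions),
    "\\[0, 100\\]")
  expect_error(assemble_covariates(shuffled[1:3], shuffled * 2, shuffled,
                                   regions),
               "missing region")
  centered <- assemble_covariates(shuffled, shuffled, shuffled, regions,
                                  center = TRUE)
  expect_lt(abs(mean(centered$sesi)), 1e-12)
  expect_lt(abs(mean(centered$pct_immigrant)), 1e-12)
})
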