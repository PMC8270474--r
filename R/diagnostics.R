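#' Multivariable Poisson regression with a standardization offset
#'
#' Maximum-likelihood fit of the log-linear model
#' \eqn{\log \mu_i = \log E_i + a + b'x_i} by iteratively reweighted least
#' squares. This is the non-spatial model used to screen for residual spatial
#' structure before the hierarchical fit: its fitted means absorb the
#' covariates, and what is left over (\code{\link{residual_risk_ratio}}) is
#' mapped and tested with Moran's I.
#'
#' @param Y non-negative integer counts
#' @param E positive expected counts (standardization offsets)
#' @param X covariate matrix (one row per region, no intercept column — an
#'   intercept is always added), or NULL for the intercept-only model
#' @param tol convergence tolerance on the relative log-likelihood change
#' @param max_iter iteration cap
#' @return list of class \code{poisson_glm}: \code{coefficients} (intercept
#'   first), \code{se} (Fisher standard errors), \code{fitted} (means
#'   \eqn{\hat\mu_i}), \code{loglik}, \code{iterations}, \code{converged}
#' @examples
#' g <- fit_poisson_glm(c(4, 6), c(5, 5), NULL)
#' exp(g$coefficients)  # = sum(Y)/sum(E)
#' @export
fit_poisson_glm <- function(Y, E, X = NULL, tol = 1e-10, max_iter = 100L) {
  Y <- as.numeric(Y)
  E <- as.numeric(E)
  if (length(Y) != length(E)) stop("Y and E length mismatch")
  if (any(E <= 0)) stop("all E must be positive (drop zero-expected regions first)")
  if (any(Y < 0)) stop("negative count")
  n <- length(Y)
  if (is.null(X)) {
    M <- matrix(1, n, 1L)
    colnames(M) <- "(Intercept)"
  } else {
    X <- as.matrix(X)
    if (nrow(X) != n) stop("X row count mismatch")
    M <- cbind("(Intercept)" = 1, X)
  }
  if (qr(M)$rank < ncol(M)) stop("rank-deficient design matrix")
  off <- log(E)
  beta <- c(log(sum(Y) / sum(E)), rep(0, ncol(M) - 1L))
  eta <- off + as.numeric(M %*% beta)
  mu <- exp(eta)
  ll <- sum(stats::dpois(Y, mu, log = TRUE))
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    w <- mu
    z <- (eta - off) + (Y - mu) / mu
    WM <- M * w
    beta <- solve(crossprod(M, WM), crossprod(WM, z))
    beta <- as.numeric(beta)
    eta <- off + as.numeric(M %*% beta)
    mu <- exp(eta)
    ll_new <- sum(stats::dpois(Y, mu, log = TRUE))
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol * (abs(ll) + tol)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  if (!converged) {
    stop("IRLS did not converge in ", max_iter,
         " iterations; log-likelihood trace: ",
         paste(format(utils::tail(trace, 5L)), collapse = ", "))
  }
  fisher <- crossprod(M, M * mu)
  se <- sqrt(diag(solve(fisher)))
  structure(list(coefficients = stats::setNames(beta, colnames(M)),
                 se = stats::setNames(se, colnames(M)),
                 fitted = mu, loglik = ll, iterations = it,
                 converged = converged),
            class = "poisson_glm")
}

#' @export
print.poisson_glm <- function(x, ...) {
  cat("Poisson GLM (log link, offset log E);",
      x$iterations, "IRLS iterations\n")
  print(cbind(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' Unexplained (covariate-adjusted) risk ratios
#'
#' \eqn{r_i = Y_i / \hat\mu_i}: observed counts over the non-spatial GLM's
#' covariate-adjusted expectation. Values far from 1 mark regions whose
#' incidence the covariates do not explain; their spatial arrangement is the
#' input to the Moran's I dependency test.
#'
#' @param Y observed counts
#' @param E expected counts (carried into the output table)
#' @param glm_fit a \code{\link{fit_poisson_glm}} result on the same regions
#' @param region_ids optional ids for the output table
#' @return data.frame \code{region_id, Y, E, mu_hat, ratio}
#' @export
residual_risk_ratio <- function(Y, E, glm_fit, region_ids = NULL) {
  stopifnot(inherits(glm_fit, "poisson_glm"))
  Y <- as.numeric(Y)
  if (length(Y) != length(glm_fit$fitted)) stop("Y length does not match the fitted model")
  if (length(E) != length(Y)) stop("E length mismatch")
  mu <- glm_fit$fitted
  keep <- mu > 0
  data.frame(region_id = (region_ids %||% as.character(seq_along(Y)))[keep],
             Y = Y[keep], E = as.numeric(E)[keep],
             mu_hat = mu[keep], ratio = Y[keep] / mu[keep],
             row.names = NULL)
}

#' Global Moran's I with binary contiguity weights
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_i \sum_j w_{ij}(y_i - \bar y)(y_j -
#' \bar y)}{\sum_i (y_i - \bar y)^2}}
#' with \eqn{w_{ij}} the raw binary contiguity weights (no row
#' standardization) and \eqn{S_0 = \sum_i \sum_j w_{ij}} the aggregate
#' weight. Positive values indicate that neighboring regions carry similar
#' values (spatial clustering).
#'
#' @param values numeric vector aligned to \code{region_ids(graph)}; must
#'   have non-zero variance
#' @param graph a \code{region_graph} with at least one edge
#' @return scalar I
#' @examples
#' g <- make_lattice(2, 2)
#' morans_i(c(1, -1, -1, 1), g)  # checkerboard -> -1
#' @export
morans_i <- function(values, graph) {
  stopifnot(inherits(graph, "region_graph"))
  values <- as.numeric(values)
  n <- graph$n
  if (length(values) != n) stop("values length != number of regions")
  if (n < 2L) stop("need at least 2 regions")
  if (nrow(graph$edges) == 0L) stop("graph has no edges; Moran's I undefined")
  yc <- values - mean(values)
  denom <- sum(yc^2)
  if (denom == 0) stop("values have zero variance; Moran's I undefined")
  num <- 2 * sum(yc[graph$edges[, 1L]] * yc[graph$edges[, 2L]])
  (n / graph$s0) * (num / denom)
}

#' Permutation test for positive spatial autocorrelation
#'
#' One-sided upper test of Moran's I under the exchangeability null: values
#' are reassigned to regions uniformly at random \code{n_permutations} times
#' and \eqn{p = (1 + \#\{I_{perm} \ge I_{obs}\}) / (1 + n_{perm})}. The +1
#' correction keeps p strictly positive and the test exact under the null.
#'
#' @inheritParams morans_i
#' @param n_permutations number of random relabelings (>= 99)
#' @param seed integer seed controlling the permutations (the global RNG
#'   state is restored on exit)
#' @return list of class \code{moran_test}: \code{i_value},
#'   \code{p_value}, \code{n_regions}, \code{n_permutations}, \code{seed},
#'   \code{perm_values}
#' @export
morans_i_permutation_test <- function(values, graph, n_permutations = 999L,
                                      seed = 1L) {
  if (n_permutations < 99L) stop("use at least 99 permutations")
  i_obs <- morans_i(values, graph)
  values <- as.numeric(values)
  yc <- values - mean(values)
  denom <- sum(yc^2)
  scale_fac <- graph$n / graph$s0
  ei <- graph$edges[, 1L]; ej <- graph$edges[, 2L]
  perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      ycp <- yc[sample.int(graph$n)]
      scale_fac * 2 * sum(ycp[ei] * ycp[ej]) / denom
    }, numeric(1))
  })
  p <- (1 + sum(perm >= i_obs)) / (1 + n_permutations)
  structure(list(i_value = i_obs, p_value = p, n_regions = graph$n,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), perm_values = perm),
            class = "moran_test")
}

#' @export
print.moran_test <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f  (n = %d, %d permutations)\n  one-sided p = %.4g\n",
              x$i_value, x$n_regions, x$n_permutations, x$p_value))
  invisible(x)
}

# run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}
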