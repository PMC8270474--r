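#' MCMC model specification
#'
#' Collects the priors and sampler settings for the hierarchical Poisson
#' models. Defaults follow the analysis conventions of the package: a flat
#' (improper) prior on the intercept, \eqn{\beta \sim N(0, 1000)}
#' (variance parameterization) on each slope, and Gamma(0.1, 0.01)
#' hyperpriors on every random-effect precision — minimally informative
#' choices for registry-scale counts. The default budget is 4 chains of
#' 30,000 iterations (10,000 burn-in, thin 10).
#'
#' @param n_chains number of chains (>= 2 recommended, for convergence
#'   diagnostics)
#' @param n_iter iterations per chain
#' @param n_burn burn-in iterations discarded per chain (must be < n_iter)
#' @param thin thinning interval (>= 1)
#' @param prior_beta_var prior variance of the regression slopes
#' @param prior_tau_shape,prior_tau_rate Gamma hyperprior on each precision
#' @param fix_tau optional named numeric vector fixing some precisions
#'   instead of sampling them, e.g. \code{c(tau_u = 1, tau_eta = 1)}
#'   (used for oracle checks and sensitivity runs)
#' @param likelihood logical; FALSE replaces the likelihood by a constant so
#'   the sampler explores the prior (prior-recovery checks)
#' @param adapt_every adaptation interval (sweeps) for the proposal scales
#'   during burn-in
#' @param seed integer master seed; per-chain streams are derived from it
#' @return object of class \code{model_spec}
#' @export
model_spec <- function(n_chains = 4L, n_iter = 30000L, n_burn = 10000L,
                       thin = 10L, prior_beta_var = 1000,
                       prior_tau_shape = 0.1, prior_tau_rate = 0.01,
                       fix_tau = NULL, likelihood = TRUE,
                       adapt_every = 100L, seed = 1L) {
  if (n_burn >= n_iter) stop("n_burn must be smaller than n_iter")
  if (thin < 1L) stop("thinning must be >= 1")
  if (n_chains < 1L) stop("need at least one chain")
  if (prior_tau_shape <= 0 || prior_tau_rate <= 0) {
    stop("Gamma hyperprior parameters must be positive")
  }
  if (prior_beta_var <= 0) stop("prior_beta_var must be positive")
  if (!is.null(fix_tau)) {
    bad <- setdiff(names(fix_tau),
                   c("tau_u", "tau_eta", "tau_gamma", "tau_phi"))
    if (length(bad)) stop("unknown fix_tau name(s): ", paste(bad, collapse = ", "))
    if (any(fix_tau <= 0)) stop("fixed precisions must be positive")
  }
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_burn = as.integer(n_burn), thin = as.integer(thin),
                 prior_beta_var = prior_beta_var,
                 prior_tau_shape = prior_tau_shape,
                 prior_tau_rate = prior_tau_rate,
                 fix_tau = fix_tau, likelihood = isTRUE(likelihood),
                 adapt_every = as.integer(adapt_every),
                 seed = as.integer(seed)),
            class = "model_spec")
}

# deterministic per-chain seed stream from one master seed (kept < 2^31)
chain_seed <- function(seed, chain) {
  as.integer((as.double(seed) * 48271 + chain * 104729) %% 2147483647)
}

#' Intrinsic CAR full conditional for one region
#'
#' Under the intrinsic CAR prior, a region's spatial effect given the rest is
#' Gaussian around its neighbor average with variance
#' \eqn{\sigma^2_\eta / |N(i)|}.
#'
#' @param eta spatial-effect vector aligned to the graph
#' @param graph a \code{region_graph}
#' @param i region index (1-based)
#' @param sigma2_eta conditional variance parameter
#' @return list with \code{mean} and \code{variance}
#' @export
icar_conditional <- function(eta, graph, i, sigma2_eta) {
  stopifnot(inherits(graph, "region_graph"), length(eta) == graph$n)
  d <- graph$degrees[i]
  if (d == 0L) {
    stop("region ", graph$region_ids[i],
         " is an island: its CAR conditional is undefined (eta is pinned to 0)")
  }
  list(mean = mean(eta[graph$nb[[i]]]), variance = sigma2_eta / d)
}

#' Pairwise-difference quadratic form of the intrinsic CAR prior
#'
#' \eqn{\eta' Q \eta = \sum_{i \sim j, i < j} (\eta_i - \eta_j)^2}; zero iff
#' the field is constant on every connected component.
#'
#' @inheritParams icar_conditional
#' @return non-negative scalar
#' @export
icar_quadratic_form <- function(eta, graph) {
  stopifnot(inherits(graph, "region_graph"), length(eta) == graph$n)
  if (nrow(graph$edges) == 0L) return(0)
  sum((eta[graph$edges[, 1L]] - eta[graph$edges[, 2L]])^2)
}

#' RW(1) full conditional for one period
#'
#' The first-order random-walk prior's conditional is the three-case step
#' function: endpoints are Gaussian around the single adjacent value with
#' variance \eqn{\sigma^2_\phi}; interior periods around the average of both
#' neighbors with variance \eqn{\sigma^2_\phi / 2}.
#'
#' @param phi temporal-effect vector of length T
#' @param t period index (1-based)
#' @param T number of periods (>= 2)
#' @param sigma2_phi innovation variance
#' @return list with \code{mean} and \code{variance}
#' @export
rw1_conditional <- function(phi, t, T = length(phi), sigma2_phi) {
  if (T < 2L) stop("temporal model needs at least 2 periods")
  if (t < 1L || t > T) stop("period index out of range")
  if (t == 1L) {
    list(mean = phi[2L], variance = sigma2_phi)
  } else if (t == T) {
    list(mean = phi[T - 1L], variance = sigma2_phi)
  } else {
    list(mean = (phi[t - 1L] + phi[t + 1L]) / 2, variance = sigma2_phi / 2)
  }
}

#' Conjugate Gibbs draw for a random-effect precision
#'
#' Under the Gamma(a, b) hyperprior the precision's full conditional is
#' Gamma(a + r/2, b + q/2), with q the structure's quadratic form and r its
#' rank: r = n for iid effects, r = n - c for the intrinsic CAR (c connected
#' components), r = T - 1 for RW(1).
#'
#' @param effect effect vector (u, eta, gamma or phi values)
#' @param structure one of \code{"iid"}, \code{"icar"}, \code{"rw1"}
#' @param graph \code{region_graph}, required for \code{"icar"}
#' @param prior \code{c(shape, rate)} of the Gamma hyperprior
#' @param n_draws number of draws to return (default 1)
#' @return numeric vector of sampled precisions, with attributes
#'   \code{shape} and \code{rate} of the full conditional
#' @export
update_precision <- function(effect, structure = c("iid", "icar", "rw1"),
                             graph = NULL, prior = c(0.1, 0.01),
                             n_draws = 1L) {
  structure <- match.arg(structure)
  a <- prior[1L]; b <- prior[2L]
  if (a <= 0 || b <= 0) stop("Gamma hyperprior parameters must be positive")
  effect <- as.numeric(effect)
  if (structure == "iid") {
    q <- sum(effect^2)
    r <- length(effect)
  } else if (structure == "icar") {
    if (is.null(graph)) stop("icar structure needs the region graph")
    q <- icar_quadratic_form(effect, graph)
    r <- graph$n - n_components(graph)
  } else {
    T <- length(effect)
    if (T < 2L) stop("rw1 structure needs length >= 2")
    q <- sum(diff(effect)^2)
    r <- T - 1L
  }
  out <- stats::rgamma(n_draws, shape = a + r / 2, rate = b + q / 2)
  attr(out, "shape") <- a + r / 2
  attr(out, "rate") <- b + q / 2
  out
}

covariate_matrix <- function(covariates, region_ids) {
  if (is.null(covariates)) {
    return(matrix(numeric(0), nrow = length(region_ids), ncol = 0L))
  }
  if (inherits(covariates, "covariate_table") || is.data.frame(covariates)) {
    df <- as.data.frame(covariates)
    if ("region_id" %in% names(df)) {
      if (!identical(as.character(df$region_id), as.character(region_ids))) {
        stop("covariate rows are not aligned to the count-table regions")
      }
      df$region_id <- NULL
    } else if (nrow(df) != length(region_ids)) {
      stop("covariate row count mismatch")
    }
    X <- as.matrix(df)
  } else {
    X <- as.matrix(covariates)
    if (nrow(X) != length(region_ids)) stop("covariate row count mismatch")
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  storage.mode(X) <- "double"
  X
}

run_chains <- function(Y, E, X, graph, spec, temporal) {
  n <- nrow(Y); T <- ncol(Y); p <- ncol(X)
  island <- graph$degrees == 0L
  rank_eta <- graph$n - n_components(graph)
  fix <- c(tau_u = FALSE, tau_eta = FALSE, tau_gamma = FALSE, tau_phi = FALSE)
  tau0 <- c(tau_u = 1, tau_eta = 1, tau_gamma = 1, tau_phi = 1)
  if (!is.null(spec$fix_tau)) {
    fix[names(spec$fix_tau)] <- TRUE
    tau0[names(spec$fix_tau)] <- spec$fix_tau
  }
  # start chains around the non-spatial MLE (overdispersed by its standard
  # errors): raw-scale covariates make blind starts wander into regions the
  # burn-in cannot always escape
  base_rate <- if (sum(E) > 0) log(max(sum(Y), 0.5) / sum(E)) else 0
  mle <- NULL
  if (spec$likelihood) {
    mle <- tryCatch(
      fit_poisson_glm(rowSums(Y), rowSums(E), if (p > 0) X else NULL),
      error = function(e) NULL)
  }
  alpha_hat <- if (!is.null(mle)) mle$coefficients[1L] else base_rate
  alpha_se <- if (!is.null(mle)) mle$se[1L] else 0.25
  beta_hat <- if (!is.null(mle) && p > 0) mle$coefficients[-1L] else numeric(p)
  beta_se <- if (!is.null(mle) && p > 0) mle$se[-1L] else rep(0.1, p)

  par_names <- c("alpha",
                 if (p > 0) paste0("beta[", colnames(X), "]"),
                 "tau_u", "tau_eta",
                 if (temporal) c("tau_gamma", "tau_phi"),
                 paste0("u[", graph$region_ids, "]"),
                 paste0("eta[", graph$region_ids, "]"),
                 if (temporal) paste0("gamma[", seq_len(T), "]"),
                 if (temporal) paste0("phi[", seq_len(T), "]"))

  chains <- vector("list", spec$n_chains)
  acceptance <- vector("list", spec$n_chains)
  for (ch in seq_len(spec$n_chains)) {
    res <- with_seed(chain_seed(spec$seed, ch), {
      # overdispersed starts around the crude rate
      eta0 <- stats::rnorm(n, 0, 0.2)
      eta0[island] <- 0
      if (any(!island)) eta0[!island] <- eta0[!island] - mean(eta0[!island])
      init <- list(alpha = alpha_hat + stats::rnorm(1, 0, 2 * alpha_se + 0.1),
                   beta = beta_hat + stats::rnorm(max(p, 0), 0,
                                                  2 * beta_se + 1e-3),
                   u = stats::rnorm(n, 0, 0.2),
                   eta = eta0,
                   gamma = if (temporal) stats::rnorm(T, 0, 0.1) else numeric(T),
                   phi = if (temporal) {
                     ph <- stats::rnorm(T, 0, 0.1); ph - mean(ph)
                   } else numeric(T))
      tau_start <- tau0
      tau_start[!fix] <- exp(stats::runif(sum(!fix), -1, 1))
      bym_mcmc_cpp(Y, E, X, graph$nb0, graph$degrees,
                   graph$edges0, island, rank_eta, temporal,
                   spec$prior_beta_var, spec$prior_tau_shape,
                   spec$prior_tau_rate, unname(fix),
                   unname(tau_start), spec$n_iter, spec$n_burn,
                   spec$thin, spec$likelihood, init,
                   spec$adapt_every)
    })
    acceptance[[ch]] <- res$acceptance
    dr <- res$draws
    colnames(dr) <- par_names
    chains[[ch]] <- dr
  }
  acc_names <- c("alpha", if (p > 0) paste0("beta[", colnames(X), "]"),
                 "u", "eta", "gamma", "phi", "gamma_phi_swap")
  acc <- do.call(rbind, acceptance)
  colnames(acc) <- acc_names
  list(chains = chains, acceptance = acc, par_names = par_names)
}

prep_graph_for_cpp <- function(graph) {
  graph$nb0 <- lapply(graph$nb, function(v) as.integer(v - 1L))
  e <- graph$edges
  if (nrow(e) == 0L) {
    graph$edges0 <- matrix(integer(0), ncol = 2L)
  } else {
    graph$edges0 <- matrix(as.integer(e - 1L), ncol = 2L)
  }
  graph
}

#' Fit the Bayesian spatial (convolution) Poisson model
#'
#' \deqn{Y_i \sim Poisson(\lambda_i E_i), \quad
#'   \log \lambda_i = \alpha + \beta' x_i + u_i + \eta_i}
#' with iid heterogeneity \eqn{u_i \sim N(0, \sigma^2_u)} and an intrinsic
#' CAR (neighbor-averaging) prior on the structured effect \eqn{\eta_i},
#' fit by adaptive Metropolis-within-Gibbs MCMC under the priors in
#' \code{\link{model_spec}}. \eqn{\eta} is recentred to sum to zero each
#' sweep for identifiability.
#'
#' @param counts a \code{count_table} (single period) with E filled and
#'   E > 0 everywhere (see \code{\link{drop_zero_expected}})
#' @param covariates a \code{covariate_table}, plain matrix/data.frame
#'   aligned to the counts, or NULL for an intercept-only model
#' @param graph a \code{region_graph} over the same regions, same order
#' @param spec a \code{\link{model_spec}}
#' @return object of class \code{posterior_draws}: per-chain matrices of
#'   retained draws, acceptance rates, split-chain R-hat per model parameter
#'   (a value above 1.1 sets \code{$converged} to FALSE with a warning
#'   recorded, not an error)
#' @export
fit_spatial <- function(counts, covariates = NULL, graph,
                        spec = model_spec()) {
  stopifnot(inherits(counts, "count_table"), inherits(graph, "region_graph"))
  if (!is.null(counts$periods)) {
    stop("counts are period-stratified; use fit_spatiotemporal()")
  }
  fit_bym(counts, covariates, graph, spec, temporal = FALSE)
}

#' Fit the Bayesian spatio-temporal Poisson model
#'
#' Extends \code{\link{fit_spatial}} with additive temporal terms,
#' \eqn{\log \lambda_{it} = \alpha + \beta' x_i + u_i + \eta_i + \gamma_t +
#' \phi_t}: exchangeable \eqn{\gamma_t \sim N(0, \sigma^2_\gamma)} and a
#' first-order random-walk prior on \eqn{\phi_t} (recentred to sum to zero).
#' No space-time interaction term is included.
#'
#' @inheritParams fit_spatial
#' @export
fit_spatiotemporal <- function(counts, covariates = NULL, graph,
                               spec = model_spec()) {
  stopifnot(inherits(counts, "count_table"), inherits(graph, "region_graph"))
  if (is.null(counts$periods) || length(counts$periods) < 2L) {
    stop("need >= 2 periods; for a single period use fit_spatial()")
  }
  fit_bym(counts, covariates, graph, spec, temporal = TRUE)
}

fit_bym <- function(counts, covariates, graph, spec, temporal) {
  stopifnot(inherits(spec, "model_spec"))
  if (!identical(counts$region_ids, graph$region_ids)) {
    stop("counts and graph regions are not aligned")
  }
  Y <- counts$Y; E <- counts$E
  if (spec$likelihood && any(E <= 0)) {
    stop("all expected counts must be positive; see drop_zero_expected()")
  }
  if (spec$likelihood && sum(Y) == 0) {
    stop("no cases at all: the flat intercept prior would leave the posterior improper")
  }
  X <- covariate_matrix(covariates, counts$region_ids)
  if (ncol(X) > 0 && qr(X)$rank < ncol(X)) stop("rank-deficient covariate matrix")
  g <- prep_graph_for_cpp(graph)
  storage.mode(Y) <- "double"; storage.mode(E) <- "double"
  res <- run_chains(Y, E, X, g, spec, temporal)

  taus <- setdiff(c("tau_u", "tau_eta", if (temporal) c("tau_gamma", "tau_phi")),
                  names(spec$fix_tau))
  model_pars <- c(if (spec$likelihood) "alpha",
                  if (ncol(X) > 0) paste0("beta[", colnames(X), "]"),
                  taus)
  out <- structure(
    list(chains = res$chains, parameters = res$par_names,
         acceptance = res$acceptance,
         region_ids = counts$region_ids,
         periods = if (temporal) counts$periods else NULL,
         covariate_names = colnames(X),
         temporal = temporal, spec = spec, seed = spec$seed,
         rhat = NULL, converged = NA),
    class = "posterior_draws")
  if (spec$n_chains >= 2L && nrow(res$chains[[1L]]) >= 10L) {
    rhat <- vapply(model_pars, function(pn) gelman_rubin(out, pn), numeric(1))
    out$rhat <- rhat
    out$converged <- all(rhat < 1.1, na.rm = TRUE)
    if (!out$converged) {
      warning("R-hat > 1.1 for: ",
              paste(names(rhat)[rhat >= 1.1], collapse = ", "),
              " - consider a longer run")
    }
  }
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", length(x$chains), "chains x",
      nrow(x$chains[[1L]]), "retained draws,",
      length(x$parameters), "parameters\n")
  cat("  model:", if (x$temporal) "spatio-temporal" else "spatial",
      "|", length(x$region_ids), "regions",
      if (x$temporal) paste0("x ", length(x$periods), " periods"), "\n")
  if (!is.null(x$rhat)) {
    cat("  max R-hat:", format(max(x$rhat, na.rm = TRUE), digits = 4),
        if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  }
  invisible(x)
}

#' Extract draws for one parameter
#'
#' @param draws a \code{posterior_draws}
#' @param parameter parameter label, e.g. \code{"alpha"},
#'   \code{"beta[sesi]"}, \code{"u[R01]"}, \code{"phi[2]"}
#' @param pooled if TRUE (default) returns one vector pooling all chains;
#'   otherwise a draws x chains matrix
#' @return numeric vector or matrix
#' @export
param_draws <- function(draws, parameter, pooled = TRUE) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (!parameter %in% draws$parameters) {
    stop("unknown parameter: ", parameter)
  }
  m <- vapply(draws$chains, function(ch) ch[, parameter],
              numeric(nrow(draws$chains[[1L]])))
  if (pooled) as.numeric(m) else m
}

#' Split-chain Gelman-Rubin potential scale reduction factor
#'
#' Each chain is split in half and the classic between/within variance ratio
#' is computed over the 2m half-chains; values near 1 indicate the chains
#' have mixed over the same distribution.
#'
#' @param draws a \code{posterior_draws}, or a numeric matrix with one
#'   column per chain
#' @param parameter parameter label (ignored when \code{draws} is a matrix)
#' @return scalar R-hat (>= 1 up to floating point)
#' @export
gelman_rubin <- function(draws, parameter = NULL) {
  if (inherits(draws, "posterior_draws")) {
    if (length(draws$chains) < 2L) stop("R-hat needs at least 2 chains")
    m <- param_draws(draws, parameter, pooled = FALSE)
  } else {
    m <- as.matrix(draws)
    if (ncol(m) < 2L) stop("R-hat needs at least 2 chains")
  }
  niter <- nrow(m)
  if (niter < 10L) stop("R-hat needs at least 10 retained draws per chain")
  half <- floor(niter / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(m)), function(j) {
    cbind(m[seq_len(half), j], m[(niter - half + 1):niter, j])
  }))
  nn <- nrow(splits); mm <- ncol(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2L, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(1)
  max(1, sqrt(((nn - 1) / nn * W + B / nn) / W))
}

#' Persist posterior draws as a long CSV plus a JSON sidecar
#'
#' The CSV has columns \code{chain,iteration,parameter,value}; the sidecar
#' records the sampler settings, seed, acceptance rates and R-hat values.
#'
#' @param draws a \code{posterior_draws}
#' @param csv_path,json_path output paths
#' @param parameters optional subset of parameter labels (default: the model
#'   parameters, i.e. everything except the latent fields, to keep files
#'   small; pass \code{draws$parameters} for everything)
#' @export
write_draws <- function(draws, csv_path, json_path = NULL,
                        parameters = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (is.null(parameters)) {
    parameters <- grep("^(alpha$|beta\\[|tau_)", draws$parameters,
                       value = TRUE)
  }
  long <- do.call(rbind, lapply(seq_along(draws$chains), function(ch) {
    mat <- draws$chains[[ch]][, parameters, drop = FALSE]
    data.frame(chain = ch,
               iteration = rep(seq_len(nrow(mat)), times = ncol(mat)),
               parameter = rep(parameters, each = nrow(mat)),
               value = as.numeric(mat))
  }))
  utils::write.csv(long, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    side <- list(seed = draws$seed,
                 spec = unclass(draws$spec)[c("n_chains", "n_iter", "n_burn",
                                              "thin", "prior_beta_var",
                                              "prior_tau_shape",
                                              "prior_tau_rate")],
                 acceptance = as.data.frame(draws$acceptance),
                 rhat = as.list(draws$rhat),
                 converged = draws$converged)
    jsonlite::write_json(side, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(csv_path)
}
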