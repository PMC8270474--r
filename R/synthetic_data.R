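#' Rook-contiguity lattice graph
#'
#' Builds an nrows x ncols grid of regions where horizontally or vertically
#' adjacent cells are neighbors — the synthetic stand-in for a real district
#' contiguity map (an 8 x 12 lattice mirrors the 96-district study
#' geography).
#'
#' @param nrows,ncols grid dimensions (>= 1)
#' @return a \code{region_graph} with ids \code{R001..Rnnn} in row-major
#'   order
#' @export
make_lattice <- function(nrows, ncols) {
  nrows <- as.integer(nrows); ncols <- as.integer(ncols)
  if (nrows < 1L || ncols < 1L) stop("lattice dimensions must be >= 1")
  n <- nrows * ncols
  ids <- sprintf("R%03d", seq_len(n))
  idx <- function(r, c) (r - 1L) * ncols + c
  edges <- list()
  for (r in seq_len(nrows)) {
    for (c in seq_len(ncols)) {
      if (c < ncols) edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
      if (r < nrows) edges[[length(edges) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
    }
  }
  em <- do.call(rbind, edges)
  build_adjacency(cbind(ids[em[, 1L]], ids[em[, 2L]]), ids)
}

#' Draw a zero-mean intrinsic-CAR field
#'
#' Exact draw from the intrinsic CAR distribution restricted to the
#' sum-to-zero subspace, via eigendecomposition of the graph Laplacian:
#' coefficients on the eigenvectors with eigenvalue \eqn{\lambda_k > 0} are
#' independent \eqn{N(0, \sigma^2/\lambda_k)}; null-space directions (one
#' per connected component) are excluded, so the field sums to zero within
#' each component and islands get exactly 0. This generative route shares no
#' code with the MCMC fitter, making it an independent cross-check.
#'
#' @param graph a \code{region_graph}
#' @param sigma2 conditional variance parameter (>= 0)
#' @param seed optional integer seed (global RNG restored on exit)
#' @return numeric field of length \code{graph$n}
#' @export
simulate_structured_field <- function(graph, sigma2, seed = NULL) {
  stopifnot(inherits(graph, "region_graph"), sigma2 >= 0)
  n <- graph$n
  if (sigma2 == 0) return(numeric(n))
  L <- matrix(0, n, n)
  if (nrow(graph$edges) > 0L) {
    for (e in seq_len(nrow(graph$edges))) {
      i <- graph$edges[e, 1L]; j <- graph$edges[e, 2L]
      L[i, j] <- L[i, j] - 1
      L[j, i] <- L[j, i] - 1
    }
  }
  diag(L) <- graph$degrees
  es <- eigen(L, symmetric = TRUE)
  pos <- es$values > 1e-9 * max(es$values, 1)
  draw <- function() {
    z <- stats::rnorm(sum(pos), 0, sqrt(sigma2 / es$values[pos]))
    as.numeric(es$vectors[, pos, drop = FALSE] %*% z)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Define a synthetic-registry scenario
#'
#' Describes the generative twin of the analysis model: a lattice contiguity
#' map, stratum populations (2 sexes x 12 age groups with an age-incidence
#' profile peaking at 75-79 and a male excess), spatially smooth or patchy
#' region covariates, and region (x period) relative risks
#' \eqn{\exp(\alpha + \beta' x_i + u_i + \eta_i [+ \gamma_t + \phi_t])}.
#' Defaults mirror the study shape: 96 regions (8 x 12), five 5-year
#' periods over 1992-2016, about 3,200 cases in total, covariate effects of
#' realistic magnitude (IRR 0.92 per SESI unit, near-null percentage
#' effects), and modest random-effect variances.
#'
#' @param nrows,ncols lattice dimensions
#' @param n_periods number of periods (uses the default 5-year scheme when
#'   5; otherwise synthetic consecutive 5-year intervals from 1992)
#' @param alpha true log baseline relative risk
#' @param beta named vector of true log-IRRs; names must be covariate
#'   columns (\code{sesi}, \code{pct_immigrant}, \code{pct_indigenous});
#'   covariates named here enter the risk, others are generated but inert
#' @param sigma2_u,sigma2_eta iid / ICAR spatial variance components
#' @param sigma2_gamma,sigma2_phi temporal variance components (used when
#'   \code{n_periods >= 2}); \code{phi_truth} overrides the RW(1) draw with
#'   a fixed, centered trend vector
#' @param phi_truth optional explicit structured temporal trend (length
#'   \code{n_periods}; centered internally)
#' @param total_cases target expected case total over the whole window
#' @param mean_region_pop mean region population (log-normal across regions)
#' @param high_risk_regions optional region indices given an extra risk
#'   multiplier
#' @param high_risk_multiplier multiplier for the planted regions
#' @param subsite_props length-3 proportions for (cardia C160, non-cardia
#'   C161-C168, unspecified C169) topography assignment
#' @param seed integer seed
#' @return object of class \code{simulation_scenario}
#' @export
simulation_scenario <- function(nrows = 8L, ncols = 12L, n_periods = 1L,
                                alpha = 0,
                                beta = c(sesi = log(0.92),
                                         pct_immigrant = log(1.003),
                                         pct_indigenous = log(1.01)),
                                sigma2_u = 0.05, sigma2_eta = 0.1,
                                sigma2_gamma = 0.01, sigma2_phi = 0.02,
                                phi_truth = NULL,
                                total_cases = 3200,
                                mean_region_pop = 12000,
                                high_risk_regions = NULL,
                                high_risk_multiplier = 2,
                                subsite_props = c(0.31, 0.49, 0.20),
                                seed = 1L) {
  if (nrows < 2L && ncols < 2L) stop("lattice must be at least 2 x 2")
  if (any(c(sigma2_u, sigma2_eta, sigma2_gamma, sigma2_phi) < 0)) {
    stop("variance components must be >= 0")
  }
  if (!is.null(beta) && length(beta) && is.null(names(beta))) {
    stop("beta must be a named vector")
  }
  if (!is.null(phi_truth) && length(phi_truth) != n_periods) {
    stop("phi_truth length must equal n_periods")
  }
  if (abs(sum(subsite_props) - 1) > 1e-8 || any(subsite_props < 0)) {
    stop("subsite_props must be non-negative and sum to 1")
  }
  structure(list(nrows = as.integer(nrows), ncols = as.integer(ncols),
                 n_periods = as.integer(n_periods), alpha = alpha,
                 beta = beta, sigma2_u = sigma2_u, sigma2_eta = sigma2_eta,
                 sigma2_gamma = sigma2_gamma, sigma2_phi = sigma2_phi,
                 phi_truth = phi_truth, total_cases = total_cases,
                 mean_region_pop = mean_region_pop,
                 high_risk_regions = high_risk_regions,
                 high_risk_multiplier = high_risk_multiplier,
                 subsite_props = subsite_props, seed = as.integer(seed)),
            class = "simulation_scenario")
}

# age-incidence shape over the 12 bands: negligible under 35, rising
# steeply, modal at 75-79, easing in the oldest bands
age_rate_profile <- function() {
  c(0.3, 0.7, 1.2, 2.2, 4, 7, 11, 15, 18, 20, 17, 12)
}

# population age shares: broad working-age base thinning with age
age_pop_shares <- function() {
  w <- c(42, 7, 7, 7, 7, 6.5, 6, 5, 4.5, 3.5, 2.5, 2)
  w / sum(w)
}

#' Generate a synthetic cancer registry
#'
#' Runs the scenario generatively: draws stratum populations, region
#' covariates, spatial and temporal random effects, builds the true region
#' (x period) relative-risk surface, draws stratum case counts
#' \eqn{y_{ijkt} \sim Poisson(n_{ijk}\, r_{jkt}\, \lambda_{it})}, and
#' explodes them into line-list case records with topography codes assigned
#' by the configured sub-site mix. Everything needed for recovery testing is
#' returned in \code{truth}.
#'
#' @param scenario a \code{\link{simulation_scenario}}
#' @return list with \code{cases} (line-list data.frame), \code{populations}
#'   (stratum data.frame), \code{covariates} (\code{covariate_table}),
#'   \code{graph} (\code{region_graph}), \code{period_scheme}, and
#'   \code{truth} (all latent quantities)
#' @export
simulate_registry <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  sc <- scenario
  with_seed(sc$seed, {
    graph <- make_lattice(sc$nrows, sc$ncols)
    n <- graph$n
    ids <- graph$region_ids
    T <- sc$n_periods
    ages <- age_group_labels()

    # --- covariates: smooth SESI, patchy percentage covariates with a
    #     smooth component (immigrants urban-clustered, Indigenous share
    #     spatially blocked) ---
    ses_field <- simulate_structured_field(graph, 1)
    sesi <- 5 + 2 * ses_field / max(stats::sd(ses_field), 1e-12)
    imm_field <- simulate_structured_field(graph, 1)
    pct_imm <- 100 * stats::plogis(-2 + imm_field + stats::rnorm(n, 0, 0.8))
    ind_field <- simulate_structured_field(graph, 1)
    pct_ind <- 100 * stats::plogis(-1.5 + 1.5 * ind_field + stats::rnorm(n, 0, 0.5))
    covariates <- assemble_covariates(stats::setNames(sesi, ids),
                                      stats::setNames(pct_imm, ids),
                                      stats::setNames(pct_ind, ids), ids)

    # --- stratum populations (held constant over periods) ---
    region_pop <- stats::rlnorm(n, log(sc$mean_region_pop) - 0.3^2 / 2, 0.3)
    shares <- age_pop_shares()
    populations <- do.call(rbind, lapply(seq_len(n), function(i) {
      do.call(rbind, lapply(c("M", "F"), function(sx) {
        data.frame(region_id = ids[i], sex = sx, age_group = ages,
                   count = round(region_pop[i] * 0.5 * shares))
      }))
    }))
    rownames(populations) <- NULL

    # --- latent effects and true risk ---
    u <- stats::rnorm(n, 0, sqrt(sc$sigma2_u))
    eta <- simulate_structured_field(graph, sc$sigma2_eta)
    if (T >= 2L) {
      gamma <- stats::rnorm(T, 0, sqrt(sc$sigma2_gamma))
      if (!is.null(sc$phi_truth)) {
        phi <- sc$phi_truth - mean(sc$phi_truth)
      } else if (sc$sigma2_phi > 0) {
        phi <- cumsum(c(0, stats::rnorm(T - 1L, 0, sqrt(sc$sigma2_phi))))
        phi <- phi - mean(phi)
      } else {
        phi <- numeric(T)
      }
    } else {
      gamma <- phi <- numeric(0)
    }
    xb <- numeric(n)
    if (!is.null(sc$beta) && length(sc$beta)) {
      for (nm in names(sc$beta)) {
        if (!nm %in% names(covariates)) stop("unknown covariate in beta: ", nm)
        xb <- xb + sc$beta[[nm]] * covariates[[nm]]
      }
    }
    log_risk <- sc$alpha + xb + u + eta
    if (!is.null(sc$high_risk_regions)) {
      log_risk[sc$high_risk_regions] <- log_risk[sc$high_risk_regions] +
        log(sc$high_risk_multiplier)
    }
    risk <- matrix(exp(log_risk), n, max(T, 1L))
    if (T >= 2L) {
      risk <- risk * matrix(exp(gamma + phi), n, T, byrow = TRUE)
    }

    # --- baseline stratum rates scaled to the target case total ---
    sex_mult <- c(M = 1.6, F = 1)           # male excess typical of GC
    prof <- age_rate_profile()
    raw <- outer(prof, sex_mult)            # 12 x 2 unnormalized rates
    pop_mat <- matrix(0, 12L, 2L, dimnames = list(ages, c("M", "F")))
    for (sx in c("M", "F")) {
      for (k in seq_along(ages)) {
        pop_mat[k, sx] <- sum(populations$count[populations$sex == sx &
                                                populations$age_group == ages[k]])
      }
    }
    scale_fac <- sc$total_cases / (max(T, 1L) * sum(raw * pop_mat))
    rate_jk <- raw * scale_fac              # per-period stratum rates

    # --- period scheme ---
    period_scheme <- if (T == 5L) {
      default_period_scheme()
    } else {
      lapply(seq_len(max(T, 1L)), function(t) c(1992L + 5L * (t - 1L),
                                                1996L + 5L * (t - 1L)))
    }
    labs <- period_labels(period_scheme)

    # --- stratum counts and line-list explosion ---
    topo_nc <- c("C161", "C162", "C163", "C164", "C165", "C166", "C168")
    case_list <- list()
    for (t in seq_len(max(T, 1L))) {
      yrs <- seq(period_scheme[[t]][1L], period_scheme[[t]][2L])
      for (sx in c("M", "F")) {
        for (k in seq_along(ages)) {
          nij <- populations$count[populations$sex == sx &
                                   populations$age_group == ages[k]]
          # populations rows are ordered region-major; realign by region id
          names(nij) <- populations$region_id[populations$sex == sx &
                                              populations$age_group == ages[k]]
          nij <- nij[ids]
          mu <- nij * rate_jk[k, sx] * risk[, t]
          yy <- stats::rpois(n, mu)
          tot <- sum(yy)
          if (tot > 0L) {
            reg <- rep(ids, yy)
            topo <- character(tot)
            cls <- sample.int(3L, tot, replace = TRUE, prob = sc$subsite_props)
            topo[cls == 1L] <- "C160"
            topo[cls == 2L] <- sample(topo_nc, sum(cls == 2L), replace = TRUE)
            topo[cls == 3L] <- "C169"
            case_list[[length(case_list) + 1L]] <-
              data.frame(region_id = reg, sex = sx, age_group = ages[k],
                         year = sample(yrs, tot, replace = TRUE),
                         topography = topo)
          }
        }
      }
    }
    cases <- if (length(case_list)) {
      do.call(rbind, case_list)
    } else {
      data.frame(region_id = character(0), sex = character(0),
                 age_group = character(0), year = integer(0),
                 topography = character(0))
    }
    rownames(cases) <- NULL
    if (nrow(cases) < 10L) {
      warning("fewer than 10 simulated cases; downstream fits will be degenerate")
    }

    # true (design-based) expected counts: population x baseline rate, no
    # risk surface and no internal standardization
    E_true <- matrix(0, n, max(T, 1L))
    for (sx in c("M", "F")) {
      for (k in seq_along(ages)) {
        nij <- populations$count[populations$sex == sx &
                                 populations$age_group == ages[k]]
        names(nij) <- populations$region_id[populations$sex == sx &
                                            populations$age_group == ages[k]]
        E_true[, 1L] <- E_true[, 1L] + nij[ids] * rate_jk[k, sx]
      }
    }
    if (T >= 2L) E_true[, 2:T] <- E_true[, 1L]

    list(cases = cases, populations = populations, covariates = covariates,
         graph = graph, period_scheme = period_scheme,
         truth = list(alpha = sc$alpha, beta = sc$beta, u = u, eta = eta,
                      gamma = gamma, phi = phi, risk = risk,
                      periods = if (T >= 2L) labs else NULL,
                      rate_jk = rate_jk, E_true = E_true,
                      high_risk_regions = sc$high_risk_regions,
                      scenario = sc))
  })
}

#' Count table with the generator's true expected counts
#'
#' Aggregates the simulated cases into observed counts and pairs them with
#' the design-based expected counts \eqn{E_{it} = \sum_{jk} n_{ijk} r_{jk}}
#' (stratum population times true baseline rate). Unlike internal
#' standardization, these E do not absorb the simulated risk surface, so
#' every planted effect — including a global temporal trend — remains
#' identifiable; this is the input for parameter-recovery checks.
#'
#' @param sim result of \code{\link{simulate_registry}}
#' @return a \code{count_table} (region x period when the scenario has
#'   \code{n_periods >= 2})
#' @export
counts_from_truth <- function(sim) {
  T <- ncol(sim$truth$E_true)
  if (T >= 2L) {
    ct <- aggregate_counts(sim$cases, region_ids(sim$graph),
                           period_scheme = sim$period_scheme)
  } else {
    ct <- aggregate_counts(sim$cases, region_ids(sim$graph))
  }
  new_count_table(ct$region_ids, ct$Y, sim$truth$E_true,
                  periods = ct$periods,
                  stratum = list(sex = "all", subsite = "all",
                                 expected_set = TRUE, design_based = TRUE))
}

#' Write a simulated registry to the pipeline's CSV dialects
#'
#' Emits \code{cases.csv}, \code{populations.csv}, \code{covariates.csv},
#' \code{edges.csv} and \code{truth.json} into \code{dir}.
#'
#' @param sim result of \code{\link{simulate_registry}}
#' @param dir output directory (created if missing)
#' @return named vector of file paths, invisibly
#' @export
write_registry <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cases = file.path(dir, "cases.csv"),
             populations = file.path(dir, "populations.csv"),
             covariates = file.path(dir, "covariates.csv"),
             edges = file.path(dir, "edges.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(sim$cases, paths["cases"], row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$populations, paths["populations"], row.names = FALSE,
                   quote = FALSE)
  write_covariates_csv(sim$covariates, paths["covariates"])
  write_edge_csv(sim$graph, paths["edges"])
  truth <- sim$truth
  truth$scenario <- unclass(truth$scenario)
  truth$risk <- as.data.frame(truth$risk)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
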