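#' Covariate incidence-risk-ratio table
#'
#' Per covariate, the posterior median and equal-tailed 95% credible interval
#' of \eqn{\exp(\beta)} across pooled post-burn-in chains. The median is used
#' (rather than the mean) because it is equivariant under the exp transform.
#'
#' @param draws a \code{posterior_draws}
#' @param covariates covariate names (default: all in the fit)
#' @return data.frame \code{covariate, IRR, lower95, upper95, significant}
#'   where \code{significant} flags intervals excluding 1
#' @export
irr_summary <- function(draws, covariates = NULL) {
  stopifnot(inherits(draws, "posterior_draws"))
  covariates <- covariates %||% draws$covariate_names
  unknown <- setdiff(covariates, draws$covariate_names)
  if (length(unknown)) {
    stop("unknown covariate name(s): ", paste(unknown, collapse = ", "))
  }
  rows <- lapply(covariates, function(cv) {
    b <- param_draws(draws, paste0("beta[", cv, "]"))
    # quantiles on the log scale, then exponentiated: exact transform
    # equivariance (flipping beta's sign inverts and swaps the bounds)
    q <- exp(stats::quantile(b, c(0.5, 0.025, 0.975), names = FALSE))
    data.frame(covariate = cv, IRR = q[1L], lower95 = q[2L],
               upper95 = q[3L],
               significant = q[2L] > 1 | q[3L] < 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Smoothed district-specific relative risks
#'
#' Per region, the posterior median and 95% credible interval of the
#' combined spatial random effect \eqn{\exp(u_i + \eta_i)}; for
#' spatio-temporal fits, optionally per period as
#' \eqn{\exp(u_i + \eta_i + \gamma_t + \phi_t)}. A region is flagged
#' \code{elevated} when its 95% interval lies entirely above 1
#' (exceedance-style rule).
#'
#' @param draws a \code{posterior_draws}
#' @param temporal if TRUE (requires a spatio-temporal fit) one row per
#'   region x period; default FALSE gives the purely spatial surface
#' @return data.frame \code{region_id[, period], risk_median, lower95,
#'   upper95, elevated}
#' @export
smoothed_region_risk <- function(draws, temporal = FALSE) {
  stopifnot(inherits(draws, "posterior_draws"))
  if (temporal && !draws$temporal) {
    stop("temporal risk surface requested from a purely spatial fit")
  }
  ids <- draws$region_ids
  risk_rows <- function(logrisk, id, period = NULL) {
    q <- exp(stats::quantile(logrisk, c(0.5, 0.025, 0.975), names = FALSE))
    out <- data.frame(region_id = id, risk_median = q[1L], lower95 = q[2L],
                      upper95 = q[3L], elevated = q[2L] > 1)
    if (!is.null(period)) {
      out <- cbind(out[1L], period = period, out[-1L])
    }
    out
  }
  spatial_log <- lapply(ids, function(id) {
    param_draws(draws, paste0("u[", id, "]")) +
      param_draws(draws, paste0("eta[", id, "]"))
  })
  if (!temporal) {
    out <- do.call(rbind, Map(risk_rows, spatial_log, ids))
  } else {
    periods <- draws$periods
    out <- do.call(rbind, unlist(lapply(seq_along(periods), function(t) {
      gt <- param_draws(draws, paste0("gamma[", t, "]")) +
        param_draws(draws, paste0("phi[", t, "]"))
      Map(risk_rows, lapply(spatial_log, `+`, gt), ids,
          MoreArgs = list(period = periods[t]))
    }), recursive = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Categorize region risks for choropleth legends
#'
#' Bins posterior median risks into ordered categories, either by quantiles
#' (default: quintiles) or at fixed breakpoints, and returns the per-category
#' counts used in map legends. Ties at a boundary go to the lower category.
#'
#' @param values finite numeric vector (one per region)
#' @param scheme \code{"quantile"} or \code{"fixed"}
#' @param n_categories number of quantile bins (quantile scheme)
#' @param breaks strictly increasing interior breakpoints (fixed scheme;
#'   k breakpoints yield k + 1 categories)
#' @return list with \code{category} (integer label per region, 1 = lowest
#'   risk) and \code{counts} (per-category tally, summing to
#'   \code{length(values)})
#' @export
categorize_risk <- function(values, scheme = c("quantile", "fixed"),
                            n_categories = 5L, breaks = NULL) {
  scheme <- match.arg(scheme)
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("non-finite risk value")
  if (scheme == "quantile") {
    if (length(values) < n_categories) {
      stop("need at least as many regions as categories")
    }
    qs <- stats::quantile(values, probs = seq_len(n_categories - 1L) / n_categories,
                          names = FALSE)
    cuts <- unique(qs)
    cat <- 1L + vapply(values, function(v) sum(v > cuts), integer(1))
    k <- n_categories
  } else {
    if (is.null(breaks) || length(breaks) == 0L) stop("fixed scheme needs breaks")
    if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
    cat <- 1L + vapply(values, function(v) sum(v > breaks), integer(1))
    k <- length(breaks) + 1L
  }
  counts <- tabulate(cat, nbins = k)
  names(counts) <- paste0("cat", seq_len(k))
  list(category = cat, counts = counts)
}

#' Write summary tables to CSV
#'
#' \code{write_irr_csv} writes \code{covariate,IRR,lower95,upper95};
#' \code{write_risk_csv} writes
#' \code{region_id[,period],risk_median,lower95,upper95,category,elevated}.
#'
#' @param x summary data.frame from \code{\link{irr_summary}} or
#'   \code{\link{smoothed_region_risk}}
#' @param path output path
#' @param categories optional result of \code{\link{categorize_risk}} to
#'   attach a \code{category} column (risk tables only)
#' @export
write_irr_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_irr_csv
#' @export
write_risk_csv <- function(x, path, categories = NULL) {
  if (!is.null(categories)) x$category <- categories$category
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
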