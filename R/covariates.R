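#' Socio-economic score index by single-factor analysis
#'
#' Builds a one-dimensional socio-economic index from region-level income,
#' employment and education indicators: indicators are z-standardized, a
#' single-factor loading vector is extracted from their correlation matrix by
#' the iterated principal-factor method (communalities on the diagonal,
#' leading eigenpair, iterate until the communalities move by less than
#' \code{tol}), and scores are the loading-weighted sum of the standardized
#' indicators. The loading sign is fixed so that income loads positively:
#' a higher score always means better socio-economic status.
#'
#' Because the indicators are z-standardized first, the scores are invariant
#' to any affine rescaling of an input column (e.g. income in dollars vs
#' thousands of dollars).
#'
#' @param indicators data.frame or matrix with one row per region and the
#'   indicator columns (default expectation: \code{income, employment,
#'   education}); a \code{region_id} column, if present, is carried through.
#' @param rescale optional numeric length-2 vector; when given, scores are
#'   affinely mapped so that their min/max hit these endpoints exactly.
#' @param tol convergence tolerance on the communalities (default 1e-8)
#' @param max_iter iteration cap for the principal-factor loop (default 500)
#' @return numeric vector of scores (named by region id when available), with
#'   attributes \code{loadings} and \code{communalities}.
#' @examples
#' set.seed(1)
#' z <- rnorm(20)
#' ind <- data.frame(income = 2 * z + 1, employment = -3 * z, education = z)
#' s <- compute_sesi(ind)
#' cor(s, ind$income)  # positive by sign convention
#' @export
compute_sesi <- function(indicators, rescale = NULL, tol = 1e-8,
                         max_iter = 500L) {
  ind <- as.data.frame(indicators)
  ids <- NULL
  if ("region_id" %in% names(ind)) {
    ids <- as.character(ind$region_id)
    ind$region_id <- NULL
  }
  X <- as.matrix(ind)
  storage.mode(X) <- "double"
  if (nrow(X) < 4L) stop("need at least 4 regions for factor extraction")
  if (ncol(X) < 2L) stop("need at least 2 indicator columns")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant indicator column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  }
  Z <- scale(X)
  R <- stats::cor(X)

  # iterated principal factor: leading eigenpair of R with communalities on
  # the diagonal, iterated to a fixed point
  h2 <- 1 - 1 / pmax(diag(solve_or_fallback(R)), 1)   # SMC start, clipped
  loadings <- NULL
  for (iter in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    es <- eigen(Rr, symmetric = TRUE)
    lambda1 <- max(es$values[1L], 0)
    v1 <- es$vectors[, 1L]
    loadings <- v1 * sqrt(lambda1)
    h2_new <- pmin(loadings^2, 1)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      break
    }
    h2 <- h2_new
  }

  # sign convention: income (first column if unnamed) loads positively
  anchor <- if ("income" %in% colnames(X)) which(colnames(X) == "income") else 1L
  if (loadings[anchor] < 0) loadings <- -loadings

  scores <- as.numeric(Z %*% loadings)
  if (!is.null(rescale)) {
    stopifnot(length(rescale) == 2L, rescale[1L] < rescale[2L])
    rng <- range(scores)
    if (rng[1L] == rng[2L]) stop("degenerate scores cannot be rescaled")
    scores <- rescale[1L] + (scores - rng[1L]) / diff(rng) * diff(rescale)
  }
  if (!is.null(ids)) names(scores) <- ids
  attr(scores, "loadings") <- stats::setNames(loadings, colnames(X))
  attr(scores, "communalities") <- stats::setNames(h2, colnames(X))
  scores
}

solve_or_fallback <- function(R) {
  # SMC starting communalities need R^{-1}; for (near-)singular R fall back
  # to an identity start, which the iteration then refines
  out <- tryCatch(solve(R), error = function(e) NULL)
  if (is.null(out)) diag(1e6, nrow(R)) else out
}

#' Assemble the region-level covariate table
#'
#' Aligns the socio-economic index and the immigrant / Indigenous population
#' percentages to the graph's region order.
#'
#' @param sesi named numeric vector (names = region ids) or data.frame with
#'   \code{region_id, sesi}
#' @param pct_immigrant,pct_indigenous named numeric vectors or data.frames
#'   (\code{region_id, value}); percentages must lie in [0, 100]
#' @param regions ordered region ids (typically \code{region_ids(graph)})
#' @param center logical; when TRUE the three covariate columns are
#'   mean-centered (recorded in the \code{centered} attribute)
#' @return data.frame of class \code{covariate_table} with columns
#'   \code{region_id, sesi, pct_immigrant, pct_indigenous}, rows in graph
#'   order
#' @export
assemble_covariates <- function(sesi, pct_immigrant, pct_indigenous, regions,
                                center = FALSE) {
  regions <- as.character(regions)
  sesi <- align_named(sesi, "sesi", regions)
  imm <- align_named(pct_immigrant, "pct_immigrant", regions)
  ind <- align_named(pct_indigenous, "pct_indigenous", regions)
  for (v in list(imm, ind)) {
    if (any(v < 0 | v > 100)) stop("percentage outside [0, 100]")
  }
  if (any(!is.finite(sesi))) stop("non-finite sesi value")
  out <- data.frame(region_id = regions, sesi = sesi,
                    pct_immigrant = imm, pct_indigenous = ind,
                    row.names = NULL)
  if (center) {
    for (cn in c("sesi", "pct_immigrant", "pct_indigenous")) {
      out[[cn]] <- out[[cn]] - mean(out[[cn]])
    }
  }
  attr(out, "centered") <- center
  class(out) <- c("covariate_table", "data.frame")
  out
}

align_named <- function(x, what, regions) {
  if (is.data.frame(x)) {
    if (!"region_id" %in% names(x)) stop(what, ": data.frame needs a region_id column")
    valcol <- setdiff(names(x), "region_id")[1L]
    x <- stats::setNames(x[[valcol]], as.character(x$region_id))
  }
  if (is.null(names(x))) {
    if (length(x) != length(regions)) stop(what, ": unnamed vector of wrong length")
    return(as.numeric(x))
  }
  miss <- setdiff(regions, names(x))
  if (length(miss)) stop(what, ": missing region(s): ", paste(miss, collapse = ", "))
  as.numeric(x[regions])
}

#' Read / write covariate CSV (\code{region_id,sesi,pct_immigrant,pct_indigenous})
#' @param path CSV file path
#' @param regions ordered region ids to align to
#' @export
read_covariates_csv <- function(path, regions) {
  df <- utils::read.csv(path, colClasses = c(region_id = "character"))
  assemble_covariates(stats::setNames(df$sesi, df$region_id),
                      stats::setNames(df$pct_immigrant, df$region_id),
                      stats::setNames(df$pct_indigenous, df$region_id),
                      regions)
}

#' @rdname read_covariates_csv
#' @param covariates a \code{covariate_table}
#' @export
write_covariates_csv <- function(covariates, path) {
  utils::write.csv(covariates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
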