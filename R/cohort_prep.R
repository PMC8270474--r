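#' @useDynLib dismap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Canonical age-group labels (12 bands, <35 to 85+)
#' @export
age_group_labels <- function() {
  c("<35", "35-39", "40-44", "45-49", "50-54", "55-59",
    "60-64", "65-69", "70-74", "75-79", "80-84", "85+")
}

#' Valid ICD-O-3 stomach topography codes
#'
#' The nine stomach sub-site codes; C167 does not exist in ICD-O-3 stomach
#' coding.
#' @export
topography_codes <- function() {
  c("C160", "C161", "C162", "C163", "C164", "C165", "C166", "C168", "C169")
}

#' Default five-year period scheme, 1992-2016
#' @export
default_period_scheme <- function() {
  list(c(1992L, 1996L), c(1997L, 2001L), c(2002L, 2006L),
       c(2007L, 2011L), c(2012L, 2016L))
}

period_labels <- function(scheme) {
  vapply(scheme, function(iv) paste0(iv[1L], "-", iv[2L]), character(1))
}

#' Classify a stomach topography code by sub-site
#'
#' C160 (gastro-esophageal cardia) is cardia disease; C161-C166 and C168 (the
#' distal sub-sites and overlapping lesions) are non-cardia; C169 is
#' site-unspecified. Vectorized.
#'
#' @param topography character vector of ICD-O-3 codes
#' @return character vector in \code{c("cardia", "non_cardia", "unspecified")}
#' @examples
#' classify_subsite(c("C160", "C163", "C169"))
#' @export
classify_subsite <- function(topography) {
  topography <- toupper(as.character(topography))
  bad <- setdiff(unique(topography), topography_codes())
  if (length(bad)) stop("invalid topography code(s): ", paste(bad, collapse = ", "))
  out <- rep("non_cardia", length(topography))
  out[topography == "C160"] <- "cardia"
  out[topography == "C169"] <- "unspecified"
  out
}

#' Assign diagnosis years to periods
#'
#' @param year integer vector of diagnosis years
#' @param period_scheme list of \code{c(start, end)} integer intervals
#'   (inclusive, disjoint); defaults to the five-year scheme 1992-2016.
#' @return character vector of period labels \code{"start-end"}
#' @export
bin_period <- function(year, period_scheme = default_period_scheme()) {
  year <- as.integer(year)
  labs <- period_labels(period_scheme)
  starts <- vapply(period_scheme, function(iv) as.numeric(iv[1L]), numeric(1))
  ends <- vapply(period_scheme, function(iv) as.numeric(iv[2L]), numeric(1))
  if (any(ends < starts)) stop("period interval with end < start")
  o <- order(starts)
  for (k in seq_along(o)[-1L]) {
    if (starts[o[k]] <= ends[o[k - 1L]]) stop("period intervals overlap")
  }
  idx <- rep(NA_integer_, length(year))
  for (k in seq_along(period_scheme)) {
    idx[year >= starts[k] & year <= ends[k]] <- k
  }
  if (anyNA(idx)) {
    stop("year(s) outside all periods: ",
         paste(unique(year[is.na(idx)]), collapse = ", "))
  }
  labs[idx]
}

validate_cases <- function(cases) {
  need <- c("region_id", "sex", "age_group", "year", "topography")
  missing_cols <- setdiff(need, names(cases))
  if (length(missing_cols)) stop("cases missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(cases$sex %in% c("M", "F"))) stop("sex must be coded M/F")
  bad_age <- setdiff(unique(cases$age_group), age_group_labels())
  if (length(bad_age)) stop("unknown age_group label(s): ", paste(bad_age, collapse = ", "))
  classify_subsite(cases$topography)  # errors on invalid codes
  invisible(cases)
}

validate_populations <- function(populations) {
  need <- c("region_id", "sex", "age_group", "count")
  missing_cols <- setdiff(need, names(populations))
  if (length(missing_cols)) stop("populations missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(populations$count < 0)) stop("negative population count")
  key <- paste(populations$region_id, populations$sex, populations$age_group)
  if (anyDuplicated(key)) stop("duplicate (region, sex, age_group) population strata")
  invisible(populations)
}

filter_cases <- function(cases, sex = NULL, subsite = NULL) {
  keep <- rep(TRUE, nrow(cases))
  if (!is.null(sex)) {
    stopifnot(sex %in% c("M", "F"))
    keep <- keep & cases$sex == sex
  }
  if (!is.null(subsite)) {
    stopifnot(subsite %in% c("cardia", "non_cardia", "unspecified"))
    keep <- keep & classify_subsite(cases$topography) == subsite
  }
  cases[keep, , drop = FALSE]
}

new_count_table <- function(region_ids, Y, E, periods = NULL,
                            reference_rates = NULL, stratum = list()) {
  Y <- as.matrix(Y); E <- as.matrix(E)
  stopifnot(nrow(Y) == length(region_ids), all(dim(Y) == dim(E)))
  if (any(Y < 0) || any(Y != round(Y))) stop("Y must hold non-negative integers")
  if (any(!is.finite(E)) || any(E < 0)) stop("E must be finite and non-negative")
  colnames(Y) <- colnames(E) <- periods %||% "all"
  structure(list(region_ids = as.character(region_ids), Y = Y, E = E,
                 periods = periods, reference_rates = reference_rates,
                 stratum = stratum),
            class = "count_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.count_table <- function(x, ...) {
  cat("count_table:", length(x$region_ids), "regions",
      if (!is.null(x$periods)) paste0("x ", length(x$periods), " periods") else "",
      "\n  total Y =", sum(x$Y), " total E =", format(sum(x$E)), "\n")
  if (length(x$stratum)) {
    cat("  stratum:", paste(names(x$stratum), unlist(x$stratum),
                            sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.count_table <- function(x, ...) {
  if (is.null(x$periods)) {
    data.frame(region_id = x$region_ids, Y = x$Y[, 1L], E = x$E[, 1L],
               row.names = NULL)
  } else {
    do.call(rbind, lapply(seq_along(x$periods), function(t) {
      data.frame(region_id = x$region_ids, period = x$periods[t],
                 Y = x$Y[, t], E = x$E[, t], row.names = NULL)
    }))
  }
}

#' Aggregate line-list case records into per-region observed counts
#'
#' Counts filtered records per region \eqn{Y_i = \sum_j \sum_k y_{ijk}}
#' (and per period when a scheme is supplied). Regions without cases get 0.
#'
#' @param cases data.frame with columns
#'   \code{region_id, sex, age_group, year, topography}
#' @param regions ordered region id vector (typically
#'   \code{region_ids(graph)})
#' @param sex optional filter, \code{"M"} or \code{"F"}
#' @param subsite optional filter, one of
#'   \code{"cardia"}, \code{"non_cardia"}, \code{"unspecified"}
#' @param period_scheme optional list of year intervals; when given, Y is a
#'   region x period matrix
#' @return a \code{count_table} with observed counts only (E set to NA-free
#'   zeros is avoided: E is filled with 0 and flagged unset in the stratum
#'   metadata)
#' @export
aggregate_counts <- function(cases, regions, sex = NULL, subsite = NULL,
                             period_scheme = NULL) {
  validate_cases(cases)
  regions <- as.character(regions)
  unknown <- setdiff(unique(cases$region_id), regions)
  if (length(unknown)) stop("case(s) in unknown region(s): ", paste(unknown, collapse = ", "))
  cases <- filter_cases(cases, sex, subsite)
  if (is.null(period_scheme)) {
    Y <- table(factor(cases$region_id, levels = regions))
    Y <- matrix(as.integer(Y), ncol = 1L)
    periods <- NULL
  } else {
    labs <- period_labels(period_scheme)
    per <- bin_period(cases$year, period_scheme)
    Y <- table(factor(cases$region_id, levels = regions),
               factor(per, levels = labs))
    Y <- matrix(as.integer(Y), nrow = length(regions))
    periods <- labs
  }
  new_count_table(regions, Y, E = matrix(0, nrow(Y), ncol(Y)), periods = periods,
                  stratum = list(sex = sex %||% "all",
                                 subsite = subsite %||% "all",
                                 expected_set = FALSE))
}

reference_rates_from <- function(cases, populations) {
  # pooled internal reference rates y_jk / n_jk over sex x age strata
  strata <- expand.grid(sex = sort(unique(populations$sex)),
                        age_group = age_group_labels(),
                        stringsAsFactors = FALSE)
  ykey <- paste(cases$sex, cases$age_group)
  nkey <- paste(populations$sex, populations$age_group)
  skey <- paste(strata$sex, strata$age_group)
  y_jk <- as.numeric(table(factor(ykey, levels = skey)))
  n_jk <- vapply(skey, function(k) sum(populations$count[nkey == k]), numeric(1))
  bad <- y_jk > 0 & n_jk == 0
  if (any(bad)) {
    stop("stratum with cases but zero population: ", paste(skey[bad], collapse = "; "))
  }
  rate <- ifelse(n_jk > 0, y_jk / n_jk, 0)   # 0/0 -> 0 by convention
  cbind(strata, y_jk = y_jk, n_jk = n_jk, rate = rate)
}

#' Indirectly standardized expected counts
#'
#' Internal indirect age-sex standardization: pooled reference rates
#' \eqn{y_{jk}/n_{jk}} are computed from the analysed cases themselves and
#' applied to each region's stratum populations,
#' \eqn{E_i = \sum_j \sum_k (y_{jk}/n_{jk}) n_{ijk}}. By construction
#' \eqn{\sum_i E_i = \sum_i Y_i}. Sex/sub-site filters are applied to cases
#' and (for sex) populations before rates are formed, so each stratified
#' analysis is standardized within its own stratum.
#'
#' @inheritParams aggregate_counts
#' @param populations data.frame with columns
#'   \code{region_id, sex, age_group, count}; every case region must have
#'   population rows
#' @return a \code{count_table} with both Y and E filled and the reference
#'   rates attached
#' @examples
#' pops <- data.frame(region_id = rep(c("A", "B"), each = 2),
#'                    sex = "M",
#'                    age_group = rep(c("60-64", "70-74"), 2),
#'                    count = c(100, 50, 100, 150))
#' cases <- data.frame(region_id = c(rep("A", 6), rep("B", 6)),
#'                     sex = "M",
#'                     age_group = rep(c("60-64", "70-74"), c(4, 8)),
#'                     year = 1995, topography = "C169")
#' ct <- expected_counts(cases, pops, c("A", "B"))
#' as.data.frame(ct)
#' @export
expected_counts <- function(cases, populations, regions, sex = NULL,
                            subsite = NULL) {
  validate_populations(populations)
  ct <- aggregate_counts(cases, regions, sex = sex, subsite = subsite)
  cases <- filter_cases(validate_cases(cases), sex, subsite)
  pops <- populations
  if (!is.null(sex)) pops <- pops[pops$sex == sex, , drop = FALSE]
  rates <- reference_rates_from(cases, pops)
  E <- expected_from_rates(rates, pops, ct$region_ids)
  new_count_table(ct$region_ids, ct$Y, E, periods = NULL,
                  reference_rates = rates,
                  stratum = list(sex = sex %||% "all",
                                 subsite = subsite %||% "all",
                                 expected_set = TRUE))
}

expected_from_rates <- function(rates, populations, regions) {
  rkey <- paste(rates$sex, rates$age_group)
  pkey <- paste(populations$sex, populations$age_group)
  prate <- rates$rate[match(pkey, rkey)]
  prate[is.na(prate)] <- 0
  contrib <- populations$count * prate
  E <- vapply(regions,
              function(r) sum(contrib[populations$region_id == r]),
              numeric(1))
  matrix(E, ncol = 1L)
}

#' Period-stratified expected counts
#'
#' Reference rates are recomputed within each period from that period's case
#' totals against the (assumed constant) stratum populations, so
#' \eqn{\sum_i E_{it} = \sum_i Y_{it}} holds separately per period.
#'
#' @inheritParams expected_counts
#' @param period_scheme list of year intervals (default: the five-year
#'   scheme)
#' @return a \code{count_table} with region x period Y and E
#' @export
expected_counts_by_period <- function(cases, populations, regions,
                                      period_scheme = default_period_scheme(),
                                      sex = NULL, subsite = NULL) {
  validate_populations(populations)
  ct <- aggregate_counts(cases, regions, sex = sex, subsite = subsite,
                         period_scheme = period_scheme)
  cases <- filter_cases(validate_cases(cases), sex, subsite)
  pops <- populations
  if (!is.null(sex)) pops <- pops[pops$sex == sex, , drop = FALSE]
  labs <- period_labels(period_scheme)
  case_period <- if (nrow(cases)) bin_period(cases$year, period_scheme) else character(0)
  E <- matrix(0, length(ct$region_ids), length(labs))
  rates <- vector("list", length(labs))
  names(rates) <- labs
  for (t in seq_along(labs)) {
    sub <- cases[case_period == labs[t], , drop = FALSE]
    rates[[t]] <- reference_rates_from(sub, pops)
    E[, t] <- expected_from_rates(rates[[t]], pops, ct$region_ids)
  }
  new_count_table(ct$region_ids, ct$Y, E, periods = labs,
                  reference_rates = rates,
                  stratum = list(sex = sex %||% "all",
                                 subsite = subsite %||% "all",
                                 expected_set = TRUE))
}

#' Drop regions whose expected count is zero
#'
#' A region with \eqn{E_i = 0} (in any period) contributes a Poisson mean
#' identically zero and cannot be fit; such regions are removed with a
#' warning before modelling.
#'
#' @param ct a \code{count_table}
#' @param graph optional \code{region_graph} to subset consistently
#' @return list with elements \code{counts} (pruned table) and \code{graph}
#'   (pruned graph, or NULL if none supplied)
#' @export
drop_zero_expected <- function(ct, graph = NULL) {
  stopifnot(inherits(ct, "count_table"))
  bad <- apply(ct$E, 1L, function(e) any(e <= 0))
  if (any(bad)) {
    warning("dropping ", sum(bad), " region(s) with zero expected count: ",
            paste(utils::head(ct$region_ids[bad], 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ..." else "")
    keep <- which(!bad)
    ct <- new_count_table(ct$region_ids[keep],
                          ct$Y[keep, , drop = FALSE],
                          ct$E[keep, , drop = FALSE],
                          periods = ct$periods,
                          reference_rates = ct$reference_rates,
                          stratum = ct$stratum)
    if (!is.null(graph)) graph <- subset_graph(graph, keep)
  }
  list(counts = ct, graph = graph)
}

subset_graph <- function(g, keep_idx) {
  ids <- g$region_ids[keep_idx]
  keep_edge <- g$edges[, 1L] %in% keep_idx & g$edges[, 2L] %in% keep_idx
  edges <- g$edges[keep_edge, , drop = FALSE]
  build_adjacency(cbind(g$region_ids[edges[, 1L]], g$region_ids[edges[, 2L]]),
                  ids)
}

#' Read cases / populations CSV files
#'
#' \code{read_cases_csv} expects columns
#' \code{region_id,sex,age_group,year,topography};
#' \code{read_populations_csv} expects
#' \code{region_id,sex,age_group,count}.
#'
#' @param path CSV file path
#' @return validated data.frame
#' @export
read_cases_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(region_id = "character",
                                             sex = "character",
                                             age_group = "character",
                                             topography = "character"))
  df$year <- as.integer(df$year)
  validate_cases(df)
  df
}

#' @rdname read_cases_csv
#' @export
read_populations_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = c(region_id = "character",
                                             sex = "character",
                                             age_group = "character"))
  df$count <- as.numeric(df$count)
  validate_populations(df)
  df
}

#' Write a count_table to CSV (\code{region_id[,period],Y,E})
#' @param ct a \code{count_table}
#' @param path output path
#' @export
write_counts_csv <- function(ct, path) {
  utils::write.csv(as.data.frame(ct), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
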