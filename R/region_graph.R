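#' Build a binary contiguity graph over analysis regions
#'
#' Constructs the first-order contiguity structure used by both the intrinsic
#' CAR prior and Moran's I. Weights are strictly binary (\eqn{w_{ij} = 1} when
#' regions i and j share a boundary, 0 otherwise); no row standardization is
#' applied anywhere downstream. Region order is fixed here and shared by every
#' downstream vector: alignment is by position against \code{region_ids(g)}.
#'
#' @param edge_records two-column matrix or data.frame of region-id pairs, one
#'   undirected edge per row. Duplicate rows and reversed duplicates collapse
#'   to a single edge.
#' @param region_ids ordered vector of unique region identifiers. Every edge
#'   endpoint must appear here. Regions absent from all edges are kept and
#'   flagged as islands (degree 0).
#' @return an object of class \code{region_graph}: a list with elements
#'   \code{region_ids}, \code{edges} (two-column integer index matrix, i < j),
#'   \code{nb} (per-region integer neighbor index list), \code{degrees},
#'   \code{s0} (aggregate weight \eqn{S_0 = \sum_i \sum_j w_{ij}}, i.e. twice
#'   the edge count), \code{n}, and \code{islands} (indices of degree-0
#'   regions).
#' @examples
#' g <- build_adjacency(cbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
#' degrees(g)
#' @export
build_adjacency <- function(edge_records, region_ids) {
  region_ids <- as.character(region_ids)
  if (length(region_ids) == 0L) stop("region_ids must be non-empty")
  if (anyDuplicated(region_ids)) {
    stop("duplicate region id(s): ",
         paste(unique(region_ids[duplicated(region_ids)]), collapse = ", "))
  }
  if (is.data.frame(edge_records)) edge_records <- as.matrix(edge_records)
  if (is.null(edge_records) || length(edge_records) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  } else {
    if (ncol(edge_records) != 2L) stop("edge_records must have two columns")
    a <- match(as.character(edge_records[, 1L]), region_ids)
    b <- match(as.character(edge_records[, 2L]), region_ids)
    if (anyNA(a) || anyNA(b)) {
      bad <- unique(c(edge_records[is.na(a), 1L], edge_records[is.na(b), 2L]))
      stop("unknown region id(s) in edge list: ", paste(bad, collapse = ", "))
    }
    if (any(a == b)) {
      stop("self-loop edge(s) not allowed: ",
           paste(unique(region_ids[a[a == b]]), collapse = ", "))
    }
    lo <- pmin(a, b); hi <- pmax(a, b)
    keep <- !duplicated(cbind(lo, hi))
    edges <- cbind(lo[keep], hi[keep])
  }
  new_region_graph(region_ids, edges)
}

new_region_graph <- function(region_ids, edges) {
  n <- length(region_ids)
  nb <- vector("list", n)
  for (i in seq_len(n)) nb[[i]] <- integer(0)
  if (nrow(edges) > 0L) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1L]; j <- edges[r, 2L]
      nb[[i]] <- c(nb[[i]], j)
      nb[[j]] <- c(nb[[j]], i)
    }
    nb <- lapply(nb, sort)
  }
  degrees <- lengths(nb)
  g <- structure(
    list(region_ids = region_ids,
         edges = edges,
         nb = nb,
         degrees = degrees,
         s0 = 2L * nrow(edges),
         n = n,
         islands = which(degrees == 0L)),
    class = "region_graph")
  validate_region_graph(g)
  g
}

#' Validate the internal consistency of a region_graph
#'
#' Checks symmetry of the neighbor lists, absence of self-loops, and the
#' identity \eqn{S_0 = 2 |E|}. Called by the constructor; exported so that
#' deserialized or hand-built graphs can be checked too.
#'
#' @param g a \code{region_graph}
#' @return \code{g}, invisibly; errors on any violation.
#' @export
validate_region_graph <- function(g) {
  stopifnot(inherits(g, "region_graph"))
  n <- g$n
  if (length(g$nb) != n || length(g$degrees) != n) stop("neighbor structure length mismatch")
  if (nrow(g$edges) > 0L) {
    if (any(g$edges < 1L) || any(g$edges > n)) stop("edge endpoint outside region_ids")
    if (any(g$edges[, 1L] == g$edges[, 2L])) stop("self-loop present")
  }
  for (i in seq_len(n)) {
    for (j in g$nb[[i]]) {
      if (j == i) stop("self-loop in neighbor set of ", g$region_ids[i])
      if (!(i %in% g$nb[[j]])) stop("asymmetric adjacency between ",
                                    g$region_ids[i], " and ", g$region_ids[j])
    }
  }
  if (g$s0 != 2L * nrow(g$edges)) stop("s0 != 2 * number of edges")
  if (g$s0 != sum(g$degrees)) stop("s0 != sum of degrees")
  invisible(g)
}

#' @export
print.region_graph <- function(x, ...) {
  cat("region_graph:", x$n, "regions,", nrow(x$edges), "edges (S0 =", x$s0, ")\n")
  if (length(x$islands)) {
    cat("  islands (degree 0):",
        paste(x$region_ids[x$islands], collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname build_adjacency
#' @export
region_ids <- function(g) {
  stopifnot(inherits(g, "region_graph"))
  g$region_ids
}

#' @rdname build_adjacency
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "region_graph"))
  stats::setNames(g$degrees, g$region_ids)
}

#' Connected components of a contiguity graph
#'
#' Labels regions by connected component (breadth-first search). The component
#' count enters the intrinsic CAR precision update through its rank
#' \eqn{n - c}, and isolated regions each form their own component.
#'
#' @param g a \code{region_graph}
#' @return integer vector of component labels (1-based, in order of first
#'   appearance), named by region id.
#' @export
connected_components <- function(g) {
  stopifnot(inherits(g, "region_graph"))
  n <- g$n
  labels <- integer(n)
  comp <- 0L
  for (start in seq_len(n)) {
    if (labels[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    labels[start] <- comp
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in g$nb[[v]]) {
        if (labels[w] == 0L) {
          labels[w] <- comp
          queue <- c(queue, w)
        }
      }
    }
  }
  stats::setNames(labels, g$region_ids)
}

n_components <- function(g) max(connected_components(g))

#' Read an undirected edge list from CSV
#'
#' Expects a header and two columns (\code{region_i,region_j}), one undirected
#' edge per row.
#'
#' @param path CSV file path
#' @param region_ids ordered region ids passed through to
#'   \code{\link{build_adjacency}}
#' @return a \code{region_graph}
#' @export
read_edge_csv <- function(path, region_ids) {
  df <- utils::read.csv(path, colClasses = "character")
  if (ncol(df) < 2L) stop("edge CSV needs two columns (region_i, region_j)")
  build_adjacency(df[, 1:2], region_ids)
}

#' Read a GAL-format spatial weights file
#'
#' Parses the legacy GAL text format: a first line giving the number of
#' regions (possibly preceded by other header tokens, as written by several
#' tools; the last-but-one token is taken as n when the line has more than one
#' token and the count is the second token per the classic dialect \code{0 n
#' name key}), followed by one header line per region (\code{id k}) and a line
#' of its k neighbor ids.
#'
#' @param path GAL file path
#' @return a \code{region_graph} over the ids listed in the file, in file
#'   order.
#' @export
read_gal <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GAL file")
  hdr <- strsplit(trimws(lines[[1L]]), "[[:space:]]+")[[1L]]
  n <- if (length(hdr) == 1L) as.integer(hdr) else as.integer(hdr[[2L]])
  if (is.na(n) || n < 1L) stop("cannot parse region count from GAL header")
  ids <- character(n)
  nb_ids <- vector("list", n)
  cursor <- 2L
  for (i in seq_len(n)) {
    if (cursor > length(lines)) stop("truncated GAL file")
    head_i <- strsplit(trimws(lines[[cursor]]), "[[:space:]]+")[[1L]]
    if (length(head_i) != 2L) stop("malformed GAL region header: ", lines[[cursor]])
    ids[i] <- head_i[[1L]]
    k <- as.integer(head_i[[2L]])
    cursor <- cursor + 1L
    if (k > 0L) {
      if (cursor > length(lines)) stop("truncated GAL file")
      nb_ids[[i]] <- strsplit(trimws(lines[[cursor]]), "[[:space:]]+")[[1L]]
      if (length(nb_ids[[i]]) != k) stop("neighbor count mismatch for region ", ids[i])
      cursor <- cursor + 1L
    } else {
      nb_ids[[i]] <- character(0)
    }
  }
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (length(nb_ids[[i]])) cbind(ids[i], nb_ids[[i]]) else NULL
  }))
  build_adjacency(edges, ids)
}

#' Write a region_graph as an edge-list CSV
#'
#' @param g a \code{region_graph}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_edge_csv <- function(g, path) {
  stopifnot(inherits(g, "region_graph"))
  df <- data.frame(region_i = g$region_ids[g$edges[, 1L]],
                   region_j = g$region_ids[g$edges[, 2L]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
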