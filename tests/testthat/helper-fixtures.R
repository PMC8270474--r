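# shared fixtures, built in code

# random connected-ish graph: lattice with a few random extra/deleted edges
random_graph <- function(n_max = 150L) {
  nr <- sample(2:12, 1L)
  nc <- sample(2:12, 1L)
  g <- make_lattice(nr, nc)
  ids <- region_ids(g)
  em <- cbind(ids[g$edges[, 1L]], ids[g$edges[, 2L]])
  # delete a few edges at random (possibly disconnecting the graph)
  if (nrow(em) > 4L) {
    em <- em[-sample(nrow(em), sample(0:3, 1L)), , drop = FALSE]
  }
  build_adjacency(em, ids)
}

# dense-matrix Moran's I oracle: literal O(n^2) double loop over w_ij
moran_oracle <- function(values, graph) {
  n <- graph$n
  W <- matrix(0, n, n)
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges[e, 1L]; j <- graph$edges[e, 2L]
    W[i, j] <- 1; W[j, i] <- 1
  }
  yc <- values - mean(values)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * yc[i] * yc[j]
  (n / sum(W)) * num / sum(yc^2)
}

# tiny line-list builder
make_cases <- function(region_id, sex = "M", age_group = "60-64",
                       year = 1995L, topography = "C169") {
  n <- length(region_id)
  data.frame(region_id = region_id, sex = rep_len(sex, n),
             age_group = rep_len(age_group, n), year = rep_len(year, n),
             topography = rep_len(topography, n),
             stringsAsFactors = FALSE)
}

# the two-region worked example: populations A=(100,50), B=(100,150),
# stratum case totals (4, 8)
two_region_example <- function() {
  pops <- data.frame(region_id = rep(c("A", "B"), each = 2),
                     sex = "M",
                     age_group = rep(c("60-64", "70-74"), 2),
                     count = c(100, 50, 100, 150))
  cases <- make_cases(c(rep("A", 4), rep("A", 2), rep("B", 6)),
                      age_group = c(rep("60-64", 4), rep("70-74", 8)))
  list(cases = cases, pops = pops, regions = c("A", "B"))
}

quiet_fit <- function(...) suppressWarnings(fit_spatial(...))
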