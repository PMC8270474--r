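test_that("rook lattice adjacency has the expected degrees and S0", {
  g <- build_adjacency(rbind(c(1, 2), c(3, 4), c(1, 3), c(2, 4)),
                       c(1, 2, 3, 4))
  expect_equal(unname(degrees(g)), rep(2L, 4))
  expect_equal(g$s0, 8L)
  expect_identical(g, validate_region_graph(g))
})

test_that("duplicate and reversed edges collapse; symmetry holds", {
  g <- build_adjacency(rbind(c("A", "B"), c("B", "A"), c("A", "B")),
                       c("A", "B"))
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$s0, 2L)
})

test_that("islands are kept and flagged, bad inputs rejected", {
  g <- build_adjacency(rbind(c("A", "B")), c("A", "B", "C"))
  expect_equal(unname(degrees(g)), c(1L, 1L, 0L))
  expect_equal(region_ids(g)[g$islands], "C")
  expect_error(build_adjacency(rbind(c("A", "A")), c("A", "B")), "self-loop")
  expect_error(build_adjacency(rbind(c("A", "Z")), c("A", "B")), "Z")
  expect_error(build_adjacency(rbind(c("A", "B")), c("A", "B", "A")),
               "duplicate")
})

test_that("connected components match definitions on small graphs", {
  g1 <- build_adjacency(rbind(c("A", "B"), c("B", "C")), c("A", "B", "C"))
  expect_equal(max(connected_components(g1)), 1L)
  g2 <- build_adjacency(rbind(c("A", "B")), c("A", "B", "C", "D"))
  expect_equal(max(connected_components(g2)), 3L)
  expect_equal(unname(connected_components(g2)[c("A", "B")]), c(1L, 1L))
})

test_that("component labels agree with an igraph oracle on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(42)
  for (rep in 1:100) {
    g <- random_graph()
    labs <- connected_components(g)
    ig <- igraph::graph_from_edgelist(
      cbind(g$edges[, 1L], g$edges[, 2L]), directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0L, g$n - igraph::vcount(ig)))
    oracle <- igraph::components(ig)$membership
    # same partition (label names may differ)
    expect_equal(max(labs), max(oracle))
    expect_true(all(tapply(oracle, labs, function(v) length(unique(v))) == 1L))
  }
})

test_that("edge-list CSV and GAL round-trips preserve the graph", {
  g <- make_lattice(3, 3)
  csv <- tempfile(fileext = ".csv")
  write_edge_csv(g, csv)
  g2 <- read_edge_csv(csv, region_ids(g))
  expect_equal(g2$edges, g$edges)
  gal <- tempfile(fileext = ".gal")
  writeLines(c("9",
               unlist(lapply(seq_len(g$n), function(i) {
                 c(paste(region_ids(g)[i], g$degrees[i]),
                   paste(region_ids(g)[g$nb[[i]]], collapse = " "))
               }))), gal)
  g3 <- read_gal(gal)
  expect_equal(g3$edges, g$edges)
  expect_equal(region_ids(g3), region_ids(g))
})
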