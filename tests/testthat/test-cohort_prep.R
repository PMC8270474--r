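test_that("sub-site classification partitions the nine topography codes", {
  expect_equal(classify_subsite("C160"), "cardia")
  expect_equal(classify_subsite("C169"), "unspecified")
  expect_equal(classify_subsite("C163"), "non_cardia")
  cls <- classify_subsite(topography_codes())
  expect_equal(sum(cls == "cardia"), 1L)
  expect_equal(sum(cls == "unspecified"), 1L)
  expect_equal(sum(cls == "non_cardia"), 7L)
  expect_error(classify_subsite("C167"), "C167")
})

test_that("years map to the default five-year periods", {
  expect_equal(bin_period(1996), "1992-1996")
  expect_equal(bin_period(2012), "2012-2016")
  expect_equal(bin_period(c(1992, 1997, 2006)),
               c("1992-1996", "1997-2001", "2002-2006"))
  expect_error(bin_period(1991), "1991")
  expect_error(bin_period(2000, list(c(1992, 1996), c(1995, 2001))),
               "overlap")
})

test_that("aggregate_counts counts filtered records per region and period", {
  cases <- make_cases(c("A", "A", "A"))
  ct <- aggregate_counts(cases, c("A", "B"))
  expect_equal(unname(ct$Y[, 1]), c(3L, 0L))

  mixed <- make_cases(rep("A", 3), topography = c("C160", "C160", "C169"))
  ct_cardia <- aggregate_counts(mixed, c("A"), subsite = "cardia")
  expect_equal(sum(ct_cardia$Y), 2L)

  spread <- make_cases(rep("A", 5), year = c(1992, 1999, 2005, 2010, 2016))
  ct_per <- aggregate_counts(spread, "A", period_scheme = default_period_scheme())
  expect_equal(ncol(ct_per$Y), 5L)
  expect_equal(sum(ct_per$Y), 5L)
  expect_error(aggregate_counts(make_cases("Z"), c("A", "B")), "Z")
})

test_that("expected counts reproduce the hand-computed standardization", {
  ex <- two_region_example()
  ct <- expected_counts(ex$cases, ex$pops, ex$regions)
  expect_equal(unname(ct$E[, 1]), c(4, 8))
  expect_equal(sum(ct$E), sum(ct$Y))
  rates <- ct$reference_rates
  expect_equal(sort(rates$rate[rates$rate > 0]), c(0.02, 0.04))
})

test_that("equal populations spread E evenly however cases cluster", {
  pops <- data.frame(region_id = rep(c("A", "B"), each = 1),
                     sex = "M", age_group = "60-64", count = c(100, 100))
  cases <- make_cases(rep("A", 6))
  ct <- expected_counts(cases, pops, c("A", "B"))
  expect_equal(unname(ct$Y[, 1]), c(6L, 0L))
  expect_equal(unname(ct$E[, 1]), c(3, 3))
})

test_that("zero-case strata contribute zero and data errors are caught", {
  pops <- data.frame(region_id = "A", sex = "M", age_group = "60-64",
                     count = 100)
  ct <- expected_counts(make_cases(character(0)), pops, "A")
  expect_equal(sum(ct$E), 0)
  # cases in a stratum with no population
  expect_error(
    expected_counts(make_cases("A", age_group = "85+"), pops, "A"),
    "zero population")
})

test_that("per-period standardization conserves within each period", {
  ex <- two_region_example()
  ex$cases$year <- rep(c(1994, 2003), 6)
  scheme <- default_period_scheme()
  ct <- expected_counts_by_period(ex$cases, ex$pops, ex$regions, scheme)
  expect_equal(colSums(ct$E), colSums(ct$Y) + 0, ignore_attr = TRUE)
  # hand check: period 1 holds half the cases, same stratum split (2, 4)
  expect_equal(unname(ct$E[, 1]), c(2, 4))
  # partition: per-period Y sums region-wise to the unstratified table
  ct_all <- aggregate_counts(ex$cases, ex$regions)
  expect_equal(rowSums(ct$Y), ct_all$Y[, 1], ignore_attr = TRUE)
})

test_that("regions with zero expected count are dropped with a warning", {
  pops <- data.frame(region_id = c("A", "B"), sex = "M",
                     age_group = "60-64", count = c(100, 0))
  ct <- expected_counts(make_cases("A"), pops, c("A", "B"))
  g <- build_adjacency(rbind(c("A", "B")), c("A", "B"))
  expect_warning(pruned <- drop_zero_expected(ct, g), "zero expected")
  expect_equal(pruned$counts$region_ids, "A")
  expect_equal(pruned$graph$n, 1L)
})

test_that("cases and populations CSV round-trip with validation", {
  ex <- two_region_example()
  cf <- tempfile(fileext = ".csv"); pf <- tempfile(fileext = ".csv")
  write.csv(ex$cases, cf, row.names = FALSE)
  write.csv(ex$pops, pf, row.names = FALSE)
  expect_equal(nrow(read_cases_csv(cf)), nrow(ex$cases))
  expect_equal(nrow(read_populations_csv(pf)), nrow(ex$pops))
  bad <- ex$cases; bad$sex[1] <- "X"
  write.csv(bad, cf, row.names = FALSE)
  expect_error(read_cases_csv(cf), "M/F")
})
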