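test_that("range partition uses half-open quartiles with D closed at 1", {
  f <- partition_ranges(c(0.1, 0.3, 0.6, 0.9))
  expect_identical(as.character(f), c("A", "B", "C", "D"))
  expect_identical(as.numeric(attr(f, "counts")), rep(1, 4))
  expect_identical(as.character(partition_ranges(c(0.25, 0.5, 0.75, 1.0))),
                   c("B", "C", "D", "D"))
  expect_identical(as.character(partition_ranges(0)), "A")
  expect_error(partition_ranges(c(0.5, 1.2)), "normalized")
  set.seed(1)
  x <- runif(500)
  expect_identical(sum(attr(partition_ranges(x), "counts")), 500L)
})

test_that("residue groups cover the alphabet disjointly", {
  g <- residue_groups()
  expect_length(g, 20)
  expect_identical(sort(unique(g)), 1:5)
  expect_identical(unname(g[c("F", "Y", "W")]), rep(1L, 3))
  expect_identical(unname(g[c("C", "I", "L", "V")]), rep(2L, 4))
  expect_identical(unname(g[c("D", "E", "K", "R")]), rep(5L, 4))
})

test_that("composition percentages are exact and sum to 100 per range", {
  peps <- c("FFFFF", "AAAAA", "ACDEF")
  ranges <- factor(c("D", "A", "B"), levels = c("A", "B", "C", "D"))
  comp <- composition_by_range(peps, ranges)
  expect_equal(comp["F", "D"], 100)
  expect_equal(comp["A", "A"], 100)
  expect_equal(comp["F", "B"], 20)
  filled <- colSums(comp[, c("A", "B", "D")])
  expect_true(all(abs(filled - 100) < 1e-9))

  per_pos <- composition_by_range(peps, ranges, per_position = TRUE)
  expect_identical(dim(per_pos), c(20L, 5L, 4L))
  expect_equal(per_pos["F", 1, "D"], 100)
  expect_true(all(abs(colSums(per_pos[, , "B"]) - 100) < 1e-9))
})

test_that("uniform random peptides give near-uniform composition", {
  set.seed(2)
  peps <- replicate(10000, paste(sample(apscreen_vocabulary()[1:20], 5,
                                        replace = TRUE), collapse = ""))
  ranges <- factor(rep("C", 10000), levels = c("A", "B", "C", "D"))
  comp <- composition_by_range(peps, ranges)
  expect_true(all(abs(comp[, "C"] - 5) < 1))
})

test_that("net side-chain charge counts K/R against D/E", {
  expect_identical(net_side_chain_charge(c("NRMMR", "DMGID", "GGGGG")),
                   c(2L, -2L, 0L))
  expect_identical(net_side_chain_charge("HHHHH"), 0L)
  expect_identical(net_side_chain_charge("KRKRD"), 3L)
})

test_that("published transfer rows reproduce their averages and filters", {
  rec <- transfer_records(table1$pen1, table1$pen2, table1$ap_pen1,
                          table1$ap_pen2, table1$ap_deca, table1$ap_mixpen)
  expect_equal(round_report(rec$ap_avepen), table1$ap_avepen)
  expect_equal(round_report(rec$delta_deca[1]), 0.512)
  expect_equal(round_report(rec$delta_mix[1]), 0.465)
  # all five rows pass the selection filter used to build the table
  out <- transfer_analysis(rec, min_deca = 1.5, min_delta = 0.4)
  expect_identical(nrow(out$selected), 5L)
  # every pair combines opposite net charges
  expect_true(all(rec$charge1 * rec$charge2 < 0))
})

test_that("transfer summaries handle degenerate all-zero deltas", {
  rec <- transfer_records(c("AAAAA", "CCCCC"), c("GGGGG", "TTTTT"),
                          c(1.25, 1.0), c(1.75, 1.5), c(1.5, 1.25),
                          c(1.5, 1.25))
  out <- transfer_analysis(rec)
  expect_equal(out$frac_mix_positive, 0)
  expect_equal(out$median_delta_mix, 0)
  expect_identical(nrow(out$selected), 0L)
})

test_that("top tables order by delta then sequence", {
  rec <- transfer_records(c("CCCCC", "AAAAA", "GGGGG"),
                          c("MMMMM", "MMMMM", "MMMMM"),
                          c(1, 1, 1), c(1, 1, 1),
                          c(1.2, 1.2, 1.4), c(1.5, 1.5, 1.1))
  top <- transfer_analysis(rec)$top_mix
  expect_identical(top$pen1, c("AAAAA", "CCCCC", "GGGGG"))
})
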