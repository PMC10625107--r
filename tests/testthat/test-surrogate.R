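test_that("degenerate parameters collapse the surrogate to its base", {
  p <- surrogate_params(position_weights = matrix(0, 20, 10), pair_bonus = 0,
                        charge_penalty = 0, mix_boost = 0, noise_sd = 0,
                        base = 1.0)
  expect_equal(surrogate_ap(c("NRMMR", "FFFFF", "AAAAA+CCCCC"), p),
               rep(1.0, 3))
})

test_that("labels are deterministic given seed and order-independent", {
  systems <- lhs_sample(5, 50, seed = 2)
  a <- surrogate_ap(systems, seed = 7)
  b <- surrogate_ap(systems, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, surrogate_ap(systems, seed = 8)))
  # counter-based noise: a system keeps its label when evaluated alone
  i <- 23L
  expect_equal(surrogate_ap(systems[i], seed = 7, indices = i), a[i])
})

test_that("opposite-charge mixing raises AP above the component mean", {
  p <- surrogate_params(noise_sd = 0)
  pos <- "KRAAA"  # +2
  neg <- "DEAAA"  # -2
  neu <- "AAAAA"
  mean_ap <- mean(surrogate_ap(c(pos, neg), p))
  mix_ap <- surrogate_ap(paste(pos, neg, sep = "+"), p)
  expect_equal(mix_ap - mean_ap, p$mix_boost * 4, tolerance = 1e-12)
  # same-sign and neutral mixtures get no boost
  expect_equal(surrogate_ap(paste(neu, pos, sep = "+"), p),
               mean(surrogate_ap(c(neu, pos), p)))
})

test_that("labelled datasets stay in the clipped AP range with provenance", {
  systems <- lhs_sample(5, 400, seed = 5)
  ds <- label_dataset(systems, seed = 5)
  expect_identical(nrow(ds), 400L)
  expect_true(all(is.finite(ds$ap)))
  expect_true(all(ds$ap >= 0.8 & ds$ap <= 2.6))
  expect_identical(attr(ds, "provenance")$seed, 5)
  expect_identical(label_dataset(systems, seed = 5)$ap, ds$ap)
})

test_that("per-position effects are recovered exactly on a factorial space", {
  seqs <- enumerate_space(3)
  p <- additive_params()
  labels <- surrogate_ap(seqs, p, seed = 0)
  est <- fit_position_weights(seqs, labels)
  truth <- p$position_weights[, 1:3]
  truth <- sweep(truth, 2, colMeans(truth))
  expect_lt(max(abs(est - truth)), 1e-9)
})

test_that("transfer fixtures plant the exact mixing boost at zero noise", {
  p <- surrogate_params(noise_sd = 0)
  rec <- make_transfer_fixture(60, p, seed = 3, opposite_frac = 0.7)
  expect_identical(nrow(rec), 60L)
  opp <- rec$charge1 * rec$charge2 < 0
  expect_equal(rec$delta_mix[opp],
               p$mix_boost * abs(rec$charge1[opp]) * abs(rec$charge2[opp]),
               tolerance = 1e-12)
  expect_equal(rec$delta_mix[!opp], rep(0, sum(!opp)))
  expect_equal(rec$ap_avepen, (rec$ap_pen1 + rec$ap_pen2) / 2)
})

test_that("aromatic-rich peptides sit at the top of the surrogate ordering", {
  p <- surrogate_params(noise_sd = 0)
  groups <- list(aromatic = c("FFFFF", "YYYYY", "WWWWW", "FYWFY"),
                 hydrophobic = c("IIIII", "LLLLL", "VVVVV", "CILVC"),
                 polar = c("HHHHH", "SSSSS", "TTTTT"),
                 charged = c("DDDDD", "KKKKK", "RRRRR", "GGGGG", "AAAAA"))
  means <- vapply(groups, function(g) mean(surrogate_ap(g, p)), numeric(1))
  expect_true(means["aromatic"] > means["hydrophobic"])
  expect_true(means["hydrophobic"] > means["polar"])
  expect_true(means["polar"] > means["charged"])
})
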