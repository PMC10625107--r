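test_that("peptide validation enforces alphabet and length", {
  expect_equal(peptide("nrmmr"), "NRMMR")
  expect_error(peptide("NRMMB"), "invalid residue")
  expect_error(peptide(""), "length")
  expect_error(peptide(strrep("A", 11)), "length")
})

test_that("mixed systems are order-insensitive with exactly two components", {
  expect_equal(peptide_system("DMGID+NRMMR"), peptide_system("NRMMR+DMGID"))
  expect_equal(peptide_system("NRMMR+DMGID", canonical = FALSE),
               "NRMMR+DMGID")
  expect_error(peptide_system("A+C+G"), "exactly two")
  expect_true(is_mixed("NRMMR+DMGID"))
  expect_false(is_mixed("NRMMR"))
})

test_that("sequence-space cardinalities follow 20^n and unordered pairing", {
  expect_identical(space_size(1), 20)
  expect_identical(space_size(5), 3.2e6)
  expect_identical(space_size(10), 20^10)
  expect_identical(space_size(5, mixed = TRUE), 5120001600000)
  n <- space_size(2)
  expect_identical(space_size(2, mixed = TRUE), n * (n + 1) / 2)
  expect_error(space_size(0), "length")
  expect_error(space_size(11), "length")
})

test_that("Latin-hypercube draws stratify residues exactly per position", {
  s <- lhs_sample(5, 20, seed = 3)
  m <- do.call(rbind, strsplit(s, ""))
  for (p in 1:5)
    expect_true(all(table(factor(m[, p], levels = apscreen_vocabulary()[1:20]))
                    == 1L))
  expect_length(lhs_sample(4, 1, seed = 0), 1)
  expect_identical(lhs_sample(5, 50, seed = 9), lhs_sample(5, 50, seed = 9))
})

test_that("enumeration is lexicographic and complete", {
  expect_identical(enumerate_space(1), apscreen_vocabulary()[1:20])
  expect_identical(enumerate_space(2, limit = 3), c("AA", "AC", "AD"))
  it <- space_iterator(3, chunk_size = 1357)
  total <- 0
  seen_first <- NULL
  repeat {
    chunk <- it()
    if (is.null(chunk)) break
    if (is.null(seen_first)) seen_first <- chunk[1]
    total <- total + length(chunk)
  }
  expect_identical(seen_first, "AAA")
  expect_identical(total, space_size(3))
})

test_that("tokenization pads with placeholders and round-trips", {
  tok <- tokenize_systems("NRMMR", 10)
  expect_identical(dim(tok), c(1L, 10L))
  pad_id <- match("_", apscreen_vocabulary())
  expect_identical(as.integer(tok[1, 6:10]), rep(pad_id, 5L))
  expect_identical(detokenize_systems(tok), "NRMMR")

  mix <- tokenize_systems("NRMMR+DMGID", 11)
  expect_identical(apscreen_vocabulary()[mix[1, 6]], "+")
  expect_identical(detokenize_systems(mix), "NRMMR+DMGID")

  expect_error(tokenize_systems("NRMMR+DMGID", 10), "exceeds")
})

test_that("swap augmentation duplicates labels and skips self-pairs", {
  out <- augment_mixed(c("AAAAA+CCCCC", "GGGGG+GGGGG"), labels = c(1.2, 1.5))
  expect_identical(nrow(out), 3L)
  expect_identical(out$system[3], "CCCCC+AAAAA")
  expect_identical(out$label[3], 1.2)
  expect_error(augment_mixed("AAAAA"), "mixed")

  set.seed(1)
  pens <- replicate(30, paste(sample(apscreen_vocabulary()[1:20], 5,
                                     replace = TRUE), collapse = ""))
  systems <- paste(pens[1:15], pens[16:30], sep = "+")
  systems[1] <- paste(pens[1], pens[1], sep = "+")
  aug <- augment_mixed(systems)
  n_self <- sum(vapply(strsplit(systems, "+", fixed = TRUE),
                       function(p) p[1] == p[2], logical(1)))
  expect_identical(nrow(aug), 2L * length(systems) - n_self)
})
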