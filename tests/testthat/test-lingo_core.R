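test_that("normalize_smiles zeroes ring digits only when asked", {
  expect_equal(normalize_smiles("C1CCCCC1"), "C1CCCCC1")
  expect_equal(normalize_smiles("C1CCCCC1", ring_digit_zeroing = TRUE),
               "C0CCCCC0")
  # digits inside bracket atoms are isotope/charge labels, not ring closures
  expect_equal(normalize_smiles("[13C]C1CC1", ring_digit_zeroing = TRUE),
               "[13C]C0CC0")
  expect_equal(normalize_smiles("c1ccc2ccccc2c1", ring_digit_zeroing = TRUE),
               "c0ccc0ccccc0c0")
})

test_that("fragment yields all sliding windows with offset 1", {
  s13 <- distinct_window_smiles13()
  expect_length(fragment(s13, 4L), 10L)  # l - 3 windows for l = 13
  expect_equal(fragment("CCCC"), "CCCC")
  expect_equal(fragment("CCO"), character(0))
  expect_equal(fragment(""), character(0))
  expect_equal(fragment("ABCDE", 2L), c("AB", "BC", "CD", "DE"))
})

test_that("pack_score matches the byte-packing oracle and is injective", {
  expect_identical(pack_score("CCCC"), 1128481603L)
  expect_identical(pack_score("0000"), 808464432L)
  set.seed(42)
  grams <- unique(vapply(1:200, function(i) random_string(4L), character(1)))
  scores <- pack_score(grams)
  expect_equal(as.numeric(scores), vapply(grams, oracle_pack, numeric(1),
                                          USE.NAMES = FALSE))
  expect_false(anyDuplicated(scores) > 0)
  expect_error(pack_score("CC"), "invalid Lingo")
  expect_error(pack_score("CCéC"), "invalid Lingo")
})

test_that("pack_score preserves lexicographic order of 4-grams", {
  set.seed(7)
  grams <- unique(vapply(1:300, function(i) random_string(4L), character(1)))
  # C collation = byte order, which the big-endian packing must replicate
  old <- Sys.getlocale("LC_COLLATE")
  Sys.setlocale("LC_COLLATE", "C")
  on.exit(Sys.setlocale("LC_COLLATE", old))
  expect_equal(order(pack_score(grams)), order(grams))
})

test_that("build_profile reproduces the 13-character worked example", {
  p <- build_profile(distinct_window_smiles13())
  expect_equal(p$length, 13L)
  expect_equal(p$magnitude, 10L)
  expect_true(all(p$numbers == 1L))
  expect_equal(sum(p$numbers), 10L)
})

test_that("build_profile aggregates repeats and handles degenerate input", {
  p <- build_profile("CCCCC")
  expect_equal(p$scores, pack_score("CCCC"))
  expect_equal(p$numbers, 2L)
  expect_equal(p$length, 5L)
  expect_equal(p$magnitude, 1L)

  for (s in c("", "C", "CCO")) {
    p <- build_profile(s)
    expect_equal(p$magnitude, 0L)
    expect_length(p$scores, 0L)
    expect_length(p$numbers, 0L)
    expect_equal(p$length, nchar(s))
  }
})

test_that("build_profile agrees with the associative-map oracle on random strings", {
  set.seed(101)
  for (i in 1:1000) {
    len <- sample(0:300, 1L)
    s <- random_string(len)
    p <- build_profile(s)
    counts <- oracle_qgrams(s, 4L)
    expect_identical(p$magnitude, length(counts))
    expect_identical(sum(p$numbers), sum(counts))
    expect_identical(sum(p$numbers), max(0L, len - 3L))
    if (length(counts)) {
      # sorted scores must equal sorted substrings (order-preserving packing)
      ord <- order(vapply(names(counts), oracle_pack, numeric(1)))
      expect_equal(as.numeric(p$scores),
                   unname(vapply(names(counts)[ord], oracle_pack, numeric(1))))
      expect_equal(p$numbers, unname(counts[ord]))
    }
  }
})

test_that("profiles are invariant in q: sum(numbers) == max(0, l - q + 1)", {
  set.seed(5)
  for (q in c(1L, 2L, 3L, 4L, 5L)) {
    for (i in 1:50) {
      len <- sample(0:40, 1L)
      p <- build_profile(random_string(len), q = q)
      expect_equal(sum(p$numbers), max(0L, len - q + 1L))
      expect_true(p$magnitude <= max(0L, len - q + 1L))
      expect_true(all(diff(p$scores) > 0))
    }
  }
})
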