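test_that("self-comparison yields a symmetric matrix with unit diagonal", {
  lib <- gen_library(5, length_dist = c(8, 40), seed = 14)
  m <- compare_a2a(lib, lib, mcc_config())
  expect_equal(dim(m$values), c(5L, 5L))
  expect_true(all(m$values >= 0 & m$values <= 1))
  expect_equal(m$values, t(m$values))
  expect_equal(unname(diag(m$values)), rep(1, 5))
  expect_equal(m$n_pairs, 25)
})

test_that("a one-compound query gives the one-to-all row vector", {
  db <- gen_library(12, length_dist = c(6, 30), seed = 3)
  q1 <- db[4, , drop = FALSE]
  o2a <- compare_a2a(q1, db, mcc_config())
  full <- compare_a2a(db, db, mcc_config())
  expect_equal(dim(o2a$values), c(1L, 12L))
  expect_equal(o2a$values[1, ], full$values[4, ])
})

test_that("every matrix entry equals the brute-force oracle on a 20x30 sweep", {
  q <- gen_library(20, length_dist = c(2, 60), seed = 21)
  d <- gen_library(30, length_dist = c(2, 60), seed = 22)
  for (mode in c("multiset", "set")) {
    m <- compare_a2a(q, d, mcc_config(mode = mode, n_workers = 3L))
    for (i in seq_len(20)) {
      for (j in seq_len(30)) {
        expect_equal(m$values[i, j],
                     oracle_jaccard(q$smiles[i], d$smiles[j],
                                    multiset = mode == "multiset"),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("results are bit-identical across worker counts, strategies, policies", {
  q <- gen_library(40, length_dist = c(3, 50), seed = 8)
  d <- gen_library(25, length_dist = c(3, 50), seed = 9)
  ref <- compare_a2a(q, d, mcc_config())$values
  for (nw in c(1L, 2L, 4L, 7L)) {
    for (strategy in c("S", "N", "L", "M")) {
      for (policy in c("greedy_lpt", "sorted_round_robin")) {
        m <- compare_a2a(q, d, mcc_config(n_workers = nw, strategy = strategy,
                                          policy = policy))
        expect_identical(m$values, ref)
      }
    }
  }
  # heterogeneous worker weights must not change values either
  m <- compare_a2a(q, d, mcc_config(n_workers = 3L,
                                    worker_weights = c(3, 1, 0.5)))
  expect_identical(m$values, ref)
})

test_that("pair-count instrumentation scales as k * r", {
  q <- gen_library(10, length_dist = c(5, 20), seed = 1)
  d1 <- gen_library(15, length_dist = c(5, 20), seed = 2)
  d2 <- gen_library(30, length_dist = c(5, 20), seed = 2)
  n1 <- compare_a2a(q, d1, mcc_config(n_workers = 2L))$n_pairs
  n2 <- compare_a2a(q, d2, mcc_config(n_workers = 2L))$n_pairs
  expect_equal(n1, 150)
  expect_equal(n2, 300)  # doubling r doubles the comparisons
})

test_that("report_hits filters strictly above threshold with canonical order", {
  lib <- gen_library(15, length_dist = c(10, 40), seed = 55)
  m <- compare_a2a(lib, lib, mcc_config())
  for (thr in c(0, 0.3, 0.85, 1)) {
    hits <- report_hits(m, thr)
    # brute-force reference filter
    ref <- which(m$values > thr, arr.ind = TRUE)
    expect_equal(nrow(hits), nrow(ref))
    if (nrow(hits)) {
      got <- paste(hits$query_id, hits$db_id)
      want <- paste(m$query_ids[ref[, 1]], m$db_ids[ref[, 2]])
      expect_setequal(got, want)
      expect_true(all(hits$tanimoto > thr))
    }
  }
  expect_equal(nrow(report_hits(m, 0)), sum(m$values > 0))
  # strict threshold 1: even identical compounds report nothing
  expect_equal(nrow(report_hits(m, 1)), 0L)
})

test_that("an entry exactly at the threshold is excluded", {
  # A has 17 windows, all distinct; B = A plus three fresh characters has 20
  # windows, the extra three distinct from A's: intersection 17, union 20,
  # so the coefficient is exactly 17/20 = 0.85.
  a <- "CN(O)=P[S]c1#l+n-os2"  # 20 distinct characters -> 17 distinct windows
  b <- paste0(a, "@/\\")
  pa <- build_profile(a)
  pb <- build_profile(b)
  expect_equal(pa$magnitude, 17L)
  expect_equal(pb$magnitude, 20L)
  coeff <- tanimoto(pa, pb)
  expect_identical(coeff, 17 / 20)
  m <- compare_a2a(data.frame(id = "qa", smiles = a),
                   data.frame(id = "db", smiles = b))
  expect_identical(m$values["qa", "db"], 0.85)
  expect_equal(nrow(report_hits(m, 0.85)), 0L)       # "more than" is strict
  expect_equal(nrow(report_hits(m, 0.8499)), 1L)
})

test_that("run_mcc streams the same hits as the materialized path", {
  q <- gen_library(30, length_dist = c(5, 45), seed = 61)
  d <- gen_library(30, length_dist = c(5, 45), seed = 62)
  cfg <- mcc_config(n_workers = 3L, threshold = 0.05)
  streamed <- run_mcc(q, d, cfg)
  materialized <- report_hits(compare_a2a(q, d, cfg), cfg$threshold)
  expect_equal(streamed$hits, materialized, ignore_attr = TRUE)
  expect_equal(streamed$n_pairs, 900)
})

test_that("engine rejects empty inputs and bad configurations", {
  lib <- gen_library(3, seed = 1)
  empty <- lib[0, ]
  expect_error(compare_a2a(empty, lib), "at least one")
  expect_error(compare_a2a(lib, empty), "at least one")
  expect_error(mcc_config(threshold = 1.5), "threshold")
  expect_error(mcc_config(n_workers = 0), "n_workers")
  expect_error(mcc_config(n_workers = 2, worker_weights = c(1, -1)), "weight")
})
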