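#' Engine configuration for a comparison run
#'
#' Bundles every knob of the comparison pipeline. Defaults follow the
#' method's standard operating point: 4-grams, multiset Tanimoto, hit
#' threshold 0.85 (hits are *strictly above* the threshold).
#'
#' @param q q-gram width (default 4).
#' @param mode Similarity interpretation, `"multiset"` (default) or `"set"`.
#' @param strategy Workload measure for partitioning, one of `"M"`
#'   (default), `"S"`, `"N"`, `"L"`; see [workload()].
#' @param policy Partition policy, `"greedy_lpt"` (default) or
#'   `"sorted_round_robin"`; see [partition_workloads()].
#' @param n_workers Number of abstract workers the query is split across
#'   (default 1).
#' @param worker_weights Relative worker capabilities (default all equal).
#' @param threshold Hit-report threshold in `[0, 1]` (default 0.85);
#'   [report_hits()] keeps coefficients strictly greater than this.
#' @param ring_digit_zeroing Passed to [normalize_smiles()] (default off).
#' @return An object of class `mcc_config`.
#' @export
mcc_config <- function(q = 4L, mode = c("multiset", "set"),
                       strategy = c("M", "S", "N", "L"),
                       policy = c("greedy_lpt", "sorted_round_robin"),
                       n_workers = 1L,
                       worker_weights = rep(1, n_workers),
                       threshold = 0.85,
                       ring_digit_zeroing = FALSE) {
  mode <- match.arg(mode)
  strategy <- match.arg(strategy)
  policy <- match.arg(policy)
  if (length(n_workers) != 1L || is.na(n_workers) || n_workers < 1L) {
    stop("n_workers must be a positive integer")
  }
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]")
  }
  if (length(worker_weights) != n_workers || any(worker_weights <= 0)) {
    stop("worker_weights must supply one positive weight per worker")
  }
  structure(
    list(q = as.integer(q), mode = mode, strategy = strategy, policy = policy,
         n_workers = as.integer(n_workers),
         worker_weights = as.numeric(worker_weights),
         threshold = threshold,
         ring_digit_zeroing = isTRUE(ring_digit_zeroing)),
    class = "mcc_config"
  )
}

#' All-to-all (and one-to-all) library comparison
#'
#' Runs the three-phase comparison pipeline over an abstract worker pool:
#'
#' 1. *Preprocessing* — every compound's LINGO profile is built once.
#' 2. *Comparison* — the query compounds are partitioned across
#'    `config$n_workers` workers by the configured workload strategy and
#'    policy (the analogue of splitting the query across devices); each
#'    worker computes its block of rows against the full database via the
#'    sorted-merge Tanimoto kernel.
#' 3. *Merge* — per-worker partial blocks are reassembled into the full
#'    `k x r` matrix in original query order.
#'
#' The result is bit-identical for any worker count, strategy, or policy:
#' partitioning affects scheduling only, never values. A one-compound query
#' gives the one-to-all row vector.
#'
#' @param query,db Compound tables (see [read_smi()]) or character vectors
#'   of SMILES strings; both non-empty.
#' @param config An [mcc_config()].
#' @return An object of class `mcc_matrix`: a list with `values` (`k x r`
#'   numeric matrix of coefficients, dimnames = ids), `query_ids`,
#'   `db_ids`, `n_pairs` (number of pairwise comparisons performed),
#'   `worker_loads` (estimated workload per worker) and `timings`
#'   (per-phase elapsed seconds).
#' @examples
#' lib <- gen_library(5, seed = 1)
#' m <- compare_a2a(lib, lib, mcc_config())
#' diag(m$values)  # all 1 (self-similarity)
#' @export
compare_a2a <- function(query, db, config = mcc_config()) {
  stopifnot(inherits(config, "mcc_config"))
  query <- coerce_library(query, "Q")
  db <- coerce_library(db, "D")
  if (!nrow(query) || !nrow(db)) {
    stop("query and database must each contain at least one compound")
  }

  t0 <- proc.time()[["elapsed"]]
  qprof <- build_profiles(query, q = config$q,
                          ring_digit_zeroing = config$ring_digit_zeroing)
  dprof <- build_profiles(db, q = config$q,
                          ring_digit_zeroing = config$ring_digit_zeroing)
  qflat <- flatten_profiles(qprof)
  dflat <- flatten_profiles(dprof)
  t1 <- proc.time()[["elapsed"]]

  loads <- workloads(qprof, config$strategy)
  part <- partition_workloads(loads, config$n_workers,
                              config$worker_weights, config$policy)

  k <- nrow(query)
  r <- nrow(db)
  values <- matrix(NA_real_, k, r,
                   dimnames = list(query$id, db$id))
  n_pairs <- 0
  for (w in seq_len(config$n_workers)) {
    ix <- part$assignments[[w]]
    if (!length(ix)) next
    block <- cpp_tanimoto_block(qflat$scores, qflat$numbers, qflat$offsets,
                                dflat$scores, dflat$numbers, dflat$offsets,
                                as.integer(ix - 1L),
                                config$mode == "multiset")
    values[ix, ] <- block$values
    n_pairs <- n_pairs + block$n_pairs
  }
  t2 <- proc.time()[["elapsed"]]

  structure(
    list(values = values, query_ids = query$id, db_ids = db$id,
         n_pairs = n_pairs,
         worker_loads = vapply(part$assignments,
                               function(ix) sum(loads[ix]), numeric(1)),
         imbalance = imbalance(part, loads),
         timings = c(preprocess = t1 - t0, compare = t2 - t1)),
    class = "mcc_matrix"
  )
}

#' Report database hits above a similarity threshold
#'
#' The output phase: filters the merged similarity matrix down to the
#' (query, database) pairs whose coefficient is *strictly greater* than the
#' threshold, and orders them by query id, then descending coefficient,
#' then database id. Strictness means an entry exactly equal to the
#' threshold is excluded — in particular, at threshold 1 even identical
#' compounds report no hit.
#'
#' @param matrix An `mcc_matrix` from [compare_a2a()].
#' @param threshold Real in `[0, 1]`, default 0.85.
#' @return A `data.frame` with columns `query_id`, `db_id`, `tanimoto`.
#' @export
report_hits <- function(matrix, threshold = 0.85) {
  stopifnot(inherits(matrix, "mcc_matrix"),
            threshold >= 0, threshold <= 1)
  keep <- which(matrix$values > threshold, arr.ind = TRUE)
  hits <- data.frame(
    query_id = matrix$query_ids[keep[, 1L]],
    db_id = matrix$db_ids[keep[, 2L]],
    tanimoto = matrix$values[keep],
    stringsAsFactors = FALSE
  )
  order_hits(hits)
}

#' Run a full screening: compare, filter, without materializing all rows
#'
#' Memory-bounded variant of [compare_a2a()] + [report_hits()]: processes
#' the query in per-worker blocks and keeps only the above-threshold hits
#' of each block, so the full `k x r` matrix never exists at once. The hit
#' list is identical to `report_hits(compare_a2a(...), threshold)`.
#'
#' @inheritParams compare_a2a
#' @return A list with `hits` (data.frame as from [report_hits()]),
#'   `n_pairs`, `worker_loads`, `imbalance`, `timings`.
#' @export
run_mcc <- function(query, db, config = mcc_config()) {
  stopifnot(inherits(config, "mcc_config"))
  query <- coerce_library(query, "Q")
  db <- coerce_library(db, "D")
  if (!nrow(query) || !nrow(db)) {
    stop("query and database must each contain at least one compound")
  }

  t0 <- proc.time()[["elapsed"]]
  qprof <- build_profiles(query, q = config$q,
                          ring_digit_zeroing = config$ring_digit_zeroing)
  dprof <- build_profiles(db, q = config$q,
                          ring_digit_zeroing = config$ring_digit_zeroing)
  qflat <- flatten_profiles(qprof)
  dflat <- flatten_profiles(dprof)
  t1 <- proc.time()[["elapsed"]]

  loads <- workloads(qprof, config$strategy)
  part <- partition_workloads(loads, config$n_workers,
                              config$worker_weights, config$policy)

  n_pairs <- 0
  pieces <- vector("list", config$n_workers)
  for (w in seq_len(config$n_workers)) {
    ix <- part$assignments[[w]]
    if (!length(ix)) next
    block <- cpp_tanimoto_block(qflat$scores, qflat$numbers, qflat$offsets,
                                dflat$scores, dflat$numbers, dflat$offsets,
                                as.integer(ix - 1L),
                                config$mode == "multiset")
    n_pairs <- n_pairs + block$n_pairs
    keep <- which(block$values > config$threshold, arr.ind = TRUE)
    pieces[[w]] <- data.frame(
      query_id = query$id[ix[keep[, 1L]]],
      db_id = db$id[keep[, 2L]],
      tanimoto = block$values[keep],
      stringsAsFactors = FALSE
    )
  }
  t2 <- proc.time()[["elapsed"]]
  hits <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(query_id = character(0), db_id = character(0),
                       tanimoto = numeric(0), stringsAsFactors = FALSE)
  }
  list(hits = order_hits(hits),
       n_pairs = n_pairs,
       worker_loads = vapply(part$assignments,
                             function(ix) sum(loads[ix]), numeric(1)),
       imbalance = imbalance(part, loads),
       timings = c(preprocess = t1 - t0, compare = t2 - t1))
}

#' @export
print.mcc_matrix <- function(x, ...) {
  cat("<mcc_matrix> ", length(x$query_ids), " query x ",
      length(x$db_ids), " database compounds (",
      format(x$n_pairs, big.mark = ","), " comparisons)\n", sep = "")
  invisible(x)
}

coerce_library <- function(x, prefix) {
  if (is.character(x)) {
    x <- data.frame(id = sprintf("%s%06d", prefix, seq_along(x)),
                    smiles = x, stringsAsFactors = FALSE)
  }
  as_compound_table(x)
}
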