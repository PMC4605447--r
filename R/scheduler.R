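#' Estimate the comparison workload of a compound
#'
#' Four per-compound quantities from the LINGO profile serve as proxies for
#' the cost of comparing that compound against another:
#'
#' * `"S"` — the sum of the profile's unique Lingo scores,
#' * `"N"` — the sum of LINGO numbers (`length - q + 1` for strings with at
#'   least `q` characters),
#' * `"L"` — the LINGO length (the SMILES character count),
#' * `"M"` — the LINGO magnitude (the count of distinct Lingos).
#'
#' `M` bounds the merge-walk cost directly, `N` and `L` track total q-gram
#' count, and `S` is a score-mass heuristic. An empty profile has workload
#' 0 under `S`, `N` and `M`; `L` still reports the raw character count.
#'
#' @param profile A `lingo_profile`.
#' @param measure One of `"S"`, `"N"`, `"L"`, `"M"`. Default `"M"`.
#' @return A non-negative number (double: `S` can exceed 32-bit range).
#' @examples
#' p <- build_profile("CCCCC")
#' workload(p, "N")  # 2
#' workload(p, "M")  # 1
#' workload(p, "L")  # 5
#' @export
workload <- function(profile, measure = c("M", "S", "N", "L")) {
  measure <- match.arg(measure)
  stopifnot(inherits(profile, "lingo_profile"))
  switch(measure,
         S = sum(as.numeric(profile$scores)),
         N = sum(as.numeric(profile$numbers)),
         L = as.numeric(profile$length),
         M = as.numeric(profile$magnitude))
}

#' Workloads for a list of profiles
#'
#' @param profiles A list of `lingo_profile` objects.
#' @inheritParams workload
#' @return A numeric vector, one workload per profile.
#' @export
workloads <- function(profiles, measure = c("M", "S", "N", "L")) {
  measure <- match.arg(measure)
  vapply(profiles, workload, numeric(1), measure = measure)
}

#' Partition compounds across workers by estimated workload
#'
#' Assigns compound indices to workers (the stand-ins for thread blocks or
#' devices) so that the estimated per-worker load is balanced relative to
#' each worker's capability weight. Two deterministic policies:
#'
#' * `"greedy_lpt"` (default) — longest-processing-time-first: indices are
#'   sorted by workload descending and each is assigned to the worker that
#'   minimizes `(current load + workload) / weight`. On equal-weight
#'   workers this carries the classical `4/3 - 1/(3m)` makespan guarantee.
#' * `"sorted_round_robin"` — indices sorted by workload descending are
#'   dealt cyclically to workers; weights are ignored. Mimics assigning a
#'   sorted database to consecutive threads.
#'
#' Ties are broken deterministically: equal workloads by lower index first,
#' equal-load workers by lower worker number first.
#'
#' @param loads Numeric vector of non-negative workloads, one per compound.
#' @param n_workers Number of workers (positive integer).
#' @param worker_weights Positive relative capabilities, one per worker.
#'   Default: all equal.
#' @param policy `"greedy_lpt"` or `"sorted_round_robin"`.
#' @return An object of class `lingo_partition`: a list with `assignments`
#'   (list of 1-based index vectors, one per worker, each in ascending
#'   index order) and `worker_weights`.
#' @examples
#' p <- partition_workloads(c(4, 3, 3, 2), n_workers = 2)
#' sapply(p$assignments, function(ix) sum(c(4, 3, 3, 2)[ix]))  # 6 6
#' @export
partition_workloads <- function(loads, n_workers,
                                worker_weights = rep(1, n_workers),
                                policy = c("greedy_lpt", "sorted_round_robin")) {
  policy <- match.arg(policy)
  if (length(n_workers) != 1L || is.na(n_workers) || n_workers < 1L) {
    stop("n_workers must be a positive integer")
  }
  n_workers <- as.integer(n_workers)
  if (length(worker_weights) != n_workers || any(worker_weights <= 0)) {
    stop("worker_weights must supply one positive weight per worker")
  }
  loads <- as.numeric(loads)
  if (any(loads < 0)) stop("workloads must be non-negative")
  n <- length(loads)
  # descending workload, ties by lower original index
  ord <- order(-loads, seq_len(n))
  assign_to <- integer(n)

  if (policy == "sorted_round_robin") {
    assign_to[ord] <- rep_len(seq_len(n_workers), n)
  } else {
    acc <- numeric(n_workers)
    for (idx in ord) {
      cand <- (acc + loads[[idx]]) / worker_weights
      w <- which.min(cand)  # which.min takes the first (lowest worker) on ties
      assign_to[[idx]] <- w
      acc[[w]] <- acc[[w]] + loads[[idx]]
    }
  }
  assignments <- lapply(seq_len(n_workers),
                        function(w) which(assign_to == w))
  structure(list(assignments = assignments, worker_weights = worker_weights),
            class = "lingo_partition")
}

#' Load imbalance of a partition
#'
#' The makespan diagnostic for a partition: the maximum weighted per-worker
#' load divided by the ideal (total load / total weight). A perfectly
#' balanced partition scores 1; all load on one of `m` equal workers scores
#' `m`. Returns 0 when the total load is 0.
#'
#' @param part A `lingo_partition`.
#' @param loads The workload vector the partition was built from.
#' @return A double `>= 1` (or 0 for zero total load).
#' @export
imbalance <- function(part, loads) {
  stopifnot(inherits(part, "lingo_partition"))
  loads <- as.numeric(loads)
  per_worker <- vapply(part$assignments,
                       function(ix) sum(loads[ix]), numeric(1))
  total <- sum(per_worker)
  if (total == 0) return(0)
  ideal <- total / sum(part$worker_weights)
  max(per_worker / part$worker_weights) / ideal
}

#' @export
print.lingo_partition <- function(x, ...) {
  sizes <- lengths(x$assignments)
  cat("<lingo_partition> ", length(sizes), " worker(s), sizes: ",
      paste(sizes, collapse = " "), "\n", sep = "")
  invisible(x)
}
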