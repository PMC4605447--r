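# Independent oracles used across tests. They deliberately avoid the
# package's score-packing / sorted-merge machinery: profiles are counted in
# a plain associative map and schedules checked by exhaustive enumeration.

# q-gram multiset of a string as a named count vector (names = substrings)
oracle_qgrams <- function(s, q = 4L) {
  l <- nchar(s)
  if (l < q) return(integer(0))
  starts <- seq_len(l - q + 1L)
  grams <- substring(s, starts, starts + q - 1L)
  tab <- table(grams)
  setNames(as.integer(tab), names(tab))
}

# multiset / set Jaccard straight from the definition
oracle_jaccard <- function(sa, sb, q = 4L, multiset = TRUE) {
  ca <- oracle_qgrams(sa, q)
  cb <- oracle_qgrams(sb, q)
  shared <- intersect(names(ca), names(cb))
  if (multiset) {
    inter <- sum(pmin(ca[shared], cb[shared]))
    uni <- sum(ca) + sum(cb) - inter
  } else {
    inter <- length(shared)
    uni <- length(ca) + length(cb) - inter
  }
  if (uni == 0) 0 else inter / uni
}

# byte-level packing oracle, independent of pack_score's arithmetic
oracle_pack <- function(gram) {
  codes <- as.integer(charToRaw(gram))
  Reduce(function(acc, c) acc * 256 + c, codes, accumulate = FALSE, init = 0)
}

# minimum makespan over all m^n worker assignments (equal weights).
# Enumerates assignments as base-m digit strings, vectorized over all of
# them at once; feasible for n <= 12, m <= 3.
oracle_opt_makespan <- function(loads, m) {
  n <- length(loads)
  stopifnot(m^n <= 6e5)
  idx <- 0:(m^n - 1)
  spans <- matrix(0, length(idx), m)
  for (item in seq_len(n)) {
    digit <- (idx %/% m^(item - 1)) %% m
    for (w in 0:(m - 1)) {
      spans[, w + 1] <- spans[, w + 1] + loads[[item]] * (digit == w)
    }
  }
  mk <- spans[, 1]
  for (w in seq_len(m)[-1]) mk <- pmax(mk, spans[, w])
  min(mk)
}

# random printable-ASCII / SMILES-alphabet string
random_string <- function(len, alphabet = smiles_alphabet()) {
  if (len == 0L) return("")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# a 13-character string whose ten 4-character sliding windows are pairwise
# distinct (13 distinct characters guarantee it); SMILES-alphabet characters
distinct_window_smiles13 <- function() {
  s <- "CN(O)=P[S]c1#"
  stopifnot(nchar(s) == 13L)
  grams <- substring(s, 1:10, 4:13)
  stopifnot(!anyDuplicated(grams))
  s
}

# per-worker load sums of a partition
worker_loads <- function(part, loads) {
  vapply(part$assignments, function(ix) sum(loads[ix]), numeric(1))
}
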