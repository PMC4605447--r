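#' Tanimoto coefficient between two LINGO profiles
#'
#' Computes intersection-over-union similarity between two compounds'
#' q-Lingo collections by a single linear merge of the two ascending score
#' arrays (no quadratic scan). Two interpretations of the q-gram collection
#' are supported:
#'
#' * `"multiset"` (default): each q-gram counts with its multiplicity.
#'   Intersection is `sum over shared scores of min(number_a, number_b)`;
#'   union is `sum(numbers_a) + sum(numbers_b) - intersection`. This is the
#'   multiset Jaccard coefficient used by SMILES q-gram screening engines.
#' * `"set"`: multiplicities are ignored. Intersection is the count of
#'   shared scores; union is `magnitude_a + magnitude_b - intersection`.
#'
#' If both profiles are empty (both strings shorter than `q`), the
#' coefficient is defined as 0: a molecule too short to produce any Lingo
#' matches nothing, not everything.
#'
#' @param a,b `lingo_profile` objects built with the same `q`.
#' @param mode `"multiset"` (default) or `"set"`.
#' @return A double in `[0, 1]`.
#' @examples
#' a <- build_profile("CCCCC")  # {CCCC: 2}
#' b <- build_profile("CCCC")   # {CCCC: 1}
#' tanimoto(a, b)               # 1/2
#' tanimoto(a, b, mode = "set") # 1
#' @export
tanimoto <- function(a, b, mode = c("multiset", "set")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "lingo_profile"), inherits(b, "lingo_profile"))
  if (a$q != b$q) {
    stop("incompatible profiles: q = ", a$q, " vs q = ", b$q)
  }
  cpp_tanimoto(as.numeric(a$scores), a$numbers,
               as.numeric(b$scores), b$numbers,
               mode == "multiset")
}

#' Brute-force Tanimoto oracle over raw SMILES strings
#'
#' Computes the same coefficient as [tanimoto()] without sorting or score
#' packing: both q-gram multisets are materialized in a named associative
#' map and the min/max (or set-intersection) definition applied directly.
#' Intended as an independent cross-check of the sorted-merge path; it is
#' O(n^2)-ish in string length and not meant for screening.
#'
#' @param smiles_a,smiles_b SMILES strings (treated as text).
#' @param q q-gram width, default 4.
#' @param mode `"multiset"` (default) or `"set"`.
#' @return A double in `[0, 1]`.
#' @examples
#' tanimoto_oracle("CCCCC", "CCCC")        # 0.5
#' tanimoto_oracle("CCO", "CCO")           # 0 — both too short for any 4-gram
#' tanimoto_oracle("ABCD", "BCDE", mode = "set")  # 0 — disjoint
#' @export
tanimoto_oracle <- function(smiles_a, smiles_b, q = 4L,
                            mode = c("multiset", "set")) {
  mode <- match.arg(mode)
  count_grams <- function(s) {
    grams <- fragment(s, q)
    if (!length(grams)) return(integer(0))
    tab <- table(grams)
    stats::setNames(as.integer(tab), names(tab))
  }
  ca <- count_grams(smiles_a)
  cb <- count_grams(smiles_b)
  if (mode == "set") {
    inter <- length(intersect(names(ca), names(cb)))
    uni <- length(ca) + length(cb) - inter
  } else {
    shared <- intersect(names(ca), names(cb))
    inter <- sum(pmin(ca[shared], cb[shared]))
    uni <- sum(ca) + sum(cb) - inter
  }
  if (uni == 0) 0 else inter / uni
}
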