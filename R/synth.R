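#' Default SMILES-like alphabet for synthetic libraries
#'
#' The common organic-subset SMILES characters: element symbols, aromatic
#' lowercase forms, bond, branch, ring-closure and charge symbols.
#' Synthetic strings drawn from it are *textually* SMILES-like; they are
#' not chemically valid molecules, and do not need to be — the whole
#' comparison method treats SMILES purely as text.
#'
#' @return A character vector of single characters.
#' @export
smiles_alphabet <- function() {
  strsplit("CNOPSFIclnos=#()[]1234567890@+-/\\Br", "", fixed = TRUE)[[1]]
}

#' Generate a deterministic synthetic SMILES library
#'
#' Emulates a screening library of short text strings over the SMILES
#' alphabet at desk scale: `n` compounds with ids `"S000001"` onward,
#' characters drawn i.i.d. from `alphabet`, lengths drawn per
#' `length_dist`. The same spec and seed always produce a byte-identical
#' library. Strings are random text, not valid molecules (see
#' [smiles_alphabet()]); the only structural constraint imposed is that a
#' string never starts with `'#'`, which is not a legal SMILES opening and
#' would collide with the `.smi` comment convention.
#'
#' @param n Number of compounds (`>= 0`).
#' @param length_dist Either `c(min, max)` with `length_kind = "uniform"`
#'   (integer lengths uniform on `[min, max]`) or `c(mean, sd)` with
#'   `length_kind = "truncnorm"` (normal lengths rounded and truncated to
#'   `[1, Inf)`). Default uniform on `[20, 80]`.
#' @param length_kind `"uniform"` (default) or `"truncnorm"`.
#' @param alphabet Character set to draw from (default [smiles_alphabet()]).
#' @param seed Integer seed; the generator uses its own RNG stream and does
#'   not disturb the caller's.
#' @return A compound table (`data.frame` with `id`, `smiles`,
#'   `source_line`) as from [read_smi()].
#' @examples
#' lib <- gen_library(3, length_dist = c(10, 20), seed = 7)
#' nchar(lib$smiles)
#' @export
gen_library <- function(n, length_dist = c(20, 80),
                        length_kind = c("uniform", "truncnorm"),
                        alphabet = smiles_alphabet(), seed = 1L) {
  length_kind <- match.arg(length_kind)
  if (length(n) != 1L || is.na(n) || n < 0) {
    stop("n must be a non-negative integer")
  }
  n <- as.integer(n)
  if (length(length_dist) != 2L || anyNA(length_dist)) {
    stop("length_dist must be a numeric pair")
  }
  if (length_kind == "uniform" &&
      (length_dist[[1]] < 1 || length_dist[[2]] < length_dist[[1]])) {
    stop("uniform length_dist requires 1 <= min <= max")
  }
  if (!length(alphabet) || any(nchar(alphabet) != 1L)) {
    stop("alphabet must be a vector of single characters")
  }
  if (n == 0L) {
    return(data.frame(id = character(0), smiles = character(0),
                      source_line = integer(0), stringsAsFactors = FALSE))
  }
  smiles <- with_local_seed(seed, {
    lens <- switch(length_kind,
      uniform = sample.int(length_dist[[2]] - length_dist[[1]] + 1L, n,
                           replace = TRUE) + as.integer(length_dist[[1]]) - 1L,
      truncnorm = pmax(1L, as.integer(round(
        stats::rnorm(n, mean = length_dist[[1]], sd = length_dist[[2]])))))
    # never start a string with '#': it is not a legal SMILES opening (a
    # bond symbol cannot lead) and would collide with the .smi comment rule
    first_pool <- setdiff(alphabet, "#")
    if (!length(first_pool)) stop("alphabet must contain a non-'#' character")
    vapply(lens, function(l) {
      chars <- sample(alphabet, l, replace = TRUE)
      if (chars[[1]] == "#") chars[[1]] <- sample(first_pool, 1L)
      paste(chars, collapse = "")
    }, character(1))
  })
  data.frame(id = sprintf("S%06d", seq_len(n)), smiles = smiles,
             source_line = seq_len(n), stringsAsFactors = FALSE)
}

#' Mutate a compound to a controlled edit distance
#'
#' Returns a copy of `base` with exactly `substitutions` character
#' positions (chosen at seeded-random) replaced by *different* characters
#' from `alphabet`. Because one substitution can destroy at most `q`
#' overlapping q-grams, the similarity to the base degrades gradually with
#' the substitution count — useful for building pairs near a similarity
#' threshold.
#'
#' @param base A single-row compound table or a SMILES string.
#' @param substitutions Number of positions to change (`<=` string length).
#' @param seed Integer seed for position and replacement choice.
#' @param alphabet Replacement character pool (default [smiles_alphabet()]).
#' @return A compound table row with id `"<base id>_mut<substitutions>"`.
#' @export
mutate_pair <- function(base, substitutions, seed = 1L,
                        alphabet = smiles_alphabet()) {
  base <- coerce_library(base, "B")
  stopifnot(nrow(base) == 1L)
  s <- base$smiles[[1]]
  l <- nchar(s)
  if (substitutions < 0 || substitutions > l) {
    stop("substitutions must lie in [0, nchar(base)]")
  }
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  with_local_seed(seed, {
    pos <- sample.int(l, substitutions)
    for (p in pos) {
      pool <- setdiff(alphabet, chars[[p]])
      if (p == 1L) pool <- setdiff(pool, "#")  # keep .smi round-trip safe
      chars[[p]] <- sample(pool, 1L)
    }
  })
  data.frame(id = paste0(base$id[[1]], "_mut", substitutions),
             smiles = paste(chars, collapse = ""),
             source_line = NA_integer_, stringsAsFactors = FALSE)
}

# Evaluate `expr` under a private RNG state, restoring the caller's.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
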