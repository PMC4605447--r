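#' Optional ring-closure digit normalization
#'
#' The original LINGO similarity method rewrites ring-closure digits to `0`
#' so that, e.g., `C1CCCCC1` and `C2CCCCC2` fragment identically. This
#' implementation leaves strings untouched by default and offers the
#' rewrite as an opt-in flag for compatibility. When enabled, every decimal
#' digit outside square-bracket atoms (where digits are isotope labels or
#' charges, not ring labels) is replaced by `'0'`; `%nn` two-digit ring
#' closures are likewise zeroed.
#'
#' @param smiles A SMILES string (printable ASCII, no whitespace).
#' @param ring_digit_zeroing If `FALSE` (default) the input is returned
#'   unchanged.
#' @return The (possibly rewritten) SMILES string.
#' @examples
#' normalize_smiles("C1CCCCC1", ring_digit_zeroing = TRUE)   # "C0CCCCC0"
#' normalize_smiles("[13C]C1CC1", ring_digit_zeroing = TRUE) # "[13C]C0CC0"
#' @export
normalize_smiles <- function(smiles, ring_digit_zeroing = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!ring_digit_zeroing) return(smiles)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    ch <- chars[[i]]
    if (ch == "[") depth <- depth + 1L
    else if (ch == "]") depth <- max(0L, depth - 1L)
    else if (depth == 0L && ch >= "0" && ch <= "9") chars[[i]] <- "0"
  }
  paste(chars, collapse = "")
}

#' Fragment a SMILES string into q-character Lingos
#'
#' Slides a window of width `q` across the string with offset 1, yielding
#' the `l - q + 1` contiguous substrings (the q-Lingos) for a string of
#' `l` characters, in left-to-right order. Strings shorter than `q` yield
#' an empty character vector.
#'
#' @param smiles A SMILES string.
#' @param q Window width (positive integer, default 4).
#' @return Character vector of q-Lingos.
#' @examples
#' fragment("CCCC")        # "CCCC"
#' fragment("CCO")         # character(0)
#' length(fragment("OC(=O)CC(C)=CC", q = 4))  # 11 windows
#' @export
fragment <- function(smiles, q = 4L) {
  stopifnot(is.character(smiles), length(smiles) == 1L, q >= 1L)
  l <- nchar(smiles)
  if (l < q) return(character(0))
  starts <- seq_len(l - q + 1L)
  substring(smiles, starts, starts + q - 1L)
}

#' Pack a q-Lingo into an integer score
#'
#' Encodes a 4-character ASCII substring as a 32-bit integer by placing the
#' first character in the most significant byte:
#' `score = c0 * 2^24 + c1 * 2^16 + c2 * 2^8 + c3`. Big-endian packing
#' makes integer order coincide with lexicographic substring order, so a
#' sorted score array is equivalently a sorted substring array. The
#' encoding is injective, and for ASCII input (code points < 128) the score
#' fits in a signed 32-bit integer.
#'
#' For `q != 4` the same base-128-safe byte layout is used with `q` bytes;
#' scores for `q > 4` are returned as doubles (exactly representable up to
#' `q = 6`).
#'
#' @param qgram A q-character ASCII string (or vector of them).
#' @param q Expected width; each element of `qgram` must have exactly this
#'   many characters.
#' @return Integer scores for `q <= 4`, doubles otherwise.
#' @examples
#' pack_score("CCCC")  # 1128481603
#' pack_score("0000")  # 808464432
#' @export
pack_score <- function(qgram, q = 4L) {
  if (length(qgram) == 0L) {
    return(if (q <= 4L) integer(0) else numeric(0))
  }
  if (q > 6L) stop("pack_score supports q <= 6 (score must be exact in a double)")
  scores <- vapply(qgram, function(g) {
    codes <- utf8ToInt(g)
    if (anyNA(codes) || length(codes) != q || any(codes >= 128L)) {
      stop("invalid Lingo: expected ", q, " ASCII characters, got '", g, "'")
    }
    sum(codes * 256^((q - 1L):0L))
  }, numeric(1), USE.NAMES = FALSE)
  if (q <= 4L) as.integer(scores) else scores
}

#' Build the LINGO profile of a compound
#'
#' The preprocessing step of the comparison pipeline: normalizes the SMILES
#' (optionally), fragments it into q-Lingos, packs each into an integer
#' score, aggregates repeated scores into (score, count) pairs, and sorts
#' by score. The result bundles the four per-compound quantities the method
#' uses:
#'
#' * `scores` — strictly ascending unique packed q-gram scores,
#' * `numbers` — the multiplicity of each score (the LINGO numbers),
#' * `length` — the character count of the (normalized) SMILES,
#' * `magnitude` — the count of distinct q-Lingos (`length(scores)`).
#'
#' For any string of `l >= q` characters, `sum(numbers) == l - q + 1`;
#' shorter strings yield an empty profile with magnitude 0.
#'
#' @param smiles A SMILES string (printable ASCII, no whitespace).
#' @param q q-gram width, default 4.
#' @param ring_digit_zeroing Passed to [normalize_smiles()].
#' @return An object of class `lingo_profile`.
#' @examples
#' p <- build_profile("CCCCC")
#' p$numbers    # 2 — "CCCC" occurs twice
#' p$magnitude  # 1
#' @export
build_profile <- function(smiles, q = 4L, ring_digit_zeroing = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1L, q >= 1L)
  s <- normalize_smiles(smiles, ring_digit_zeroing)
  grams <- fragment(s, q)
  if (length(grams) == 0L) {
    scores <- if (q <= 4L) integer(0) else numeric(0)
    numbers <- integer(0)
  } else {
    packed <- sort(pack_score(grams, q))
    runs <- rle(packed)
    scores <- runs$values
    numbers <- as.integer(runs$lengths)
  }
  structure(
    list(scores = scores, numbers = numbers,
         length = nchar(s), magnitude = length(scores), q = as.integer(q)),
    class = "lingo_profile"
  )
}

#' Build LINGO profiles for a whole library
#'
#' @param compounds A compound table (see [read_smi()]) or a character
#'   vector of SMILES strings.
#' @param q q-gram width, default 4.
#' @param ring_digit_zeroing Passed to [normalize_smiles()].
#' @return A list of `lingo_profile` objects, one per compound, named by
#'   compound id when ids are available.
#' @export
build_profiles <- function(compounds, q = 4L, ring_digit_zeroing = FALSE) {
  if (is.character(compounds)) {
    smiles <- compounds
    ids <- NULL
  } else {
    compounds <- as_compound_table(compounds)
    smiles <- compounds$smiles
    ids <- compounds$id
  }
  profiles <- lapply(smiles, build_profile, q = q,
                     ring_digit_zeroing = ring_digit_zeroing)
  if (!is.null(ids)) names(profiles) <- ids
  profiles
}

#' @export
print.lingo_profile <- function(x, ...) {
  cat("<lingo_profile> q=", x$q, " length=", x$length,
      " magnitude=", x$magnitude, "\n", sep = "")
  if (x$magnitude) {
    show <- seq_len(min(8L, x$magnitude))
    cat("  scores:  ", paste(x$scores[show], collapse = " "),
        if (x$magnitude > 8L) " ..." else "", "\n", sep = "")
    cat("  numbers: ", paste(x$numbers[show], collapse = " "),
        if (x$magnitude > 8L) " ..." else "", "\n", sep = "")
  }
  invisible(x)
}

# Flatten a list of profiles into parallel arrays for the C++ kernel:
# concatenated scores/numbers plus 0-based offsets (CSR-style layout).
flatten_profiles <- function(profiles) {
  mags <- vapply(profiles, function(p) p$magnitude, integer(1))
  list(
    scores = as.numeric(unlist(lapply(profiles, `[[`, "scores"), use.names = FALSE)),
    numbers = as.integer(unlist(lapply(profiles, `[[`, "numbers"), use.names = FALSE)),
    offsets = as.integer(c(0L, cumsum(mags)))
  )
}
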