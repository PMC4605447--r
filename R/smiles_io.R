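#' Read a SMILES library from a `.smi` file
#'
#' Parses the de-facto `.smi` dialect: one record per line, the first
#' whitespace-delimited token is the SMILES string and an optional second
#' token is the compound identifier. Blank lines and lines starting with
#' `#` are skipped. Records without an identifier receive the positional
#' default `"L<line>"`, where `<line>` is the 1-based line number in the
#' file.
#'
#' SMILES strings are treated purely as text: no chemical validation is
#' performed. Tokens must be printable ASCII because downstream score
#' packing encodes one byte per character; offending lines are either
#' skipped with a warning or abort the read, depending on `on_error`.
#'
#' @param path Path to a readable `.smi` text file.
#' @param on_error How to treat lines whose SMILES token contains
#'   non-printable or non-ASCII characters: `"abort"` (default) stops with
#'   an error naming the line, `"skip"` drops the line with a warning.
#' @return A `data.frame` with columns `id` (character, unique), `smiles`
#'   (character) and `source_line` (integer, 1-based line number), one row
#'   per retained record, in file order.
#' @examples
#' smi <- tempfile(fileext = ".smi")
#' writeLines(c("CCO ethanol", "c1ccccc1 benzene", "", "# comment", "CCN"), smi)
#' read_smi(smi)
#' @export
read_smi <- function(path, on_error = c("abort", "skip")) {
  on_error <- match.arg(on_error)
  if (!file.exists(path)) {
    stop("cannot read SMILES library: file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  line_no <- seq_along(lines)
  trimmed <- trimws(lines)
  keep <- nzchar(trimmed) & !startsWith(trimmed, "#")
  trimmed <- trimmed[keep]
  line_no <- line_no[keep]

  ids <- character(length(trimmed))
  smiles <- character(length(trimmed))
  bad <- logical(length(trimmed))
  for (i in seq_along(trimmed)) {
    tokens <- strsplit(trimmed[[i]], "[[:space:]]+")[[1]]
    smi <- tokens[[1]]
    if (!is_printable_ascii(smi)) {
      if (on_error == "abort") {
        stop("invalid SMILES token (non-printable or non-ASCII) on line ",
             line_no[[i]], " of ", path)
      }
      warning("skipping line ", line_no[[i]], " of ", path,
              ": SMILES token contains non-printable or non-ASCII characters")
      bad[[i]] <- TRUE
      next
    }
    smiles[[i]] <- smi
    ids[[i]] <- if (length(tokens) >= 2L) tokens[[2]] else paste0("L", line_no[[i]])
  }
  ids <- ids[!bad]
  smiles <- smiles[!bad]
  line_no <- line_no[!bad]

  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate compound id(s) in ", path, ": ",
         paste(utils::head(dup, 5L), collapse = ", "))
  }
  data.frame(id = ids, smiles = smiles, source_line = as.integer(line_no),
             stringsAsFactors = FALSE)
}

#' Write a SMILES library to a `.smi` file
#'
#' Inverse of [read_smi()]: one `SMILES<TAB>id` record per line.
#'
#' @param compounds A `data.frame` with columns `id` and `smiles`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_smi <- function(compounds, path) {
  compounds <- as_compound_table(compounds)
  writeLines(paste(compounds$smiles, compounds$id, sep = "\t"), path)
  invisible(path)
}

#' Write a similarity hit report
#'
#' Writes the hit list produced by [report_hits()] (or any data frame with
#' columns `query_id`, `db_id`, `tanimoto`) as a tab-separated file with a
#' header line. Coefficients are printed with six decimal places. Rows are
#' ordered by query id, then descending coefficient, with ties broken by
#' database id ascending.
#'
#' @param hits A `data.frame` with columns `query_id`, `db_id`, `tanimoto`;
#'   every coefficient must lie in `[0, 1]`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  stopifnot(is.data.frame(hits),
            all(c("query_id", "db_id", "tanimoto") %in% names(hits)))
  if (nrow(hits) && (any(hits$tanimoto < 0) || any(hits$tanimoto > 1))) {
    stop("hit coefficients must lie in [0, 1]")
  }
  hits <- order_hits(hits)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("query_id\tdb_id\ttanimoto", con)
  if (nrow(hits)) {
    writeLines(sprintf("%s\t%s\t%.6f", hits$query_id, hits$db_id, hits$tanimoto),
               con)
  }
  invisible(path)
}

#' Read a hit report written by [write_hits()]
#'
#' @param path Path to a TSV hit report.
#' @return A `data.frame` with columns `query_id`, `db_id`, `tanimoto`.
#' @export
read_hits <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "numeric"))
}

# canonical hit ordering: query id, descending coefficient, db id
order_hits <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits[order(hits$query_id, -hits$tanimoto, hits$db_id), , drop = FALSE]
}

is_printable_ascii <- function(s) {
  codes <- utf8ToInt(s)
  !anyNA(codes) && length(codes) > 0L && all(codes >= 33L & codes <= 126L)
}

# Accept a compound table (data.frame with id + smiles) and validate it.
as_compound_table <- function(x) {
  if (!is.data.frame(x) || !all(c("id", "smiles") %in% names(x))) {
    stop("expected a compound table: a data.frame with columns 'id' and 'smiles'")
  }
  x$id <- as.character(x$id)
  x$smiles <- as.character(x$smiles)
  x
}
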