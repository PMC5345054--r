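#' Construct a cladistic character matrix
#'
#' Taxa by characters table of discrete morphological state codings:
#' digit states `0`-`9`, `'?'` for missing information and `'-'` for
#' inapplicable characters. Characters are indexed 1-based.
#'
#' @param cells character matrix of single-symbol strings with taxon
#'   row names.
#' @return An object of class `"character_matrix"` with fields `taxa`,
#'   `n_chars` and `cells`.
#' @export
character_matrix <- function(cells) {
  stopifnot(is.matrix(cells), is.character(cells))
  if (is.null(rownames(cells)) || any(!nzchar(rownames(cells))))
    stop("character matrix rows must be named by taxon")
  bad <- which(!grepl("^[0-9?-]$", cells))
  if (length(bad) > 0L) {
    i <- (bad[1] - 1L) %% nrow(cells) + 1L
    stop("illegal coding symbol '", cells[bad[1]],
         "' for taxon '", rownames(cells)[i], "'")
  }
  structure(list(taxa = rownames(cells), n_chars = ncol(cells), cells = cells),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Character matrix: ", length(x$taxa), " taxa x ", x$n_chars,
      " characters\n", sep = "")
  invisible(x)
}

#' Read a character matrix (NONA/Hennig86-style or TSV)
#'
#' Auto-detects the dialect. The `.ss` dialect is an optional `xread`
#' line, a header `<n_chars> <n_taxa>`, then one `taxon codings` line
#' per taxon (codings as one contiguous string), optionally terminated
#' by `;`. The TSV dialect is one line per taxon of tab-separated
#' fields: the taxon name followed by either one contiguous coding
#' string or one field per character.
#'
#' @param file path, or `NULL` when `text` is given.
#' @param text character vector of lines.
#' @return A [character_matrix()].
#' @export
read_charmatrix <- function(file = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  if (length(lines) == 1L && grepl("\n", lines, fixed = TRUE))
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & lines != ";"]
  if (length(lines) == 0L) stop("empty character matrix input")
  if (any(grepl("\t", lines, fixed = TRUE))) {           # TSV dialect
    rows <- strsplit(lines, "\t", fixed = TRUE)
    # drop a header row of character indices, if present
    if (length(rows[[1]]) > 2L &&
        all(grepl("^[0-9]+$", rows[[1]][-1])))
      rows <- rows[-1]
    taxa <- vapply(rows, `[[`, "", 1L)
    cells <- lapply(rows, function(r) {
      f <- r[-1]
      if (length(f) == 1L) strsplit(f, "")[[1]] else f
    })
    n_declared <- NULL
  } else {                                                # .ss dialect
    if (grepl("^xread", lines[1])) lines <- lines[-1]
    hdr <- strsplit(lines[1], "[[:space:]]+")[[1]]
    if (length(hdr) != 2L || any(!grepl("^[0-9]+$", hdr)))
      stop("malformed .ss header (expected '<n_chars> <n_taxa>'): '",
           lines[1], "'")
    n_declared <- as.integer(hdr[1]); n_taxa <- as.integer(hdr[2])
    body <- lines[-1]
    if (length(body) != n_taxa)
      stop("header declares ", n_taxa, " taxa but ", length(body),
           " rows follow")
    parts <- strsplit(body, "[[:space:]]+")
    taxa <- vapply(parts, `[[`, "", 1L)
    cells <- lapply(parts, function(p) strsplit(paste(p[-1], collapse = ""), "")[[1]])
  }
  lens <- vapply(cells, length, 1L)
  ref <- n_declared %||NULL% lens[1]
  short <- which(lens != ref)
  if (length(short) > 0L)
    stop("row for taxon '", taxa[short[1]], "' has ", lens[short[1]],
         " codings, expected ", ref)
  m <- do.call(rbind, cells)
  rownames(m) <- taxa
  character_matrix(m)
}

#' Write a character matrix
#'
#' @param matrix a [character_matrix()].
#' @param path optional file path; when `NULL` the lines are returned.
#' @param format `"ss"` (NONA/Hennig86-style) or `"tsv"`.
#' @return Character vector of lines, invisibly when written.
#' @export
write_charmatrix <- function(matrix, path = NULL, format = c("ss", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(matrix, "character_matrix"))
  rows <- apply(matrix$cells, 1L, paste, collapse = "")
  out <- if (format == "ss") {
    c("xread", paste(matrix$n_chars, length(matrix$taxa)),
      paste(matrix$taxa, rows), ";")
  } else {
    paste(matrix$taxa, rows, sep = "\t")
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Coded-coverage statistics of a character matrix
#'
#' For a taxon subset, reports how far into the character list the
#' taxa could be assessed: `max_coded_index` is the highest 1-based
#' character index at which any selected taxon has a non-`'?'` cell
#' (`'-'` counts as assessed), `percent_of_total` is that index over
#' the character count, rounded half-up to one decimal. Per-taxon
#' `coded_count` and the strict count of characters with at least one
#' non-`'?'` cell are reported alongside.
#'
#' @param matrix a [character_matrix()].
#' @param taxa subset of taxon names (default all).
#' @return List with `max_coded_index`, `coded_count` (named integer),
#'   `percent_of_total`, and `strict_coded_count`.
#' @export
#' @examples
#' coded_stats(fossil_matrix())[c("max_coded_index", "percent_of_total")]
coded_stats <- function(matrix, taxa = matrix$taxa) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (length(taxa) == 0L) stop("empty taxon set")
  missing_taxa <- setdiff(taxa, matrix$taxa)
  if (length(missing_taxa) > 0L)
    stop("unknown taxa: ", paste(missing_taxa, collapse = ", "))
  sub <- matrix$cells[taxa, , drop = FALSE]
  assessed <- sub != "?"
  any_assessed <- apply(assessed, 2L, any)
  max_idx <- if (any(any_assessed)) max(which(any_assessed)) else 0L
  list(max_coded_index = max_idx,
       coded_count = stats::setNames(rowSums(assessed), taxa),
       percent_of_total = round_half_up(max_idx / matrix$n_chars * 100, 1L),
       strict_coded_count = sum(any_assessed))
}

#' Taxa matching a diagnostic combination of character states
#'
#' Returns the taxa whose coding equals the queried state at every
#' queried character. Missing (`'?'`) and inapplicable (`'-'`) cells
#' never match a state, so the query is conservative; an empty query
#' matches every taxon.
#'
#' @param matrix a [character_matrix()].
#' @param assignments named vector; names are 1-based character
#'   indices, values the required digit states, e.g. `c("18" = 1,
#'   "34" = 1)`.
#' @return Character vector of matching taxon names.
#' @export
#' @examples
#' diagnostic_match(fossil_matrix(), c("18" = 1, "34" = 1))
diagnostic_match <- function(matrix, assignments = NULL) {
  stopifnot(inherits(matrix, "character_matrix"))
  if (is.null(assignments) || length(assignments) == 0L)
    return(matrix$taxa)
  idx <- as.integer(names(assignments))
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > matrix$n_chars))
    stop("character index out of range 1..", matrix$n_chars)
  states <- as.character(unlist(assignments))
  keep <- rep(TRUE, length(matrix$taxa))
  for (k in seq_along(idx))
    keep <- keep & matrix$cells[, idx[k]] == states[k]
  matrix$taxa[keep]
}

#' Morphometric ratio with half-up rounding
#'
#' Length/width style ratio as reported in descriptions, rounded
#' half-up to one decimal place.
#'
#' @param numerator,denominator measurements (same unit, e.g. mm);
#'   the denominator must be positive.
#' @return The rounded ratio.
#' @export
#' @examples
#' ratio_check(9.0, 3.2) # 2.8
#' ratio_check(8.6, 3.6) # 2.4
ratio_check <- function(numerator, denominator) {
  if (!is.numeric(denominator) || any(denominator <= 0))
    stop("denominator must be positive")
  round_half_up(numerator / denominator, 1L)
}

#' Round half away from zero at a fixed number of decimals
#'
#' Unlike [round()] (banker's rounding), ties round up: `2.75` at one
#' decimal gives `2.8`.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}
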