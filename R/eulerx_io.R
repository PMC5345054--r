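# Euler/X-dialect alignment text, MIR CSV, and DOT exports.
#
# File grammar (line oriented; blank lines and "#" comments ignored):
#   taxonomy <tag> <title...>
#   (<parent> <child1> ... <childN>)        one or more groups
#   articulation <tag1>-<tag2> <title...>
#   [<tag1>.<name> <rel> <tag2>.<name>]     rel in {equals, includes,
#       is_included_in, overlaps, disjoint} or a braced disjunction
#       "{rel rel ...}"
# A parent token may carry the prefix "nc_", relaxing its coverage
# constraint. Concepts mentioned only as children are implicitly
# declared; a root is any concept never listed as a child. Names are
# ASCII tokens of letters, digits, underscore and hyphen.

.kw_to_sym <- function() stats::setNames(rcc5_relations(), .rel_keywords)
.sym_to_kw <- function() stats::setNames(.rel_keywords, rcc5_relations())

parse_error <- function(lineno, msg) stop("parse error (line ", lineno, "): ", msg)

#' Read an Euler/X-dialect alignment input
#'
#' @param file path to an alignment text file, or `NULL` when `text`
#'   is given.
#' @param text character vector of lines (alternative to `file`).
#' @return An [alignment_problem()].
#' @export
#' @examples
#' f <- system.file("extdata", "scelianoma.txt", package = "rcc5align")
#' read_eulerx(f)
read_eulerx <- function(file = NULL, text = NULL) {
  lines <- if (is.null(text)) readLines(file, warn = FALSE) else text
  if (length(lines) == 1L && grepl("\n", lines, fixed = TRUE))
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1]]
  tax_order <- character(0)
  tax_title <- list(); tax_groups <- list(); tax_nc <- list()
  cur_tag <- NULL
  in_articulation <- FALSE
  art <- data.frame(left = character(), relation = character(),
                    right = character(), stringsAsFactors = FALSE)
  name_re <- "[A-Za-z0-9_-]+"
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    s <- trimws(raw)
    if (!nzchar(s)) next
    if (grepl("^taxonomy\\b", s)) {
      toks <- strsplit(s, "[[:space:]]+")[[1]]
      if (length(toks) < 2L) parse_error(ln, "taxonomy line needs a tag")
      tag <- toks[2]
      if (tag %in% tax_order) parse_error(ln, paste0("duplicate taxonomy tag '", tag, "'"))
      tax_order <- c(tax_order, tag)
      tax_title[[tag]] <- paste(toks[-(1:2)], collapse = " ")
      tax_groups[[tag]] <- list()
      tax_nc[[tag]] <- character(0)
      cur_tag <- tag; in_articulation <- FALSE
    } else if (grepl("^articulation\\b", s)) {
      in_articulation <- TRUE; cur_tag <- NULL
    } else if (grepl("^\\(", s)) {
      if (is.null(cur_tag)) parse_error(ln, "concept group outside a taxonomy block")
      if (!grepl("^\\(.*\\)$", s)) parse_error(ln, "unterminated concept group")
      toks <- strsplit(trimws(substr(s, 2L, nchar(s) - 1L)), "[[:space:]]+")[[1]]
      toks <- toks[nzchar(toks)]
      if (length(toks) == 0L) parse_error(ln, "empty concept group")
      bad <- toks[!grepl(paste0("^(nc_)?", name_re, "$"), toks)]
      if (length(bad)) parse_error(ln, paste0("illegal concept token '", bad[1], "'"))
      parent <- toks[1]
      if (startsWith(parent, "nc_")) {
        parent <- sub("^nc_", "", parent)
        if (length(toks) < 2L)
          parse_error(ln, "'nc_' prefix on a concept without children")
        tax_nc[[cur_tag]] <- c(tax_nc[[cur_tag]], parent)
      }
      kids <- toks[-1]
      if (anyDuplicated(kids))
        parse_error(ln, paste0("parent '", parent, "' lists a repeated child"))
      g <- tax_groups[[cur_tag]]
      if (parent %in% names(g)) {
        if (anyDuplicated(c(g[[parent]], kids)))
          parse_error(ln, paste0("parent '", parent, "' lists a repeated child"))
        g[[parent]] <- c(g[[parent]], kids)
      } else g[[parent]] <- kids
      tax_groups[[cur_tag]] <- g
    } else if (grepl("^\\[", s)) {
      if (!in_articulation) parse_error(ln, "articulation outside an articulation block")
      if (!grepl("^\\[.*\\]$", s)) parse_error(ln, "unterminated articulation")
      body <- trimws(substr(s, 2L, nchar(s) - 1L))
      m <- regexec(paste0("^(", name_re, ")\\.(", name_re, ")[[:space:]]+",
                          "(\\{[^}]*\\}|[A-Za-z_]+)[[:space:]]+",
                          "(", name_re, ")\\.(", name_re, ")$"), body)
      g <- regmatches(body, m)[[1]]
      if (length(g) == 0L) parse_error(ln, paste0("malformed articulation '", body, "'"))
      reltok <- g[4]
      kw <- .kw_to_sym()
      to_sym <- function(word, lineno) {
        if (!(word %in% names(kw)))
          parse_error(lineno, paste0("unknown relation keyword '", word, "'"))
        kw[[word]]
      }
      if (startsWith(reltok, "{")) {
        words <- strsplit(trimws(substr(reltok, 2L, nchar(reltok) - 1L)),
                          "[[:space:]]+")[[1]]
        words <- words[nzchar(words)]
        if (length(words) == 0L) parse_error(ln, "empty relation disjunction")
        rel <- render_relset(vapply(words, to_sym, "", lineno = ln))
      } else rel <- to_sym(reltok, ln)
      art <- rbind(art, data.frame(
        left = paste0(g[2], ".", g[3]), relation = rel,
        right = paste0(g[5], ".", g[6]), stringsAsFactors = FALSE))
    } else {
      parse_error(ln, paste0("unrecognized line '", s, "'"))
    }
  }
  taxa <- lapply(tax_order, function(tag)
    taxonomy(tag, tax_groups[[tag]], title = tax_title[[tag]],
             not_covered = unique(tax_nc[[tag]])))
  tryCatch(alignment_problem(taxa, art),
           error = function(e) stop("parse error: ", conditionMessage(e)))
}

#' Write an alignment problem in the Euler/X dialect
#'
#' Taxonomy blocks are emitted in taxonomy order with parent-child
#' groups in preorder; non-covered parents carry the `nc_` prefix.
#' Articulations are grouped by taxonomy pair (taxonomy order),
#' preserving their stored order within each pair; re-reading the
#' output with [read_eulerx()] reproduces the problem.
#'
#' @param problem an [alignment_problem()].
#' @param path optional file path; when `NULL` the text is returned.
#' @return Character vector of lines, invisibly when written to a file.
#' @export
write_eulerx <- function(problem, path = NULL) {
  out <- character(0)
  for (tax in problem$taxonomies) {
    out <- c(out, trimws(paste("taxonomy", tax$tag, tax$title)))
    for (p in preorder_concepts(tax)) {
      kids <- tax$children[[p]]
      if (is.null(kids)) next
      ptok <- if (isTRUE(tax$covered[[p]])) p else paste0("nc_", p)
      out <- c(out, paste0("(", paste(c(ptok, kids), collapse = " "), ")"))
    }
    # isolated roots (no parent, no children) still need declaring
    roots <- tax$concepts[is.na(tax$parent[tax$concepts])]
    for (r in roots) if (is.null(tax$children[[r]]))
      out <- c(out, paste0("(", r, ")"))
    out <- c(out, "")
  }
  tags <- vapply(problem$taxonomies, `[[`, "", "tag")
  art <- problem$articulations
  if (nrow(art) > 0L) {
    ltag <- label_tag(art$left); rtag <- label_tag(art$right)
    pi_ <- pmin(match(ltag, tags), match(rtag, tags))
    pj <- pmax(match(ltag, tags), match(rtag, tags))
    for (i in seq_len(length(tags) - 1L)) for (j in seq.int(i + 1L, length(tags))) {
      rows <- which(pi_ == i & pj == j)
      if (length(rows) == 0L) next
      out <- c(out, paste0("articulation ", tags[i], "-", tags[j], " alignment"))
      kw <- .sym_to_kw()
      for (r in rows) {
        relset <- parse_relset(art$relation[r])
        reltok <- if (length(relset) == 1L) kw[[relset]] else
          paste0("{", paste(kw[relset], collapse = " "), "}")
        out <- c(out, paste0("[", art$left[r], " ", reltok, " ", art$right[r], "]"))
      }
      out <- c(out, "")
    }
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Write a MIR table as CSV text
#'
#' Header `left,relation,right`, one line per cross-taxonomy pair;
#' relation sets with more than one member are rendered inside braces,
#' e.g. `{< ><}`.
#'
#' @param table a `"mir_table"` from [compute_mir()].
#' @param path optional file path; when `NULL` the text is returned.
#' @return Character vector of CSV lines, invisibly when written.
#' @export
write_mir_csv <- function(table, path = NULL) {
  stopifnot(inherits(table, "mir_table"))
  out <- c("left,relation,right",
           if (nrow(table) > 0L)
             paste(table$left, table$relation, table$right, sep = ","))
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Export an alignment input or a merged graph as DOT text
#'
#' Input mode emits one node per concept, solid black edges for
#' parent-child links within a taxonomy and dashed magenta edges
#' (labelled with the relation symbols) for provided articulations.
#' Alignment mode emits one node per congruence class (multi-member
#' classes drawn as filled rounded boxes), solid edges for the reduced
#' proper-inclusion order and dashed blue undirected edges for overlap.
#'
#' @param x an [alignment_problem()] or a [merged_graph()].
#' @param mode `"input"` or `"alignment"`; defaults to whichever
#'   matches the class of `x`.
#' @param path optional file path.
#' @return Character vector of DOT lines, invisibly when written.
#' @export
export_graph <- function(x, mode = c("auto", "input", "alignment"), path = NULL) {
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (inherits(x, "merged_graph")) "alignment" else "input"
  q <- function(s) paste0("\"", s, "\"")
  out <- "digraph alignment {"
  if (mode == "input") {
    stopifnot(inherits(x, "alignment_problem"))
    for (lab in concept_labels(x)) out <- c(out, paste0("  ", q(lab), ";"))
    for (tax in x$taxonomies)
      for (p in names(tax$children)) for (k in tax$children[[p]])
        out <- c(out, paste0("  ", q(concept_label(tax$tag, p)), " -> ",
                             q(concept_label(tax$tag, k)),
                             " [style=solid, color=black];"))
    art <- x$articulations
    for (i in seq_len(nrow(art)))
      out <- c(out, paste0("  ", q(art$left[i]), " -> ", q(art$right[i]),
                           " [style=dashed, color=magenta, label=",
                           q(art$relation[i]), "];"))
  } else {
    stopifnot(inherits(x, "merged_graph"))
    for (k in seq_along(x$classes)) {
      members <- x$classes[[k]]
      style <- if (length(members) > 1L)
        ", style=\"rounded,filled\", fillcolor=grey" else ""
      out <- c(out, paste0("  c", k, " [shape=box, label=",
                           q(paste(members, collapse = "\\n")), style, "];"))
    }
    for (i in seq_len(nrow(x$inclusion)))
      out <- c(out, paste0("  c", x$inclusion$from[i], " -> c",
                           x$inclusion$to[i], " [style=solid, color=black];"))
    for (i in seq_len(nrow(x$overlap)))
      out <- c(out, paste0("  c", x$overlap$a[i], " -> c", x$overlap$b[i],
                           " [style=dashed, color=blue, dir=none];"))
  }
  out <- c(out, "}")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
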