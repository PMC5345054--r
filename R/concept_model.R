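#' Construct a taxonomy (one classification hierarchy)
#'
#' A taxonomy is one published treatment's classification: a forest of
#' taxonomic concepts identified by name within the treatment's tag.
#' Concepts used in two treatments under the same name are distinct
#' concepts; their rendered labels are `"tag.name"`.
#'
#' Parents carry a coverage flag: `covered = TRUE` (the default) means a
#' parent's region is exactly the union of its children's regions;
#' parents listed in `not_covered` may hold an additional, unsampled
#' residue region (the "nc" device used for purposefully undersampled
#' concepts).
#'
#' @param tag short treatment identifier (e.g. a year-like string).
#' @param children named list; names are parent concept names, each
#'   element a character vector of child names. Concepts appearing only
#'   as children are implicitly declared; a root is any concept never
#'   listed as a child.
#' @param title free-text description of the treatment.
#' @param not_covered character vector of parent names whose coverage
#'   constraint is relaxed.
#' @return An object of class `"taxonomy"`.
#' @export
#' @examples
#' taxonomy("2017", list(Scelianoma = c("elydimorpha", "compacta")))
taxonomy <- function(tag, children = list(), title = "", not_covered = character()) {
  stopifnot(is.character(tag), length(tag) == 1L, nzchar(tag))
  stopifnot(is.list(children))
  concepts <- character()
  parent <- character()
  for (p in names(children)) {
    kids <- as.character(children[[p]])
    if (!nzchar(p) || any(!nzchar(kids)))
      stop("taxonomy '", tag, "': empty concept name")
    if (anyDuplicated(kids))
      stop("taxonomy '", tag, "': parent '", p, "' lists a repeated child")
    if (!(p %in% concepts)) concepts <- c(concepts, p)
    for (k in kids) {
      if (!is.na(parent[k]) && nzchar(parent[k] %||% ""))
        stop("taxonomy '", tag, "': concept '", k, "' assigned two parents")
      if (!(k %in% concepts)) concepts <- c(concepts, k)
      parent[k] <- p
    }
  }
  if (length(children) == 0L)
    stop("taxonomy '", tag, "' declares no concepts; give at least one group ",
         "(a single root can be declared as list(root = character(0))) ")
  # allow declaring an isolated root via an empty child vector
  kids_per_parent <- lapply(children, as.character)
  parents_with_kids <- names(kids_per_parent)[vapply(kids_per_parent, length, 1L) > 0L]
  covered <- stats::setNames(rep(TRUE, length(parents_with_kids)), parents_with_kids)
  bad_nc <- setdiff(not_covered, parents_with_kids)
  if (length(bad_nc) > 0L)
    stop("taxonomy '", tag, "': non-covered flag on concept(s) without children: ",
         paste(bad_nc, collapse = ", "))
  covered[not_covered] <- FALSE
  full_parent <- stats::setNames(rep(NA_character_, length(concepts)), concepts)
  full_parent[names(parent)] <- parent
  structure(
    list(tag = tag, title = title, concepts = concepts,
         parent = full_parent,
         children = kids_per_parent[parents_with_kids],
         covered = covered),
    class = "taxonomy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.taxonomy <- function(x, ...) {
  cat("Taxonomy '", x$tag, "'", if (nzchar(x$title)) paste0(" (", x$title, ")"),
      ": ", length(x$concepts), " concepts, ",
      sum(is.na(x$parent)), " root(s)\n", sep = "")
  invisible(x)
}

# concept names in preorder: roots in declaration order, parent before
# children, siblings in declared order
preorder_concepts <- function(tax) {
  roots <- tax$concepts[is.na(tax$parent[tax$concepts])]
  out <- character(0)
  visit <- function(n) {
    out <<- c(out, n)
    for (k in tax$children[[n]] %||% character(0)) visit(k)
  }
  for (r in roots) visit(r)
  out
}

# all descendants of concept `name` including itself
descendants_self <- function(tax, name) {
  out <- name
  i <- 1L
  while (i <= length(out)) {
    kids <- tax$children[[out[i]]]
    if (!is.null(kids)) out <- c(out, kids)
    i <- i + 1L
  }
  out
}

concept_label <- function(tag, name) paste0(tag, ".", name)

split_label <- function(label) {
  m <- regexpr(".", label, fixed = TRUE)
  if (m < 0L) stop("not a 'tag.name' concept label: '", label, "'")
  c(tag = substr(label, 1L, m - 1L), name = substr(label, m + 1L, nchar(label)))
}

label_name <- function(label) vapply(label, function(l) split_label(l)[["name"]], "")
label_tag <- function(label) vapply(label, function(l) split_label(l)[["tag"]], "")

#' Assemble an alignment problem
#'
#' Bundles 2-5 taxonomies with the expert-provided cross-taxonomy RCC-5
#' articulations that relate their concepts. Articulations may assert a
#' single base relation or a disjunction (e.g. `"{< ><}"`).
#'
#' @param taxonomies list of [taxonomy()] objects with distinct tags.
#' @param articulations `data.frame` with character columns `left`,
#'   `relation`, `right`; `left`/`right` are `"tag.name"` labels and
#'   `relation` a symbol from [rcc5_relations()] or a braced
#'   disjunction such as `"{< ><}"`. `NULL` means no articulations.
#' @return An object of class `"alignment_problem"`.
#' @seealso [validate_problem()], [compute_mir()]
#' @export
alignment_problem <- function(taxonomies, articulations = NULL) {
  if (inherits(taxonomies, "taxonomy")) taxonomies <- list(taxonomies)
  stopifnot(all(vapply(taxonomies, inherits, TRUE, "taxonomy")))
  if (is.null(articulations))
    articulations <- data.frame(left = character(), relation = character(),
                                right = character(), stringsAsFactors = FALSE)
  stopifnot(is.data.frame(articulations),
            all(c("left", "relation", "right") %in% names(articulations)))
  articulations <- articulations[, c("left", "relation", "right")]
  rownames(articulations) <- NULL
  prob <- structure(list(taxonomies = taxonomies, articulations = articulations),
                    class = "alignment_problem")
  viol <- validate_problem(prob)
  if (length(viol) > 0L)
    stop("invalid alignment problem:\n  ", paste(viol, collapse = "\n  "))
  prob
}

#' @export
print.alignment_problem <- function(x, ...) {
  cat("Alignment problem: ", length(x$taxonomies), " taxonomies (",
      paste(vapply(x$taxonomies, `[[`, "", "tag"), collapse = ", "), "), ",
      length(concept_labels(x)), " concepts, ",
      nrow(x$articulations), " articulations\n", sep = "")
  invisible(x)
}

#' All concept labels of a problem, in canonical order
#'
#' Canonical order is taxonomy input order, then preorder within each
#' taxonomy (parent before children, siblings in declared order). All
#' deterministic outputs of the package sort by it.
#'
#' @param problem an [alignment_problem()].
#' @return Character vector of `"tag.name"` labels.
#' @export
concept_labels <- function(problem) {
  unlist(lapply(problem$taxonomies, function(t)
    concept_label(t$tag, preorder_concepts(t))), use.names = FALSE)
}

#' All cross-taxonomy concept pairs, in canonical order
#'
#' One row per unordered pair of concepts drawn from two different
#' taxonomies; the left concept always comes from the earlier taxonomy.
#' The number of rows is the MIR row-count identity
#' \eqn{\sum_{i<j} |T_i|\,|T_j|}.
#'
#' @param problem an [alignment_problem()].
#' @return `data.frame` with columns `left`, `right`.
#' @export
cross_pairs <- function(problem) {
  taxa <- problem$taxonomies
  nt <- length(taxa)
  lab <- lapply(taxa, function(t) concept_label(t$tag, preorder_concepts(t)))
  left <- character(0); right <- character(0)
  for (i in seq_len(nt - 1L)) for (j in seq.int(i + 1L, nt)) {
    grid <- expand.grid(b = lab[[j]], a = lab[[i]],
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # expand.grid varies the first factor fastest; reorder so the left
    # concept is the slow index (a in preorder, then b in preorder)
    left <- c(left, grid$a)
    right <- c(right, grid$b)
  }
  data.frame(left = left, right = right, stringsAsFactors = FALSE)
}

#' Check the structural invariants of an alignment problem
#'
#' Violations are returned as data rather than raised, so a caller can
#' report all of them at once: taxonomy count within 2-5, unique tags,
#' acyclic parent maps, articulations referencing declared concepts of
#' two different taxonomies with valid relation sets.
#'
#' @param problem an `alignment_problem` (or a bare list shaped like one).
#' @return Character vector of violation descriptions; empty if valid.
#' @export
validate_problem <- function(problem) {
  v <- character(0)
  taxa <- problem$taxonomies
  nt <- length(taxa)
  if (nt < 2L || nt > 5L)
    v <- c(v, sprintf("taxonomy count %d outside the supported range 2-5", nt))
  tags <- vapply(taxa, `[[`, "", "tag")
  if (anyDuplicated(tags))
    v <- c(v, paste0("duplicate taxonomy tag(s): ",
                     paste(unique(tags[duplicated(tags)]), collapse = ", ")))
  all_labels <- character(0)
  for (t in taxa) {
    if (any(!nzchar(t$concepts)))
      v <- c(v, paste0("taxonomy '", t$tag, "' has an empty concept name"))
    if (anyDuplicated(t$concepts))
      v <- c(v, paste0("taxonomy '", t$tag, "' declares duplicate concept(s): ",
                       paste(unique(t$concepts[duplicated(t$concepts)]), collapse = ", ")))
    # acyclicity: walking parents must terminate
    for (cpt in t$concepts) {
      seen <- character(0); cur <- cpt
      repeat {
        p <- t$parent[[cur]]
        if (is.na(p)) break
        if (p %in% c(seen, cpt)) {
          v <- c(v, paste0("taxonomy '", t$tag, "': concept '", cpt,
                           "' is its own ancestor"))
          break
        }
        seen <- c(seen, cur); cur <- p
      }
    }
    all_labels <- c(all_labels, concept_label(t$tag, t$concepts))
  }
  art <- problem$articulations
  for (i in seq_len(nrow(art))) {
    lt <- tryCatch(split_label(art$left[i]), error = function(e) NULL)
    rt <- tryCatch(split_label(art$right[i]), error = function(e) NULL)
    if (is.null(lt) || is.null(rt)) {
      v <- c(v, sprintf("articulation %d: malformed concept label", i))
      next
    }
    if (!(art$left[i] %in% all_labels))
      v <- c(v, sprintf("articulation %d references undeclared concept '%s'",
                        i, art$left[i]))
    if (!(art$right[i] %in% all_labels))
      v <- c(v, sprintf("articulation %d references undeclared concept '%s'",
                        i, art$right[i]))
    if (lt[["tag"]] == rt[["tag"]])
      v <- c(v, sprintf(
        "articulation %d relates two concepts of the same taxonomy '%s'",
        i, lt[["tag"]]))
    ok <- tryCatch({parse_relset(art$relation[i]); TRUE},
                   error = function(e) FALSE)
    if (!ok)
      v <- c(v, sprintf("articulation %d has invalid relation '%s'",
                        i, art$relation[i]))
  }
  v
}
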