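#' Build the merged congruence graph from a MIR table
#'
#' Concepts whose pairwise MIR is the singleton `==` collapse into one
#' congruence class (connected components of the congruence relation);
#' classes are ordered by proper inclusion inferred from singleton `>` /
#' `<` rows together with within-taxonomy parenthood, transitively
#' reduced; singleton `><` rows contribute undirected overlap edges.
#' Rows whose relation set is ambiguous (more than one relation)
#' contribute no edge.
#'
#' @param table a `"mir_table"` from [compute_mir()] (must come from a
#'   consistent problem).
#' @param problem the alignment problem; defaults to the one attached
#'   to the table.
#' @return An object of class `"merged_graph"`: a list with `classes`
#'   (list of character vectors of concept labels), `inclusion`
#'   (`data.frame` of class indices `from`, `to`, meaning from properly
#'   includes to, transitively reduced) and `overlap` (`data.frame` of
#'   class indices `a`, `b`).
#' @export
#' @examples
#' g <- merged_graph(compute_mir(scelianoma_problem()))
#' length(g$classes) # 3
merged_graph <- function(table, problem = attr(table, "problem")) {
  stopifnot(inherits(table, "mir_table"))
  if (!isTRUE(attr(table, "consistent")))
    stop("cannot merge an inconsistent alignment (empty relation sets)")
  labels <- concept_labels(problem)
  singles <- lengths(table$relset) == 1L
  sym <- ifelse(singles, vapply(table$relset, `[[`, "", 1L), NA_character_)

  # congruence classes: components of the == relation
  eq <- which(singles & sym == "==")
  g_eq <- igraph::graph_from_data_frame(
    data.frame(from = table$left[eq], to = table$right[eq]),
    directed = FALSE, vertices = labels)
  comp <- igraph::components(g_eq)$membership[labels]
  class_ids <- unique(unname(comp)) # first-appearance order over canonical labels
  class_of <- match(comp, class_ids)
  names(class_of) <- labels
  classes <- lapply(seq_along(class_ids), function(k) labels[class_of == k])

  # proper-inclusion candidates at class level
  from <- integer(0); to <- integer(0)
  gt <- which(singles & sym == ">")
  from <- c(from, class_of[table$left[gt]]); to <- c(to, class_of[table$right[gt]])
  lt <- which(singles & sym == "<")
  from <- c(from, class_of[table$right[lt]]); to <- c(to, class_of[table$left[lt]])
  for (tax in problem$taxonomies) {
    for (p in names(tax$children)) {
      pk <- class_of[[concept_label(tax$tag, p)]]
      for (k in tax$children[[p]]) {
        ck <- class_of[[concept_label(tax$tag, k)]]
        if (ck != pk) { from <- c(from, pk); to <- c(to, ck) }
      }
    }
  }
  keep <- !duplicated(paste(from, to))
  from <- from[keep]; to <- to[keep]
  if (any(from == to))
    stop("internal error: self-inclusion at class level")
  inc <- transitive_reduce(length(classes), from, to)

  ov <- which(singles & sym == "><")
  a <- pmin(class_of[table$left[ov]], class_of[table$right[ov]])
  b <- pmax(class_of[table$left[ov]], class_of[table$right[ov]])
  keep <- a != b & !duplicated(paste(a, b))
  overlap <- data.frame(a = unname(a[keep]), b = unname(b[keep]))

  structure(list(classes = classes, class_of = class_of,
                 inclusion = inc, overlap = overlap),
            class = "merged_graph")
}

# transitive reduction of an acyclic relation given as edge lists
transitive_reduce <- function(n, from, to) {
  if (length(from) == 0L)
    return(data.frame(from = integer(0), to = integer(0)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = TRUE,
    vertices = data.frame(name = as.character(seq_len(n))))
  if (!igraph::is_dag(g))
    stop("internal error: cycle in the class-level inclusion order")
  d <- igraph::distances(g, mode = "out")
  keep <- logical(length(from))
  for (i in seq_along(from)) {
    f <- as.character(from[i]); t <- as.character(to[i])
    # redundant iff some other out-neighbour of f reaches t
    # redundant iff some other out-neighbour w of f reaches t
    nb <- setdiff(names(which(d[f, ] == 1)), t)
    keep[i] <- !any(vapply(nb, function(w) is.finite(d[w, t]), TRUE))
  }
  data.frame(from = from[keep], to = to[keep])
}

#' @export
print.merged_graph <- function(x, ...) {
  multi <- sum(lengths(x$classes) > 1L)
  cat("Merged graph: ", length(x$classes), " congruence classes (",
      multi, " with >1 member), ", nrow(x$inclusion),
      " inclusion edge(s), ", nrow(x$overlap), " overlap edge(s)\n", sep = "")
  invisible(x)
}

#' Count congruence classes carrying a given taxon name
#'
#' The number of taxonomically distinct regions labelled with one name
#' across treatments: congruence classes of the merged graph containing
#' at least one concept whose name part equals `name` (the treatment
#' tag is ignored).
#'
#' @param graph a [merged_graph()].
#' @param name taxon name string.
#' @return Integer count.
#' @export
#' @examples
#' g <- merged_graph(compute_mir(scelianoma_problem()))
#' count_label_regions(g, "Scelianoma") # 2
count_label_regions <- function(graph, name) {
  stopifnot(inherits(graph, "merged_graph"))
  sum(vapply(graph$classes, function(cl)
    any(unname(label_name(cl)) == name), TRUE))
}
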