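#' Build the finite place space of an alignment problem
#'
#' The joint partition of all taxonomies is encoded by *places*: one
#' place per combination of, for each taxonomy, either a membership set
#' of its concepts or an "outside" marker. A possible world is a
#' nonempty set of occupied places; the region a concept denotes is the
#' union of the occupied places lying under it.
#'
#' With sibling disjointness assumed (the default), the valid
#' membership sets of one taxonomy are exactly the root-to-node chains
#' ending at a childless concept or, for a parent whose coverage
#' constraint is relaxed, at the parent's unsampled residue (a "gap"
#' slot). Sibling disjointness, parent-includes-child and coverage
#' (where it applies) then hold by construction for every world.
#'
#' @param problem an [alignment_problem()].
#' @param cap maximum admissible number of places; larger spaces abort
#'   with an error (default `1e6`).
#' @param sibling_disjoint logical; assume children of one parent denote
#'   pairwise disjoint regions (default `TRUE`). When `FALSE`, every
#'   membership set consistent with parenthood and coverage is a slot,
#'   enumerated over subsets of each taxonomy's concepts.
#' @return An object of class `"place_space"`: a list with the number
#'   of places `n`, per-taxonomy slot descriptors, and for every
#'   concept label the integer set of places under it.
#' @export
#' @examples
#' p <- scelianoma_problem()
#' build_places(p)$n # 12
build_places <- function(problem, cap = 1e6, sibling_disjoint = TRUE) {
  taxa <- problem$taxonomies
  slot_sets <- vector("list", length(taxa)) # per taxonomy: list of concept-name sets
  slot_ids <- vector("list", length(taxa))
  for (ti in seq_along(taxa)) {
    tax <- taxa[[ti]]
    if (sibling_disjoint) {
      sets <- list(); ids <- character(0)
      for (cpt in preorder_concepts(tax)) {
        anc <- ancestors_self(tax, cpt)
        if (is.null(tax$children[[cpt]])) {            # childless concept
          sets <- c(sets, list(anc)); ids <- c(ids, cpt)
        } else if (!isTRUE(tax$covered[[cpt]])) {      # non-covered parent residue
          sets <- c(sets, list(anc)); ids <- c(ids, paste0("gap:", cpt))
        }
      }
      sets <- c(sets, list(character(0))); ids <- c(ids, "outside")
    } else {
      if (length(tax$concepts) > 14L)
        stop("taxonomy '", tax$tag, "' too large for membership-set ",
             "enumeration without sibling disjointness")
      sets <- enumerate_membership_sets(tax)
      ids <- vapply(sets, function(s)
        if (length(s) == 0L) "outside" else paste(s, collapse = "+"), "")
    }
    slot_sets[[ti]] <- sets
    slot_ids[[ti]] <- ids
  }
  n_slots <- vapply(slot_sets, length, 1L)
  n <- prod(as.double(n_slots))
  if (n > cap)
    stop("place count ", format(n, big.mark = ","), " exceeds cap ",
         format(cap, big.mark = ","),
         "; reduce the problem or raise `cap`")
  n <- as.integer(n)
  # grid[k, ti] = index of the slot taxonomy ti takes in place k
  grid <- as.matrix(expand.grid(lapply(n_slots, seq_len),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- vapply(taxa, `[[`, "", "tag")
  under <- list()
  for (ti in seq_along(taxa)) {
    tax <- taxa[[ti]]
    for (cpt in tax$concepts) {
      in_slot <- vapply(slot_sets[[ti]], function(s) cpt %in% s, TRUE)
      under[[concept_label(tax$tag, cpt)]] <- which(in_slot[grid[, ti]])
    }
  }
  structure(list(n = n, slot_ids = slot_ids, slot_sets = slot_sets,
                 grid = grid, under = under, problem = problem,
                 sibling_disjoint = sibling_disjoint),
            class = "place_space")
}

#' @export
print.place_space <- function(x, ...) {
  cat("Place space: ", x$n, " places (",
      paste(vapply(x$slot_ids, length, 1L), collapse = " x "), " slots), ",
      length(x$under), " concepts\n", sep = "")
  invisible(x)
}

ancestors_self <- function(tax, name) {
  out <- name
  repeat {
    p <- tax$parent[[out[length(out)]]]
    if (is.na(p)) break
    out <- c(out, p)
  }
  out
}

# All membership sets of one taxonomy's concepts valid without the
# sibling-disjointness assumption: upward closed under parenthood, and a
# covered parent in the set must have at least one child in the set.
enumerate_membership_sets <- function(tax) {
  cpts <- preorder_concepts(tax)
  n <- length(cpts)
  sets <- list(character(0))
  for (mask in seq_len(2^n - 1L)) {
    mem <- cpts[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
    ok <- TRUE
    for (cpt in mem) {
      p <- tax$parent[[cpt]]
      if (!is.na(p) && !(p %in% mem)) { ok <- FALSE; break }
      kids <- tax$children[[cpt]]
      if (!is.null(kids) && isTRUE(tax$covered[[cpt]]) &&
          !any(kids %in% mem)) { ok <- FALSE; break }
    }
    if (ok) sets <- c(sets, list(mem))
  }
  sets
}

# Zones of a concept pair within a place space: places under a only,
# under both, under b only.
pair_zones <- function(ps, a, b) {
  ua <- ps$under[[a]]; ub <- ps$under[[b]]
  if (is.null(ua)) stop("unknown concept '", a, "'")
  if (is.null(ub)) stop("unknown concept '", b, "'")
  list(za = setdiff(ua, ub), zab = intersect(ua, ub), zb = setdiff(ub, ua))
}
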